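# Synthetic-data generators: determinism and construction guarantees.

test_that("proteome generation is seed-deterministic and plants valid motifs", {
  tr1 <- generate_proteome(60, seed = 91)
  tr2 <- generate_proteome(60, seed = 91)
  expect_identical(tr1, tr2)
  tr3 <- generate_proteome(60, seed = 92)
  expect_false(identical(tr1$proteins$sequence, tr3$proteins$sequence))
  # every implanted core matches its class consensus at its position
  for (i in seq_len(nrow(tr1$motifs))) {
    m <- tr1$motifs[i, ]
    s <- tr1$proteins$sequence[tr1$proteins$protein_id == m$protein_id]
    expect_equal(substr(s, m$start, m$start + nchar(m$core_seq) - 1L),
                 m$core_seq)
    re <- if (m$class_id == 1L) "^[RK]..P..P$" else "^P..P.[RK]$"
    expect_true(grepl(re, m$core_seq))
    # implants sit inside the disordered stretch
    mask <- tr1$disorder[[m$protein_id]]
    expect_true(all(mask[m$start:(m$start + nchar(m$core_seq) - 1L)]))
  }
  # binder protein Kd never exceeds its best motif Kd (avidity >= 1)
  bind <- tr1$motifs[!is.na(tr1$motifs$kd), ]
  if (nrow(bind)) {
    best <- tapply(bind$kd, bind$protein_id, min)
    pkd <- tr1$proteins$kd[match(names(best), tr1$proteins$protein_id)]
    expect_true(all(pkd <= best + 1e-18))
  }
})

test_that("implant_rate 1 guarantees a scannable PRM in every protein", {
  tr <- generate_proteome(50, implant_rate = 1, binder_rate = 0.5, seed = 93)
  for (i in 1:50) {
    hits <- scan_prms(tr$proteins$sequence[i], tr$disorder[[i]],
                      tr$proteins$protein_id[i])
    expect_gte(nrow(hits), 1L)
  }
})

test_that("zero-noise nHU tables reproduce the planted depletion exactly", {
  tr <- generate_proteome(120, implant_rate = 0.4, binder_rate = 0.2,
                          seed = 94)
  tab <- simulate_nhu_ms(tr, cv = 0, dropout_scale = 0, seed = 95)
  expect_false(anyNA(tab$values))
  res <- nhu_depletion(tab, seed = 96, normalize = FALSE, impute = FALSE)
  p <- tr$proteins
  binders <- !is.na(p$kd)
  bi_true <- kd_to_bi(p$kd[binders], 10e-6)
  got <- res$bi[match(p$protein_id[binders], res$protein_id)]
  expect_equal(got, bi_true, tolerance = 1e-12)
  # non-binders: exactly zero depletion
  nb <- res$bi[match(p$protein_id[!binders], res$protein_id)]
  expect_equal(nb, rep(0, sum(!binders)), tolerance = 1e-12)
})

test_that("non-binder log2 fold changes center at zero under noise", {
  tr <- generate_proteome(600, binder_rate = 0, seed = 97)
  tab <- simulate_nhu_ms(tr, seed = 98)
  res <- nhu_depletion(tab, seed = 99)
  expect_lt(abs(median(res$log2fc)), 0.05)
})

test_that("zero-noise plate readouts give exact BI and stable censoring", {
  panel <- data.frame(peptide_id = c("s", "w", "n"),
                      kd = c(2e-6, 50e-6, NA))
  ro <- simulate_fragment_holdup(panel, noise_cv = 0, loading_sd = 0,
                                 seed = 100)
  b <- plate_to_bi(ro$trp_sample, ro$trp_control, ro$std1_sample,
                   ro$std1_control, ro$std2_sample, ro$std2_control)
  expect_equal(b$bi, c(kd_to_bi(2e-6, 4e-6), kd_to_bi(50e-6, 4e-6), 0),
               tolerance = 1e-12)
  # truth below the detection threshold stays censored after conversion
  weak <- data.frame(peptide_id = "x", kd = 5e-3)
  row <- simulate_fragment_holdup(weak, noise_cv = 0, loading_sd = 0,
                                  seed = 101)
  prof <- build_profile(row, bi_threshold = 0.02)
  expect_true(prof$censored)
  # loading drift is removed by the internal-standard correction
  ro2 <- simulate_fragment_holdup(panel, noise_cv = 0, loading_sd = 0.2,
                                  seed = 102)
  b2 <- plate_to_bi(ro2$trp_sample, ro2$trp_control, ro2$std1_sample,
                    ro2$std1_control, ro2$std2_sample, ro2$std2_control)
  expect_equal(b2$bi, b$bi, tolerance = 1e-9)
})

test_that("titration, ortholog and variant generators honor their seeds", {
  concs <- 10^seq(-8, -4, length.out = 8)
  expect_identical(simulate_titration(1e-6, 0.7, concs, seed = 103),
                   simulate_titration(1e-6, 0.7, concs, seed = 103))
  hw <- paste(rep("A", 15), collapse = "")
  expect_identical(simulate_orthologs(hw, "Eumetazoa", seed = 104),
                   simulate_orthologs(hw, "Eumetazoa", seed = 104))
  panel <- data.frame(peptide_id = paste0("p", 1:30),
                      kd = 10^runif(30, -6, -4))
  wt <- profile_from_kds(panel)
  expect_identical(simulate_variant_profile(wt, "PAP", seed = 105),
                   simulate_variant_profile(wt, "PAP", seed = 105))
})
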