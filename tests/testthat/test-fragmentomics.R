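# Plate readout conversion, affinity profiles, FL-vs-motif statistics,
# specificity logos.

test_that("internal-standard correction recovers the true depletion", {
  # no depletion, no drift
  expect_equal(plate_to_bi(100, 100, 50, 50, 80, 80)$bi, 0)
  # trp halved, standards unchanged
  expect_equal(plate_to_bi(50, 100, 50, 50, 80, 80)$bi, 0.5)
  # standards drifted x1.1 and trp x0.55: corrected bi = 0.5 by arithmetic
  expect_equal(plate_to_bi(55, 100, 55, 50, 88, 80)$bi, 0.5)
  # apparent enrichment clamps to 0 with a flag
  r <- plate_to_bi(120, 100, 50, 50, 80, 80)
  expect_equal(r$bi, 0)
  expect_true(r$clamped)
  expect_error(plate_to_bi(0, 100, 50, 50, 80, 80), "positive")
})

test_that("profiles censor at the threshold and respect panel order", {
  ro <- data.frame(peptide_id = c("a", "b", "c"),
                   trp_sample = c(99, 50, 100), trp_control = rep(100, 3),
                   std1_sample = 50, std1_control = 50,
                   std2_sample = 80, std2_control = 80)
  prof <- build_profile(ro, bait_conc = 4e-6, bi_threshold = 0.02,
                        bait_id = "WT", panel = c("c", "b", "a", "d"))
  expect_s3_class(prof, "affinity_profile")
  expect_equal(prof$peptide_id, c("c", "b", "a", "d"))
  expect_equal(prof$censored, c(TRUE, FALSE, TRUE, TRUE))
  expect_false(prof$measured[prof$peptide_id == "d"])
  # half-saturation at 4 uM bait
  expect_equal(prof$pk[prof$peptide_id == "b"], kd_to_pk(4e-6))
  expect_error(build_profile(rbind(ro, ro)), "duplicate")
})

test_that("simulated plates recover pk within propagated-noise bounds", {
  # Error propagation through bi = 1 - ratio gives an approximate pk
  # standard deviation of 0.434 * sigma_ratio / bi; at 2% per-channel noise
  # (six channels, sigma_ratio ~ 3.5%) a +-0.15 pk bound is a ~3-sigma
  # envelope only where bi >= ~0.3, i.e. Kd <= ~8 uM at 4 uM bait. Weaker
  # binders carry proportionally larger pk uncertainty by arithmetic, so
  # the full-panel check is on the median error.
  set.seed(51)
  kds <- 10^runif(120, log10(0.5e-6), log10(100e-6))
  panel <- data.frame(peptide_id = sprintf("pep%03d", 1:120), kd = kds)
  ro <- simulate_fragment_holdup(panel, bait_conc = 4e-6, noise_cv = 0.02,
                                 seed = 52)
  prof <- build_profile(ro, bait_conc = 4e-6, bi_threshold = 0.02)
  err <- abs(prof$pk - (-log10(kds)))
  strong <- kds <= 8e-6
  expect_true(all(err[strong & !prof$censored] <= 0.15))
  expect_lt(median(err[!prof$censored]), 0.15)
})

test_that("FL vs best-motif statistics match a hand-rolled oracle", {
  prof <- affinity_profile(paste0("m", 1:6),
                           c(5.0, 4.5, 6.0, 3.7, 5.5, 3.7),
                           c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
                           detection_pk = 3.7)
  mapping <- data.frame(peptide_id = paste0("m", 1:6),
                        protein_id = c("A", "A", "B", "B", "C", "D"))
  fl <- data.frame(protein_id = c("A", "B", "C", "D", "E"),
                   pk = c(5.8, 6.0, 5.2, 5.0, 6.6))
  r <- compare_fl_vs_motifs(fl, prof, mapping)
  # best motifs: A -> 5.0, B -> 6.0, C -> 5.5; D all censored, E unmapped
  expect_equal(r$n, 3L)
  expect_equal(r$n_all_censored, 1L)
  delta <- c(5.8 - 5.0, 6.0 - 6.0, 5.2 - 5.5)
  expect_equal(sort(r$per_protein$delta), sort(delta))
  expect_equal(r$delta_mean, mean(delta))
  expect_equal(r$delta_median, median(delta))
  # ties and negatives excluded: only strictly stronger FL counts
  expect_equal(r$fraction_fl_stronger, 1 / 3)
  expect_equal(r$pcc, cor(c(5.8, 6.0, 5.2), c(5.0, 6.0, 5.5)))
  # identical FL and best-motif affinities
  fl2 <- data.frame(protein_id = c("A", "B", "C"), pk = c(5.0, 6.0, 5.5))
  r2 <- compare_fl_vs_motifs(fl2, prof, mapping)
  expect_equal(r2$pcc, 1)
  expect_equal(r2$delta_mean, 0)
  expect_equal(r2$fraction_fl_stronger, 0)
  # insufficient overlap flagged
  r3 <- compare_fl_vs_motifs(fl[1:2, ], prof, mapping)
  expect_true(r3$undefined)
})

test_that("specificity logo weights by pk margin and normalizes positions", {
  dpk <- 3.7
  prof1 <- affinity_profile("a", 5.7, FALSE, dpk)
  logo1 <- specificity_logo(prof1, c(a = "PAK"))
  expect_equal(logo1[1, "P"], 1)
  expect_equal(logo1[2, "A"], 1)
  expect_equal(logo1[3, "K"], 1)
  # two binders with equal margins differing at one position split 0.5/0.5
  prof2 <- affinity_profile(c("a", "b"), c(5.7, 5.7), c(FALSE, FALSE), dpk)
  logo2 <- specificity_logo(prof2, c(a = "PAK", b = "PGK"))
  expect_equal(logo2[2, "A"], 0.5)
  expect_equal(logo2[2, "G"], 0.5)
  # brute-force weighted counting oracle on a 10-peptide panel
  set.seed(61)
  cores <- replicate(10, random_aa_sequence(6))
  pk <- runif(10, dpk - 0.2, 6.5)
  cens <- pk <= dpk + 0.05
  pk[cens] <- dpk
  prof <- affinity_profile(paste0("p", 1:10), pk, cens, dpk)
  logo <- specificity_logo(prof, setNames(cores, paste0("p", 1:10)))
  w <- ifelse(cens, 0, pmax(0, pk - dpk))
  for (pos in 1:6) {
    for (aa in c("A", "K", "P")) {
      manual <- sum(w[substr(cores, pos, pos) == aa]) / sum(w)
      expect_equal(logo[pos, aa], manual)
    }
  }
  # rows sum to one; scaling margins leaves the logo unchanged
  expect_equal(rowSums(logo), rep(1, 6), ignore_attr = TRUE)
  prof_scaled <- affinity_profile(paste0("p", 1:10), dpk + 3 * (pk - dpk),
                                  cens, dpk)
  expect_equal(specificity_logo(prof_scaled,
                                setNames(cores, paste0("p", 1:10))), logo)
  # all censored: error
  profc <- affinity_profile("a", dpk, TRUE, dpk)
  expect_error(specificity_logo(profc, c(a = "PAK")), "undefined")
})
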