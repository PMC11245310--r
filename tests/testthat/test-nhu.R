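# Native-holdup MS depletion statistics.

test_that("median normalization equalizes sample medians and is idempotent", {
  v <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2)  # B = 2 x A elementwise
  tab <- toy_table(v, 1, 1)
  norm <- normalize_median(tab)
  meds <- apply(norm$values, 2, median, na.rm = TRUE)
  expect_equal(unname(meds[1]), unname(meds[2]))
  # manual 3x3 oracle: sample medians 2, 8, 30; grand median of the nine
  # values {1,2,4,6,8,10,20,30,40} is 8
  v3 <- matrix(c(1, 2, 4,
                 6, 8, 10,
                 20, 30, 40), ncol = 3)
  t3 <- toy_table(v3, 2, 1)
  n3 <- normalize_median(t3)
  expect_equal(n3$values[, 1], v3[, 1] * 8 / 2, ignore_attr = TRUE)
  expect_equal(n3$values[, 2], v3[, 2] * 8 / 8, ignore_attr = TRUE)
  expect_equal(n3$values[, 3], v3[, 3] * 8 / 30, ignore_attr = TRUE)
  # idempotence
  expect_equal(normalize_median(n3)$values, n3$values)
  # all-missing sample is a named error
  vbad <- matrix(c(1, 2, NA, NA), ncol = 2)
  expect_error(normalize_median(toy_table(vbad, 1, 1)), "c1")
})

test_that("imputation draws from the low decile, leaves detected cells, and is seed-deterministic", {
  set.seed(3)
  v <- matrix(rlnorm(300, 10, 1), ncol = 6)
  v[sample(length(v), 40)] <- NA
  tab <- toy_table(v, 3, 3)
  detected <- v[!is.na(v)]
  lowq <- quantile(detected, 0.10)
  imp1 <- impute_missing(tab, seed = 11)
  imp2 <- impute_missing(tab, seed = 11)
  imp3 <- impute_missing(tab, seed = 12)
  expect_identical(imp1$values, imp2$values)
  # detected cells bit-identical
  expect_identical(imp1$values[!is.na(v)], v[!is.na(v)])
  # imputed cells come from at or below the lowest-decile pool
  expect_true(all(imp1$values[is.na(v)] <= lowq))
  # different seed differs only at imputed cells
  expect_identical(imp3$values[!is.na(v)], v[!is.na(v)])
  # no-missing table is returned unchanged
  full <- toy_table(matrix(rlnorm(60, 10, 1), ncol = 6), 3, 3)
  expect_identical(impute_missing(full, seed = 1)$values, full$values)
})

test_that("depletion t-test matches the textbook equal-variance computation", {
  # identical groups: no depletion, p = 1
  r0 <- test_depletion(c(2, 4, 6), c(2, 4, 6))
  expect_equal(r0$log2fc, 0)
  expect_equal(r0$pvalue, 1)
  # bait exactly half of control: log2fc = -1; p from the hand-rolled
  # pooled-variance t statistic and the t CDF
  bait <- c(2, 4, 6); ctrl <- c(4, 8, 12)
  r <- test_depletion(bait, ctrl)
  expect_equal(r$log2fc, -1)
  lb <- log2(bait); lc <- log2(ctrl)
  sp2 <- (sum((lb - mean(lb))^2) + sum((lc - mean(lc))^2)) / 4
  tstat <- (mean(lb) - mean(lc)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$pvalue, 2 * pt(-abs(tstat), df = 4))
  # zero variance, different means: representable positive p
  rz <- test_depletion(c(2, 2, 2), c(8, 8, 8))
  expect_gt(rz$pvalue, 0)
  expect_lt(rz$pvalue, 1e-10)
  expect_error(test_depletion(2, c(1, 2)), ">= 2")
})

test_that("log2 fold change converts to BI through the depletion chain", {
  expect_equal(depletion_to_bi(0)$bi, 0)
  expect_equal(depletion_to_bi(-1)$bi, 0.5)
  expect_true(depletion_to_bi(0.5)$clamped)
  expect_equal(depletion_to_bi(0.5)$bi, 0)
  # chain oracle: lfc -> bi -> kd -> pk computed stepwise by hand
  lfc <- -2.1375
  bi <- 1 - 2^lfc
  expect_equal(bi, 0.7727, tolerance = 1e-4)
  pk <- -log10(10e-6 * (1 - bi) / bi)
  expect_equal(pk, 5.53, tolerance = 1e-2)
  got <- censor_affinity(depletion_to_bi(lfc)$bi, 0.128, 10e-6)
  expect_equal(got$pk, pk)
  expect_false(got$censored)
})

test_that("significance gate is conjunctive in p-value and BI", {
  res <- data.frame(protein_id = c("a", "b", "c", "d"),
                    pvalue = c(0.5, 1e-4, 1e-4, 0.04),
                    bi = c(0.9, 0.5, 0.05, 0.128))
  out <- call_significant(res)
  expect_equal(out$significant, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(attr(out, "p_cap"), 0.05)
  expect_equal(attr(out, "bi_threshold"), 0.128)
  empty <- call_significant(res[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("cross-experiment recall and correlation behave on constructed sets", {
  mk <- function(ids, pvals, bis, pks) {
    call_significant(data.frame(protein_id = ids, pvalue = pvals, bi = bis,
                                pk = pks, stringsAsFactors = FALSE))
  }
  pk <- c(6.2, 5.8, 5.4, 5.0, 4.6)
  a <- mk(paste0("P", 1:5), rep(1e-4, 5), rep(0.5, 5), pk)
  # identical experiments: perfect recall and correlation
  self <- compare_experiments(a, a)
  expect_equal(self$recall_ab, 1)
  expect_equal(self$recall_ba, 1)
  expect_equal(self$pcc, 1)
  # disjoint significant sets, nothing depleted: recall 0
  b0 <- mk(paste0("P", 1:5), rep(0.9, 5), rep(0.01, 5), pk)
  expect_equal(compare_experiments(a, b0)$recall_ab, 0)
  # sub-significant but depleted counts as recovered under the default,
  # not under the strict option
  b1 <- mk(paste0("P", 1:5), c(1e-4, 1e-4, 1e-4, 0.9, 0.9),
           c(0.5, 0.5, 0.5, 0.3, 0.05), pk + 0.1)
  cmp <- compare_experiments(a, b1)
  expect_equal(cmp$recall_ab, 4 / 5)   # P4 depleted above threshold, P5 not
  strict <- compare_experiments(a, b1, recovered = "significant")
  expect_equal(strict$recall_ab, 3 / 5)
  # affine pk relation: pcc 1, slope 1, and a defined 95% band
  expect_equal(cmp$pcc, 1)
  expect_equal(cmp$fit_slope, 1, tolerance = 1e-8)
  expect_equal(cmp$fit_intercept, 0.1, tolerance = 1e-8)
  expect_true(all(cmp$ci95_band$lwr <= cmp$ci95_band$fit))
  # correlation p-value matches the t = r sqrt((n-2)/(1-r^2)) formula on a
  # noisy pair
  set.seed(21)
  pkb <- pk + rnorm(5, 0, 0.2)
  b2 <- mk(paste0("P", 1:5), rep(1e-4, 5), rep(0.5, 5), pkb)
  cmp2 <- compare_experiments(a, b2)
  r <- cor(pk, pkb)
  tt <- r * sqrt(3 / (1 - r^2))
  expect_equal(cmp2$correlation_pvalue, 2 * pt(abs(tt), 3, lower.tail = FALSE))
  # < 3 shared significant: flagged undefined
  b3 <- mk(paste0("P", 1:5), c(1e-4, 1e-4, 0.9, 0.9, 0.9),
           c(0.5, 0.5, 0.01, 0.01, 0.01), pk)
  expect_true(compare_experiments(a, b3)$undefined)
})

test_that("interactome similarity matrix is symmetric with unit diagonal", {
  mk <- function(ids, pks) {
    call_significant(data.frame(protein_id = ids, pvalue = 1e-4,
                                bi = 0.5, pk = pks))
  }
  p <- list(A = mk(paste0("P", 1:6), c(5, 6, 7, 5.5, 6.5, 4.8)),
            B = mk(paste0("P", 1:6), c(5.1, 6.1, 7.1, 5.6, 6.6, 4.9)),
            C = mk(paste0("P", c(1, 2, 9)), c(7, 5, 6)))
  sim <- interactome_similarity(p)
  expect_equal(diag(sim$pcc), c(A = 1, B = 1, C = 1))
  expect_equal(sim$pcc["A", "B"], 1)          # affine relation
  expect_equal(sim$pcc, t(sim$pcc))
  expect_true(is.na(sim$pcc["A", "C"]))       # only 2 shared partners
  expect_equal(sim$n["A", "C"], 2)
})

test_that("planted binders are recovered through the full nHU pipeline", {
  tr <- generate_proteome(800, seed = 501)
  tab <- simulate_nhu_ms(tr, seed = 502)
  res <- nhu_depletion(tab, seed = 503)
  p <- tr$proteins
  sel <- !is.na(p$kd) & p$kd >= 0.5e-6 & p$kd <= 34e-6 &
    p$abundance > median(p$abundance)
  est <- res$pk[match(p$protein_id[sel], res$protein_id)]
  truth <- -log10(p$kd[sel])
  expect_gte(mean(abs(est - truth) <= 0.3), 0.8)
  expect_gte(cor(truth, est, method = "spearman"), 0.9)
})

test_that("false-positive rate without planted binders reflects the gate's design precision", {
  # At the default analytical noise (CV 15%) the BI gate barely tightens the
  # 2.5% one-sided t-test level; at injection-replicate precision (CV 5%)
  # the conjunctive gate keeps false calls below 1%.
  fp_default <- sapply(1:8, function(i) {
    tr <- generate_proteome(400, binder_rate = 0, seed = 1000 + i)
    res <- nhu_depletion(simulate_nhu_ms(tr, seed = 2000 + i), seed = 3000 + i)
    mean(res$significant)
  })
  expect_lt(mean(fp_default), 0.025)
  fp_tight <- sapply(1:8, function(i) {
    tr <- generate_proteome(400, binder_rate = 0, seed = 1000 + i)
    res <- nhu_depletion(simulate_nhu_ms(tr, cv = 0.05, seed = 2000 + i),
                         seed = 3000 + i)
    mean(res$significant)
  })
  expect_lte(mean(fp_tight), 0.01)
})
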