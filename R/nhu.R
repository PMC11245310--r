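# Native-holdup MS stage: normalization, low-intensity imputation,
# per-protein depletion statistics, conversion to apparent affinities, and
# cross-experiment comparison. The prey is a dilute total cell extract; the
# readout is a protein-level label-free XIC intensity table with bait-arm
# and control-arm samples.

#' Construct an intensity table
#'
#' Container for a proteins x samples matrix of label-free XIC-style
#' intensities with missing values (`NA`), plus the sample sheet annotating
#' each column with its role (bait or control resin) and replicate index.
#'
#' @param values Numeric matrix, rows = proteins (rownames are unique
#'   protein ids), columns = samples; missing measurements are `NA`, present
#'   values must be `>= 0`.
#' @param samples data.frame with columns `sample_id`, `role` (`"bait"` or
#'   `"control"`) and `replicate`; one row per column of `values`, matched
#'   by `sample_id` to `colnames(values)`.
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique protein-id rownames")
  if (!all(c("sample_id", "role", "replicate") %in% names(samples)))
    stop("sample sheet needs columns sample_id, role, replicate")
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stop("colnames(values) must match samples$sample_id in order")
  if (!all(samples$role %in% c("bait", "control")))
    stop("sample roles must be 'bait' or 'control'")
  if (!any(samples$role == "bait") || !any(samples$role == "control"))
    stop("need at least one bait and one control sample")
  if (any(values < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  structure(list(values = values, samples = samples), class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d proteins x %d samples (%d bait, %d control), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              sum(x$samples$role == "bait"), sum(x$samples$role == "control"),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Median-normalize an intensity table
#'
#' Rescales every sample by a single factor so that its median detected
#' intensity equals the grand median of all detected values in the table,
#' correcting minor loading differences between injections. Missing entries
#' are untouched. The operation is idempotent.
#'
#' @param table An [intensity_table()].
#' @return The normalized `intensity_table`.
#' @export
normalize_median <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  v <- table$values
  n_det <- colSums(!is.na(v))
  if (any(n_det == 0))
    stop("sample(s) with no detected values: ",
         paste(colnames(v)[n_det == 0], collapse = ", "))
  grand <- stats::median(v, na.rm = TRUE)
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  table$values <- sweep(v, 2, grand / med, `*`)
  table
}

#' Impute missing intensities from the low tail of the detected values
#'
#' Every missing entry is replaced by a value drawn uniformly at random from
#' the pool of detected intensities at or below the `low_fraction` quantile
#' of the entire dataset, emulating the assumption that undetected proteins
#' sit near the instrument's sensitivity floor. Detected cells are left
#' bit-identical. Calls `set.seed(seed)`, so the result is deterministic.
#'
#' @param table An [intensity_table()].
#' @param low_fraction Quantile defining the low-intensity pool
#'   (default 0.10, i.e. the lowest decile of the whole dataset).
#' @param seed Integer RNG seed.
#' @return The imputed `intensity_table` with no missing values.
#' @export
impute_missing <- function(table, low_fraction = 0.10, seed = 1L) {
  stopifnot(inherits(table, "intensity_table"))
  v <- table$values
  detected <- v[!is.na(v)]
  if (length(detected) < 10L) stop("need at least 10 detected values to impute")
  pool <- detected[detected <= stats::quantile(detected, low_fraction)]
  miss <- is.na(v)
  if (any(miss)) {
    set.seed(seed)
    v[miss] <- sample(pool, sum(miss), replace = TRUE)
  }
  table$values <- v
  table
}

#' Per-protein depletion test
#'
#' Unpaired two-tailed equal-variance t-test on log2 intensities of the bait
#' arm versus the control arm, the standard depletion statistic for holdup
#' proteomics. Negative `log2fc` means the protein was depleted by the bait.
#'
#' @param bait_values,control_values Linear-scale intensities (length >= 2
#'   each, all positive).
#' @return List with `log2fc` (mean log2 bait minus mean log2 control) and
#'   `pvalue`.
#' @export
test_depletion <- function(bait_values, control_values) {
  if (length(bait_values) < 2L || length(control_values) < 2L)
    stop("need >= 2 values per group")
  if (any(c(bait_values, control_values) <= 0))
    stop("intensities must be positive for log2 transform")
  lb <- log2(bait_values); lc <- log2(control_values)
  log2fc <- mean(lb) - mean(lc)
  pooled_var <- (sum((lb - mean(lb))^2) + sum((lc - mean(lc))^2)) /
    (length(lb) + length(lc) - 2)
  if (pooled_var == 0) {
    # degenerate: identical replicates; equal means are maximally
    # non-significant, unequal means underflow but stay representable
    pvalue <- if (log2fc == 0) 1 else .Machine$double.xmin
  } else {
    pvalue <- stats::t.test(lb, lc, var.equal = TRUE)$p.value
  }
  list(log2fc = log2fc, pvalue = pvalue)
}

#' Convert a log2 depletion fold change to a binding intensity
#'
#' The fraction of prey depleted is `1 - 2^log2fc`; positive fold changes
#' (apparent enrichment, i.e. noise) clamp to BI 0 and are flagged.
#'
#' @param log2fc Log2 fold change(s), bait vs control.
#' @return data.frame with columns `bi` and `clamped`.
#' @export
depletion_to_bi <- function(log2fc) {
  stopifnot(is.numeric(log2fc), all(is.finite(log2fc)))
  clamp_bi(1 - 2^log2fc)
}

#' Run the full depletion analysis on an intensity table
#'
#' Median normalization, low-decile imputation, per-protein equal-variance
#' t-tests on log2 intensities, conversion of the depletion fold change to
#' BI and then to a censored apparent affinity at the stated bait
#' concentration, and significance calling.
#'
#' @param table An [intensity_table()].
#' @param bait_conc Estimated immobilized bait concentration, molar
#'   (default 10 uM, the single-point native-holdup condition).
#' @param p_cap Significance cap on the raw t-test p-value (default 0.05).
#' @param bi_threshold BI detection/significance threshold (default 0.128).
#' @param low_fraction Imputation pool quantile, see [impute_missing()].
#' @param seed RNG seed for imputation.
#' @param normalize,impute Logical switches for the preprocessing steps.
#' @return A data.frame of class `depletion_results` with one row per
#'   protein: `protein_id`, `log2fc`, `pvalue`, `bi`, `pk`, `censored`,
#'   `significant`; thresholds recorded as attributes.
#' @export
nhu_depletion <- function(table, bait_conc = 10e-6, p_cap = 0.05,
                          bi_threshold = 0.128, low_fraction = 0.10,
                          seed = 1L, normalize = TRUE, impute = TRUE) {
  stopifnot(inherits(table, "intensity_table"))
  if (normalize) table <- normalize_median(table)
  if (impute) table <- impute_missing(table, low_fraction, seed)
  bait_cols <- table$samples$role == "bait"
  v <- table$values
  res <- vapply(seq_len(nrow(v)), function(i) {
    t <- test_depletion(v[i, bait_cols], v[i, !bait_cols])
    c(t$log2fc, t$pvalue)
  }, numeric(2))
  log2fc <- res[1, ]; pvalue <- res[2, ]
  bi <- depletion_to_bi(log2fc)$bi
  aff <- censor_affinity(bi, bi_threshold, bait_conc)
  out <- data.frame(protein_id = rownames(v), log2fc = log2fc,
                    pvalue = pvalue, bi = bi, pk = aff$pk,
                    censored = aff$censored, row.names = NULL,
                    stringsAsFactors = FALSE)
  call_significant(out, p_cap = p_cap, bi_threshold = bi_threshold,
                   bait_conc = bait_conc)
}

#' Call significant binders
#'
#' Conjunctive gate: a protein is a significant interaction partner when its
#' depletion p-value is at or below `p_cap` and its BI is at or above
#' `bi_threshold`. Both knobs are recorded on the result.
#'
#' @param results data.frame with at least `pvalue` and `bi` columns.
#' @param p_cap,bi_threshold Gate parameters.
#' @param bait_conc Bait concentration recorded for downstream conversions.
#' @return `results` with a logical `significant` column, classed
#'   `depletion_results`, with `p_cap`, `bi_threshold` and `bait_conc`
#'   attributes.
#' @export
call_significant <- function(results, p_cap = 0.05, bi_threshold = 0.128,
                             bait_conc = 10e-6) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) {
    results$significant <- logical(0)
  } else {
    results$significant <- results$pvalue <= p_cap & results$bi >= bi_threshold
  }
  attr(results, "p_cap") <- p_cap
  attr(results, "bi_threshold") <- bi_threshold
  attr(results, "bait_conc") <- bait_conc
  class(results) <- c("depletion_results", "data.frame")
  results
}

#' Compare two depletion experiments on one bait
#'
#' Computes cross-experiment recall and the affinity correlation between two
#' independent native-holdup measurements. A partner significant in one
#' experiment counts as "recovered" in the other if it is significant there
#' too, or (by default) if it is depleted there above the BI threshold even
#' though sub-significant — treating measured depletion values as true for
#' partners under the significance threshold. The affinity agreement is
#' summarized by the Pearson correlation of pK values over partners
#' significant in both, an ordinary least-squares fit with a pointwise 95%
#' confidence band, and a correlation p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param a,b `depletion_results` for the same bait.
#' @param recovered `"depleted"` (default: significant or depleted above the
#'   BI threshold) or `"significant"` (strict).
#' @return List: `recall_ab`, `recall_ba`, `n_shared_significant`, `pcc`,
#'   `correlation_pvalue`, `fit_slope`, `fit_intercept`, `ci95_band`
#'   (data.frame `pk_a`, `fit`, `lwr`, `upr`), and `undefined` flag when
#'   fewer than 3 shared significant partners exist.
#' @export
compare_experiments <- function(a, b, recovered = c("depleted", "significant")) {
  recovered <- match.arg(recovered)
  shared <- intersect(a$protein_id, b$protein_id)
  if (length(shared) == 0L) stop("no shared protein ids")
  ai <- a[match(shared, a$protein_id), ]
  bi <- b[match(shared, b$protein_id), ]
  thr_a <- attr(a, "bi_threshold"); thr_b <- attr(b, "bi_threshold")

  recall <- function(from, to, thr) {
    sig <- which(from$significant)
    if (length(sig) == 0L) return(NA_real_)
    hit <- to$significant[sig] |
      (recovered == "depleted" & to$bi[sig] >= thr)
    mean(hit)
  }
  recall_ab <- recall(ai, bi, thr_b)
  recall_ba <- recall(bi, ai, thr_a)

  both <- ai$significant & bi$significant
  n <- sum(both)
  out <- list(recall_ab = recall_ab, recall_ba = recall_ba,
              n_shared_significant = n)
  if (n < 3L) {
    out$undefined <- TRUE
    out$pcc <- NA_real_
    return(out)
  }
  x <- ai$pk[both]; y <- bi$pk[both]
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  fit <- stats::lm(y ~ x)
  grid <- data.frame(x = sort(x))
  band <- stats::predict(fit, newdata = grid, interval = "confidence",
                         level = 0.95)
  out$undefined <- FALSE
  out$pcc <- r
  out$correlation_pvalue <- 2 * stats::pt(abs(tstat), df = n - 2,
                                          lower.tail = FALSE)
  out$fit_slope <- unname(stats::coef(fit)[2])
  out$fit_intercept <- unname(stats::coef(fit)[1])
  out$ci95_band <- data.frame(pk_a = grid$x, fit = band[, "fit"],
                              lwr = band[, "lwr"], upr = band[, "upr"])
  out
}

#' Pairwise interactome similarity across baits
#'
#' Pearson correlation of apparent affinities over partners significant for
#' both members of each bait pair, the statistic used to quantify how alike
#' two domains' affinity interactomes are.
#'
#' @param profiles Named list of `depletion_results`, one per bait.
#' @return List of matrices `pcc`, `n`, `pvalue` (baits x baits). Pairs with
#'   fewer than 3 shared significant partners have `NA` pcc/pvalue.
#' @export
interactome_similarity <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2L,
            !is.null(names(profiles)))
  k <- length(profiles)
  pcc <- nmat <- pval <- matrix(NA_real_, k, k,
                                dimnames = list(names(profiles), names(profiles)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- profiles[[i]]; b <- profiles[[j]]
    shared <- intersect(a$protein_id[a$significant], b$protein_id[b$significant])
    nmat[i, j] <- length(shared)
    if (i == j) { pcc[i, j] <- 1; pval[i, j] <- 0; next }
    if (length(shared) < 3L) next
    x <- a$pk[match(shared, a$protein_id)]
    y <- b$pk[match(shared, b$protein_id)]
    r <- stats::cor(x, y)
    pcc[i, j] <- r
    tstat <- r * sqrt((length(shared) - 2) / (1 - r^2))
    pval[i, j] <- 2 * stats::pt(abs(tstat), df = length(shared) - 2,
                                lower.tail = FALSE)
  }
  list(pcc = pcc, n = nmat, pvalue = pval)
}
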