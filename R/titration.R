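# Titration holdup: fraction bound measured across a series of effective
# bait concentrations, fit with the single-site model extended by a partial
# binding activity a (the maximal fraction of the prey population that is
# binding-competent): FB(c) = a * c / (c + Kd).

#' Effective bait concentrations from resin-mixing proportions
#'
#' Titration series are produced by mixing bait-saturated and control resin
#' in set proportions while keeping the total resin-to-analyte ratio
#' constant, so the effective bait concentration is simply the proportion
#' times the saturated-stock concentration.
#'
#' @param stock_conc Bait concentration of the saturated resin slurry, molar.
#' @param proportions Fractions of bait resin in each mix, each in `[0, 1]`.
#' @return Molar concentrations, order preserved.
#' @examples
#' make_dilution_series(10e-6, c(1, 0.5, 0))
#' @export
make_dilution_series <- function(stock_conc, proportions) {
  stopifnot(is.numeric(stock_conc), length(stock_conc) == 1L, stock_conc > 0)
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  proportions * stock_conc
}

#' Fit a titration holdup curve with the partial-activity model
#'
#' Least-squares fit of `FB(c) = a * c / (c + Kd)` with the active fraction
#' `a` constrained to (0, 1] and `Kd` to a broad positive range. With `a`
#' fixed at 1 the model reduces to the standard hyperbola; a fitted `a < 1`
#' indicates that only part of the prey population is binding-competent.
#' Starting values are scale-free: `a0` is the maximum observed fraction
#' bound (clipped into (0, 1]) and `Kd0` the concentration whose response is
#' nearest `a0 / 2`. Standard errors come from the curvature at the optimum.
#'
#' @param conc Bait concentrations, molar (>= 3 distinct values).
#' @param fraction_bound Observed fraction bound at each concentration;
#'   raw values may spill slightly outside `[0, 1]` from noise.
#' @param weights Optional weights (e.g. 1/sd^2 of replicate means).
#' @param min_signal If all responses fall below this level the prey is
#'   reported as showing no detectable binding instead of being fit
#'   (default 0.05).
#' @return List of class `titration_fit`: `kd` (molar), `pk`,
#'   `active_fraction`, `se_kd`, `se_active`, `converged`, `censored`.
#' @examples
#' conc <- 10^seq(-8, -4, length.out = 8)
#' fb <- 0.8 * conc / (conc + 1e-6)
#' fit_titration(conc, fb)
#' @export
fit_titration <- function(conc, fraction_bound, weights = NULL,
                          min_signal = 0.05) {
  stopifnot(is.numeric(conc), is.numeric(fraction_bound),
            length(conc) == length(fraction_bound))
  if (length(unique(conc)) < 3L)
    stop("need >= 3 distinct bait concentrations to fit")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (any(fraction_bound < -0.2 | fraction_bound > 1.2))
    stop("fraction_bound outside plausible raw range [-0.2, 1.2]")

  if (max(fraction_bound) < min_signal) {
    return(structure(list(kd = NA_real_, pk = NA_real_,
                          active_fraction = NA_real_, se_kd = NA_real_,
                          se_active = NA_real_, converged = FALSE,
                          censored = TRUE),
                     class = "titration_fit"))
  }

  a0 <- min(max(fraction_bound), 1)
  pos <- conc > 0
  kd0 <- conc[pos][which.min(abs(fraction_bound[pos] - a0 / 2))]
  dat <- data.frame(c = conc, fb = fraction_bound)
  fit <- minpack.lm::nlsLM(
    fb ~ a * c / (c + kd), data = dat,
    start = list(a = a0, kd = kd0),
    lower = c(a = 1e-6, kd = 1e-12),
    upper = c(a = 1, kd = 1e-2),
    weights = if (is.null(weights)) rep(1, nrow(dat)) else weights,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- summary(fit)$coefficients
  kd <- est["kd", "Estimate"]
  if (kd <= 1.5e-12 || kd >= 0.99e-2)
    warning("Kd estimate at parameter bound; data may not bracket the Kd")
  structure(list(kd = kd, pk = kd_to_pk(kd),
                 active_fraction = est["a", "Estimate"],
                 se_kd = est["kd", "Std. Error"],
                 se_active = est["a", "Std. Error"],
                 converged = fit$convInfo$isConv,
                 censored = FALSE),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  if (x$censored) {
    cat("titration_fit: no detectable binding\n")
  } else {
    cat(sprintf("titration_fit: Kd = %.3g M (pK %.2f), active fraction = %.3f%s\n",
                x$kd, x$pk, x$active_fraction,
                if (x$converged) "" else " [NOT converged]"))
  }
  invisible(x)
}
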