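# Closed-form equilibrium holdup mathematics: single-site hyperbolic model
# relating the fraction of prey depleted by an immobilized bait (binding
# intensity, BI) to the equilibrium dissociation constant, plus pK transforms
# and detection-threshold censoring. All concentrations are molar internally.

#' Convert a dissociation constant to pK
#'
#' Affinities are expressed as the negative base-10 logarithm of the molar
#' dissociation constant, so that pK 4 corresponds to a Kd of 100 uM and a
#' larger pK means a stronger interaction. Differences in pK are proportional
#' to binding free-energy differences.
#'
#' @param kd Dissociation constant(s) in molar. Must be strictly positive.
#' @return Numeric vector of pK values (dimensionless).
#' @examples
#' kd_to_pk(100e-6)  # 4
#' kd_to_pk(100e-9)  # 7
#' @seealso [pk_to_kd()], [bi_to_kd()]
#' @export
kd_to_pk <- function(kd) {
  stopifnot(is.numeric(kd))
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be finite and strictly positive (molar)")
  -log10(kd)
}

#' Convert pK back to a molar dissociation constant
#'
#' @param pk pK value(s), the negative log10 of Kd in molar.
#' @return Kd in molar.
#' @export
pk_to_kd <- function(pk) {
  stopifnot(is.numeric(pk), all(is.finite(pk)))
  10^(-pk)
}

#' Binding intensity expected from a dissociation constant
#'
#' Forward form of the single-site hyperbolic binding model under bait
#' excess: the fraction of prey bound (and hence depleted from the
#' supernate) at equilibrium is `bait / (bait + kd)`.
#'
#' @param kd Dissociation constant(s), molar, `>= 0` (0 is the
#'   infinite-affinity limit and gives BI = 1).
#' @param bait_conc Immobilized bait concentration in the slurry, molar.
#' @return Binding intensity in (0, 1].
#' @examples
#' kd_to_bi(10e-6, 10e-6)  # half-saturation: 0.5
#' @export
kd_to_bi <- function(kd, bait_conc) {
  stopifnot(is.numeric(kd), is.numeric(bait_conc))
  if (any(kd < 0)) stop("kd must be non-negative (molar)")
  if (any(bait_conc <= 0)) stop("bait_conc must be positive (molar)")
  bait_conc / (bait_conc + kd)
}

#' Dissociation constant implied by a binding intensity
#'
#' Inverts the hyperbolic model: `kd = bait * (1 - bi) / bi`. BI values at
#' or below 0 carry no finite Kd (binding below detection) and must be
#' handled by [censor_affinity()]; BI `>= 1` is physically impossible and is
#' rejected.
#'
#' @param bi Binding intensity (fraction of prey depleted), in (0, 1).
#' @param bait_conc Bait concentration, molar.
#' @return Kd in molar.
#' @export
bi_to_kd <- function(bi, bait_conc) {
  stopifnot(is.numeric(bi), is.numeric(bait_conc))
  if (any(bait_conc <= 0)) stop("bait_conc must be positive (molar)")
  if (any(bi >= 1)) stop("bi >= 1 is degenerate: no finite Kd exists")
  if (any(bi <= 0)) stop("bi <= 0 has no finite Kd; use censor_affinity() for below-detection values")
  bait_conc * (1 - bi) / bi
}

#' Clamp raw binding-intensity measurements into the model domain
#'
#' Negative raw depletion is expected measurement noise and is clipped to 0
#' (and flagged); values `>= 1` are impossible and raise an error.
#'
#' @param bi Raw BI measurement(s).
#' @return A data.frame with columns `bi` (clamped value) and `clamped`.
#' @export
clamp_bi <- function(bi) {
  stopifnot(is.numeric(bi), all(is.finite(bi)))
  if (any(bi >= 1)) stop("raw bi >= 1 is physically impossible")
  data.frame(bi = pmax(bi, 0), clamped = bi < 0)
}

#' Convert a binding intensity to a censoring-aware affinity value
#'
#' Measurements at or below the panel's BI detection threshold carry no
#' quantifiable affinity; they are reported as censored, with pK set to the
#' threshold's own hyperbolic pK, interpretable as an upper bound on the
#' true affinity. The boundary `bi == bi_threshold` counts as censored.
#'
#' @param bi Binding intensity value(s); raw negatives are treated as 0.
#' @param bi_threshold Detection threshold on the BI scale, in (0, 1).
#' @param bait_conc Bait concentration, molar.
#' @return A data.frame with columns `pk` and `censored`.
#' @examples
#' censor_affinity(c(0.01, 0.5), bi_threshold = 0.05, bait_conc = 10e-6)
#' @export
censor_affinity <- function(bi, bi_threshold, bait_conc) {
  stopifnot(is.numeric(bi), length(bi_threshold) == 1L)
  if (bi_threshold <= 0 || bi_threshold >= 1)
    stop("bi_threshold must lie strictly inside (0, 1)")
  if (any(bi >= 1)) stop("bi >= 1 is degenerate")
  detection_pk <- kd_to_pk(bi_to_kd(bi_threshold, bait_conc))
  censored <- bi <= bi_threshold
  pk <- rep(detection_pk, length(bi))
  if (any(!censored))
    pk[!censored] <- kd_to_pk(bi_to_kd(bi[!censored], bait_conc))
  data.frame(pk = pk, censored = censored)
}

#' Detection-threshold pK of a panel
#'
#' The pK corresponding to the BI detection threshold at the given bait
#' concentration; censored measurements hold this value.
#'
#' @inheritParams censor_affinity
#' @return A single pK value.
#' @export
detection_pk <- function(bi_threshold, bait_conc) {
  kd_to_pk(bi_to_kd(bi_threshold, bait_conc))
}
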