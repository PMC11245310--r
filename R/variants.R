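# Variant affinity-profile comparison: censoring-aware cumulative Euclidean
# distance in pK space (delta-pK is proportional to delta-delta-G, so the
# distance summarizes the overall binding-energy perturbation across the
# panel) and classification into WT-like / perturbed affinity profile (PAP)
# / loss of function (LOF).

#' Cumulative Euclidean affinity distance between two profiles
#'
#' `distance = sqrt(sum_i (pk_wt,i - pk_var,i)^2)` over the shared panel.
#' Where no detectable binding was observed the detection-threshold pK is
#' used in place of the unknown value, so whenever any censored entry enters
#' the sum only a lower limit of the distance can be estimated
#' (`is_lower_bound`). Dimensions censored in both profiles carry no
#' information about either value and contribute zero.
#'
#' @param wt,var `affinity_profile`s on the identical panel with the same
#'   detection pK.
#' @return List of class `variant_comparison`: `variant_id`, `distance`,
#'   `is_lower_bound`, `n_dims`, `n_lost` (WT-detectable motifs censored in
#'   the variant), `n_gained`, `n_wt_detectable`, `per_motif_delta`.
#' @export
euclidean_affinity_distance <- function(wt, var) {
  stopifnot(inherits(wt, "affinity_profile"), inherits(var, "affinity_profile"))
  if (!identical(wt$peptide_id, var$peptide_id))
    stop("profiles must share an identical peptide panel (same order)")
  if (!isTRUE(all.equal(attr(wt, "detection_pk"), attr(var, "detection_pk"))))
    stop("profiles must share the same detection threshold")
  dpk <- attr(wt, "detection_pk")
  pw <- ifelse(wt$censored, dpk, wt$pk)
  pv <- ifelse(var$censored, dpk, var$pk)
  both <- wt$censored & var$censored
  delta <- pw - pv
  delta[both] <- 0
  used_threshold <- xor(wt$censored, var$censored)
  structure(list(
    variant_id = attr(var, "bait_id"),
    distance = sqrt(sum(delta^2)),
    is_lower_bound = any(used_threshold),
    n_dims = length(delta),
    n_lost = sum(!wt$censored & var$censored),
    n_gained = sum(wt$censored & !var$censored),
    n_wt_detectable = sum(!wt$censored),
    per_motif_delta = stats::setNames(delta, wt$peptide_id)),
    class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat(sprintf("variant_comparison %s: distance %s%.3f pK over %d dims (%d lost, %d gained)\n",
              x$variant_id, if (x$is_lower_bound) ">= " else "",
              x$distance, x$n_dims, x$n_lost, x$n_gained))
  invisible(x)
}

#' Classify a variant from its affinity-distance comparison
#'
#' LOF (general loss of function) when at least `lof_fraction` of the
#' WT-detectable motifs show no detectable binding in the variant; PAP
#' (perturbed affinity profile) when binding is broadly retained but the
#' cumulative distance exceeds the measurement-noise distance; otherwise
#' WT-like. Thresholds are recorded in the output.
#'
#' @param cmp A `variant_comparison`.
#' @param noise_distance Distance expected from measurement noise alone,
#'   e.g. from [noise_distance_from_replicates()] on WT replicate profiles.
#' @param lof_fraction Fraction of WT-detectable motifs that must be lost to
#'   call LOF (default 0.9).
#' @return List: `label` (`"WT-like"`, `"PAP"`, `"LOF"`), `distance`,
#'   `noise_distance`, `lof_fraction`, `lost_fraction`.
#' @export
classify_variant <- function(cmp, noise_distance, lof_fraction = 0.9) {
  stopifnot(inherits(cmp, "variant_comparison"), noise_distance >= 0)
  lost_fraction <- if (cmp$n_wt_detectable > 0)
    cmp$n_lost / cmp$n_wt_detectable else 0
  label <- if (lost_fraction >= lof_fraction) "LOF"
  else if (cmp$distance > noise_distance) "PAP"
  else "WT-like"
  list(label = label, distance = cmp$distance,
       noise_distance = noise_distance, lof_fraction = lof_fraction,
       lost_fraction = lost_fraction)
}

#' Noise distance from replicate wild-type profiles
#'
#' Estimates the affinity distance attributable to measurement noise as a
#' safety multiple of the largest pairwise distance among replicate
#' measurements of the same (wild-type) domain.
#'
#' @param replicates List of >= 2 `affinity_profile`s of one bait.
#' @param factor Safety multiplier on the maximum replicate-replicate
#'   distance (default 1.5).
#' @return A scalar noise distance.
#' @export
noise_distance_from_replicates <- function(replicates, factor = 1.5) {
  stopifnot(is.list(replicates), length(replicates) >= 2L)
  d <- c()
  for (i in seq_along(replicates)) for (j in seq_along(replicates)) {
    if (j <= i) next
    d <- c(d, euclidean_affinity_distance(replicates[[i]],
                                          replicates[[j]])$distance)
  }
  factor * max(d)
}
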