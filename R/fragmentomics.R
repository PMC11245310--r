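# Fragmentomic holdup: plate-format holdup against a panel of synthetic
# 15-mer PRM peptides, read out by intrinsic Trp fluorescence of the
# MBP-fused SH3 analyte with fluorescein and mCherry spiked in as internal
# loading standards. Yields a per-motif affinity profile for one bait.

#' Internal-standard-corrected binding intensity from a plate readout
#'
#' The Trp signal ratio between the peptide well (sample) and the
#' biotin-control well is divided by the geometric mean of the two internal
#' standard ratios, removing per-well volume and loading drift; the
#' corrected depletion is `bi = 1 - ratio`, clamped into `[0, 1)`.
#'
#' @param trp_sample,trp_control Trp-fluorescence signals (analyte channel).
#' @param std1_sample,std1_control First internal standard (fluorescein).
#' @param std2_sample,std2_control Second internal standard (mCherry).
#' @return data.frame with columns `bi` and `clamped`. Vectorized.
#' @examples
#' plate_to_bi(55, 100, 110, 100, 110, 100)  # standards drifted x1.1: bi 0.5
#' @export
plate_to_bi <- function(trp_sample, trp_control,
                        std1_sample, std1_control,
                        std2_sample, std2_control) {
  sig <- cbind(trp_sample, trp_control, std1_sample, std1_control,
               std2_sample, std2_control)
  if (any(sig <= 0)) stop("all plate signals must be positive")
  std_ratio <- sqrt((std1_sample / std1_control) * (std2_sample / std2_control))
  ratio <- (trp_sample / trp_control) / std_ratio
  raw <- 1 - ratio
  out <- clamp_bi(pmin(raw, 1 - 1e-12))
  out$clamped <- out$clamped | raw >= 1
  out
}

#' Build a censored affinity profile from per-peptide readouts
#'
#' Applies [plate_to_bi()] and [censor_affinity()] over a complete peptide
#' panel, producing the panel-ordered affinity profile of one bait.
#'
#' @param readouts data.frame with columns `peptide_id`, `trp_sample`,
#'   `trp_control`, `std1_sample`, `std1_control`, `std2_sample`,
#'   `std2_control`; one row per peptide, ids unique.
#' @param bait_conc Bait concentration in the plate wells, molar
#'   (default 4 uM, the purified MBP-SH3 condition).
#' @param bi_threshold BI detection threshold of the panel (default 0.02).
#' @param bait_id Label for the bait (wild type or variant domain).
#' @param panel Optional character vector fixing the panel order; peptides
#'   missing from `readouts` are flagged censored with `measured = FALSE`.
#' @return data.frame of class `affinity_profile` with columns
#'   `peptide_id`, `bi`, `pk`, `censored`, `measured`; attributes `bait_id`,
#'   `bait_conc`, `bi_threshold`, `detection_pk`.
#' @export
build_profile <- function(readouts, bait_conc = 4e-6, bi_threshold = 0.02,
                          bait_id = "bait", panel = NULL) {
  need <- c("peptide_id", "trp_sample", "trp_control", "std1_sample",
            "std1_control", "std2_sample", "std2_control")
  if (!all(need %in% names(readouts)))
    stop("readouts missing columns: ",
         paste(setdiff(need, names(readouts)), collapse = ", "))
  if (anyDuplicated(readouts$peptide_id)) stop("duplicate peptide ids")
  b <- plate_to_bi(readouts$trp_sample, readouts$trp_control,
                   readouts$std1_sample, readouts$std1_control,
                   readouts$std2_sample, readouts$std2_control)
  aff <- censor_affinity(b$bi, bi_threshold, bait_conc)
  prof <- data.frame(peptide_id = as.character(readouts$peptide_id),
                     bi = b$bi, pk = aff$pk, censored = aff$censored,
                     measured = TRUE, stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    miss <- setdiff(panel, prof$peptide_id)
    if (length(miss)) {
      dpk <- detection_pk(bi_threshold, bait_conc)
      prof <- rbind(prof, data.frame(peptide_id = miss, bi = 0, pk = dpk,
                                     censored = TRUE, measured = FALSE,
                                     stringsAsFactors = FALSE))
    }
    prof <- prof[match(panel, prof$peptide_id), , drop = FALSE]
    rownames(prof) <- NULL
  }
  structure(prof,
            bait_id = bait_id, bait_conc = bait_conc,
            bi_threshold = bi_threshold,
            detection_pk = detection_pk(bi_threshold, bait_conc),
            class = c("affinity_profile", "data.frame"))
}

#' Assemble an affinity profile directly from pK values
#'
#' Constructor used by simulators and readers: takes per-peptide pK and
#' censoring flags that are already on the affinity scale.
#'
#' @param peptide_id,pk,censored Parallel vectors over the panel; censored
#'   entries hold the detection pK.
#' @param detection_pk Panel detection-threshold pK.
#' @param bait_id,bait_conc Metadata.
#' @return An `affinity_profile`.
#' @export
affinity_profile <- function(peptide_id, pk, censored, detection_pk,
                             bait_id = "bait", bait_conc = 4e-6) {
  stopifnot(length(peptide_id) == length(pk), length(pk) == length(censored))
  if (anyDuplicated(peptide_id)) stop("duplicate peptide ids")
  structure(data.frame(peptide_id = as.character(peptide_id), pk = pk,
                       censored = censored, measured = TRUE,
                       stringsAsFactors = FALSE),
            bait_id = bait_id, bait_conc = bait_conc,
            detection_pk = detection_pk,
            class = c("affinity_profile", "data.frame"))
}

#' Full-length versus best-motif affinity comparison
#'
#' For each protein with a measured full-length (intact-protein) apparent
#' affinity and at least one uncensored motif affinity, takes the strongest
#' (max pK) motif and summarizes the relationship: Pearson correlation,
#' mean and median of `pk_FL - pk_bestmotif`, and the fraction of proteins
#' whose intact protein binds strictly stronger than any isolated motif.
#' Proteins whose motifs are all censored are excluded and counted
#' separately.
#'
#' @param fl data.frame with columns `protein_id`, `pk` (full-length
#'   apparent affinities, uncensored).
#' @param profile An `affinity_profile` over the motif panel.
#' @param mapping data.frame with columns `peptide_id`, `protein_id`.
#' @return List: `n`, `pcc`, `delta_mean`, `delta_median`,
#'   `fraction_fl_stronger`, `n_all_censored`, `per_protein` table; or
#'   `undefined = TRUE` when fewer than 3 proteins overlap.
#' @export
compare_fl_vs_motifs <- function(fl, profile, mapping) {
  stopifnot(all(c("protein_id", "pk") %in% names(fl)),
            all(c("peptide_id", "protein_id") %in% names(mapping)))
  prof <- as.data.frame(profile)
  prof$protein_id <- mapping$protein_id[match(prof$peptide_id,
                                              mapping$peptide_id)]
  prof <- prof[!is.na(prof$protein_id), , drop = FALSE]
  best <- lapply(split(prof, prof$protein_id), function(d) {
    unc <- d[!d$censored, , drop = FALSE]
    if (nrow(unc) == 0L) return(NA_real_)
    max(unc$pk)
  })
  best <- data.frame(protein_id = names(best),
                     pk_best = unlist(best), stringsAsFactors = FALSE)
  merged <- merge(fl, best, by = "protein_id")
  n_all_censored <- sum(is.na(merged$pk_best))
  merged <- merged[!is.na(merged$pk_best), , drop = FALSE]
  if (nrow(merged) < 3L)
    return(list(undefined = TRUE, n = nrow(merged),
                n_all_censored = n_all_censored))
  delta <- merged$pk - merged$pk_best
  list(undefined = FALSE,
       n = nrow(merged),
       pcc = stats::cor(merged$pk, merged$pk_best),
       delta_mean = mean(delta),
       delta_median = stats::median(delta),
       fraction_fl_stronger = mean(delta > 0),
       n_all_censored = n_all_censored,
       per_protein = data.frame(protein_id = merged$protein_id,
                                pk_fl = merged$pk, pk_best = merged$pk_best,
                                delta = delta, stringsAsFactors = FALSE))
}

#' Affinity-weighted specificity logo
#'
#' Position-wise amino-acid preference of a domain, weighted by how far each
#' binder's affinity sits above the panel detection limit: the weight of
#' peptide i is `max(0, pk_i - detection_pk)` (proportional to its binding
#' free-energy margin), censored peptides contribute nothing, and each
#' position's column is normalized to sum to 1.
#'
#' @param profile An `affinity_profile`.
#' @param cores Named character vector (or vector parallel to the profile)
#'   of aligned equal-length core sequences, one per peptide in the profile.
#' @return Matrix, rows = positions, columns = the 20 amino acids, each row
#'   summing to 1.
#' @export
specificity_logo <- function(profile, cores) {
  stopifnot(inherits(profile, "affinity_profile"))
  if (!is.null(names(cores)))
    cores <- cores[profile$peptide_id]
  if (length(cores) != nrow(profile))
    stop("need one aligned core per profile peptide")
  wlen <- unique(nchar(cores))
  if (length(wlen) != 1L) stop("cores must be aligned to one common length")
  dpk <- attr(profile, "detection_pk")
  w <- pmax(0, profile$pk - dpk)
  w[profile$censored] <- 0
  if (all(w == 0)) stop("no uncensored binders: logo undefined")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  logo <- matrix(0, nrow = wlen, ncol = 20,
                 dimnames = list(seq_len(wlen), aa))
  chars <- do.call(rbind, strsplit(cores, ""))
  for (p in seq_len(wlen)) {
    tot <- tapply(w, factor(chars[, p], levels = aa), sum)
    tot[is.na(tot)] <- 0
    logo[p, ] <- tot / sum(tot)
  }
  logo
}
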