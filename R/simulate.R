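# Seed-deterministic synthetic-data generators emulating every measurement
# type the pipeline consumes: a proteome with implanted PxxP motifs inside
# disordered stretches, native-holdup MS intensity tables (log-normal
# abundances, hyperbolic depletion at the bait concentration,
# intensity-dependent dropout), fragmentomic plate readouts with
# internal-standard drift, titration curves, ortholog sets with a planted
# conservation depth, and benign/PAP/LOF variant profiles. Every generator
# calls set.seed(seed) so reruns are identical.

sample_sequence <- function(n, freqs = aa_background()) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

random_core <- function(class_id) {
  aa <- names(aa_background())
  x <- function(k) paste(sample(aa, k, replace = TRUE), collapse = "")
  if (class_id == 1L) paste0(sample(c("R", "K"), 1), x(2), "P", x(2), "P")
  else paste0("P", x(2), "P", x(1), sample(c("R", "K"), 1))
}

#' Generate a synthetic proteome with implanted PRMs and ground truth
#'
#' Random protein sequences drawn from background amino-acid frequencies,
#' each with one contiguous disordered stretch; a fraction of proteins get
#' 1-3 class 1/2 PxxP cores implanted inside the disordered stretch. Motif
#' Kds are log-uniform over `kd_range`; each binder protein's full-length
#' apparent Kd is its best motif Kd divided by an avidity factor
#' (log-uniform over `avidity_range`), emulating the observation that
#' intact proteins bind several-fold stronger than their isolated motifs.
#' Abundances are log-normal.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Min/max sequence length (default 150-400).
#' @param implant_rate Fraction of proteins given implanted motifs
#'   (default 0.25, the proteome-wide PRM-containing baseline).
#' @param binder_rate Fraction of all proteins that truly bind the bait
#'   (default 0.03, matching the sparse binder prevalence of a
#'   native-holdup screen, ~200 partners among ~6,400 assayed proteins).
#'   Binders are drawn from the motif-implanted proteins; motifs of
#'   non-binder proteins keep `kd = NA`.
#' @param kd_range Motif Kd range, molar (default 0.5-300 uM).
#' @param avidity_range Full-length avidity factor range (default 1-10).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters.
#' @param seed Integer RNG seed.
#' @return List of class `ground_truth`: `proteins` (data.frame
#'   `protein_id`, `sequence`, `length`, `abundance`, `kd` — `NA` for
#'   non-binders), `disorder` (named list of logical masks), `motifs`
#'   (data.frame `protein_id`, `class_id`, `start`, `core_seq`, `kd`).
#' @export
generate_proteome <- function(n_proteins, length_range = c(150L, 400L),
                              implant_rate = 0.25, binder_rate = 0.03,
                              kd_range = c(0.5e-6, 300e-6),
                              avidity_range = c(1, 10),
                              abundance_meanlog = log(1e6),
                              abundance_sdlog = 1.5,
                              seed = 1L) {
  stopifnot(n_proteins >= 1L, implant_rate >= 0, implant_rate <= 1,
            binder_rate >= 0, binder_rate <= implant_rate)
  set.seed(seed)
  ids <- sprintf("SYN%04d", seq_len(n_proteins))
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  has_motif <- stats::runif(n_proteins) < implant_rate
  # true binders are a sparse subset of the motif-carrying proteins
  is_binder <- has_motif & stats::runif(n_proteins) <
    ifelse(has_motif, binder_rate / max(implant_rate, 1e-12), 0)
  seqs <- character(n_proteins)
  disorder <- vector("list", n_proteins)
  motif_rows <- list()
  for (i in seq_len(n_proteins)) {
    s <- sample_sequence(lens[i])
    # one contiguous disordered stretch covering roughly 40% of the chain
    dlen <- max(30L, round(0.4 * lens[i]))
    dstart <- sample(seq_len(lens[i] - dlen + 1L), 1)
    mask <- rep(FALSE, lens[i])
    mask[dstart:(dstart + dlen - 1L)] <- TRUE
    if (has_motif[i]) {
      n_mot <- sample(1:3, 1)
      # non-overlapping implant slots inside the disordered stretch
      slots <- seq(dstart, dstart + dlen - 8L, by = 9L)
      slots <- slots[seq_len(min(length(slots), n_mot))]
      for (st in slots) {
        cls <- sample(1:2, 1)
        core <- random_core(cls)
        substr(s, st, st + nchar(core) - 1L) <- core
        kd <- if (is_binder[i])
          10^stats::runif(1, log10(kd_range[1]), log10(kd_range[2]))
        else NA_real_
        motif_rows[[length(motif_rows) + 1L]] <- data.frame(
          protein_id = ids[i], class_id = cls, start = st,
          core_seq = core, kd = kd, stringsAsFactors = FALSE)
      }
    }
    seqs[i] <- s
    disorder[[i]] <- mask
  }
  names(disorder) <- ids
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(protein_id = character(0), class_id = integer(0),
               start = integer(0), core_seq = character(0),
               kd = numeric(0), stringsAsFactors = FALSE)
  bind_mot <- motifs[!is.na(motifs$kd), , drop = FALSE]
  best_kd <- tapply(bind_mot$kd, bind_mot$protein_id, min)
  kd_fl <- rep(NA_real_, n_proteins)
  idx <- match(names(best_kd), ids)
  kd_fl[idx] <- as.numeric(best_kd) /
    10^stats::runif(length(idx), log10(avidity_range[1]), log10(avidity_range[2]))
  proteins <- data.frame(
    protein_id = ids, sequence = seqs, length = lens,
    abundance = stats::rlnorm(n_proteins, abundance_meanlog, abundance_sdlog),
    kd = kd_fl, stringsAsFactors = FALSE)
  structure(list(proteins = proteins, disorder = disorder, motifs = motifs),
            class = "ground_truth")
}

#' Simulate a native-holdup MS intensity table from ground truth
#'
#' Control-arm intensities are proportional to protein abundance with
#' log-normal injection noise; bait-arm intensities are additionally
#' multiplied by `1 - BI_true`, where `BI_true` is the hyperbolic fraction
#' bound of the protein's full-length Kd at the bait concentration (1 for
#' non-binders). Missingness follows a logistic
#' missing-not-at-random model decreasing with log10 intensity.
#'
#' @param truth A [generate_proteome()] object.
#' @param bait_conc Bait concentration, molar (default 10 uM).
#' @param n_reps Injection replicates per arm (default 3).
#' @param cv Coefficient of variation of the multiplicative intensity noise
#'   (default 0.15).
#' @param dropout_location Log10-intensity at which the dropout probability
#'   is 50%; default the 3rd percentile of log10 abundance, giving sparse,
#'   low-intensity-biased missingness.
#' @param dropout_scale Logistic scale in log10 units (default 0.3).
#' @param seed Integer RNG seed.
#' @return An [intensity_table()] with `n_reps` bait and `n_reps` control
#'   samples.
#' @export
simulate_nhu_ms <- function(truth, bait_conc = 10e-6, n_reps = 3L, cv = 0.15,
                            dropout_location = NULL, dropout_scale = 0.3,
                            seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), n_reps >= 2L)
  set.seed(seed)
  p <- truth$proteins
  n <- nrow(p)
  sdlog <- sqrt(log(1 + cv^2))
  bi_true <- rep(0, n)
  bi_true[!is.na(p$kd)] <- kd_to_bi(p$kd[!is.na(p$kd)], bait_conc)
  if (is.null(dropout_location))
    dropout_location <- stats::quantile(log10(p$abundance), 0.03)
  cols <- c(paste0("bait_", seq_len(n_reps)),
            paste0("control_", seq_len(n_reps)))
  v <- matrix(NA_real_, nrow = n, ncol = 2L * n_reps,
              dimnames = list(p$protein_id, cols))
  for (r in seq_len(n_reps)) {
    v[, r] <- p$abundance * (1 - bi_true) *
      (if (cv > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else 1)
    v[, n_reps + r] <- p$abundance *
      (if (cv > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else 1)
  }
  if (dropout_scale > 0) {
    p_miss <- stats::plogis((dropout_location - log10(v)) / dropout_scale)
    miss <- matrix(stats::runif(length(v)) < p_miss, nrow = n)
    # never delete a whole group: the depletion test needs >= 2 per arm
    for (arm in list(seq_len(n_reps), n_reps + seq_len(n_reps))) {
      bad <- rowSums(miss[, arm, drop = FALSE]) > n_reps - 2L
      if (any(bad)) {
        keep2 <- t(apply(miss[bad, arm, drop = FALSE], 1, function(x) {
          x[utils::head(order(x), 2L)] <- FALSE; x
        }))
        miss[bad, arm] <- keep2
      }
    }
    v[miss] <- NA_real_
  }
  samples <- data.frame(sample_id = cols,
                        role = rep(c("bait", "control"), each = n_reps),
                        replicate = rep(seq_len(n_reps), 2),
                        stringsAsFactors = FALSE)
  intensity_table(v, samples)
}

#' Simulate fragmentomic plate readouts for a peptide panel
#'
#' Each well carries a multiplicative loading factor shared by all three
#' fluorescence channels (which the internal-standard correction is designed
#' to remove) plus independent per-channel noise. The peptide well's Trp
#' signal is scaled by `1 - BI_true` from the motif Kd at the bait
#' concentration; non-binders (`kd = NA`) are not depleted.
#'
#' @param panel data.frame with columns `peptide_id` and `kd` (molar, `NA`
#'   for non-binders).
#' @param bait_conc Bait concentration, molar (default 4 uM).
#' @param noise_cv Per-channel signal CV (default 0.02).
#' @param loading_sd Log-sd of the per-well loading factor (default 0.05).
#' @param seed Integer RNG seed.
#' @return data.frame of plate readouts accepted by [build_profile()].
#' @export
simulate_fragment_holdup <- function(panel, bait_conc = 4e-6,
                                     noise_cv = 0.02, loading_sd = 0.05,
                                     seed = 1L) {
  stopifnot(all(c("peptide_id", "kd") %in% names(panel)))
  set.seed(seed)
  n <- nrow(panel)
  bi_true <- rep(0, n)
  bi_true[!is.na(panel$kd)] <- kd_to_bi(panel$kd[!is.na(panel$kd)], bait_conc)
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  noise <- function() if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  load_s <- stats::rlnorm(n, 0, loading_sd)   # peptide wells
  load_c <- stats::rlnorm(n, 0, loading_sd)   # control wells
  base_trp <- 1000; base_std1 <- 500; base_std2 <- 800
  data.frame(
    peptide_id = panel$peptide_id,
    trp_sample = base_trp * (1 - bi_true) * load_s * noise(),
    trp_control = base_trp * load_c * noise(),
    std1_sample = base_std1 * load_s * noise(),
    std1_control = base_std1 * load_c * noise(),
    std2_sample = base_std2 * load_s * noise(),
    std2_control = base_std2 * load_c * noise(),
    stringsAsFactors = FALSE)
}

#' Simulate a titration holdup curve
#'
#' Fraction bound from the partial-activity model
#' `FB(c) = a * c / (c + kd)` with additive Gaussian noise.
#'
#' @param kd Dissociation constant, molar.
#' @param active_fraction Maximal fraction bound `a` in (0, 1].
#' @param concs Bait concentrations, molar.
#' @param sd Gaussian noise standard deviation (default 0.03).
#' @param seed Integer RNG seed.
#' @return data.frame `conc_molar`, `fraction_bound`.
#' @export
simulate_titration <- function(kd, active_fraction, concs, sd = 0.03,
                               seed = 1L) {
  stopifnot(kd > 0, active_fraction > 0, active_fraction <= 1)
  set.seed(seed)
  fb <- active_fraction * concs / (concs + kd)
  if (sd > 0) fb <- fb + stats::rnorm(length(concs), 0, sd)
  data.frame(conc_molar = concs,
             fraction_bound = pmin(pmax(fb, -0.2), 1.2))
}

#' Simulate an ortholog set with a planted conservation depth
#'
#' Levels up to and including `planted_depth` receive motif instances that
#' preserve the reference's core positions and substitute non-core residues
#' at rate `sub_rate`; more distal levels receive random background windows
#' (motif destroyed). The conservation signal is therefore encoded by where
#' the motif is destroyed, while conserved levels stay unambiguously
#' conserved under the normalized-score definition.
#' `planted_depth = "human-only"` destroys the motif at every level.
#'
#' @param human_window Reference (human) motif window.
#' @param planted_depth One of Mammalia, Vertebrata, Eumetazoa, Unicellular,
#'   or "human-only".
#' @param n_per_level Orthologs per level (default 5).
#' @param sub_rate Per-residue substitution probability at conserved levels
#'   for non-core positions (default 0.05).
#' @param core_positions Positions never substituted at conserved levels
#'   (default 7:10, the PxxP core frame).
#' @param seed Integer RNG seed.
#' @return data.frame `sequence_id`, `level`, `window`.
#' @export
simulate_orthologs <- function(human_window, planted_depth,
                               n_per_level = 5L, sub_rate = 0.05,
                               core_positions = 7:10, seed = 1L) {
  stopifnot(planted_depth %in% c(CONSERVATION_LEVELS, "human-only"))
  set.seed(seed)
  wlen <- nchar(human_window)
  planted_idx <- match(planted_depth, CONSERVATION_LEVELS, nomatch = 0L)
  aa <- names(aa_background())
  rows <- list()
  for (k in seq_along(CONSERVATION_LEVELS)) {
    for (r in seq_len(n_per_level)) {
      if (k <= planted_idx) {
        chars <- strsplit(human_window, "")[[1]]
        mut <- stats::runif(wlen) < sub_rate
        mut[core_positions] <- FALSE
        chars[mut] <- sample(aa, sum(mut), replace = TRUE)
        w <- paste(chars, collapse = "")
      } else {
        w <- sample_sequence(wlen)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sprintf("%s_%d", CONSERVATION_LEVELS[k], r),
        level = CONSERVATION_LEVELS[k], window = w,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Affinity profile implied by a panel of true Kds
#'
#' Converts ground-truth motif Kds into the censored affinity profile a
#' noise-free fragmentomic measurement would produce, optionally with
#' Gaussian pK noise before censoring.
#'
#' @param panel data.frame with `peptide_id` and `kd` (`NA` = non-binder).
#' @param bait_conc,bi_threshold Assay conditions (defaults 4 uM, 0.02).
#' @param pk_noise_sd Optional Gaussian noise on pK (default 0).
#' @param bait_id Profile label.
#' @param seed RNG seed (used only when `pk_noise_sd > 0`).
#' @return An `affinity_profile`.
#' @export
profile_from_kds <- function(panel, bait_conc = 4e-6, bi_threshold = 0.02,
                             pk_noise_sd = 0, bait_id = "WT", seed = 1L) {
  stopifnot(all(c("peptide_id", "kd") %in% names(panel)))
  dpk <- detection_pk(bi_threshold, bait_conc)
  pk <- ifelse(is.na(panel$kd), -Inf, -log10(panel$kd))
  if (pk_noise_sd > 0) {
    set.seed(seed)
    pk <- pk + stats::rnorm(length(pk), 0, pk_noise_sd)
  }
  censored <- pk <= dpk
  pk[censored] <- dpk
  affinity_profile(panel$peptide_id, pk, censored, dpk,
                   bait_id = bait_id, bait_conc = bait_conc)
}

#' Simulate a variant affinity profile from the wild-type profile
#'
#' Benign variants reproduce the WT profile up to replicate noise; PAP
#' (perturbed affinity profile) variants shift a fraction of the
#' WT-detectable binders weaker by `shift` pK units (plus noise); LOF
#' variants lose all detectable binding. Values falling at or below the
#' detection pK are re-censored.
#'
#' @param wt The wild-type `affinity_profile`.
#' @param mode `"benign"`, `"PAP"`, or `"LOF"`.
#' @param noise_sd Replicate pK noise (default 0.05).
#' @param shift PAP affinity shift in pK units (default -0.8).
#' @param shift_fraction Fraction of WT-detectable binders shifted
#'   (default 0.6).
#' @param variant_id Label for the simulated variant.
#' @param seed Integer RNG seed.
#' @return An `affinity_profile`.
#' @export
simulate_variant_profile <- function(wt, mode = c("benign", "PAP", "LOF"),
                                     noise_sd = 0.05, shift = -0.8,
                                     shift_fraction = 0.6,
                                     variant_id = NULL, seed = 1L) {
  stopifnot(inherits(wt, "affinity_profile"))
  mode <- match.arg(mode)
  set.seed(seed)
  dpk <- attr(wt, "detection_pk")
  if (is.null(variant_id)) variant_id <- mode
  n <- nrow(wt)
  if (mode == "LOF") {
    return(affinity_profile(wt$peptide_id, rep(dpk, n), rep(TRUE, n), dpk,
                            bait_id = variant_id,
                            bait_conc = attr(wt, "bait_conc")))
  }
  pk <- wt$pk
  detectable <- !wt$censored
  pk[detectable] <- pk[detectable] + stats::rnorm(sum(detectable), 0, noise_sd)
  if (mode == "PAP") {
    idx <- which(detectable)
    hit <- sample(idx, round(shift_fraction * length(idx)))
    pk[hit] <- pk[hit] + shift
  }
  censored <- wt$censored | pk <= dpk
  pk[censored] <- dpk
  affinity_profile(wt$peptide_id, pk, censored, dpk,
                   bait_id = variant_id, bait_conc = attr(wt, "bait_conc"))
}
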