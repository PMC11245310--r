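# Proline-rich motif (PRM) discovery: class 1 ([RK]..P..P) and class 2
# (P..P.[RK]) PxxP consensus scanning restricted to disordered regions, and
# design of the 15-mer peptides used in fragmentomic holdup. Coordinates are
# 1-based inclusive; "." in the consensus means any residue, including P/R/K.

PRM_CLASSES <- data.frame(
  class_id = c(1L, 2L),
  pattern = c("[RK]..P..P", "P..P.[RK]"),
  width = c(7L, 6L)
)

#' Scan a protein for class 1 and class 2 PxxP motifs
#'
#' Reports every (possibly overlapping) match of the class 1 consensus
#' `[RK]..P..P` (7 residues) and the class 2 consensus `P..P.[RK]`
#' (6 residues). A window matching both classes yields two records. When
#' `require_disorder` is `TRUE` every residue of the core must fall inside
#' the disorder mask, reflecting that SH3-binding PRMs live in
#' intrinsically disordered regions.
#'
#' @param sequence Amino-acid string, one-letter uppercase (20 standard
#'   residues plus X).
#' @param disorder_mask Logical vector, one element per residue (`TRUE` =
#'   disordered). Required when `require_disorder` is `TRUE`.
#' @param protein_id Identifier copied into the output.
#' @param require_disorder Restrict matches to disordered cores
#'   (default `TRUE`).
#' @param peptide_length Length of the designed peptide (default 15).
#' @return data.frame of PRM records sorted by (start, class_id):
#'   `protein_id`, `class_id`, `start`, `end`, `core_seq`, `peptide15`,
#'   `peptide_start`, `truncated`. Empty when no motif matches.
#' @examples
#' scan_prms("AAARAAPAAPAAA", rep(TRUE, 13), "toy")
#' @export
scan_prms <- function(sequence, disorder_mask = NULL, protein_id = "protein",
                      require_disorder = TRUE, peptide_length = 15L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))
    stop("sequence contains characters outside the amino-acid alphabet")
  n <- nchar(sequence)
  if (require_disorder) {
    if (is.null(disorder_mask))
      stop("disorder_mask required when require_disorder = TRUE")
    if (length(disorder_mask) != n)
      stop("disorder_mask length must equal sequence length")
  }
  rows <- list()
  for (k in seq_len(nrow(PRM_CLASSES))) {
    pat <- paste0("(?=", PRM_CLASSES$pattern[k], ")")
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    w <- PRM_CLASSES$width[k]
    starts <- as.integer(m)
    starts <- starts[starts + w - 1L <= n]
    if (require_disorder && length(starts)) {
      ok <- vapply(starts, function(s) all(disorder_mask[s:(s + w - 1L)]),
                   logical(1))
      starts <- starts[ok]
    }
    if (length(starts))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = protein_id, class_id = PRM_CLASSES$class_id[k],
        start = starts, end = starts + w - 1L,
        core_seq = substring(sequence, starts, starts + w - 1L),
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(protein_id = character(0), class_id = integer(0),
                      start = integer(0), end = integer(0),
                      core_seq = character(0), peptide15 = character(0),
                      peptide_start = integer(0), truncated = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$class_id), , drop = FALSE]
  rownames(out) <- NULL
  pep <- mapply(function(s, e) design_peptide(sequence, s, e, peptide_length),
                out$start, out$end, SIMPLIFY = FALSE)
  out$peptide15 <- vapply(pep, `[[`, character(1), "peptide")
  out$peptide_start <- vapply(pep, `[[`, integer(1), "start")
  out$truncated <- vapply(pep, `[[`, logical(1), "truncated")
  out
}

#' Design the synthesis peptide covering a motif core
#'
#' A window of `length` residues centered on the core's midpoint (ties
#' broken toward the N-terminus) so that the designed peptide carries the
#' core flanked symmetrically by native context. Windows running past a
#' protein terminus are truncated (shorter peptide, flagged), never shifted.
#'
#' @param sequence Parent protein sequence.
#' @param core_start,core_end 1-based inclusive core coordinates.
#' @param length Target peptide length (default 15).
#' @return List: `peptide`, `start` (1-based position of the peptide in the
#'   protein), `truncated`.
#' @export
design_peptide <- function(sequence, core_start, core_end, length = 15L) {
  n <- nchar(sequence)
  stopifnot(core_start >= 1L, core_end <= n, core_start <= core_end)
  core_len <- core_end - core_start + 1L
  if (core_len > length) stop("core longer than the designed peptide length")
  mid <- core_start + (core_len - 1L) %/% 2L   # tie toward the N-terminus
  want_start <- mid - (length %/% 2L)          # core midpoint sits at peptide position 8 for a 15-mer
  want_end <- want_start + length - 1L
  s <- max(1L, want_start)
  e <- min(n, want_end)
  list(peptide = substring(sequence, s, e), start = as.integer(s),
       truncated = (s != want_start) || (e != want_end))
}

#' Expected PRM-containing partner count under random occurrence
#'
#' Given the baseline fraction of proteome proteins that carry PxxP motifs,
#' the number of interaction partners expected to contain a PRM by chance is
#' `n * fraction`; the fold enrichment of an observed count is the observed
#' fraction over the baseline.
#'
#' @param n_partners Number of identified interaction partners.
#' @param proteome_prm_fraction Baseline fraction of PRM-containing proteins
#'   in the proteome (e.g. ~5,000 of ~20,000 = 0.25).
#' @param observed Observed number of PRM-containing partners (optional).
#' @return List: `expected`, and when `observed` is given
#'   `observed_fraction` and `fold_enrichment` (`Inf`, flagged, when the
#'   baseline is 0 and something was observed).
#' @examples
#' random_prm_expectation(206, 0.25, observed = 133)
#' @export
random_prm_expectation <- function(n_partners, proteome_prm_fraction,
                                   observed = NULL) {
  stopifnot(n_partners >= 0, proteome_prm_fraction >= 0,
            proteome_prm_fraction <= 1)
  out <- list(expected = n_partners * proteome_prm_fraction)
  if (!is.null(observed)) {
    out$observed_fraction <- observed / n_partners
    if (proteome_prm_fraction == 0 && observed > 0) {
      out$fold_enrichment <- Inf
      out$undefined_baseline <- TRUE
    } else {
      out$fold_enrichment <- out$observed_fraction / proteome_prm_fraction
    }
  }
  out
}
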