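# Motif conservation: pseudocount-corrected position-specific scoring
# matrix (PSSM) built from the measured binding motifs, PSSM scoring of
# aligned ortholog motif instances normalized to the human reference, and
# per-taxonomic-level conservation calls yielding a conservation depth.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ordered from the reference outward; larger index = more distal
CONSERVATION_LEVELS <- c("Mammalia", "Vertebrata", "Eumetazoa", "Unicellular")

#' Background amino-acid frequencies
#'
#' Average amino-acid composition of the eukaryotic proteome (UniProt-style
#' averages), normalized to sum to 1. Used as the default PSSM background.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
aa_background <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.65, T = 5.36, V = 6.86,
         W = 1.10, Y = 2.92)
  f / sum(f)
}

#' Build a pseudocount log-odds PSSM from measured motifs
#'
#' With `c_ij` the count of amino acid i at position j over the `m` motif
#' sequences, `B` the pseudocount and `D_i` the background frequency of
#' amino acid i, each matrix element is the natural-log odds of the
#' pseudocount-smoothed position frequency over background:
#' `P[j, i] = log(((c_ij + B/20) / (m + B)) / D_i)`.
#' The smoothing guarantees finite scores for amino acids absent from a
#' position in the training set.
#'
#' @param motifs Character vector of >= 2 equal-length motif sequences
#'   (e.g. the measured binder 15-mers with the PxxP core at positions
#'   7-10).
#' @param background Named amino-acid frequency vector summing to 1;
#'   defaults to [aa_background()].
#' @param B Pseudocount (default 5).
#' @return Object of class `pssm`: list with `scores` (positions x 20
#'   matrix), `background`, `B`, `m`, `length`.
#' @export
build_pssm <- function(motifs, background = aa_background(), B = 5) {
  stopifnot(is.character(motifs), length(motifs) >= 2L)
  motifs <- toupper(motifs)
  wlen <- unique(nchar(motifs))
  if (length(wlen) != 1L) stop("motifs must all have the same length")
  if (any(grepl(paste0("[^", paste(AA20, collapse = ""), "]"), motifs)))
    stop("motifs contain characters outside the 20-residue alphabet")
  background <- background[AA20]
  if (any(is.na(background)) || any(background <= 0))
    stop("background must give a positive frequency for all 20 amino acids")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  m <- length(motifs)
  chars <- do.call(rbind, strsplit(motifs, ""))
  scores <- matrix(NA_real_, nrow = wlen, ncol = 20,
                   dimnames = list(seq_len(wlen), AA20))
  for (j in seq_len(wlen)) {
    counts <- table(factor(chars[, j], levels = AA20))
    smoothed <- (as.numeric(counts) + B / 20) / (m + B)
    scores[j, ] <- log(smoothed / background)
  }
  structure(list(scores = scores, background = background, B = B, m = m,
                 length = wlen), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("pssm: %d positions x 20 amino acids, m = %d motifs, pseudocount B = %g\n",
              x$length, x$m, x$B))
  invisible(x)
}

#' Raw PSSM score of a sequence window
#'
#' Sum of the per-position log-odds scores. Alignment gaps (`-`) and unknown
#' residues (`X`) contribute the position's minimum score, since a gap
#' cannot support the motif.
#'
#' @param pssm A [build_pssm()] object.
#' @param window Sequence of length `pssm$length` (may contain `-`/`X`).
#' @return Scalar raw score.
#' @export
score_window <- function(pssm, window) {
  stopifnot(inherits(pssm, "pssm"), is.character(window), length(window) == 1L)
  window <- toupper(window)
  if (nchar(window) != pssm$length)
    stop("window length must equal the PSSM length")
  chars <- strsplit(window, "")[[1]]
  s <- 0
  for (j in seq_len(pssm$length)) {
    if (chars[j] %in% AA20) s <- s + pssm$scores[j, chars[j]]
    else s <- s + min(pssm$scores[j, ])
  }
  s
}

#' Ortholog motif score normalized to the human reference
#'
#' Ratio of the ortholog window's raw PSSM score to the human reference
#' window's score. The human window itself scores 1. A non-positive human
#' reference score makes the ratio uninterpretable and is flagged undefined
#' (`NA`).
#'
#' @param pssm A `pssm`.
#' @param ortholog_window,human_window Aligned motif windows.
#' @return Scalar normalized score, or `NA` when undefined.
#' @export
normalized_score <- function(pssm, ortholog_window, human_window) {
  hs <- score_window(pssm, human_window)
  if (hs <= 0) return(NA_real_)
  score_window(pssm, ortholog_window) / hs
}

#' Per-level conservation scores and conservation depth of a motif
#'
#' For each taxonomic level (Mammalia, Vertebrata, Eumetazoa, Unicellular
#' eukaryotes, ordered outward from the human reference), the level score
#' is the mean normalized PSSM score of the level's ortholog motif
#' instances. A level with fewer than `min_orthologs` sequences is flagged
#' insufficient and not scored. The motif counts as conserved at a level
#' when the level score exceeds `threshold`; the conservation depth is the
#' most distal conserved level, or `"human-only"` when no level is
#' conserved or scorable.
#'
#' @param orthologs data.frame with columns `level` (one of the four level
#'   names) and `window` (aligned motif instance, gaps allowed).
#' @param human_window The reference (human) motif window.
#' @param pssm A `pssm`.
#' @param min_orthologs Minimum sequences per level (default 3).
#' @param threshold Conservation threshold on the level score (default 0.5).
#' @return List: `levels` (data.frame `level`, `n`, `score`, `status` in
#'   conserved/not_conserved/insufficient), `depth`, and `undefined = TRUE`
#'   with `depth = NA` when the human reference score is non-positive.
#' @export
conservation_depth <- function(orthologs, human_window, pssm,
                               min_orthologs = 3L, threshold = 0.5) {
  stopifnot(all(c("level", "window") %in% names(orthologs)))
  if (!all(orthologs$level %in% CONSERVATION_LEVELS))
    stop("levels must be among: ", paste(CONSERVATION_LEVELS, collapse = ", "))
  hs <- score_window(pssm, human_window)
  tab <- data.frame(level = CONSERVATION_LEVELS,
                    n = NA_integer_, score = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  if (hs <= 0) {
    tab$status <- "undefined"
    return(list(levels = tab, depth = NA_character_, undefined = TRUE))
  }
  for (k in seq_along(CONSERVATION_LEVELS)) {
    w <- orthologs$window[orthologs$level == CONSERVATION_LEVELS[k]]
    tab$n[k] <- length(w)
    if (length(w) < min_orthologs) {
      tab$status[k] <- "insufficient"
      next
    }
    sc <- vapply(w, function(x) score_window(pssm, x), numeric(1)) / hs
    tab$score[k] <- mean(sc)
    tab$status[k] <- if (tab$score[k] > threshold) "conserved" else "not_conserved"
  }
  conserved <- which(tab$status == "conserved")
  depth <- if (length(conserved)) tab$level[max(conserved)] else "human-only"
  list(levels = tab, depth = depth, undefined = FALSE)
}
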