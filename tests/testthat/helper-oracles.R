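# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the PRM oracle enumerates every window with
# anchored regexes, and profile fixtures are built by hand.

# exhaustive sliding-window PRM scan: tests every 6-mer and 7-mer against
# the anchored class consensus
oracle_scan <- function(sequence, disorder_mask = NULL,
                        require_disorder = FALSE) {
  n <- nchar(sequence)
  hits <- list()
  specs <- list(list(class_id = 1L, w = 7L, re = "^[RK]..P..P$"),
                list(class_id = 2L, w = 6L, re = "^P..P.[RK]$"))
  for (sp in specs) {
    if (n < sp$w) next
    for (s in seq_len(n - sp$w + 1L)) {
      win <- substr(sequence, s, s + sp$w - 1L)
      if (!grepl(sp$re, win)) next
      if (require_disorder && !all(disorder_mask[s:(s + sp$w - 1L)])) next
      hits[[length(hits) + 1L]] <- data.frame(class_id = sp$class_id,
                                              start = s)
    }
  }
  if (!length(hits))
    return(data.frame(class_id = integer(0), start = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$start, out$class_id), , drop = FALSE]
}

random_aa_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# uncensored affinity profile with random pK values above the detection
# threshold, for metric-axiom checks
random_uncensored_profile <- function(n_dims, dpk = 3.7, id = "x") {
  affinity_profile(sprintf("pep%03d", seq_len(n_dims)),
                   stats::runif(n_dims, dpk + 0.1, 7),
                   rep(FALSE, n_dims), dpk, bait_id = id)
}

# small intensity table fixture built by hand
toy_table <- function(values, n_bait, n_control) {
  cols <- c(paste0("b", seq_len(n_bait)), paste0("c", seq_len(n_control)))
  colnames(values) <- cols
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  intensity_table(values, data.frame(
    sample_id = cols,
    role = rep(c("bait", "control"), c(n_bait, n_control)),
    replicate = c(seq_len(n_bait), seq_len(n_control)),
    stringsAsFactors = FALSE))
}

# A synthetic PRM family for conservation tests: a class-2-like 15-mer
# frame with P at core positions 7 and 10 and, at every other position, a
# positional preference (60% mass on three preferred residues, 40%
# background), emulating that measured binder motifs share sequence
# preferences beyond the consensus core. Returns a sampling function; the
# human reference is drawn from the same family the PSSM is trained on,
# as in the study where the scored references are the training motifs.
make_prm_family <- function() {
  aa <- names(affinomap::aa_background())
  bg <- affinomap::aa_background()
  prefs <- lapply(1:15, function(j) {
    if (j %in% c(7, 10)) {
      p <- setNames(rep(0, 20), aa); p["P"] <- 1; return(p)
    }
    fav <- sample(aa, 3)
    p <- 0.4 * bg
    p[fav] <- p[fav] + 0.6 / 3
    p / sum(p)
  })
  function() {
    paste(vapply(prefs, function(p) sample(aa, 1, prob = p), character(1)),
          collapse = "")
  }
}
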