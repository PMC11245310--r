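# Plain-text readers and writers for every format the pipeline consumes or
# emits: FASTA (via Biostrings), TSV tables with a header row and empty
# cells for missing values, per-residue disorder masks (long or interval
# form), intensity tables with a companion sample sheet, affinity profiles
# and depletion results.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped). An empty file yields an
#'   empty vector, not an error.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output file; sequences are wrapped at 60 columns.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path,
                              width = 60L)
  invisible(path)
}

#' Read a TSV table with required columns
#'
#' Header row required; empty cells (not `.`) encode missing values.
#'
#' @param path TSV file.
#' @param required Character vector of column names that must be present.
#' @return data.frame.
#' @export
read_table_tsv <- function(path, required = character(0)) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = "")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  d
}

#' Write a data.frame as TSV
#'
#' @param d data.frame; `NA` written as empty cells.
#' @param path Output file.
#' @export
write_table_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read an intensity table plus its sample sheet
#'
#' @param values_path TSV whose first column is the protein id and remaining
#'   columns are samples; empty cells are missing measurements.
#' @param samples_path TSV sample sheet with columns `sample_id`, `role`,
#'   `replicate`.
#' @return An [intensity_table()].
#' @export
read_intensity_table <- function(values_path, samples_path) {
  d <- read_table_tsv(values_path)
  samples <- read_table_tsv(samples_path,
                            c("sample_id", "role", "replicate"))
  ids <- as.character(d[[1]])
  v <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- ids
  intensity_table(v[, as.character(samples$sample_id), drop = FALSE], samples)
}

#' Write an intensity table and its sample sheet
#'
#' @param table An [intensity_table()].
#' @param values_path,samples_path Output TSV paths.
#' @export
write_intensity_table <- function(table, values_path, samples_path) {
  stopifnot(inherits(table, "intensity_table"))
  d <- data.frame(protein_id = rownames(table$values),
                  table$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write_table_tsv(d, values_path)
  write_table_tsv(table$samples, samples_path)
  invisible(values_path)
}

#' Read per-residue disorder masks
#'
#' Accepts either the long form (`protein_id`, `position`, `disordered` in
#' 0/1) or the interval form (`protein_id`, `start`, `end`, 1-based
#' inclusive), detected from the header.
#'
#' @param path TSV file.
#' @param lengths Named integer vector of protein lengths (required for the
#'   interval form; optional check for the long form).
#' @return Named list of logical masks.
#' @export
read_disorder_masks <- function(path, lengths = NULL) {
  d <- read_table_tsv(path)
  if (all(c("protein_id", "position", "disordered") %in% names(d))) {
    out <- lapply(split(d, d$protein_id), function(x) {
      n <- if (!is.null(lengths)) lengths[[x$protein_id[1]]] else max(x$position)
      mask <- rep(FALSE, n)
      mask[x$position[x$disordered == 1]] <- TRUE
      mask
    })
  } else if (all(c("protein_id", "start", "end") %in% names(d))) {
    if (is.null(lengths))
      stop("interval-form disorder masks need protein lengths")
    out <- lapply(split(d, d$protein_id), function(x) {
      mask <- rep(FALSE, lengths[[x$protein_id[1]]])
      for (i in seq_len(nrow(x))) mask[x$start[i]:x$end[i]] <- TRUE
      mask
    })
  } else {
    stop("disorder mask TSV must have columns (protein_id, position, disordered) or (protein_id, start, end)")
  }
  out
}

#' Write per-residue disorder masks (long form)
#'
#' @param masks Named list of logical vectors.
#' @param path Output TSV.
#' @export
write_disorder_masks <- function(masks, path) {
  d <- do.call(rbind, lapply(names(masks), function(id) {
    data.frame(protein_id = id, position = seq_along(masks[[id]]),
               disordered = as.integer(masks[[id]]),
               stringsAsFactors = FALSE)
  }))
  write_table_tsv(d, path)
}

#' Write an affinity profile as TSV
#'
#' Bait metadata (`bait_id`, `bait_conc`, `detection_pk`) is stored in
#' `#`-prefixed header comment lines so the profile round-trips.
#'
#' @param profile An `affinity_profile`.
#' @param path Output TSV.
#' @export
write_affinity_profile <- function(profile, path) {
  stopifnot(inherits(profile, "affinity_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bait_id=%s", attr(profile, "bait_id")), con)
  writeLines(sprintf("# bait_conc=%.10g", attr(profile, "bait_conc")), con)
  writeLines(sprintf("# detection_pk=%.10g", attr(profile, "detection_pk")), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE)
  invisible(path)
}

#' Read an affinity profile written by [write_affinity_profile()]
#'
#' @param path TSV file.
#' @return An `affinity_profile`.
#' @export
read_affinity_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- function(key, cast = identity) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop("profile header missing ", key)
    cast(sub(paste0("^# ", key, "="), "", ln[1]))
  }
  d <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                         sep = "\t", stringsAsFactors = FALSE)
  prof <- affinity_profile(d$peptide_id, d$pk, as.logical(d$censored),
                           meta("detection_pk", as.numeric),
                           bait_id = meta("bait_id"),
                           bait_conc = meta("bait_conc", as.numeric))
  if ("measured" %in% names(d)) prof$measured <- as.logical(d$measured)
  prof
}

#' Write depletion results as TSV
#'
#' @param results A `depletion_results` data.frame.
#' @param path Output TSV.
#' @export
write_depletion_results <- function(results, path) {
  write_table_tsv(as.data.frame(results), path)
}
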