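#' Build a peptide map from residue ranges
#'
#' Validates 1-based inclusive residue ranges against the construct,
#' removes duplicate `(start, end)` pairs, sorts by `(start, end)`, and
#' fills in each peptide's sequence and exchange-observable amide count
#' (`n_max`, see [count_exchangeable_amides()]).
#'
#' @param protein A [protein_sequence()].
#' @param ranges Two-column matrix or data frame of `(start, end)` pairs
#'   (1-based inclusive); may be empty.
#' @return An object of class `peptide_map`: list with `protein` and
#'   `peptides` (data frame with columns `start`, `end`, `sequence`,
#'   `n_max`).
#' @examples
#' p <- protein_sequence("demo", "GFLKAMPQRS")
#' build_peptide_map(p, cbind(c(1, 4), c(5, 9)))
#' @export
build_peptide_map <- function(protein, ranges) {
  stopifnot(inherits(protein, "protein_sequence"))
  ranges <- as.matrix(ranges)
  if (length(ranges) == 0L) {
    peptides <- data.frame(start = integer(), end = integer(),
                           sequence = character(), n_max = integer(),
                           stringsAsFactors = FALSE)
    return(structure(list(protein = protein, peptides = peptides),
                     class = "peptide_map"))
  }
  if (ncol(ranges) != 2L) stop("ranges must have two columns (start, end)")
  start <- as.integer(ranges[, 1L]); end <- as.integer(ranges[, 2L])
  bad <- which(!(start >= 1L & start <= end & end <= protein$length))
  if (length(bad) > 0L)
    stop("peptide range(s) out of bounds for protein of length ",
         protein$length, ": ",
         paste(sprintf("(%d,%d)", start[bad], end[bad]), collapse = " "),
         call. = FALSE)
  keep <- !duplicated(paste(start, end))
  start <- start[keep]; end <- end[keep]
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  sequence <- substring(protein$seq, start, end)
  n_max <- vapply(sequence, count_exchangeable_amides, integer(1L),
                  USE.NAMES = FALSE)
  peptides <- data.frame(start = start, end = end, sequence = sequence,
                         n_max = n_max, stringsAsFactors = FALSE)
  structure(list(protein = protein, peptides = peptides),
            class = "peptide_map")
}

#' @export
print.peptide_map <- function(x, ...) {
  cat("Peptide map: ", nrow(x$peptides), " peptides on '",
      x$protein$id, "' (", x$protein$length, " residues)\n", sep = "")
  invisible(x)
}

#' Coverage and redundancy statistics of a peptide map
#'
#' Sequence coverage counts every residue inside a covered range
#' (including peptide first residues and prolines); exchangeability
#' filtering applies to uptake, not to coverage, matching how HDX
#' software reports coverage tables. Redundancy is the sum of peptide
#' lengths divided by the number of covered residues.
#'
#' @param map A `peptide_map`.
#' @return Object of class `coverage_stats`: list with
#'   `coverage_percent`, `n_peptides`, `mean_peptide_length`,
#'   `redundancy`, `n_uncovered_residues`, `covered_positions`.
#' @examples
#' p <- protein_sequence("demo", "GFLKAMPQRS")
#' coverage_stats(build_peptide_map(p, cbind(c(1, 4), c(5, 9))))
#' @export
coverage_stats <- function(map) {
  stopifnot(inherits(map, "peptide_map"))
  L <- map$protein$length
  pep <- map$peptides
  if (nrow(pep) == 0L) {
    covered <- integer()
  } else {
    covered <- sort(unique(unlist(
      mapply(seq.int, pep$start, pep$end, SIMPLIFY = FALSE))))
  }
  ncov <- length(covered)
  lens <- if (nrow(pep)) pep$end - pep$start + 1L else integer()
  structure(list(
    coverage_percent = 100 * ncov / L,
    n_peptides = nrow(pep),
    mean_peptide_length = if (nrow(pep)) mean(lens) else NA_real_,
    redundancy = if (ncov > 0L) sum(lens) / ncov else NA_real_,
    n_uncovered_residues = L - ncov,
    covered_positions = covered
  ), class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf(
    "Coverage: %.1f%% (%d peptides, mean length %.1f, redundancy %.2f, %d uncovered residues)\n",
    x$coverage_percent, x$n_peptides,
    if (is.na(x$mean_peptide_length)) 0 else x$mean_peptide_length,
    if (is.na(x$redundancy)) 0 else x$redundancy,
    x$n_uncovered_residues))
  invisible(x)
}

#' Read a confirmed-peptide pool CSV
#'
#' Expects header `protein_id,start,end,sequence` (comma-separated,
#' UTF-8). Each row's sequence must match the construct subsequence at
#' `[start, end]`.
#'
#' @param path CSV path.
#' @param protein The construct [protein_sequence()] to validate against.
#' @return A `peptide_map`.
#' @export
read_peptide_csv <- function(path, protein) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end", "sequence")
  if (!identical(names(df)[seq_along(need)], need))
    stop("peptide CSV must have header ", paste(need, collapse = ","),
         call. = FALSE)
  map <- build_peptide_map(protein, df[, c("start", "end")])
  expect <- substring(protein$seq, df$start, df$end)
  bad <- which(toupper(df$sequence) != expect)
  if (length(bad) > 0L)
    stop("peptide sequence mismatch vs construct at CSV line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  map
}

#' Amide-bearing positions of a peptide on the construct
#'
#' Positions `start+1 ... end` excluding prolines: the residues whose
#' backbone amide contributes observable deuterium to the peptide.
#'
#' @param protein A `protein_sequence`.
#' @param start,end 1-based inclusive peptide range.
#' @return Integer vector of construct positions (possibly empty).
#' @export
amide_positions <- function(protein, start, end) {
  if (end <= start) return(integer())
  pos <- (start + 1L):end
  pos[.residues_at(protein, pos) != "P"]
}
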