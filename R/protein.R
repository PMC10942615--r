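#' @keywords internal
"_PACKAGE"

## 20-letter amino-acid alphabet used for all sequence validation
.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_aa <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), .AA_ALPHABET)
  if (length(bad) > 0L)
    stop("invalid residue code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(chars)
}

#' Protein sequence with display-numbering offset
#'
#' Container for the analyzed construct (including any affinity tag).
#' Residues are stored with 1-based internal numbering; published residue
#' numbers are recovered as `internal position + numbering_offset`, which
#' accommodates conventions such as subtracting one position for a
#' processed initiator methionine.
#'
#' @param id Single identifier string.
#' @param seq Amino-acid sequence (one string, 20-letter alphabet, upper
#'   or lower case).
#' @param numbering_offset Integer added to internal positions for display
#'   (default 0; use -1 when position 1 is a processed Met).
#' @return An object of class `protein_sequence`: list with elements
#'   `id`, `seq`, `length`, `numbering_offset`.
#' @examples
#' p <- protein_sequence("demo", "GFLKAMPQRS")
#' p$length
#' @export
protein_sequence <- function(id, seq, numbering_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  seq <- toupper(seq)
  .check_aa(seq)
  structure(list(id = id, seq = seq, length = nchar(seq),
                 numbering_offset = as.integer(numbering_offset)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("Protein sequence '", x$id, "': ", x$length, " residues",
      if (x$numbering_offset != 0L)
        paste0(" (display offset ", x$numbering_offset, ")"), "\n", sep = "")
  invisible(x)
}

#' Residue characters of a protein at given positions
#' @noRd
.residues_at <- function(protein, positions) {
  substring(protein$seq, positions, positions)
}

#' Count exchange-observable backbone amides of a peptide
#'
#' The theoretic maximum deuterium uptake of a peptide counts one backbone
#' amide per residue except the first residue (its amide deuterium
#' back-exchanges too fast to observe) and prolines after the first
#' position (no backbone amide hydrogen): `L - 1 - #internal prolines`.
#'
#' @param peptide_sequence Peptide sequence string.
#' @return Integer count (the peptide's N_max, in Da-equivalents at full
#'   labeling).
#' @examples
#' count_exchangeable_amides("GFLKA")  # 4
#' count_exchangeable_amides("GPLPA")  # 2
#' @export
count_exchangeable_amides <- function(peptide_sequence) {
  stopifnot(is.character(peptide_sequence), length(peptide_sequence) == 1L,
            nchar(peptide_sequence) >= 1L)
  chars <- .check_aa(toupper(peptide_sequence))
  L <- length(chars)
  P <- if (L > 1L) sum(chars[2:L] == "P") else 0L
  as.integer(L - 1L - P)
}

#' Read a single-record FASTA file as a protein sequence
#'
#' The construct is read exactly as deposited; affinity tags present in
#' the FASTA record are part of the analyzed sequence.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @param numbering_offset Display-numbering offset (see
#'   [protein_sequence()]).
#' @return A `protein_sequence`.
#' @export
read_protein_fasta <- function(path, numbering_offset = 0L) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) != 1L)
    stop("expected exactly one FASTA record, found ", length(recs),
         call. = FALSE)
  protein_sequence(id = names(recs)[1L], seq = as.character(recs[[1L]]),
                   numbering_offset = numbering_offset)
}

#' Write a protein sequence to FASTA
#' @param protein A `protein_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(protein, path) {
  seqinr::write.fasta(sequences = protein$seq, names = protein$id,
                      file.out = path, as.string = TRUE)
  invisible(path)
}
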