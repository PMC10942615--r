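#' Map peptide-level significance onto residues
#'
#' A residue's contributing peptides are those whose amide-bearing
#' positions (start+1 ... end, excluding prolines) include it; a
#' peptide's first residue and prolines receive no status from that
#' peptide. Status is decided per residue from the contributing
#' peptides' significance flags at one timepoint:
#' \describe{
#'   \item{any}{one significant contributor suffices (default); when
#'     contributors disagree in direction, protection wins and the
#'     conflict is reported via a message.}
#'   \item{majority}{more than half of the contributors must be
#'     significant; direction by majority among the significant ones,
#'     protection winning ties.}
#'   \item{all}{every contributor must be significant (direction as for
#'     majority).}
#' }
#' Residues with contributors but no qualifying significance are
#' `insignificant`; residues without any contributing amide are
#' `uncovered`.
#'
#' @param fit An [hdx_hybrid()] fit (or a data frame of its `$deltas`
#'   shape with `start`, `end`, `timepoint_s`, `delta`, `significant`,
#'   `direction`).
#' @param map A `peptide_map` for the same peptides.
#' @param timepoint Labeling time (s) whose flags are mapped.
#' @param rule Consensus rule: `"any"`, `"majority"` or `"all"`.
#' @return Object of class `residue_status_map`: data frame with columns
#'   `position`, `display_position`, `status`, `n_peptides`,
#'   `mean_delta_da`; attributes `timepoint` and `rule`.
#' @export
map_significance_to_residues <- function(fit, map, timepoint = 3000,
                                         rule = c("any", "majority", "all")) {
  rule <- match.arg(rule)
  deltas <- if (inherits(fit, "hdx_hybrid")) fit$deltas else fit
  stopifnot(inherits(map, "peptide_map"),
            all(c("start", "end", "timepoint_s", "delta", "significant",
                  "direction") %in% names(deltas)))
  d <- deltas[deltas$timepoint_s == timepoint, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no cells at timepoint ", timepoint, " s", call. = FALSE)
  protein <- map$protein
  L <- protein$length

  n_pep <- integer(L)
  n_sig <- integer(L)
  n_prot <- integer(L)
  n_dep <- integer(L)
  sum_delta <- numeric(L)
  for (i in seq_len(nrow(d))) {
    pos <- amide_positions(protein, d$start[i], d$end[i])
    if (length(pos) == 0L) next
    n_pep[pos] <- n_pep[pos] + 1L
    sum_delta[pos] <- sum_delta[pos] + d$delta[i]
    if (d$significant[i]) {
      n_sig[pos] <- n_sig[pos] + 1L
      if (d$direction[i] == "protected") n_prot[pos] <- n_prot[pos] + 1L
      else n_dep[pos] <- n_dep[pos] + 1L
    }
  }

  qualifies <- switch(rule,
    any = n_sig >= 1L,
    majority = n_sig > n_pep / 2,
    all = n_pep > 0L & n_sig == n_pep)
  status <- rep("uncovered", L)
  status[n_pep > 0L] <- "insignificant"
  ## protection wins direction ties/conflicts
  status[qualifies & n_prot >= n_dep] <- "protected"
  status[qualifies & n_prot < n_dep] <- "deprotected"
  conflicts <- sum(qualifies & n_prot > 0L & n_dep > 0L)
  if (conflicts > 0L)
    message(conflicts,
            " residue(s) with conflicting directions resolved toward protection")

  out <- data.frame(
    position = seq_len(L),
    display_position = seq_len(L) + protein$numbering_offset,
    status = status, n_peptides = n_pep,
    mean_delta_da = ifelse(n_pep > 0L, sum_delta / pmax(n_pep, 1L), NA_real_),
    stringsAsFactors = FALSE)
  structure(out, class = c("residue_status_map", "data.frame"),
            timepoint = timepoint, rule = rule)
}

#' Residue counts per consensus status
#'
#' @param statusmap A [map_significance_to_residues()] result.
#' @return Named integer vector over
#'   `protected, deprotected, insignificant, uncovered`; sums to the
#'   protein length.
#' @export
position_counts <- function(statusmap) {
  stopifnot(inherits(statusmap, "residue_status_map"))
  lv <- c("protected", "deprotected", "insignificant", "uncovered")
  counts <- table(factor(statusmap$status, levels = lv))
  stats::setNames(as.integer(counts), lv)
}

#' Write the per-residue consensus table as TSV
#'
#' Columns: `position,display_position,status,n_peptides,mean_delta_da`
#' (mean delta printed with 4 decimals, `NA` for uncovered residues).
#'
#' @param statusmap A `residue_status_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_residue_tsv <- function(statusmap, path) {
  stopifnot(inherits(statusmap, "residue_status_map"))
  out <- statusmap
  out$mean_delta_da <- ifelse(is.na(out$mean_delta_da), "NA",
                              sprintf("%.4f", out$mean_delta_da))
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Annotate a structure model with per-residue consensus values
#'
#' Writes a per-residue value into the B-factor column of a PDB file.
#' With `value = "mean_delta"`, residues with significant consensus
#' status carry their mean differential uptake (Da) and other matched
#' residues carry 0; with `value = "status_code"`, codes are protected
#' -1, deprotected +1, insignificant 0, uncovered -2. Structure residue
#' numbers are matched against display positions (construct position +
#' numbering offset); unmatched structure residues get the sentinel -99.
#'
#' @param statusmap A `residue_status_map`.
#' @param structure_in Input PDB path.
#' @param structure_out Output PDB path.
#' @param value `"mean_delta"` (default) or `"status_code"`.
#' @return Invisibly, the named vector of values written (one per
#'   matched display position).
#' @export
write_structure_annotation <- function(statusmap, structure_in,
                                       structure_out,
                                       value = c("mean_delta", "status_code")) {
  stopifnot(inherits(statusmap, "residue_status_map"))
  value <- match.arg(value)
  pdb <- bio3d::read.pdb(structure_in)
  sig <- statusmap$status %in% c("protected", "deprotected")
  per_res <- switch(value,
    mean_delta = ifelse(sig, statusmap$mean_delta_da, 0),
    status_code = c(protected = -1, deprotected = 1, insignificant = 0,
                    uncovered = -2)[statusmap$status])
  names(per_res) <- statusmap$display_position
  idx <- match(pdb$atom$resno, statusmap$display_position)
  if (all(is.na(idx)))
    stop("no structure residue matched the construct numbering",
         call. = FALSE)
  b <- ifelse(is.na(idx), -99, per_res[idx])
  pdb$atom$b <- round(b, 2)
  bio3d::write.pdb(pdb, file = structure_out)
  invisible(stats::setNames(unname(per_res), names(per_res)))
}
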