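#' Cutoffs for dynamic-group classification
#'
#' Operational parameters, in percent of the theoretic maximum uptake
#' (D%), for sorting peptides into four dynamic groups and flagging fast
#' exchangers. Boundary comparisons on the fast-exchanger flag are
#' strict.
#'
#' @param fast_d_percent_at_30s Fast-exchanger cutoff on the free-state
#'   D% at the first timepoint (default 5, flagged when strictly above).
#' @param group3_d_percent Group III floor: both states at or above this
#'   D% at the first timepoint (default 60).
#' @param group4_band Group IV free-state band across all timepoints
#'   (default `c(40, 50)`).
#' @param group1_bound_max_d_percent Group I ceiling on the bound-state
#'   D% at all timepoints (default 10).
#' @return List of class `classification_params`.
#' @export
classification_params <- function(fast_d_percent_at_30s = 5,
                                  group3_d_percent = 60,
                                  group4_band = c(40, 50),
                                  group1_bound_max_d_percent = 10) {
  p <- list(fast_d_percent_at_30s = fast_d_percent_at_30s,
            group3_d_percent = group3_d_percent,
            group4_band = group4_band,
            group1_bound_max_d_percent = group1_bound_max_d_percent)
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 100),
            group4_band[1L] <= group4_band[2L])
  structure(p, class = "classification_params")
}

## per-peptide D% curves (rows: peptides, cols: timepoints) plus flags,
## assembled from an hdx_hybrid fit
.classification_table <- function(fit) {
  d <- fit$deltas
  tps <- sort(unique(d$timepoint_s))
  pep <- unique(d[, c("peptide_index", "start", "end", "sequence")])
  pep <- pep[order(pep$peptide_index), , drop = FALSE]
  n_max <- vapply(pep$sequence, count_exchangeable_amides, integer(1L),
                  USE.NAMES = FALSE)
  get <- function(col) {
    m <- matrix(NA_real_, nrow(pep), length(tps))
    idx <- cbind(d$peptide_index, match(d$timepoint_s, tps))
    m[idx] <- d[[col]]
    m
  }
  mf <- get("mean_free"); mb <- get("mean_bound")
  list(pep = pep, tps = tps, n_max = n_max,
       dpct_free = 100 * mf / n_max, dpct_bound = 100 * mb / n_max,
       sig = get("significant") > 0, delta = get("delta"))
}

#' Classify peptides into dynamic groups
#'
#' Sorts each peptide into one of four groups using its D% uptake curves
#' in both states and its hybrid significance flags, with precedence
#' III, IV, I, II (absolute-uptake bands are more specific than
#' protection behavior):
#' \describe{
#'   \item{III}{high exchangers: both states at or above
#'     `group3_d_percent` D% already at the first timepoint.}
#'   \item{IV}{medium-level free-state uptake inside `group4_band` at
#'     all timepoints with significant deprotection at >= 1 timepoint.}
#'   \item{I}{significant protection at all timepoints with the bound
#'     state held at or below `group1_bound_max_d_percent` D%
#'     throughout (binding fully suppresses exchange).}
#'   \item{II}{significant protection at >= 1 timepoint with strictly
#'     rising free-state uptake.}
#' }
#' Peptides matching none of the rules are `unassigned`. Peptides with
#' `n_max` 0 (no observable amide) are `unassigned`.
#'
#' @param fit An [hdx_hybrid()] fit covering all timepoints.
#' @param params A [classification_params()] list.
#' @return Data frame with columns `start`, `end`, `sequence`, `group`
#'   (factor: I, II, III, IV, unassigned) and `fast_exchanger` (logical,
#'   see [flag_fast_exchangers()]).
#' @export
classify_peptides <- function(fit, params = classification_params()) {
  stopifnot(inherits(fit, "hdx_hybrid"),
            inherits(params, "classification_params"))
  ct <- .classification_table(fit)
  if (anyNA(ct$dpct_free[ct$n_max > 0, ]))
    stop("missing timepoints: every peptide needs D% at all timepoints",
         call. = FALSE)
  n <- nrow(ct$pep)
  group <- rep("unassigned", n)
  prot <- ct$sig & ct$delta < 0
  dep <- ct$sig & ct$delta > 0
  for (i in seq_len(n)) {
    if (ct$n_max[i] == 0L) next
    f <- ct$dpct_free[i, ]; b <- ct$dpct_bound[i, ]
    if (f[1L] >= params$group3_d_percent && b[1L] >= params$group3_d_percent) {
      group[i] <- "III"
    } else if (all(f >= params$group4_band[1L] & f <= params$group4_band[2L]) &&
               any(dep[i, ])) {
      group[i] <- "IV"
    } else if (all(prot[i, ]) &&
               all(b <= params$group1_bound_max_d_percent)) {
      group[i] <- "I"
    } else if (any(prot[i, ]) && all(diff(f) > 0)) {
      group[i] <- "II"
    }
  }
  data.frame(start = ct$pep$start, end = ct$pep$end,
             sequence = ct$pep$sequence,
             group = factor(group, levels = c("I", "II", "III", "IV",
                                              "unassigned")),
             fast_exchanger = flag_fast_exchangers(fit, params),
             stringsAsFactors = FALSE)
}

#' Flag fast-exchanging peptides
#'
#' A peptide is a fast exchanger when its free-state D% at the first
#' (shortest) timepoint is strictly above the cutoff (default 5%).
#'
#' @param fit An [hdx_hybrid()] fit.
#' @param params A [classification_params()] list.
#' @return Logical vector, one flag per peptide in peptide-index order.
#' @export
flag_fast_exchangers <- function(fit, params = classification_params()) {
  stopifnot(inherits(fit, "hdx_hybrid"))
  ct <- .classification_table(fit)
  flags <- ct$dpct_free[, 1L] > params$fast_d_percent_at_30s
  flags[ct$n_max == 0L] <- FALSE
  unname(flags)
}

#' Write the classification table as CSV
#'
#' Columns: `start,end,group,fast_exchanger`.
#'
#' @param classification Result of [classify_peptides()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_classification_csv <- function(classification, path) {
  out <- classification[, c("start", "end", "group", "fast_exchanger")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
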