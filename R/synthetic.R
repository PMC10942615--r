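#' Labeling-experiment design
#'
#' Defaults follow the triplicate 30/300/3000 s design of a typical
#' automated differential HDX-MS comparability study.
#'
#' @param timepoints Labeling times (s), strictly increasing, positive.
#' @param n_replicates Technical replicates per state, >= 2.
#' @param noise_sd Replicate standard deviation of peptide uptake (Da).
#'   The default 0.13 Da places the 3-replicate global significance
#'   threshold on the scale seen in real membrane-protein datasets.
#' @param states Two state labels, reference first.
#' @param seed Integer seed for table generation.
#' @return List of class `experiment_design`.
#' @export
experiment_design <- function(timepoints = c(30, 300, 3000),
                              n_replicates = 3L,
                              noise_sd = 0.13,
                              states = c("free", "bound"),
                              seed = 1L) {
  stopifnot(length(timepoints) >= 1L, all(timepoints > 0),
            all(diff(timepoints) > 0), n_replicates >= 2L, noise_sd >= 0,
            length(states) == 2L, states[1L] != states[2L])
  structure(list(timepoints = as.numeric(timepoints),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, states = as.character(states),
                 seed = as.integer(seed)),
            class = "experiment_design")
}

## random amino-acid sequence; proline kept at a modest frequency so that
## amide bookkeeping is exercised without dominating the sequence
.random_protein <- function(length) {
  weights <- rep(1, 20)
  weights[match("P", .AA_ALPHABET)] <- 0.9
  paste(sample(.AA_ALPHABET, length, replace = TRUE, prob = weights),
        collapse = "")
}

#' Simulate a ground-truth two-state exchange system
#'
#' Draws per-residue intrinsic exchange rates and protection factors for
#' a reference ("free") state, then derives a "bound" state by adding a
#' protection-factor increment on one contiguous footprint and removing
#' protection on a small patch near the N-terminus — the
#' protection-dominant pattern with slight N-terminal deprotection that a
#' conformation-trapping binder imprints on a transporter. Residue 1 and
#' prolines carry no exchange parameters (NA).
#'
#' @param length Protein length (>= 20) when `seq` is NULL.
#' @param seq Optional explicit sequence (overrides `length`).
#' @param log10_kint_range Range for log10 intrinsic rate (1/s);
#'   default `c(-3, 0)`.
#' @param log10_pf_range Range for log10 protection factor in the free
#'   state; default `c(0.5, 3)`.
#' @param delta_log10_pf Protection increment (log10) applied to the
#'   footprint in the bound state, and subtracted (floored at 0) on the
#'   deprotected patch; default 1.5.
#' @param footprint_fraction Fraction of residues in the contiguous
#'   protected footprint; default 0.15.
#' @param deprotected_n Number of deprotected residues directly after
#'   position 1; default 3.
#' @param d2o_fraction Deuterium fraction of the labeling buffer
#'   (default 0.9, a tenfold dilution into D2O).
#' @param seed Integer seed; the same seed reproduces the system exactly.
#' @return Object of class `ground_truth_system`: list with `protein`,
#'   `k_int`, `log10_pf_free`, `log10_pf_bound`, `footprint_protected`,
#'   `footprint_deprotected`, `d2o_fraction`.
#' @export
simulate_system <- function(length = 400L, seq = NULL,
                            log10_kint_range = c(-3, 0),
                            log10_pf_range = c(0.5, 3),
                            delta_log10_pf = 1.5,
                            footprint_fraction = 0.15,
                            deprotected_n = 3L,
                            d2o_fraction = 0.9,
                            seed = 1L) {
  if (diff(log10_kint_range) < 0 || diff(log10_pf_range) < 0)
    stop("invalid distribution bounds", call. = FALSE)
  stopifnot(footprint_fraction >= 0, footprint_fraction <= 1,
            d2o_fraction > 0, d2o_fraction <= 1, delta_log10_pf >= 0)
  set.seed(seed)
  if (is.null(seq)) {
    stopifnot(length >= 20L)
    seq <- .random_protein(length)
  }
  protein <- protein_sequence("synthetic", seq)
  L <- protein$length
  if (L < 20L) stop("protein too short (length >= 20 required)", call. = FALSE)

  k_int <- 10^stats::runif(L, log10_kint_range[1L], log10_kint_range[2L])
  lpf_free <- stats::runif(L, log10_pf_range[1L], log10_pf_range[2L])
  ## no exchange parameters at position 1 or prolines
  silent <- c(1L, which(strsplit(protein$seq, "")[[1]] == "P"))
  k_int[silent] <- NA_real_
  lpf_free[silent] <- NA_real_

  dep <- if (deprotected_n > 0L) 1L + seq_len(deprotected_n) else integer()
  n_fp <- round(footprint_fraction * L)
  if (n_fp > 0L) {
    lo <- max(dep, 1L) + 2L          # keep footprint clear of the patch
    hi <- L - n_fp + 1L
    fp_start <- if (hi <= lo) lo else sample(lo:hi, 1L)
    fp <- fp_start:(fp_start + n_fp - 1L)
  } else fp <- integer()

  lpf_bound <- lpf_free
  lpf_bound[fp] <- lpf_free[fp] + delta_log10_pf
  lpf_bound[dep] <- pmax(0, lpf_free[dep] - delta_log10_pf)

  structure(list(protein = protein, k_int = k_int,
                 log10_pf_free = lpf_free, log10_pf_bound = lpf_bound,
                 footprint_protected = fp, footprint_deprotected = dep,
                 d2o_fraction = d2o_fraction),
            class = "ground_truth_system")
}

#' @export
print.ground_truth_system <- function(x, ...) {
  cat("Ground-truth system: ", x$protein$length, " residues; footprint ",
      length(x$footprint_protected), " protected / ",
      length(x$footprint_deprotected), " deprotected residues; D2O ",
      x$d2o_fraction, "\n", sep = "")
  invisible(x)
}

#' Simulate a nonspecific-digestion peptide map
#'
#' Emulates a confirmed-peptide pool from nonspecific proteolysis:
#' contiguous gap regions totalling `100 - target_coverage` percent of
#' the construct are excluded (real maps never cover everything), then
#' random overlapping peptides with lengths uniform in `length_range`
#' are drawn inside the remaining segments until the target coverage and
#' redundancy are met or a draw cap is hit.
#'
#' @param protein A [protein_sequence()].
#' @param target_coverage Target sequence coverage, percent (default 86).
#' @param target_redundancy Target sum-of-lengths / covered-residues
#'   (default 2.9).
#' @param length_range Peptide length range (default `c(5, 15)`).
#' @param seed Integer seed.
#' @param max_draws Draw cap (default 20000). If the targets are not
#'   reached, the achieved statistics are reported in a warning.
#' @return A `peptide_map`.
#' @export
simulate_digestion <- function(protein, target_coverage = 86,
                               target_redundancy = 2.9,
                               length_range = c(5L, 15L),
                               seed = 1L, max_draws = 20000L) {
  stopifnot(inherits(protein, "protein_sequence"),
            length_range[1L] <= length_range[2L],
            target_coverage > 0, target_coverage <= 100)
  set.seed(seed)
  L <- protein$length
  min_len <- as.integer(length_range[1L]); max_len <- as.integer(length_range[2L])

  ## carve out gap blocks totalling ~ (100 - target) % of the construct
  allowed <- rep(TRUE, L)
  gap_goal <- round((1 - target_coverage / 100) * L)
  placed <- 0L; attempts <- 0L
  while (placed < gap_goal && attempts < 200L) {
    attempts <- attempts + 1L
    blk <- min(sample(5:20, 1L), gap_goal - placed)
    s <- sample.int(L - blk + 1L, 1L)
    idx <- s:(s + blk - 1L)
    if (all(allowed[idx])) {
      allowed[idx] <- FALSE
      placed <- placed + blk
    }
  }

  ## allowed segments long enough to host a peptide
  r <- rle(allowed)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  ok <- r$values & r$lengths >= min_len
  seg_start <- seg_start[ok]; seg_end <- seg_end[ok]
  if (length(seg_start) == 0L)
    stop("no allowed segment can host a peptide; widen length_range",
         call. = FALSE)
  seg_len <- seg_end - seg_start + 1L

  ## tiling pass: cover each allowed segment end to end with abutting
  ## peptides of random length (last peptide right-aligned), then enrich
  ## with random overlapping peptides until the redundancy target is met
  starts <- integer(); ends <- integer()
  for (k in seq_along(seg_start)) {
    s <- seg_start[k]
    while (s <= seg_end[k]) {
      len <- sample(min_len:min(max_len, seg_len[k]), 1L)
      if (s + len - 1L > seg_end[k]) s <- seg_end[k] - len + 1L
      starts <- c(starts, s); ends <- c(ends, s + len - 1L)
      s <- s + len
    }
  }
  ncov <- sum(seg_len)
  total_len <- sum(ends - starts + 1L)
  for (i in seq_len(max_draws)) {
    if (total_len / ncov >= target_redundancy) break
    sidx <- sample.int(length(seg_start), 1L, prob = seg_len)
    len <- sample(min_len:min(max_len, seg_len[sidx]), 1L)
    s <- seg_start[sidx] + sample.int(seg_len[sidx] - len + 1L, 1L) - 1L
    e <- s + len - 1L
    if (!any(starts == s & ends == e)) {
      starts <- c(starts, s); ends <- c(ends, e)
      total_len <- total_len + len
    }
  }
  map <- build_peptide_map(protein, cbind(starts, ends))
  st <- coverage_stats(map)
  if (st$coverage_percent < target_coverage - 3 ||
      st$redundancy < target_redundancy * 0.9)
    warning(sprintf(
      "digestion targets not reached within draw cap: achieved coverage %.1f%%, redundancy %.2f",
      st$coverage_percent, st$redundancy), call. = FALSE)
  map
}

#' Simulate replicate uptake tables for both states
#'
#' For every peptide, timepoint and replicate the noise-free forward
#' uptake ([peptide_uptake()]) receives additive Gaussian replicate noise
#' and is truncated to the physical range `[0, d2o_fraction * n_max]`.
#'
#' @param truth A [simulate_system()] ground-truth system.
#' @param map A `peptide_map` on the same protein.
#' @param design An [experiment_design()].
#' @return Named list of two uptake tables (data frames in the standard
#'   dialect: `protein_id,start,end,sequence,state,timepoint_s,replicate,
#'   uptake_da`), names = `design$states`. The ground truth is attached
#'   as attribute `truth` for recovery tests.
#' @export
simulate_uptake_tables <- function(truth, map, design = experiment_design()) {
  stopifnot(inherits(truth, "ground_truth_system"),
            inherits(map, "peptide_map"),
            inherits(design, "experiment_design"))
  if (!identical(map$protein$seq, truth$protein$seq))
    stop("peptide map and ground truth use different proteins", call. = FALSE)
  set.seed(design$seed)
  pep <- map$peptides
  np <- nrow(pep); nt <- length(design$timepoints); nr <- design$n_replicates
  out <- list()
  for (state in design$states) {
    gstate <- if (state == design$states[1L]) "free" else "bound"
    ## noise-free uptake matrix, peptides x timepoints
    d0 <- t(vapply(seq_len(np), function(i)
      peptide_uptake(truth, gstate, pep$start[i], pep$end[i],
                     design$timepoints),
      numeric(nt)))
    idx <- rep(seq_len(np), each = nt * nr)
    tp <- rep(rep(design$timepoints, each = nr), times = np)
    jdx <- rep(rep(seq_len(nt), each = nr), times = np)
    u <- d0[cbind(idx, jdx)] + stats::rnorm(np * nt * nr, 0, design$noise_sd)
    cap <- truth$d2o_fraction * pep$n_max[idx]
    u <- pmin(pmax(u, 0), cap)
    out[[state]] <- data.frame(
      protein_id = truth$protein$id, start = pep$start[idx],
      end = pep$end[idx], sequence = pep$sequence[idx], state = state,
      timepoint_s = tp, replicate = rep(seq_len(nr), times = np * nt),
      uptake_da = u, stringsAsFactors = FALSE)
  }
  attr(out, "truth") <- truth
  attr(out, "design") <- design
  out
}

#' Write the per-residue ground truth as a sidecar CSV
#'
#' Columns: `residue,k_int,pf_free,pf_bound,footprint` where `footprint`
#' is `protected`, `deprotected` or empty.
#'
#' @param truth A `ground_truth_system`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(truth, path) {
  L <- truth$protein$length
  fp <- character(L)
  fp[truth$footprint_protected] <- "protected"
  fp[truth$footprint_deprotected] <- "deprotected"
  df <- data.frame(residue = seq_len(L),
                   k_int = sprintf("%.6g", truth$k_int),
                   pf_free = sprintf("%.6g", 10^truth$log10_pf_free),
                   pf_bound = sprintf("%.6g", 10^truth$log10_pf_bound),
                   footprint = fp, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
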