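# Brute-force reference implementations and tiny fixtures, independent of
# the package's own code paths.

# position-set union by direct enumeration
brute_union <- function(starts, ends) {
  pos <- integer()
  for (i in seq_along(starts)) pos <- union(pos, starts[i]:ends[i])
  sort(pos)
}

# Welch statistic from first principles
brute_welch <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  t <- (mean(y) - mean(x)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# per-position consensus mapping by direct enumeration over positions
brute_consensus <- function(protein, d, rule) {
  L <- protein$length
  chars <- strsplit(protein$seq, "")[[1]]
  status <- character(L)
  for (pos in seq_len(L)) {
    contrib <- which(d$start + 1 <= pos & pos <= d$end &
                       chars[pos] != "P")
    if (length(contrib) == 0L) { status[pos] <- "uncovered"; next }
    sig <- contrib[d$significant[contrib]]
    ok <- switch(rule,
      any = length(sig) >= 1L,
      majority = length(sig) > length(contrib) / 2,
      all = length(sig) == length(contrib))
    if (!ok) { status[pos] <- "insignificant"; next }
    np <- sum(d$direction[sig] == "protected")
    nd <- sum(d$direction[sig] == "deprotected")
    status[pos] <- if (np >= nd) "protected" else "deprotected"
  }
  status
}

# minimal CA-trace PDB text for a polyalanine chain
make_ca_pdb <- function(path, resnos) {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d      %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(resnos), resnos, seq_along(resnos) * 3.8, 0, 0)
  writeLines(c(lines, "END"), path)
  path
}

# hand-built ground-truth system with chosen per-residue kinetics
manual_truth <- function(seq, k_int, pf_free, pf_bound, d2o = 0.9) {
  protein <- protein_sequence("manual", seq)
  structure(list(protein = protein, k_int = k_int,
                 log10_pf_free = log10(pf_free),
                 log10_pf_bound = log10(pf_bound),
                 footprint_protected = integer(),
                 footprint_deprotected = integer(),
                 d2o_fraction = d2o),
            class = "ground_truth_system")
}

# small two-state uptake tables built directly from replicate values:
# reps is a list of lists reps[[pep]][[tp]] = c(free reps, bound reps)
manual_tables <- function(protein_id, peptides, timepoints, free_reps,
                          bound_reps) {
  build <- function(reps, state) {
    rows <- list()
    for (i in seq_len(nrow(peptides))) {
      for (j in seq_along(timepoints)) {
        u <- reps[[i]][[j]]
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = protein_id, start = peptides$start[i],
          end = peptides$end[i], sequence = peptides$sequence[i],
          state = state, timepoint_s = timepoints[j],
          replicate = seq_along(u), uptake_da = u,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  list(free = build(free_reps, "free"), bound = build(bound_reps, "bound"))
}
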