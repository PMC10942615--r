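.UPTAKE_COLS <- c("protein_id", "start", "end", "sequence", "state",
                  "timepoint_s", "replicate", "uptake_da")

.check_uptake_table <- function(table) {
  if (!is.data.frame(table) || !all(.UPTAKE_COLS %in% names(table)))
    stop("uptake table must contain columns ",
         paste(.UPTAKE_COLS, collapse = ","), call. = FALSE)
  invisible(table)
}

#' Read an uptake CSV
#'
#' Dialect shared by all stages (one row per peptide x state x timepoint
#' x replicate): header
#' `protein_id,start,end,sequence,state,timepoint_s,replicate,uptake_da`.
#' Malformed rows are rejected with their file line number; when a
#' construct is supplied, peptide ranges and sequences are validated
#' against it.
#'
#' @param path CSV path.
#' @param protein Optional [protein_sequence()] for validation.
#' @return Data frame in the uptake dialect.
#' @export
read_uptake_csv <- function(path, protein = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .UPTAKE_COLS))
    stop("uptake CSV must have header ", paste(.UPTAKE_COLS, collapse = ","),
         call. = FALSE)
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  bad <- !is.finite(df$start) | !is.finite(df$end) | df$end < df$start |
    df$start < 1
  if (any(bad))
    stop("malformed peptide range at line(s): ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  bad <- !is.finite(df$uptake_da) | df$uptake_da < 0
  if (any(bad))
    stop("malformed uptake at line(s): ", paste(line[bad], collapse = ", "),
         call. = FALSE)
  bad <- !is.finite(df$timepoint_s) | df$timepoint_s <= 0
  if (any(bad))
    stop("malformed timepoint at line(s): ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  dup <- duplicated(df[, c("start", "end", "state", "timepoint_s",
                           "replicate")])
  if (any(dup))
    stop("duplicate replicate index at line(s): ",
         paste(line[dup], collapse = ", "), call. = FALSE)
  if (!is.null(protein)) {
    if (any(df$end > protein$length))
      stop("peptide range(s) beyond construct length ", protein$length,
           call. = FALSE)
    expect <- substring(protein$seq, df$start, df$end)
    bad <- toupper(df$sequence) != expect
    if (any(bad))
      stop("sequence/range mismatch vs construct at line(s): ",
           paste(line[bad], collapse = ", "), call. = FALSE)
  }
  df
}

#' Write an uptake CSV
#'
#' Uptake values are printed with 4 decimals; writing and re-reading a
#' table already at that precision reproduces it exactly.
#'
#' @param table Uptake table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_uptake_csv <- function(table, path) {
  .check_uptake_table(table)
  out <- table[, .UPTAKE_COLS]
  out$uptake_da <- sprintf("%.4f", out$uptake_da)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Peptide map induced by an uptake table
#'
#' Distinct `(start, end, sequence)` triples of the table become the
#' confirmed peptide list.
#'
#' @param table Uptake table data frame.
#' @param protein The construct [protein_sequence()].
#' @return A `peptide_map`.
#' @export
peptide_map_from_table <- function(table, protein) {
  .check_uptake_table(table)
  u <- unique(table[, c("start", "end")])
  build_peptide_map(protein, u)
}

#' Assemble and validate a pipeline run configuration
#'
#' All knobs of the end-to-end analysis in one validated list; the
#' configuration is serialized into the output directory for
#' provenance. When `simulate = TRUE` the synthetic module generates the
#' inputs; otherwise `fasta`, `free_csv` and `bound_csv` must point to
#' existing files.
#'
#' @param out_dir Output directory (created if missing).
#' @param simulate Generate synthetic inputs (default TRUE).
#' @param seed Integer seed used for every random stage.
#' @param protein_length Synthetic construct length.
#' @param delta_log10_pf,footprint_fraction Synthetic effect size (see
#'   [simulate_system()]).
#' @param timepoints,n_replicates,noise_sd Experiment design (see
#'   [experiment_design()]).
#' @param states Two state labels, reference first.
#' @param alpha_global,alpha_ttest,threshold Hybrid-test settings (see
#'   [hdx_hybrid()]).
#' @param consensus_rule,consensus_timepoint Residue-mapping settings.
#' @param fasta,free_csv,bound_csv Input paths when `simulate = FALSE`.
#' @param structure_path Optional PDB path to annotate.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = TRUE, seed = 1L,
                       protein_length = 400L, delta_log10_pf = 1.5,
                       footprint_fraction = 0.15,
                       timepoints = c(30, 300, 3000), n_replicates = 3L,
                       noise_sd = 0.13, states = c("free", "bound"),
                       alpha_global = 0.05, alpha_ttest = 0.05,
                       threshold = NULL,
                       consensus_rule = "any", consensus_timepoint = 3000,
                       fasta = NULL, free_csv = NULL, bound_csv = NULL,
                       structure_path = NULL) {
  cfg <- list(out_dir = out_dir, simulate = simulate, seed = as.integer(seed),
              protein_length = as.integer(protein_length),
              delta_log10_pf = delta_log10_pf,
              footprint_fraction = footprint_fraction,
              timepoints = as.numeric(timepoints),
              n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
              states = states, alpha_global = alpha_global,
              alpha_ttest = alpha_ttest, threshold = threshold,
              consensus_rule = consensus_rule,
              consensus_timepoint = consensus_timepoint,
              fasta = fasta, free_csv = free_csv, bound_csv = bound_csv,
              structure_path = structure_path)
  stopifnot(length(cfg$states) == 2L, cfg$alpha_global > 0,
            cfg$alpha_global < 1, cfg$alpha_ttest > 0, cfg$alpha_ttest < 1,
            cfg$consensus_rule %in% c("any", "majority", "all"),
            cfg$consensus_timepoint %in% cfg$timepoints)
  if (!cfg$simulate) {
    for (f in c("fasta", "free_csv", "bound_csv")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop("configuration error: input '", f,
             "' missing or does not exist", call. = FALSE)
    }
  }
  if (!is.null(cfg$structure_path) && !file.exists(cfg$structure_path))
    stop("configuration error: structure file does not exist",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full differential-HDX pipeline
#'
#' Executes simulate (optional) -> replicate summaries -> differential
#' uptake -> hybrid significance -> residue consensus -> dynamic-group
#' classification -> structure annotation (optional), writing the
#' residual-plot CSV, per-residue TSV, classification CSV and a
#' machine-readable `summary.json` (pooled sd, threshold, status counts,
#' group tallies, config echo with MD5 hash) into `config$out_dir`.
#' Re-running the same configuration reproduces every output
#' byte-identically.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the fit, status map, classification
#'   and the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)

  stage <- "configuration"
  res <- tryCatch({
    cfg_path <- p("config.yaml")
    cfg_list <- unclass(config)
    cfg_list <- cfg_list[!vapply(cfg_list, is.null, logical(1L))]
    yaml::write_yaml(cfg_list, cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))

    stage <- "input"
    if (config$simulate) {
      truth <- simulate_system(length = config$protein_length,
                               delta_log10_pf = config$delta_log10_pf,
                               footprint_fraction = config$footprint_fraction,
                               seed = config$seed)
      map <- simulate_digestion(truth$protein, seed = config$seed)
      design <- experiment_design(timepoints = config$timepoints,
                                  n_replicates = config$n_replicates,
                                  noise_sd = config$noise_sd,
                                  states = config$states,
                                  seed = config$seed)
      tabs <- simulate_uptake_tables(truth, map, design)
      free <- tabs[[config$states[1L]]]
      bound <- tabs[[config$states[2L]]]
      write_uptake_csv(free, p("uptake_free.csv"))
      write_uptake_csv(bound, p("uptake_bound.csv"))
      write_ground_truth_csv(truth, p("ground_truth.csv"))
      protein <- truth$protein
    } else {
      protein <- read_protein_fasta(config$fasta)
      free <- read_uptake_csv(config$free_csv, protein)
      bound <- read_uptake_csv(config$bound_csv, protein)
      map <- peptide_map_from_table(rbind(free, bound), protein)
    }

    stage <- "hybrid significance"
    fit <- hdx_hybrid(free, bound, alpha_global = config$alpha_global,
                      alpha_ttest = config$alpha_ttest,
                      threshold = config$threshold)
    write_residual_csv(fit, p("residuals.csv"))

    stage <- "residue consensus"
    statusmap <- map_significance_to_residues(
      fit, map, timepoint = config$consensus_timepoint,
      rule = config$consensus_rule)
    write_residue_tsv(statusmap, p("residues.tsv"))
    counts <- position_counts(statusmap)

    stage <- "classification"
    classification <- classify_peptides(fit)
    write_classification_csv(classification, p("classification.csv"))

    if (!is.null(config$structure_path)) {
      stage <- "structure annotation"
      write_structure_annotation(statusmap, config$structure_path,
                                 p("annotated.pdb"))
    }

    stage <- "summary"
    cov <- coverage_stats(map)
    summary <- list(
      config_hash = cfg_hash, seed = config$seed,
      n_peptides = cov$n_peptides,
      coverage_percent = round(cov$coverage_percent, 4),
      redundancy = round(cov$redundancy, 4),
      s_pooled = round(fit$params$s_pooled, 6),
      df_pooled = fit$params$df_pooled,
      threshold = round(fit$params$threshold, 6),
      n_significant_cells = sum(fit$deltas$significant),
      status_counts = as.list(counts),
      group_counts = as.list(table(classification$group)),
      n_fast_exchangers = sum(classification$fast_exchanger),
      config = cfg_list)
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    list(fit = fit, statusmap = statusmap,
         classification = classification, summary = summary)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
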