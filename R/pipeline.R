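default_run_config <- function() {
  list(
    seed = 1,
    output_dir = "igumi_out",
    reference = list(n_genes = 20, v_length = 200, j_length = 42,
                     c_length = 90, anchor_5p = "TGTGCG",
                     anchor_3p = "TGGGGC", seed = 101),
    simulate = list(mode = "repertoire", n_cells = 500, copies_mean = 2,
                    umi_min = 13, umi_max = 16, depth_multiplier = 40,
                    error_rate = 0.003, read_length = 300, pcr_sigma = 0.5,
                    junction_min = 30, junction_max = 60,
                    n_clones = 58, n_mutated = 21,
                    cells_per_clone_equivalent = 2, background_cells = 5000,
                    clone_copies_mean = 5, dilution_fraction = 1),
    process = list(max_errors = 1, identity_threshold = 0.90, window = 150,
                   min_overlap = 20, max_mismatch = 0.10, min_reads = 3,
                   min_umigs = 3, umi_spacer = "GCTAGCC", min_region = 50),
    detectability = list(enabled = FALSE, n_quantiles = 100, min_points = 100,
                         with_intercept = FALSE),
    spikein_eval = list(enabled = FALSE, max_junction_mismatches = 0)
  )
}

merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(c(paste(path, collapse = "/"), unknown), collapse = "/"),
         call. = FALSE)
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], c(path, k))
    else user[[k]]
  }
  defaults
}

#' Read a pipeline run configuration
#'
#' Loads a YAML configuration, fills unset knobs with package defaults
#' and rejects unknown keys. See `default_run_config()` (internal) for
#' the full schema: top-level `seed`, `output_dir`, and sections
#' `reference`, `simulate`, `process`, `detectability`, `spikein_eval`.
#'
#' @param path YAML file; `NULL` gives the defaults.
#' @return a validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  stopifnot(cfg$simulate$mode %in% c("repertoire", "spikein"),
            cfg$process$min_reads >= 1,
            cfg$simulate$error_rate >= 0, cfg$simulate$error_rate < 0.25)
  structure(cfg, class = "run_config")
}

#' Run the complete simulate-process-analyse pipeline
#'
#' Executes the configured stages and writes all artifacts to
#' `output_dir`: paired FASTQ plus truth table (simulate), the
#' unique-rearrangement table and a stage-count log (process/annotate),
#' and, as configured, a detectability table or a spike-in detection
#' report. Identical configuration and seed yield byte-identical output
#' files.
#'
#' @param config a [read_run_config()] result (or `NULL` for defaults).
#' @return invisibly, a list with the written file paths, the stage log
#'   and the in-memory results.
#' @export
run_pipeline <- function(config = read_run_config()) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  rf <- cfg$reference
  reference <- germline_reference(n_genes = rf$n_genes, v_length = rf$v_length,
                                  j_length = rf$j_length, c_length = rf$c_length,
                                  anchor_5p = rf$anchor_5p,
                                  anchor_3p = rf$anchor_3p, seed = rf$seed)
  sm <- cfg$simulate
  paths <- list()
  panel <- NULL
  if (sm$mode == "repertoire") {
    cells <- generate_repertoire(sm$n_cells, gene_frequency_profile(reference),
                                 reference,
                                 junction_length_range = c(sm$junction_min, sm$junction_max),
                                 seed = stage_seed(cfg$seed, "cells"))
    pool <- transcribe_and_tag(cells, copies_mean = sm$copies_mean,
                               umi_length_range = c(sm$umi_min, sm$umi_max),
                               seed = stage_seed(cfg$seed, "pool"))
  } else {
    panel <- generate_spikein_panel(sm$n_clones, sm$n_mutated, reference,
                                    junction_length_range = c(sm$junction_min, sm$junction_max),
                                    seed = stage_seed(cfg$seed, "panel"))
    pool <- build_spikein_experiment(panel, sm$cells_per_clone_equivalent,
                                     sm$background_cells, reference,
                                     clone_copies_mean = sm$clone_copies_mean,
                                     copies_mean = sm$copies_mean,
                                     umi_length_range = c(sm$umi_min, sm$umi_max),
                                     seed = stage_seed(cfg$seed, "pool"))
    paths$panel <- write_clone_panel(panel, out("clone_panel.tsv"))
  }
  if (sm$dilution_fraction < 1)
    pool <- dilute_pool(pool, sm$dilution_fraction,
                        seed = stage_seed(cfg$seed, "dilution"))
  reads <- amplify_and_sequence(pool, depth_multiplier = sm$depth_multiplier,
                                error_rate = sm$error_rate,
                                read_length = sm$read_length,
                                pcr_sigma = sm$pcr_sigma,
                                umi_spacer = cfg$process$umi_spacer,
                                seed = stage_seed(cfg$seed, "sequencing"))
  paths$truth <- write_truth_table(pool, out("truth.tsv"))
  paths$fastq <- write_fastq_pairs(reads, out("reads_R1.fastq"),
                                   out("reads_R2.fastq"))
  pc <- cfg$process
  pconfig <- process_config(
    umi = umi_spec(sm$umi_min, sm$umi_max, pc$umi_spacer),
    max_errors = pc$max_errors, identity_threshold = pc$identity_threshold,
    window = pc$window, min_overlap = pc$min_overlap,
    max_mismatch = pc$max_mismatch, min_reads = pc$min_reads,
    min_umigs = pc$min_umigs, anchor_5p = rf$anchor_5p,
    anchor_3p = rf$anchor_3p, min_region = pc$min_region)
  res <- process_reads(reads, reference, pconfig)
  paths$rearrangements <- write_rearrangement_table(res$rearrangements,
                                                    out("rearrangements.tsv"))
  results <- list(rearrangements = res$rearrangements, log = res$log,
                  panel = panel)
  if (isTRUE(cfg$detectability$enabled)) {
    dt <- detectability_table(list(sample1 = res$rearrangements),
                              n_quantiles = cfg$detectability$n_quantiles,
                              min_points = cfg$detectability$min_points,
                              with_intercept = cfg$detectability$with_intercept)
    paths$detectability <- write_detectability_table(dt, out("detectability.tsv"))
    results$detectability <- dt
  }
  if (isTRUE(cfg$spikein_eval$enabled) && !is.null(panel)) {
    det <- detect_signatures(res$rearrangements, panel,
                             cfg$spikein_eval$max_junction_mismatches)
    paths$spikein <- write_tsv(det, out("spikein_detection.tsv"))
    results$spikein <- det
  }
  log_lines <- c(sprintf("%s\t%d", names(res$log), res$log))
  writeLines(log_lines, out("stage_counts.tsv"))
  paths$log <- out("stage_counts.tsv")
  invisible(list(paths = paths, log = res$log, results = results))
}
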