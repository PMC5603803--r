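#' Detect clone signatures among unique rearrangements
#'
#' A panel clone is detected iff some passing unique rearrangement's
#' junction matches the clone's junction within
#' `max_junction_mismatches` substitutions (default exact match;
#' junctions of different length never match). Detection is a
#' deterministic function of the rearrangement table and the panel.
#'
#' @param rearrangements an annotated `unique_rearrangements` data frame
#'   (column `junction`).
#' @param panel a [generate_spikein_panel()] result (junctions must be
#'   pairwise distinct).
#' @param max_junction_mismatches allowed substitutions (default 0).
#' @return data frame with one row per clone: `clone_id`, `detected`,
#'   `umig_count`, `read_count` (counts summed over matching
#'   rearrangements).
#' @export
detect_signatures <- function(rearrangements, panel,
                              max_junction_mismatches = 0) {
  if (anyDuplicated(panel$junction))
    stop("panel clones must have pairwise distinct junctions", call. = FALSE)
  jx <- rearrangements$junction
  ok <- !is.na(jx)
  umig <- integer(nrow(panel)); reads <- integer(nrow(panel))
  if (max_junction_mismatches == 0) {
    idx <- match(jx[ok], panel$junction)
    hit <- which(ok)[!is.na(idx)]
    cl <- idx[!is.na(idx)]
    if (length(hit)) {
      au <- rowsum(rearrangements$umig_count[hit], cl)
      ar <- rowsum(rearrangements$read_count[hit], cl)
      umig[as.integer(rownames(au))] <- as.integer(au[, 1])
      reads[as.integer(rownames(ar))] <- as.integer(ar[, 1])
    }
  } else {
    jlen <- nchar(jx)
    for (i in seq_len(nrow(panel))) {
      pj <- panel$junction[i]
      cand <- which(ok & jlen == nchar(pj))
      if (!length(cand)) next
      d <- vapply(jx[cand], hamming_dist, integer(1), b = pj, USE.NAMES = FALSE)
      m <- cand[!is.na(d) & d <= max_junction_mismatches]
      umig[i] <- sum(rearrangements$umig_count[m])
      reads[i] <- sum(rearrangements$read_count[m])
    }
  }
  data.frame(clone_id = panel$clone_id, detected = umig > 0L,
             umig_count = umig, read_count = reads, stringsAsFactors = FALSE)
}

# one simulated library -> processed result + detection row block
run_spikein_library <- function(pool, panel, reference, depth, error_rate,
                                read_length, pcr_sigma, config, seed) {
  reads <- amplify_and_sequence(pool, depth_multiplier = depth,
                                error_rate = error_rate,
                                read_length = read_length,
                                pcr_sigma = pcr_sigma, seed = seed)
  res <- process_reads(reads, reference, config)
  det <- detect_signatures(res$rearrangements, panel)
  list(detection = det, records = res$records, log = res$log)
}

#' Spike-in sensitivity across input amount and sequencing depth
#'
#' For every replicate and every input amount, a fresh spike-in lysate
#' pool is simulated with [build_spikein_experiment()]; each pool is then
#' sequenced at every depth multiplier, processed with the full pipeline
#' and screened for the panel signatures.
#'
#' @param panel a clone panel.
#' @param reference a [germline_reference()].
#' @param cells_per_clone numeric vector of cell-equivalents per clone.
#' @param depths numeric vector of depth multipliers.
#' @param replicates number of independent replicates (default 3).
#' @param background_cells polyclonal background size (default 5000).
#' @param error_rate,read_length,pcr_sigma sequencing model parameters.
#' @param clone_copies_mean,copies_mean mRNA copy means (see
#'   [build_spikein_experiment()]).
#' @param config a [process_config()].
#' @param seed integer RNG seed.
#' @param keep_records keep per-library subgroup records (needed for
#'   [threshold_sweep()]).
#' @return object of class `spikein_report`: list with `report` (tidy
#'   data frame: clone_id, cells_per_clone, depth, replicate, detected,
#'   umig_count, read_count), `records` (named list or `NULL`), `panel`,
#'   and `anchors`.
#' @export
sensitivity_grid <- function(panel, reference, cells_per_clone = c(0.5, 1, 2),
                             depths = c(10, 20, 40), replicates = 3,
                             background_cells = 5000, error_rate = 0.003,
                             read_length = 300, pcr_sigma = 0.5,
                             clone_copies_mean = 5, copies_mean = 2,
                             config = process_config(), seed = 1,
                             keep_records = FALSE) {
  rows <- list(); records <- list()
  for (r in seq_len(replicates)) {
    for (cpc in cells_per_clone) {
      pool <- build_spikein_experiment(
        panel, cells_per_clone_equivalent = cpc,
        background_cells = background_cells, reference = reference,
        clone_copies_mean = clone_copies_mean, copies_mean = copies_mean,
        seed = stage_seed(seed, sprintf("grid_pool_r%d_c%g", r, cpc)))
      for (d in depths) {
        lib <- run_spikein_library(
          pool, panel, reference, d, error_rate, read_length, pcr_sigma,
          config, seed = stage_seed(seed, sprintf("grid_lib_r%d_c%g_d%g", r, cpc, d)))
        det <- lib$detection
        det$cells_per_clone <- cpc; det$depth <- d; det$replicate <- r
        rows[[length(rows) + 1L]] <- det
        if (keep_records)
          records[[sprintf("c%g_d%g_r%d", cpc, d, r)]] <- lib$records
      }
    }
  }
  report <- do.call(rbind, rows)
  structure(list(report = report,
                 records = if (keep_records) records else NULL,
                 panel = panel,
                 anchors = c(reference$anchor_5p, reference$anchor_3p)),
            class = "spikein_report")
}

#' Summarise a spike-in report
#'
#' Per clone and condition, the detection frequency across replicates;
#' per condition, the number of clones detected in every replicate
#' ("complete coverage" when this equals the panel size).
#'
#' @param x a `spikein_report` (or its `report` data frame).
#' @param condition_cols columns defining a condition.
#' @return list with `per_clone` and `per_condition` data frames.
#' @export
summarize_detection <- function(x, condition_cols = NULL) {
  rep <- if (inherits(x, "spikein_report")) x$report else x
  condition_cols <- condition_cols %||%
    intersect(c("cells_per_clone", "depth", "fraction"), names(rep))
  per_clone <- stats::aggregate(rep["detected"],
                                by = c(rep[c("clone_id", condition_cols)]),
                                FUN = mean)
  names(per_clone)[names(per_clone) == "detected"] <- "detection_frequency"
  all_reps <- stats::aggregate(rep["detected"],
                               by = rep[c("clone_id", condition_cols)],
                               FUN = all)
  per_condition <- stats::aggregate(all_reps["detected"],
                                    by = all_reps[condition_cols], FUN = sum)
  names(per_condition)[names(per_condition) == "detected"] <- "clones_detected_all_replicates"
  list(per_clone = per_clone, per_condition = per_condition)
}

#' Re-apply the read-count filter at a range of thresholds
#'
#' Re-runs [filter_and_collapse()] on the retained subgroup records of
#' every library in a [sensitivity_grid()] result (built with
#' `keep_records = TRUE`) for each read-count threshold, re-annotates the
#' junctions and re-detects the panel. Detected-clone counts are
#' monotonically non-increasing in the threshold.
#'
#' @param grid a `spikein_report` with retained records.
#' @param thresholds integer vector of `min_reads` values (default 2:10).
#' @param min_umigs rescue-rule threshold (default 3).
#' @return data frame: threshold, condition fields, replicate,
#'   `n_detected`.
#' @export
threshold_sweep <- function(grid, thresholds = 2:10, min_umigs = 3) {
  stopifnot(inherits(grid, "spikein_report"), !is.null(grid$records))
  out <- list()
  for (key in names(grid$records)) {
    rec <- grid$records[[key]]
    parts <- as.numeric(sub("^c", "", strsplit(key, "_[dr]")[[1]]))
    for (t in thresholds) {
      ur <- filter_and_collapse(rec, min_reads = t, min_umigs = min_umigs)
      jc <- locate_junction(ur$sequence, grid$anchors[1], grid$anchors[2])
      ur$junction <- jc$junction
      det <- detect_signatures(ur, grid$panel)
      out[[length(out) + 1L]] <- data.frame(
        threshold = t, cells_per_clone = parts[1], depth = parts[2],
        replicate = as.integer(parts[3]), n_detected = sum(det$detected))
    }
  }
  do.call(rbind, out)
}

#' Spike-in detection under ds-cDNA dilution
#'
#' Emulates dividing the tagged ds-cDNA of a spike-in tube into aliquots:
#' per replicate, one pool is built (default 1 cell-equivalent per
#' clone), then each dilution fraction is applied to the pool by binomial
#' thinning, sequenced at `depth` (relative to the tube's starting cell
#' count, i.e. constant sequencing effort), processed and screened.
#' Also reports the rank association between each clone's undiluted UMIG
#' count and its detection frequency after the strongest dilution.
#'
#' @param panel a clone panel.
#' @param reference a [germline_reference()].
#' @param fractions dilution fractions (default 1, 1/2, 1/4, 1/8, 1/16).
#' @param replicates number of tubes (default 3).
#' @param cells_per_clone cell-equivalents per clone per tube (default 1).
#' @param depth depth multiplier (default 40).
#' @param background_cells polyclonal background size.
#' @param error_rate,read_length,pcr_sigma,clone_copies_mean,copies_mean,config
#'   as in [sensitivity_grid()].
#' @param seed integer RNG seed.
#' @return object of class `spikein_report` with `report` (clone_id,
#'   fraction, replicate, detected, umig_count, read_count) and
#'   `correlation`: Spearman rank correlation between undiluted UMIG
#'   count and detection frequency at the strongest dilution.
#' @export
dilution_experiment <- function(panel, reference,
                                fractions = c(1, 1/2, 1/4, 1/8, 1/16),
                                replicates = 3, cells_per_clone = 1,
                                depth = 40, background_cells = 5000,
                                error_rate = 0.003, read_length = 300,
                                pcr_sigma = 0.5, clone_copies_mean = 5,
                                copies_mean = 2, config = process_config(),
                                seed = 1) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  rows <- list()
  for (r in seq_len(replicates)) {
    pool <- build_spikein_experiment(
      panel, cells_per_clone_equivalent = cells_per_clone,
      background_cells = background_cells, reference = reference,
      clone_copies_mean = clone_copies_mean, copies_mean = copies_mean,
      seed = stage_seed(seed, sprintf("dil_pool_r%d", r)))
    n_cells <- attr(pool, "n_source_cells")
    for (f in fractions) {
      aliquot <- if (f < 1)
        dilute_pool(pool, f, seed = stage_seed(seed, sprintf("dil_f%g_r%d", f, r)))
      else pool
      attr(aliquot, "n_source_cells") <- n_cells
      lib <- run_spikein_library(
        aliquot, panel, reference, depth, error_rate, read_length,
        pcr_sigma, config,
        seed = stage_seed(seed, sprintf("dil_lib_f%g_r%d", f, r)))
      det <- lib$detection
      det$fraction <- f; det$replicate <- r
      rows[[length(rows) + 1L]] <- det
    }
  }
  report <- do.call(rbind, rows)
  und <- report[report$fraction == max(fractions), , drop = FALSE]
  strong <- report[report$fraction == min(fractions), , drop = FALSE]
  umig_und <- tapply(und$umig_count, und$clone_id, mean)
  freq_strong <- tapply(as.numeric(strong$detected), strong$clone_id, mean)
  shared <- intersect(names(umig_und), names(freq_strong))
  correlation <- if (length(shared) >= 3 &&
                     stats::sd(umig_und[shared]) > 0 &&
                     stats::sd(freq_strong[shared]) > 0)
    stats::cor(umig_und[shared], freq_strong[shared], method = "spearman")
  else NA_real_
  structure(list(report = report, correlation = correlation, panel = panel,
                 anchors = c(reference$anchor_5p, reference$anchor_3p)),
            class = "spikein_report")
}
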