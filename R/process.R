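#' Processing configuration
#'
#' Collects every knob of the error-correction pipeline with the default
#' thresholds of the protocol: one error allowed in the UMI, 90% identity
#' over the first 150 nt for sub-clustering, the junction required on
#' both mates, a 20 nt minimum assembly overlap with at most 10%
#' mismatches, and a pass filter of 3 reads (or 3 identical sequences
#' from distinct UMI groups).
#'
#' @param umi a [umi_spec()].
#' @param max_errors substitutions allowed when clustering UMIs (0 =
#'   group by exact identity only).
#' @param identity_threshold,window sub-clustering identity threshold and
#'   window length.
#' @param min_overlap,max_mismatch paired-end assembly parameters.
#' @param min_reads,min_umigs pass-filter thresholds.
#' @param anchor_5p,anchor_3p junction anchor motifs (must match the
#'   reference used for annotation).
#' @param min_region minimum pre-junction length for a V gene call.
#' @return a list of class `process_config`.
#' @export
process_config <- function(umi = umi_spec(), max_errors = 1,
                           identity_threshold = 0.90, window = 150,
                           min_overlap = 20, max_mismatch = 0.10,
                           min_reads = 3, min_umigs = 3,
                           anchor_5p = "TGTGCG", anchor_3p = "TGGGGC",
                           min_region = 50) {
  stopifnot(inherits(umi, "umi_spec"), max_errors >= 0,
            identity_threshold > 0, identity_threshold <= 1, window >= 1,
            min_overlap >= 1, max_mismatch >= 0, max_mismatch < 1,
            min_reads >= 1, min_umigs >= 1)
  structure(as.list(environment()), class = "process_config")
}

#' Run the full error-correction pipeline on raw read pairs
#'
#' Transforms raw paired reads into annotated unique rearrangements:
#' UMI extraction, UMI clustering (with `max_errors` substitutions
#' allowed), identity sub-clustering within each UMI group, per-mate
#' majority consensus, the junction-on-both-mates filter, paired-end
#' assembly, read-count filtering with the distinct-UMIG rescue rule,
#' collapsing to unique sequences, and anchor/gene annotation.
#'
#' @param reads a `read_pairs` data frame (simulated or from
#'   [read_fastq_pairs()]).
#' @param reference a [germline_reference()] used for annotation; its
#'   anchors override the config anchors when supplied.
#' @param config a [process_config()].
#' @return list with elements `rearrangements` (annotated
#'   `unique_rearrangements`), `records` (one row per subgroup consensus,
#'   for threshold sweeps), and `log` (named integer stage counts).
#' @export
process_reads <- function(reads, reference = NULL, config = process_config()) {
  a5 <- if (!is.null(reference)) reference$anchor_5p else config$anchor_5p
  a3 <- if (!is.null(reference)) reference$anchor_3p else config$anchor_3p
  ex <- extract_umi(reads, config$umi)
  rr <- ex$reads
  cl <- cluster_umis(rr$umi, max_errors = config$max_errors)
  sub <- subcluster_by_identity(rr$r1_seq, cl$assignment,
                                identity_threshold = config$identity_threshold,
                                window = config$window)
  c1 <- consensus_by_subgroup(rr$r1_seq, sub)
  c2 <- consensus_by_subgroup(rr$r2_seq, sub)
  stopifnot(identical(c1$subgroup, c2$subgroup))
  group_of_sub <- cl$assignment[match(c1$subgroup, sub)]
  cdr3_ok <- require_cdr3_on_both_mates(c1$sequence, c2$sequence, a5, a3)
  asm <- data.frame(sequence = rep(NA_character_, nrow(c1)),
                    assembled = FALSE, n_conflicts = 0L,
                    stringsAsFactors = FALSE)
  if (any(cdr3_ok))
    asm[cdr3_ok, ] <- assemble_pairs(c1$sequence[cdr3_ok], c2$sequence[cdr3_ok],
                                     min_overlap = config$min_overlap,
                                     max_mismatch = config$max_mismatch)
  records <- data.frame(group = group_of_sub, subgroup = c1$subgroup,
                        read_count = c1$read_count,
                        r1_consensus = c1$sequence, r2_consensus = c2$sequence,
                        cdr3_ok = cdr3_ok, sequence = asm$sequence,
                        assembled = asm$assembled,
                        n_conflicts = asm$n_conflicts,
                        stringsAsFactors = FALSE)
  records$n_count <- ifelse(records$assembled,
                            nchar(records$sequence) -
                              nchar(gsub("N", "", records$sequence, fixed = TRUE)),
                            NA_integer_)
  rearr <- filter_and_collapse(records, min_reads = config$min_reads,
                               min_umigs = config$min_umigs)
  if (!is.null(reference)) {
    rearr <- annotate_rearrangements(rearr, reference,
                                     min_region = config$min_region)
  } else {
    jc <- locate_junction(rearr$sequence, a5, a3)
    rearr$junction <- jc$junction
    rearr$junction_start <- jc$start
    rearr$junction_end <- jc$end
    rearr$v_call <- NA_character_
  }
  log <- c(n_reads_in = nrow(reads),
           n_umi_fail = ex$n_discarded,
           n_reads_kept = nrow(rr),
           n_umi_groups = nrow(cl$groups),
           n_subgroups = nrow(records),
           n_cdr3_fail = sum(!cdr3_ok),
           n_unassembled = sum(cdr3_ok) - sum(asm$assembled),
           n_records_usable = sum(records$assembled),
           n_unique_rearrangements = nrow(rearr))
  list(rearrangements = rearr, records = records, log = log)
}

#' Compare UMI grouping modes on the same input
#'
#' Processes the same raw reads twice — grouping UMIs by exact identity
#' only versus single-error clustering — and tabulates, per mode, the
#' total number of UMI groups, subgroup records passing the filter,
#' records built from three or more reads (and how many of those carry
#' an ambiguous `N` call after assembly), the mean read and UMIG count
#' per unique sequence, the fraction of unique sequences supported by a
#' single UMIG, and the fraction of unique sequences containing an `N`.
#'
#' @param reads a `read_pairs` data frame.
#' @param reference a [germline_reference()].
#' @param config a [process_config()]; its `max_errors` is overridden per
#'   mode.
#' @return data frame with one row per mode (`identity_only`,
#'   `one_error_clustered`).
#' @export
grouping_mode_report <- function(reads, reference = NULL,
                                 config = process_config()) {
  run_mode <- function(max_errors, mode) {
    config$max_errors <- max_errors
    res <- process_reads(reads, reference, config)
    rec <- res$records
    usable <- rec[rec$assembled, , drop = FALSE]
    seq_umigs <- table(usable$sequence)
    pass <- usable$read_count >= config$min_reads |
      as.integer(seq_umigs[usable$sequence]) >= config$min_umigs
    ur <- res$rearrangements
    data.frame(mode = mode,
               total_umigs = unname(res$log["n_umi_groups"]),
               umigs_passing_filter = sum(pass),
               records_3plus_reads = sum(usable$read_count >= 3),
               n_containing_3plus = sum(usable$read_count >= 3 &
                                          usable$n_count > 0),
               n_unique = nrow(ur),
               mean_read_count = if (nrow(ur)) mean(ur$read_count) else NA_real_,
               mean_umig_count = if (nrow(ur)) mean(ur$umig_count) else NA_real_,
               frac_umig1 = if (nrow(ur)) mean(ur$umig_count == 1) else NA_real_,
               frac_n_containing = if (nrow(ur))
                 mean(grepl("N", ur$sequence, fixed = TRUE)) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(run_mode(0, "identity_only"), run_mode(1, "one_error_clustered"))
}
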