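#' UMI window declaration
#'
#' Describes where the UMI sits on read 1: a random prefix whose length
#' lies in `[min_length, max_length]`, followed by a constant spacer
#' (the remnant of the tagging primer's partial adaptor). Extraction scans
#' the allowed offsets for the spacer to delimit the UMI.
#'
#' @param min_length,max_length UMI length bounds (default 13 and 16).
#' @param spacer constant spacer sequence between UMI and insert.
#' @return a list of class `umi_spec`.
#' @export
umi_spec <- function(min_length = 13, max_length = 16, spacer = "GCTAGCC") {
  stopifnot(min_length >= 1, min_length <= max_length, nchar(spacer) >= 1)
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length), spacer = spacer),
            class = "umi_spec")
}

#' Extract UMIs from read 1
#'
#' Removes the UMI (and spacer) from the biological sequence of read 1
#' and records it alongside the read. Reads in which the spacer cannot be
#' found at any allowed offset — too short, or spacer destroyed by a
#' sequencing error — are discarded and counted.
#'
#' @param reads a `read_pairs` data frame.
#' @param spec a [umi_spec()].
#' @return list with `reads` (the surviving reads, `r1_seq`/`r1_qual`
#'   trimmed, plus a `umi` column) and `n_discarded`.
#' @export
extract_umi <- function(reads, spec = umi_spec()) {
  n <- nrow(reads)
  sp_len <- nchar(spec$spacer)
  offset <- rep.int(NA_integer_, n)
  for (L in spec$min_length:spec$max_length) {
    hit <- is.na(offset) &
      substr(reads$r1_seq, L + 1L, L + sp_len) == spec$spacer
    offset[hit] <- L
  }
  keep <- !is.na(offset)
  out <- reads[keep, , drop = FALSE]
  off <- offset[keep]
  out$umi <- substr(out$r1_seq, 1L, off)
  out$r1_seq <- substring(out$r1_seq, off + sp_len + 1L)
  out$r1_qual <- substring(out$r1_qual, off + sp_len + 1L)
  rownames(out) <- NULL
  list(reads = out, n_discarded = sum(!keep))
}

# all sequences within one substitution of u (equal length)
umi_neighbours <- function(u) {
  L <- nchar(u)
  pos <- rep(seq_len(L), each = 4L)
  alt <- rep.int(DNA_BASES, L)
  pre <- substr(rep.int(u, 4L * L), 1L, pos - 1L)
  suf <- substring(rep.int(u, 4L * L), pos + 1L)
  out <- paste0(pre, alt, suf)
  out[out != u]
}

#' Cluster UMIs with an error allowance
#'
#' Greedy directional clustering: observed UMIs are sorted by descending
#' read support (ties broken lexicographically); each UMI in turn either
#' merges into the earliest-created existing seed within `max_errors`
#' substitutions (equal length only — length-mismatched UMIs never merge)
#' or seeds a new group. With `max_errors = 0` this reduces to grouping by
#' exact UMI identity. The seed UMI of each group is its canonical UMI.
#'
#' @param umis character vector, one observed UMI per read.
#' @param max_errors maximum substitutions allowed for a merge (default 1).
#' @return list with `assignment` (integer group id per read) and
#'   `groups` (data frame `group_id`, `canonical_umi`, `n_reads`).
#' @export
cluster_umis <- function(umis, max_errors = 1) {
  stopifnot(max_errors >= 0)
  if (!length(umis))
    return(list(assignment = integer(),
                groups = data.frame(group_id = integer(),
                                    canonical_umi = character(),
                                    n_reads = integer(),
                                    stringsAsFactors = FALSE)))
  cnt <- table(umis)
  uniq <- names(cnt)
  n_reads_u <- as.integer(cnt)
  ord <- order(-n_reads_u, uniq)
  uniq <- uniq[ord]; n_reads_u <- n_reads_u[ord]
  group_of <- integer(length(uniq))
  seeds <- character()
  if (max_errors == 0) {
    group_of <- seq_along(uniq)
    seeds <- uniq
  } else if (max_errors == 1) {
    env <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(uniq)) {
      u <- uniq[i]
      hits <- unlist(mget(umi_neighbours(u), envir = env, ifnotfound = list(NULL)),
                     use.names = FALSE)
      if (length(hits)) {
        group_of[i] <- min(hits)
      } else {
        seeds <- c(seeds, u)
        g <- length(seeds)
        group_of[i] <- g
        assign(u, g, envir = env)
      }
    }
  } else {
    # generic pairwise scan, adequate for small inputs
    for (i in seq_along(uniq)) {
      u <- uniq[i]
      g <- 0L
      for (j in seq_along(seeds)) {
        d <- hamming_dist(u, seeds[j])
        if (!is.na(d) && d <= max_errors) { g <- j; break }
      }
      if (g == 0L) { seeds <- c(seeds, u); g <- length(seeds) }
      group_of[i] <- g
    }
  }
  assignment <- group_of[match(umis, uniq)]
  groups <- data.frame(group_id = seq_along(seeds), canonical_umi = seeds,
                       n_reads = as.integer(tabulate(assignment, length(seeds))),
                       stringsAsFactors = FALSE)
  list(assignment = assignment, groups = groups)
}

# identity over the shared prefix of two raw byte vectors
raw_prefix_identity <- function(ra, rb) {
  m <- min(length(ra), length(rb))
  if (m == 0L) return(0)
  sum(ra[seq_len(m)] == rb[seq_len(m)]) / m
}

#' Sub-cluster a UMI group by read identity
#'
#' Splits the reads of each UMI group into subgroups of mutually similar
#' sequences, compensating for independent molecules that were tagged
#' with the same (or a near-identical) UMI. Greedy centroid partition:
#' the most frequent exact first-`window` string of read 1 (ties broken
#' lexicographically) seeds a subgroup; reads whose first-window identity
#' to the centroid is at least `identity_threshold` join; the procedure
#' repeats on the remainder. Reads shorter than `window` are compared
#' over the shared prefix.
#'
#' @param r1 character vector of read-1 sequences (UMI removed).
#' @param groups integer group id per read (from [cluster_umis()]).
#' @param identity_threshold minimum identity to the centroid (default
#'   0.90).
#' @param window comparison window length in nt (default 150).
#' @return integer vector of global subgroup ids (one per read); each
#'   subgroup is contained in a single group.
#' @export
subcluster_by_identity <- function(r1, groups, identity_threshold = 0.90,
                                   window = 150) {
  stopifnot(length(r1) == length(groups), identity_threshold > 0,
            identity_threshold <= 1, window >= 1)
  win <- substr(r1, 1L, window)
  sub <- integer(length(r1))
  next_id <- 0L
  for (idx in split(seq_along(r1), groups)) {
    remaining <- idx
    while (length(remaining)) {
      ws <- win[remaining]
      tab <- sort(table(ws), decreasing = TRUE)
      centroid <- names(tab)[1L]  # table names are sorted, ties -> lexicographic
      rc <- charToRaw(centroid)
      member <- vapply(ws, function(w)
        raw_prefix_identity(charToRaw(w), rc) >= identity_threshold,
        logical(1), USE.NAMES = FALSE)
      next_id <- next_id + 1L
      sub[remaining[member]] <- next_id
      remaining <- remaining[!member]
    }
  }
  sub
}
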