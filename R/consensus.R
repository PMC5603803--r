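RAW_BASES <- vapply(c("A", "C", "G", "T", "N"), charToRaw, raw(1))
RAW_N <- charToRaw("N")

#' Build a majority-rule consensus from a subgroup of reads
#'
#' Per position, the strict-majority base (more than half of the reads
#' covering that position) is called; positions without a strict majority
#' are called `N`. The consensus length is the modal read length of the
#' subgroup (ties resolved towards the longer length); shorter reads
#' simply stop covering trailing positions.
#'
#' @param seqs character vector of reads from one subgroup (one mate).
#' @return list with `sequence`, `read_count` and `n_count` (number of
#'   ambiguous `N` calls).
#' @export
build_consensus <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  k <- length(seqs)
  if (k == 1L)
    return(list(sequence = seqs, read_count = 1L,
                n_count = sum(charToRaw(seqs) == RAW_N)))
  if (all(seqs == seqs[1L]))
    return(list(sequence = seqs[1L], read_count = k,
                n_count = sum(charToRaw(seqs[1L]) == RAW_N)))
  lens <- nchar(seqs)
  lt <- table(lens)
  modal <- max(as.integer(names(lt)[lt == max(lt)]))
  raws <- lapply(seqs, charToRaw)
  raws <- lapply(raws, function(r) { length(r) <- modal; r })  # pads with 00
  M <- do.call(rbind, raws)
  cover <- colSums(M != as.raw(0))
  counts <- vapply(RAW_BASES, function(b) colSums(M == b), numeric(modal))
  if (modal == 1L) counts <- matrix(counts, nrow = 1L)
  best <- max.col(counts, ties.method = "first")
  called <- counts[cbind(seq_len(modal), best)] > cover / 2
  out <- rep(RAW_N, modal)
  out[called] <- RAW_BASES[best[called]]
  list(sequence = rawToChar(out), read_count = k, n_count = sum(out == RAW_N))
}

# batch consensus over many subgroups; returns one row per subgroup
consensus_by_subgroup <- function(seqs, subgroup) {
  idx_list <- split(seq_along(seqs), subgroup)
  n <- length(idx_list)
  sequence <- character(n); read_count <- integer(n); n_count <- integer(n)
  for (i in seq_len(n)) {
    cons <- build_consensus(seqs[idx_list[[i]]])
    sequence[i] <- cons$sequence
    read_count[i] <- cons$read_count
    n_count[i] <- cons$n_count
  }
  data.frame(subgroup = as.integer(names(idx_list)), sequence = sequence,
             read_count = read_count, n_count = n_count,
             stringsAsFactors = FALSE)
}

#' Check that the junction is present on both mate consensus sequences
#'
#' A consensus record is usable only if the HCDR3 junction — delimited by
#' the 5' and 3' anchor motifs — can be located on the read-1 consensus
#' and on the (reverse-complemented) read-2 consensus. Absence (e.g. an
#' anchor destroyed by an `N` call or a truncated mate) is a filter
#' outcome, not an error.
#'
#' @param r1_consensus,r2_consensus character vectors of per-subgroup
#'   consensus sequences; read 2 in raw (reverse-complement) orientation.
#' @param anchor_5p,anchor_3p junction anchor motifs.
#' @return logical vector, `TRUE` where both mates contain the junction.
#' @export
require_cdr3_on_both_mates <- function(r1_consensus, r2_consensus,
                                       anchor_5p, anchor_3p) {
  ok1 <- !is.na(locate_junction(r1_consensus, anchor_5p, anchor_3p)$start)
  ok2 <- !is.na(locate_junction(revcomp_with_n(r2_consensus), anchor_5p,
                                anchor_3p)$start)
  ok1 & ok2
}

# resolve the overlap of two raw vectors: agreement wins, N yields to the
# other mate, a hard disagreement takes the read-1 base (counted)
resolve_overlap <- function(a, b) {
  out <- a
  useb <- a == RAW_N & b != RAW_N
  out[useb] <- b[useb]
  conflicts <- sum(a != b & a != RAW_N & b != RAW_N)
  list(seq = out, conflicts = conflicts)
}

# score one candidate alignment offset q (1-based position of s2rc[1] on s1)
score_overlap <- function(r1, r2rc, q, min_overlap, max_mismatch) {
  len1 <- length(r1); len2 <- length(r2rc)
  o <- min(len1 - q + 1L, len2)
  if (o < min_overlap) return(NULL)
  a <- r1[q:(q + o - 1L)]
  b <- r2rc[seq_len(o)]
  both <- a != RAW_N & b != RAW_N
  nm <- sum(a[both] != b[both])
  if (sum(both) == 0L || nm > max_mismatch * o) return(NULL)
  list(q = q, o = o, score = sum(a[both] == b[both]), nm = nm)
}

#' Assemble paired consensus sequences into a full-length rearrangement
#'
#' Finds the maximal-scoring ungapped overlap between the read-1
#' consensus and the reverse-complement-oriented read-2 consensus,
#' requiring at least `min_overlap` overlapping positions and a mismatch
#' fraction of at most `max_mismatch` (positions where either mate is `N`
#' are not counted as mismatches). Within the overlap, agreement keeps
#' the base, an `N` on one mate takes the other mate's base, both-`N`
#' stays `N`, and a hard disagreement takes the read-1 base (counted as a
#' conflict). Candidate offsets are located by exact 20-mer seeding with
#' a full scan as fallback; pairs without a qualifying overlap are
#' reported unassembled.
#'
#' @param r1_consensus,r2_consensus character vectors (read 2 in raw
#'   orientation).
#' @param min_overlap minimum overlap length (default 20).
#' @param max_mismatch maximum mismatch fraction in the overlap (default
#'   0.10).
#' @return data frame with `sequence` (`NA` when unassembled),
#'   `assembled` flag and `n_conflicts`.
#' @export
assemble_pairs <- function(r1_consensus, r2_consensus, min_overlap = 20,
                           max_mismatch = 0.10) {
  stopifnot(length(r1_consensus) == length(r2_consensus), min_overlap >= 1)
  n <- length(r1_consensus)
  r2rc_all <- revcomp_with_n(r2_consensus)
  sequence <- rep(NA_character_, n)
  assembled <- logical(n)
  n_conflicts <- integer(n)
  for (i in seq_len(n)) {
    r1 <- charToRaw(r1_consensus[i])
    r2 <- charToRaw(r2rc_all[i])
    len1 <- length(r1); len2 <- length(r2)
    best <- NULL
    # seed candidate offsets with exact 20-mers from the start of r2rc
    for (sp in c(1L, 21L, 41L)) {
      if (sp + 19L > len2) break
      seed <- r2[sp:(sp + 19L)]
      if (any(seed == RAW_N)) next
      hits <- gregexpr(rawToChar(seed), r1_consensus[i], fixed = TRUE)[[1]]
      if (hits[1L] == -1L) next
      for (p in hits) {
        q <- p - sp + 1L
        if (q < 1L) next
        cand <- score_overlap(r1, r2, q, min_overlap, max_mismatch)
        if (!is.null(cand) &&
            (is.null(best) || cand$score > best$score ||
             (cand$score == best$score && cand$q < best$q)))
          best <- cand
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) {
      for (q in seq_len(max(0L, len1 - min_overlap + 1L))) {
        cand <- score_overlap(r1, r2, q, min_overlap, max_mismatch)
        if (!is.null(cand) &&
            (is.null(best) || cand$score > best$score ||
             (cand$score == best$score && cand$q < best$q)))
          best <- cand
      }
    }
    if (is.null(best)) next
    q <- best$q; o <- best$o
    ov <- resolve_overlap(r1[q:(q + o - 1L)], r2[seq_len(o)])
    tail_part <- if (q - 1L + len2 > len1) r2[(o + 1L):len2]
                 else if (q + o - 1L < len1) r1[(q + o):len1]
                 else raw(0)
    sequence[i] <- rawToChar(c(r1[seq_len(q - 1L)], ov$seq, tail_part))
    assembled[i] <- TRUE
    n_conflicts[i] <- ov$conflicts
  }
  data.frame(sequence = sequence, assembled = assembled,
             n_conflicts = n_conflicts, stringsAsFactors = FALSE)
}

# reverse complement tolerating N
revcomp_with_n <- function(x) {
  if (!length(x)) return(character())
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, NULL), function(ch)
    paste(rev(ch), collapse = ""), character(1), USE.NAMES = FALSE)
}

#' Filter consensus records and collapse to unique rearrangements
#'
#' A record passes if it was built from at least `min_reads` reads, or if
#' its exact full-length sequence is shared by at least `min_umigs`
#' distinct subgroups (the rescue rule for well-supported molecules with
#' few reads each). Passing records with identical sequences collapse
#' into one unique rearrangement, accumulating the subgroup (UMIG) count
#' and total read count.
#'
#' @param records data frame with columns `sequence` and `read_count`
#'   (one row per subgroup consensus; rows with `NA` sequence are
#'   ignored).
#' @param min_reads read-count threshold (default 3; sweepable).
#' @param min_umigs subgroup-count threshold of the rescue rule (default
#'   3).
#' @return data frame of class `unique_rearrangements` with columns
#'   `sequence`, `umig_count`, `read_count`, ordered by descending
#'   `umig_count`, descending `read_count`, then sequence.
#' @export
filter_and_collapse <- function(records, min_reads = 3, min_umigs = 3) {
  stopifnot(min_reads >= 1, min_umigs >= 1)
  rec <- records[!is.na(records$sequence), , drop = FALSE]
  if (!nrow(rec)) {
    return(structure(data.frame(sequence = character(), umig_count = integer(),
                                read_count = integer(), stringsAsFactors = FALSE),
                     class = c("unique_rearrangements", "data.frame")))
  }
  seq_umigs <- table(rec$sequence)
  pass <- rec$read_count >= min_reads |
    as.integer(seq_umigs[rec$sequence]) >= min_umigs
  rec <- rec[pass, , drop = FALSE]
  if (!nrow(rec)) {
    return(structure(data.frame(sequence = character(), umig_count = integer(),
                                read_count = integer(), stringsAsFactors = FALSE),
                     class = c("unique_rearrangements", "data.frame")))
  }
  umig_count <- as.integer(table(rec$sequence))
  read_count <- as.integer(tapply(rec$read_count, rec$sequence, sum))
  out <- data.frame(sequence = names(table(rec$sequence)),
                    umig_count = umig_count, read_count = read_count,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$umig_count, -out$read_count, out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("unique_rearrangements", "data.frame"))
}
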