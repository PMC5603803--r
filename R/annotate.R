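#' Locate the HCDR3 junction by anchor motifs
#'
#' The junction is delimited by the conserved anchor motifs the simulator
#' embeds at the V-junction and junction-J boundaries: its 3' end is the
#' last occurrence of the 3' anchor, and its 5' start is the last
#' occurrence of the 5' anchor before that point (the anchor pair
#' closest to the junction, mirroring the conserved Cys and Trp codons
#' nearest the CDR3). Taking last occurrences makes the call robust to
#' spurious motif copies created upstream in V by somatic mutation,
#' which would otherwise mislocate the junction of a whole mutated
#' clone; on unmutated sequences, whose transcripts carry each anchor
#' exactly once, the rule coincides with taking the first occurrences.
#' Coordinates are 0-based
#' half-open into the rearrangement sequence. Absence of either anchor
#' is a reportable outcome, not an error.
#'
#' @param sequences character vector of rearrangement sequences.
#' @param anchor_5p,anchor_3p anchor motifs.
#' @return data frame with columns `start`, `end` (0-based half-open,
#'   `NA` when not found) and `junction`.
#' @export
locate_junction <- function(sequences, anchor_5p, anchor_3p) {
  n <- length(sequences)
  a5len <- nchar(anchor_5p)
  p3 <- regexpr(anchor_3p, sequences, fixed = TRUE)
  start <- rep(NA_integer_, n); end <- rep(NA_integer_, n)
  cand <- which(p3 > 0)
  if (length(cand)) {
    hits5 <- gregexpr(anchor_5p, sequences[cand], fixed = TRUE)
    hits3 <- gregexpr(anchor_3p, sequences[cand], fixed = TRUE)
    for (k in seq_along(cand)) {
      i <- cand[k]
      h3 <- hits3[[k]]
      p <- h3[length(h3)]                               # last 3' anchor
      h <- hits5[[k]]
      h <- h[h > 0 & h + a5len <= p]
      if (length(h)) {
        start[i] <- h[length(h)] + a5len - 1L           # 0-based
        end[i] <- p - 1L
      }
    }
  }
  bad <- !is.na(start) & end <= start
  start[bad] <- NA_integer_; end[bad] <- NA_integer_
  junction <- ifelse(is.na(start), NA_character_,
                     substring(sequences, start + 1L, end))
  data.frame(start = start, end = end, junction = junction,
             stringsAsFactors = FALSE)
}

#' Assign the best-matching germline V gene
#'
#' Alignment-free positional comparison of the pre-junction region of
#' each rearrangement against every leader+V sequence of the reference
#' (the simulator produces co-linear sequences, so no alignment is
#' needed; for real data a user aligner can replace this step). The gene
#' with maximal identity wins; ties are broken lexicographically and
#' flagged. Sequences whose pre-junction region is shorter than
#' `min_region` receive no call.
#'
#' @param sequences character vector of rearrangement sequences.
#' @param reference a [germline_reference()].
#' @param junction_start integer vector of 0-based junction starts (from
#'   [locate_junction()]); `NA` yields no call.
#' @param min_region minimum pre-junction length for a call (default 50).
#' @return data frame with `v_call`, `identity` and `tie` columns.
#' @export
assign_gene <- function(sequences, reference, junction_start,
                        min_region = 50) {
  validate_reference(reference)
  n <- length(sequences)
  pre <- substr(sequences, 1L, ifelse(is.na(junction_start), 0L, junction_start))
  callable <- !is.na(junction_start) & nchar(pre) >= min_region
  v_call <- rep(NA_character_, n)
  identity <- rep(NA_real_, n)
  tie <- rep(FALSE, n)
  if (any(callable)) {
    # most pre-junction regions repeat a germline V verbatim: score unique
    # strings once
    uniq <- unique(pre[callable])
    gene_names <- sort(names(reference$genes))
    gene_raw <- lapply(reference$genes[gene_names], charToRaw)
    score_one <- function(s) {
      rs <- charToRaw(s)
      ids <- vapply(gene_raw, function(g) raw_prefix_identity(rs, g), numeric(1))
      best <- max(ids)
      hits <- which(ids == best)
      c(call = gene_names[hits[1L]], identity = best, tie = length(hits) > 1L)
    }
    sc <- vapply(uniq, score_one, c(call = "", identity = "", tie = ""))
    m <- match(pre[callable], uniq)
    v_call[callable] <- sc["call", m]
    identity[callable] <- as.numeric(sc["identity", m])
    tie[callable] <- as.logical(sc["tie", m])
  }
  data.frame(v_call = v_call, identity = identity, tie = tie,
             stringsAsFactors = FALSE)
}

#' Annotate unique rearrangements in place
#'
#' Fills the `junction`, `junction_start`, `junction_end`, `v_call` and
#' `v_identity` columns of a unique-rearrangement table using
#' [locate_junction()] and [assign_gene()].
#'
#' @param rearrangements a [filter_and_collapse()] result.
#' @param reference a [germline_reference()].
#' @param min_region minimum pre-junction length for a gene call.
#' @return the annotated `unique_rearrangements` data frame.
#' @export
annotate_rearrangements <- function(rearrangements, reference,
                                    min_region = 50) {
  jc <- locate_junction(rearrangements$sequence, reference$anchor_5p,
                        reference$anchor_3p)
  gc <- assign_gene(rearrangements$sequence, reference, jc$start, min_region)
  rearrangements$junction <- jc$junction
  rearrangements$junction_start <- jc$start
  rearrangements$junction_end <- jc$end
  rearrangements$v_call <- gc$v_call
  rearrangements$v_identity <- gc$identity
  rearrangements$v_call_tie <- gc$tie
  rearrangements
}
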