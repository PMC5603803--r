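#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a base seed
#'
#' All stochastic stages draw their randomness from one user seed; each
#' stage perturbs it with a stable hash of its name so that stages are
#' statistically decoupled but fully reproducible.
#'
#' @param seed integer base seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stage_seed <- function(seed, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483646)
}

#' Generate random DNA sequences
#'
#' Uniform i.i.d. A/C/G/T strings, optionally rejecting sequences that
#' contain any of a set of forbidden motifs (used to keep junction anchor
#' motifs unique within simulated transcripts).
#'
#' @param n number of sequences.
#' @param len length, scalar or vector of length `n`.
#' @param avoid character vector of motifs that must not occur.
#' @return character vector of length `n`.
#' @keywords internal
random_dna <- function(n, len, avoid = character()) {
  if (n == 0L) return(character())
  if (length(len) == 1L) len <- rep.int(len, n)
  stopifnot(length(len) == n, all(len >= 1L))
  draw <- function(lens) {
    chars <- sample(DNA_BASES, sum(lens), replace = TRUE)
    f <- rep.int(seq_along(lens), lens)
    vapply(split(chars, f), paste, character(1), collapse = "")
  }
  out <- draw(len)
  if (length(avoid)) {
    repeat {
      bad <- Reduce(`|`, lapply(avoid, function(m) grepl(m, out, fixed = TRUE)))
      if (!any(bad)) break
      out[bad] <- draw(len[bad])
    }
  }
  unname(out)
}

#' Hamming distance between two equal-length strings
#' @keywords internal
hamming_dist <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) return(NA_integer_)
  sum(ra != rb)
}

#' Reverse complement (vectorised)
#' @keywords internal
revcomp <- function(x) {
  if (!length(x)) return(character())
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' Apply random substitution errors to a set of sequences
#'
#' Each base is independently substituted with probability `rate`; the
#' replacement base is uniform over the three alternatives. Implemented by
#' drawing a binomial error total over the concatenated base space and
#' placing errors uniformly without replacement, which is equivalent to
#' per-base i.i.d. Bernoulli errors.
#'
#' @param seqs character vector of upper-case DNA strings.
#' @param rate substitution probability per base.
#' @return list with `seqs` (mutated vector) and `n_errors`.
#' @keywords internal
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(list(seqs = seqs, n_errors = 0L))
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(list(seqs = seqs, n_errors = 0L))
  pos <- sort(sample.int(total, n_err))
  ends <- cumsum(lens)
  read_idx <- findInterval(pos - 1, ends) + 1L
  offset <- pos - c(0, ends)[read_idx]
  cur <- substring(seqs[read_idx], offset, offset)
  shift <- sample.int(3L, n_err, replace = TRUE)
  new <- DNA_BASES[(match(cur, DNA_BASES) - 1L + shift) %% 4L + 1L]
  # multiple errors can hit the same read; apply in passes so no write is lost
  rank <- stats::ave(seq_len(n_err), read_idx, FUN = seq_along)
  for (k in seq_len(max(rank))) {
    sel <- rank == k
    i <- read_idx[sel]
    s <- seqs[i]
    substring(s, offset[sel], offset[sel]) <- new[sel]
    seqs[i] <- s
  }
  list(seqs = seqs, n_errors = n_err)
}

#' Substitute a fixed number of positions in one sequence
#'
#' Picks `n` distinct positions within `region` (1-based inclusive bounds)
#' and replaces each base with a different one. Used for somatic-mutation
#' style divergence in spike-in clones.
#' @keywords internal
mutate_fixed_count <- function(seq, n, region = c(1L, nchar(seq))) {
  if (n == 0L) return(seq)
  span <- region[2] - region[1] + 1L
  stopifnot(n <= span)
  pos <- region[1] - 1L + sample.int(span, n)
  ch <- strsplit(seq, NULL)[[1]]
  shift <- sample.int(3L, n, replace = TRUE)
  ch[pos] <- DNA_BASES[(match(ch[pos], DNA_BASES) - 1L + shift) %% 4L + 1L]
  paste(ch, collapse = "")
}
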