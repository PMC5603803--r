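#' Build a synthetic germline reference
#'
#' Constructs a small synthetic stand-in for the human IGH germline locus:
#' a set of leader+V segments, one J segment and one constant segment,
#' plus the pair of conserved junction anchor motifs. Each leader+V
#' sequence ends with the 5' anchor (mimicking the conserved Cys codon at
#' the start of the HCDR3) and the J segment starts with the 3' anchor
#' (the conserved Trp-Gly motif), so the junction can be located by exact
#' motif match without V(D)J alignment. Genes are random and therefore
#' pairwise dissimilar (about 25% identity), which makes positional gene
#' assignment unambiguous even at 10% somatic divergence.
#'
#' Real IGHV alleles may be supplied instead via [read_germline_fasta()];
#' the only structural requirement is that each sequence ends with the
#' configured 5' anchor.
#'
#' @param n_genes number of V genes to simulate (default 20).
#' @param v_length total length of each leader+V segment in nt, anchor
#'   included (default 200; must leave the junction within reach of read 1
#'   after the UMI, see [amplify_and_sequence()]).
#' @param j_length length of the J segment, anchor included.
#' @param c_length length of the constant segment.
#' @param anchor_5p conserved motif ending every leader+V segment.
#' @param anchor_3p conserved motif starting the J segment.
#' @param seed integer RNG seed.
#' @return an object of class `germline_reference`: a list with elements
#'   `genes` (named character vector), `j_segment`, `constant` (named
#'   character vector of isotype segments), `anchor_5p`, `anchor_3p`.
#' @export
germline_reference <- function(n_genes = 20, v_length = 200, j_length = 42,
                               c_length = 90, anchor_5p = "TGTGCG",
                               anchor_3p = "TGGGGC", seed = 101) {
  stopifnot(n_genes >= 1, v_length > nchar(anchor_5p) + 50,
            j_length > nchar(anchor_3p), nchar(anchor_5p) >= 4,
            nchar(anchor_3p) >= 4, anchor_5p != anchor_3p)
  avoid <- c(anchor_5p, anchor_3p)
  withr::with_seed(stage_seed(seed, "germline"), {
    bodies <- random_dna(n_genes, v_length - nchar(anchor_5p), avoid = avoid)
    genes <- paste0(bodies, anchor_5p)
    names(genes) <- sprintf("IGHV-SIM%02d", seq_len(n_genes))
    j_seg <- paste0(anchor_3p,
                    random_dna(1, j_length - nchar(anchor_3p), avoid = avoid))
    cons <- c(IGHM = random_dna(1, c_length, avoid = avoid))
  })
  structure(list(genes = genes, j_segment = j_seg, constant = cons,
                 anchor_5p = anchor_5p, anchor_3p = anchor_3p),
            class = "germline_reference")
}

validate_reference <- function(reference) {
  stopifnot(inherits(reference, "germline_reference"))
  g <- reference$genes
  if (!length(g)) stop("germline reference contains no genes", call. = FALSE)
  if (anyDuplicated(names(g))) stop("duplicated gene names in reference", call. = FALSE)
  if (any(grepl("[^ACGT]", c(g, reference$j_segment, reference$constant))))
    stop("reference sequences must be uppercase A/C/G/T", call. = FALSE)
  if (!all(endsWith(g, reference$anchor_5p)))
    stop("every leader+V sequence must end with the 5' anchor motif", call. = FALSE)
  if (!all(startsWith(reference$j_segment, reference$anchor_3p)))
    stop("the J segment must start with the 3' anchor motif", call. = FALSE)
  invisible(reference)
}

#' @export
print.germline_reference <- function(x, ...) {
  cat("Synthetic germline reference\n")
  cat(sprintf("  %d V genes (leader+V %d nt), J %d nt, %d constant segment(s)\n",
              length(x$genes), nchar(x$genes[[1]]), nchar(x$j_segment),
              length(x$constant)))
  cat(sprintf("  junction anchors: 5' %s / 3' %s\n", x$anchor_5p, x$anchor_3p))
  invisible(x)
}

#' Read a user germline reference from FASTA
#'
#' Loads leader+V sequences from a FASTA file into a `germline_reference`.
#' Sequences must be uppercase A/C/G/T and end with the configured 5'
#' anchor motif so that the junction remains locatable.
#'
#' @inheritParams germline_reference
#' @param path FASTA file of leader+V sequences (one record per gene).
#' @param j_segment,constant character; J and constant segments to append.
#' @return a `germline_reference`.
#' @export
read_germline_fasta <- function(path, j_segment, constant = c(IGHM = ""),
                                anchor_5p = "TGTGCG", anchor_3p = "TGGGGC") {
  seqs <- Biostrings::readDNAStringSet(path)
  ref <- structure(list(genes = stats::setNames(as.character(seqs), names(seqs)),
                        j_segment = j_segment, constant = constant,
                        anchor_5p = anchor_5p, anchor_3p = anchor_3p),
                   class = "germline_reference")
  validate_reference(ref)
}

#' Gene sampling profile
#'
#' A named vector of sampling probabilities over the V genes of a
#' reference. Probabilities must be non-negative and sum to one (within
#' 1e-9).
#'
#' @param reference a `germline_reference`.
#' @param probs optional named numeric vector over (a subset of) the
#'   reference gene names; `NULL` gives the uniform profile.
#' @return named numeric vector of class `gene_frequency_profile`.
#' @export
gene_frequency_profile <- function(reference, probs = NULL) {
  validate_reference(reference)
  if (is.null(probs)) {
    probs <- stats::setNames(rep(1 / length(reference$genes),
                                 length(reference$genes)),
                             names(reference$genes))
  }
  if (is.null(names(probs)) || !all(names(probs) %in% names(reference$genes)))
    stop("profile names must be a subset of reference gene names", call. = FALSE)
  if (any(probs < 0)) stop("profile probabilities must be non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9)
    stop("profile probabilities must sum to 1", call. = FALSE)
  structure(probs, class = c("gene_frequency_profile", "numeric"))
}
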