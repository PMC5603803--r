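truth_header <- function(reads) {
  if (all(c("cell_id", "molecule_id", "true_umi") %in% names(reads)))
    paste0(reads$read_id, " cell=", reads$cell_id, ";mol=", reads$molecule_id,
           ";umi=", reads$true_umi, ";")
  else reads$read_id
}

#' Write paired FASTQ files
#'
#' Truth tags (cell, molecule, true UMI), when present, travel in the
#' FASTQ header as a `key=value;` suffix; processing ignores them, while
#' evaluation code can parse them back. Files remain standard FASTQ.
#'
#' @param reads a `read_pairs` data frame.
#' @param r1_path,r2_path output paths.
#' @return invisibly, the two paths.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  hdr <- truth_header(reads)
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- hdr
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(reads$r1_seq, reads$r1_qual, r1_path)
  write_one(reads$r2_seq, reads$r2_qual, r2_path)
  invisible(c(r1_path, r2_path))
}

parse_truth_tag <- function(headers, key) {
  m <- regmatches(headers, regexpr(paste0(key, "=[^;]*;"), headers))
  out <- rep(NA_character_, length(headers))
  has <- grepl(paste0(key, "=[^;]*;"), headers)
  out[has] <- sub(";$", "", sub(paste0("^", key, "="), "", m))
  out
}

#' Read paired FASTQ files
#'
#' Records pair up by order; a mismatch in pair counts or read
#' identifiers is fatal. Truth tags embedded by [write_fastq_pairs()]
#' are recovered when present, so simulator output round-trips
#' losslessly.
#'
#' @param r1_path,r2_path FASTQ paths.
#' @return a `read_pairs` data frame.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  read_one <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(header = names(x), seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
  }
  a <- read_one(r1_path); b <- read_one(r2_path)
  if (length(a$seq) != length(b$seq))
    stop("mismatched pair counts: ", length(a$seq), " in R1 vs ",
         length(b$seq), " in R2", call. = FALSE)
  if (!length(a$seq)) warning("empty FASTQ input")
  id_a <- sub(" .*$", "", a$header); id_b <- sub(" .*$", "", b$header)
  if (!identical(id_a, id_b))
    stop("read identifiers do not pair up between R1 and R2", call. = FALSE)
  out <- data.frame(read_id = id_a, r1_seq = a$seq, r1_qual = a$qual,
                    r2_seq = b$seq, r2_qual = b$qual, stringsAsFactors = FALSE)
  cell <- parse_truth_tag(a$header, "cell")
  if (!all(is.na(cell))) {
    out$cell_id <- cell
    out$molecule_id <- parse_truth_tag(a$header, "mol")
    out$true_umi <- parse_truth_tag(a$header, "umi")
  }
  structure(out, class = c("read_pairs", "data.frame"))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = NA, na.strings = "", comment.char = "",
                    quote = "")
}

#' Write the molecule truth table
#' @param pool a `molecule_pool`.
#' @param path output path (tab-separated).
#' @export
write_truth_table <- function(pool, path) {
  write_tsv(pool[c("molecule_id", "cell_id", "umi", "v_gene", "junction")],
            path)
}

#' Write / read a clone panel table
#' @param panel a `clone_panel`.
#' @param path file path (tab-separated).
#' @export
write_clone_panel <- function(panel, path) write_tsv(panel, path)

#' @rdname write_clone_panel
#' @export
read_clone_panel <- function(path) {
  structure(read_tsv(path), class = c("clone_panel", "data.frame"))
}

REARRANGEMENT_COLUMNS <- c("sequence", "umig_count", "read_count", "v_call",
                           "junction")

#' Write a unique-rearrangement table
#'
#' Tab-separated text with AIRR-style columns `sequence`, `umig_count`
#' (consensus/duplicate count, the molecule proxy), `read_count`,
#' `v_call`, `junction`; rows ordered by descending `umig_count` then
#' sequence, so identical inputs produce byte-identical files.
#'
#' @param rearrangements an annotated `unique_rearrangements` data frame.
#' @param path output path.
#' @export
write_rearrangement_table <- function(rearrangements, path) {
  d <- rearrangements
  for (col in REARRANGEMENT_COLUMNS)
    if (is.null(d[[col]])) d[[col]] <- NA
  d <- d[order(-d$umig_count, d$sequence), REARRANGEMENT_COLUMNS, drop = FALSE]
  write_tsv(d, path)
}

#' @rdname write_rearrangement_table
#' @export
read_rearrangement_table <- function(path) {
  d <- read_tsv(path)
  missing <- setdiff(REARRANGEMENT_COLUMNS, names(d))
  if (length(missing))
    stop("rearrangement table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(d, class = c("unique_rearrangements", "data.frame"))
}

#' Write a detectability table
#' @param x a [detectability_table()] result.
#' @param path output path for the per-gene table; per-sample slopes go
#'   to `<path>.per_sample.tsv`.
#' @export
write_detectability_table <- function(x, path) {
  write_tsv(x$table, path)
  write_tsv(x$per_sample, paste0(path, ".per_sample.tsv"))
  invisible(path)
}
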