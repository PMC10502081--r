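# FASTA and table I/O thin wrappers.

#' Read TR sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_tr_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write TR sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_tr_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED-like interval table
#'
#' Three-column (or more) tab-separated file; columns beyond `chrom`,
#' `start`, `end` are kept with their header names if a header is present.
#'
#' @param path BED/TSV file (0-based half-open coordinates).
#' @return data.frame with at least `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("start", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[1:3] <- c("chrom", "start", "end")
  }
  df
}

#' Write a BED-like interval table
#'
#' @param df data.frame with `chrom`, `start`, `end` first.
#' @param path Output file.
#' @param header Write a header line (default FALSE, plain BED).
#' @export
write_bed <- function(df, path, header = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}
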