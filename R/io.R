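# Small plain-text interchange helpers around Biostrings I/O.

#' Write / read a pooled read set as FASTA
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_reads_fasta <- function(reads, path) {
  Biostrings::writeXStringSet(reads, path)
  invisible(path)
}

#' @rdname write_reads_fasta
#' @export
read_reads_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname write_reads_fasta
#' @param quality constant Phred quality character assigned to every base
#'   of synthetic reads.
#' @export
write_reads_fastq <- function(reads, path, quality = "I") {
  q <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
                                     function(w) strrep(quality, w),
                                     character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write / read a read truth table (read id, library, source gene,
#' duplicate flag) as tab-separated text
#'
#' @param truth data.frame as produced by [emit_reads()].
#' @param path file path.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path)
  read.delim(path, stringsAsFactors = FALSE)
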