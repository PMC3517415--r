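# Count and expression containers plus their plain-text interchange formats.

#' Raw read-count matrix with library totals
#'
#' Genes x libraries matrix of non-negative read counts, together with the
#' per-library total non-redundant read numbers. The totals — not the mapped
#' column sums — are the normalization denominators, so a column sum may be
#' smaller than its total (reads hitting no gene are simply unmapped).
#'
#' @param counts integer matrix, genes as rows (rownames = gene ids),
#'   libraries as columns (colnames = library labels).
#' @param library_totals named vector of total non-redundant reads per
#'   library; defaults to the column sums.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, library_totals = colSums(counts)) {
  if (!is.matrix(counts) || is.null(colnames(counts)) ||
      (nrow(counts) > 0 && is.null(rownames(counts))))
    stop_param("counts must be a matrix with gene and library dimnames")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_param("counts must be non-negative integers")
  if (!all(colnames(counts) %in% names(library_totals)))
    stop_param("library_totals must cover every library column")
  library_totals <- library_totals[colnames(counts)]
  if (any(colSums(counts) > library_totals + 1e-9))
    stop_param("column sums cannot exceed library totals")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, library_totals = library_totals),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library totals:", paste(sprintf("%s=%s", names(x$library_totals),
                                       x$library_totals), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Normalize counts to reads per million
#'
#' Applies the exact normalization
#' `(read count of a gene) / (total non-redundant reads of the library) * 1e6`
#' with no pseudocounts; zeros stay zero.
#'
#' @param counts a [count_matrix()].
#' @return A numeric genes x libraries matrix of per-million expression.
#' @export
normalize_per_million <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  bad <- names(counts$library_totals)[counts$library_totals <= 0]
  if (length(bad))
    stop_param("zero library total for: ", paste(bad, collapse = ", "))
  sweep(counts$counts, 2, counts$library_totals, "/") * 1e6
}

#' Write / read a count matrix as tab-separated text
#'
#' The matrix file has a `gene_id` first column and library labels as
#' header; a companion totals file holds `library` / `total` pairs.
#'
#' @param x a [count_matrix()].
#' @param path matrix file path; the totals go to `<path>.totals`.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns a [count_matrix()].
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tot <- data.frame(library = names(x$library_totals),
                    total = as.vector(x$library_totals))
  write.table(tot, paste0(path, ".totals"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @param path matrix file written by [write_count_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  tot <- read.delim(paste0(path, ".totals"), stringsAsFactors = FALSE)
  count_matrix(m, setNames(tot$total, tot$library))
}

#' Write / read an expression matrix as tab-separated text
#'
#' @param x numeric genes x libraries matrix.
#' @param path file path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
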