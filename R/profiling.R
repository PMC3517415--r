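# Profiling: read-to-contig hit records (external BLAST tabular or the
# internal mapper), best-hit resolution at the E-value threshold, count
# matrix construction and per-million normalization.

#' Parse BLAST tabular hit records (outfmt 6)
#'
#' Reads the 12-column BLAST tabular dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`) into a hit
#' record table suitable for [resolve_best_hits()]. Malformed lines raise an
#' error naming the line number.
#'
#' @param path tabular file path.
#' @return A data.frame with columns `read_id`, `contig_id`, `identity`,
#'   `overlap`, `evalue`, `score`.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop_param("malformed BLAST tabular record at line ",
               which(nf != 12L)[1], " (", nf[which(nf != 12L)[1]],
               " fields, expected 12)")
  m <- do.call(rbind, parts)
  ev <- suppressWarnings(as.numeric(m[, 11]))
  sc <- suppressWarnings(as.numeric(m[, 12]))
  if (anyNA(ev) || anyNA(sc))
    stop_param("malformed BLAST tabular record at line ",
               which(is.na(ev) | is.na(sc))[1], " (non-numeric evalue/score)")
  data.frame(read_id = m[, 1], contig_id = m[, 2],
             identity = as.numeric(m[, 3]) / 100,
             overlap = as.integer(m[, 4]),
             evalue = ev, score = sc, stringsAsFactors = FALSE)
}

#' Map reads to a reference with the internal k-mer mapper
#'
#' A self-contained seeded, ungapped mapper: k-mers of the reference are
#' indexed, each seeded diagonal is extended without gaps, and a hit is
#' emitted when identity and overlap pass their thresholds. The score is
#' `matches - mismatches` and a surrogate expectation value, monotone
#' decreasing in the score (`4^-score`, the chance of that many matched
#' bases arising at random), is attached so [resolve_best_hits()] applies
#' unchanged. For real data supply BLAST tabular hits instead.
#'
#' @param reads a [Biostrings::DNAStringSet].
#' @param reference a non-empty [Biostrings::DNAStringSet].
#' @param k seed k-mer length.
#' @param min_identity minimum fraction of matching bases in the overlap.
#' @param min_overlap minimum aligned length in nt.
#' @param stride distance between successive seed positions on a read.
#' @return A hit-record data.frame as in [read_blast_tab()].
#' @export
map_reads_internal <- function(reads, reference, k = 15, min_identity = 0.95,
                               min_overlap = 50, stride = 5) {
  if (length(reference) == 0) stop_param("empty reference")
  hits <- .map_reads_cpp(as.character(reads), as.character(reference),
                         k = as.integer(k), min_identity = min_identity,
                         min_overlap = as.integer(min_overlap),
                         stride = as.integer(stride))
  score <- hits$matches - hits$mismatches
  data.frame(read_id = names(reads)[hits$read],
             contig_id = names(reference)[hits$ref],
             identity = hits$matches / hits$overlap,
             overlap = hits$overlap,
             evalue = exp(-score * log(4)),
             score = score, stringsAsFactors = FALSE)
}

#' Resolve the best hit per read at an E-value threshold
#'
#' Hits with `evalue >= evalue_max` are discarded; for each read the
#' minimum-E-value hit is kept, with the higher score breaking E-value ties
#' and the lexicographically smaller contig id breaking remaining ties.
#'
#' @param hits hit-record data.frame with columns `read_id`, `contig_id`,
#'   `evalue`, `score`.
#' @param evalue_max E-value threshold (hits must satisfy
#'   `evalue < evalue_max`; default `1e-30`).
#' @return One row per surviving read.
#' @export
resolve_best_hits <- function(hits, evalue_max = 1e-30) {
  need <- c("read_id", "contig_id", "evalue", "score")
  if (!all(need %in% names(hits)))
    stop_param("hits must have columns ", paste(need, collapse = ", "))
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  ord <- order(hits$read_id, hits$evalue, -hits$score, hits$contig_id,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$read_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Build the genes x libraries count matrix from best hits
#'
#' `counts[g, l]` is the number of reads of library `l` whose best hit is
#' gene `g`. The library totals are the libraries' non-redundant read counts
#' — not the mapped counts — so they serve as the per-million denominators.
#'
#' @param best_hits output of [resolve_best_hits()].
#' @param libraries named list of non-redundant [read_library()] objects, or
#'   a named list of read-id character vectors (then supply
#'   `library_totals`).
#' @param gene_ids optional row universe (defaults to the genes observed in
#'   `best_hits`, sorted).
#' @param library_totals named totals per library; defaults to each
#'   library's `n_nonredundant` (or its read count).
#' @return A [count_matrix()].
#' @export
build_count_matrix <- function(best_hits, libraries, gene_ids = NULL,
                               library_totals = NULL) {
  ids <- lapply(libraries, function(l) {
    if (inherits(l, "read_library")) names(l$reads) else as.character(l)
  })
  if (is.null(library_totals))
    library_totals <- vapply(libraries, function(l) {
      if (inherits(l, "read_library")) {
        if (!is.na(l$n_nonredundant)) l$n_nonredundant else length(l$reads)
      } else length(l)
    }, numeric(1))
  read2lib <- rep(names(ids), lengths(ids))
  names(read2lib) <- unlist(ids, use.names = FALSE)
  lib <- read2lib[best_hits$read_id]
  if (anyNA(lib))
    stop_param("hit read id(s) belong to no library: ",
               paste(utils::head(best_hits$read_id[is.na(lib)], 3),
                     collapse = ", "))
  if (is.null(gene_ids)) gene_ids <- sort(unique(best_hits$contig_id))
  tab <- table(factor(best_hits$contig_id, levels = gene_ids),
               factor(lib, levels = names(ids)))
  m <- matrix(as.integer(tab), nrow = length(gene_ids),
              dimnames = list(gene_ids, names(ids)))
  count_matrix(m, library_totals)
}
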