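# Preprocessing: MID demultiplexing, adaptor/quality/length cleaning, and
# exact-duplicate removal per library.

#' A demultiplexed read library
#'
#' Holds the reads of one library together with its stage label, MID and the
#' per-stage bookkeeping counts (`n_raw` >= `n_clean` >= `n_nonredundant`,
#' `NA` until the corresponding step has run).
#'
#' @param label stage label.
#' @param mid the library's MID barcode.
#' @param reads a [Biostrings::DNAStringSet].
#' @param qualities optional [Biostrings::BStringSet] of Phred+33 strings,
#'   aligned with `reads`.
#' @return An object of class `read_library`.
#' @export
read_library <- function(label, mid, reads, qualities = NULL) {
  if (!is.null(qualities) &&
      (length(qualities) != length(reads) ||
       !all(Biostrings::width(qualities) == Biostrings::width(reads))))
    stop_param("qualities must align with reads")
  structure(list(label = label, mid = mid, reads = reads,
                 qualities = qualities, n_raw = length(reads),
                 n_clean = NA_integer_, n_nonredundant = NA_integer_),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("read_library %s (MID %s): raw %d, clean %s, non-redundant %s\n",
              x$label, x$mid, x$n_raw, x$n_clean, x$n_nonredundant))
  invisible(x)
}

# mismatch count between the w-length prefix of each read and a barcode
.prefix_mismatches <- function(seqs, mid) {
  w <- nchar(mid)
  pre <- substr(seqs, 1L, w)
  mm <- rep.int(w, length(seqs)) # short reads can never match
  ok <- nchar(seqs) >= w
  if (any(ok)) {
    m <- integer(sum(ok))
    p <- pre[ok]
    for (j in seq_len(w))
      m <- m + (substr(p, j, j) != substr(mid, j, j))
    mm[ok] <- m
  }
  mm
}

#' Demultiplex pooled reads by 5' MID barcode
#'
#' A read is assigned to a library if and only if exactly one MID matches
#' its 5' prefix within `max_mismatches`; the matching MID is stripped on
#' assignment. Reads matching no MID, or more than one, go to the
#' unassigned pool (ambiguous ties are discarded rather than guessed, to
#' avoid cross-library contamination).
#'
#' @param reads pooled [Biostrings::DNAStringSet] (named by read id).
#' @param mids named character vector, library label -> MID; must be
#'   distinct.
#' @param max_mismatches allowed mismatches in the MID prefix (default 0,
#'   anchored exact matching).
#' @param qualities optional [Biostrings::BStringSet] aligned with `reads`.
#' @return A list with `libraries` (named list of [read_library()]) and
#'   `unassigned` (a [Biostrings::DNAStringSet]).
#' @export
demultiplex <- function(reads, mids, max_mismatches = 0, qualities = NULL) {
  if (anyDuplicated(mids)) stop_param("duplicate MID sequences")
  if (max_mismatches < 0) stop_param("max_mismatches must be >= 0")
  seqs <- as.character(reads)
  hits <- vapply(mids, function(m) .prefix_mismatches(seqs, m) <= max_mismatches,
                 logical(length(seqs)))
  if (length(seqs) == 1L) hits <- matrix(hits, nrow = 1L)
  n_hit <- rowSums(hits)
  assigned <- n_hit == 1L
  lib_idx <- ifelse(assigned, max.col(hits, ties.method = "first"), NA_integer_)

  libraries <- lapply(seq_along(mids), function(i) {
    sel <- which(!is.na(lib_idx) & lib_idx == i)
    w <- nchar(mids[[i]])
    r <- Biostrings::subseq(reads[sel], start = w + 1L)
    q <- if (!is.null(qualities))
      Biostrings::subseq(qualities[sel], start = w + 1L)
    read_library(names(mids)[i], mids[[i]], r, q)
  })
  names(libraries) <- names(mids)
  list(libraries = libraries, unassigned = reads[!assigned])
}

# 3' position at which to cut a read given its Phred+33 quality string:
# first sliding window (length w) whose mean quality < min_mean_q.
.quality_cut <- function(qual, w, min_mean_q) {
  q <- utf8ToInt(qual) - 33L
  n <- length(q)
  if (n < w) return(n)
  cs <- cumsum(c(0L, q))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  bad <- which(means < min_mean_q)
  if (!length(bad)) n else bad[1] - 1L
}

#' Clean a read library: adaptor trimming, quality trimming, length filter
#'
#' Removes adaptor prefixes, truncates reads at an embedded/3' adaptor
#' occurrence, 3'-trims at the first sliding window whose mean Phred quality
#' falls below `min_mean_q` (skipped when qualities are absent), and drops
#' reads shorter than `min_len`. Read order is preserved.
#'
#' @param library a [read_library()].
#' @param adaptors character vector of adaptor sequences.
#' @param min_len minimum surviving read length (reads `< min_len` are
#'   removed; a read of exactly `min_len` is retained).
#' @param window sliding-window length for the quality filter.
#' @param min_mean_q minimum mean Phred quality per window.
#' @return The cleaned [read_library()] with `n_clean` set.
#' @export
clean_reads <- function(library, adaptors = DEFAULT_ADAPTOR, min_len = 50,
                        window = 10, min_mean_q = 20) {
  stopifnot(inherits(library, "read_library"))
  if (min_len < 1) stop_param("min_len must be >= 1")
  seqs <- as.character(library$reads)
  quals <- if (!is.null(library$qualities))
    as.character(library$qualities)

  for (ad in adaptors) {
    w <- nchar(ad)
    pref <- startsWith(seqs, ad)
    seqs[pref] <- substr(seqs[pref], w + 1L, nchar(seqs[pref]))
    if (!is.null(quals))
      quals[pref] <- substr(quals[pref], w + 1L, nchar(quals[pref]))
    pos <- regexpr(ad, seqs, fixed = TRUE)
    emb <- pos > 0L
    seqs[emb] <- substr(seqs[emb], 1L, pos[emb] - 1L)
    if (!is.null(quals))
      quals[emb] <- substr(quals[emb], 1L, pos[emb] - 1L)
  }

  if (!is.null(quals) && length(seqs)) {
    cut <- vapply(quals, .quality_cut, integer(1), w = window,
                  min_mean_q = min_mean_q, USE.NAMES = FALSE)
    seqs <- substr(seqs, 1L, cut)
    quals <- substr(quals, 1L, cut)
  }

  keep <- nchar(seqs) >= min_len
  out <- library
  out$reads <- Biostrings::DNAStringSet(
    setNames(seqs[keep], names(library$reads)[keep]))
  out$qualities <- if (!is.null(quals))
    Biostrings::BStringSet(setNames(quals[keep], names(library$reads)[keep]))
  out$n_clean <- sum(keep)
  out
}

#' Remove exact duplicate reads within a library
#'
#' Reads carrying the same sequence (hence the same length) are collapsed to
#' their first-encountered representative; reads that are proper substrings
#' of others differ in length and are both retained. Idempotent.
#'
#' @param library a cleaned [read_library()].
#' @return The non-redundant [read_library()] with `n_nonredundant` set.
#' @export
dedup <- function(library) {
  stopifnot(inherits(library, "read_library"))
  keep <- !duplicated(as.character(library$reads))
  out <- library
  out$reads <- library$reads[keep]
  if (!is.null(library$qualities)) out$qualities <- library$qualities[keep]
  out$n_nonredundant <- sum(keep)
  if (is.na(out$n_clean)) out$n_clean <- out$n_raw
  out
}

#' Per-library preprocessing summary
#'
#' Raw / clean / non-redundant read counts per library, in the row structure
#' of a sequencing summary table (one column per library plus a total).
#'
#' @param libraries a list of [read_library()] objects.
#' @return A data.frame with rows `raw`, `clean`, `nonredundant`.
#' @export
library_summary <- function(libraries) {
  m <- vapply(libraries, function(l)
    c(raw = l$n_raw, clean = l$n_clean, nonredundant = l$n_nonredundant),
    numeric(3))
  df <- as.data.frame(m, check.names = FALSE)
  df$Total <- rowSums(m)
  df
}

#' Read a MID map from two-column tab-separated text (label, MID)
#' @param path file path.
#' @return Named character vector, label -> MID.
#' @export
read_mid_map <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(df[[2]], df[[1]])
}
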