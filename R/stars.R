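# Gene-reliability framework: Poisson relative counting error and its count
# cutoff, count-depth confidence stars (tau-sigma), Dixon Q-test outlier
# stars, and candidate selection.

#' Dixon r10 critical values for n = 7
#'
#' Two-sided Dean–Dixon r10 critical values at the 90/95/99% confidence
#' levels for seven observations.
#'
#' @format Named numeric vector.
#' @export
DIXON_CRIT_N7 <- c(`90` = 0.507, `95` = 0.568, `99` = 0.680)

#' Poisson relative counting error
#'
#' For an observed count `N` under Poisson statistics, the relative
#' statistical error at a `k`-sigma confidence interval is
#' `E[\%] = 100 * k / sqrt(N)` (k = 1 -> 68.3\%, k = 2 -> 95.5\%,
#' k = 3 -> 99.7\%): the true count lies within `(1 +/- E/100) * N` at its
#' widest with that confidence.
#'
#' @param N observed count(s), > 0.
#' @param k confidence multiplier (number of sigmas), > 0.
#' @return Relative error in percent.
#' @export
relative_error <- function(N, k = 1) {
  if (any(N <= 0)) stop_param("N must be positive")
  if (any(k <= 0)) stop_param("k must be positive")
  100 * k / sqrt(N)
}

#' Count cutoff for a target relative error
#'
#' Inverts [relative_error()]: the smallest integer count whose relative
#' error does not exceed `E_target` percent at `k` sigma,
#' `N = ceiling((100 * k / E_target)^2)`. At the defaults (25\%, 1 sigma)
#' the cutoff is 16.
#'
#' @param E_target target relative error, percent (> 0).
#' @param k confidence multiplier.
#' @return Integer count cutoff.
#' @export
cutoff_count <- function(E_target = 25, k = 1) {
  if (any(E_target <= 0)) stop_param("E_target must be positive")
  as.integer(ceiling((100 * k / E_target)^2))
}

#' Filter genes by summed early-stage counts
#'
#' Sums each gene's raw counts over the developmental-stage subset (by
#' default the seven early stages, excluding the adult tissue library) and
#' retains genes whose sum passes the cutoff. Row order is preserved.
#'
#' @param counts a [count_matrix()].
#' @param stage_subset stage labels to sum over (default [EARLY_STAGES]).
#' @param cutoff count threshold (default [cutoff_count()] at 25\%, 1
#'   sigma, i.e. 16).
#' @param op comparison operator, `">="` (default) or `">"`.
#' @return The filtered [count_matrix()] (all columns kept).
#' @export
filter_by_total <- function(counts, stage_subset = EARLY_STAGES,
                            cutoff = cutoff_count(25, 1), op = c(">=", ">")) {
  stopifnot(inherits(counts, "count_matrix"))
  op <- match.arg(op)
  unknown <- setdiff(stage_subset, colnames(counts$counts))
  if (length(unknown))
    stop_param("unknown stage label(s): ", paste(unknown, collapse = ", "))
  tot <- rowSums(counts$counts[, stage_subset, drop = FALSE])
  keep <- if (op == ">=") tot >= cutoff else tot > cutoff
  count_matrix(counts$counts[keep, , drop = FALSE], counts$library_totals)
}

#' Count-depth confidence stars (tau-sigma)
#'
#' Scores the counting-depth confidence of a gene's seven-stage temporal
#' dynamic. Under the default `min` aggregator the weakest stage limits the
#' confidence of the whole profile: `tau_sigma = floor(sqrt(min(N)) / 4)`,
#' so a gene counted 16 times in each of the seven stages earns exactly one
#' star (each stage at the 25\% one-sigma error level), 64 per stage earns
#' two, and any zero-count stage earns none. A mean-count aggregator is
#' selectable.
#'
#' @param counts_7 the gene's seven early-stage raw counts.
#' @param aggregate `"min"` (default) or `"mean"`.
#' @return Integer star count (>= 0).
#' @export
tau_sigma_stars <- function(counts_7, aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  if (length(counts_7) != 7L)
    stop_param("tau_sigma_stars expects seven stage counts")
  if (any(!is.finite(counts_7)) || any(counts_7 < 0))
    stop_param("counts must be finite and non-negative")
  n <- if (aggregate == "min") min(counts_7) else mean(counts_7)
  as.integer(floor(sqrt(n) / 4))
}

#' Dixon Q test for a single outlier among seven values
#'
#' Computes the Dixon r10 gap-to-range statistics on the sorted values
#' `x(1) <= ... <= x(7)`: `q_low = (x(2) - x(1)) / (x(7) - x(1))` tests the
#' low extreme and `q_high = (x(7) - x(6)) / (x(7) - x(1))` the high one.
#' The larger of the two is compared against the n = 7 critical values to
#' grade the confidence that one data point deviates from the other six.
#' A zero range makes the statistic undefined (`confidence = "none"`).
#'
#' @param values_7 seven finite expression values.
#' @param critical named critical values at the `"90"`, `"95"` and `"99"`
#'   levels (default [DIXON_CRIT_N7]).
#' @return A list of class `q_test` with `q_low`, `q_high`, `q_max` and
#'   `confidence` (one of `"none"`, `"90"`, `"95"`, `"99"`).
#' @export
dixon_q <- function(values_7, critical = DIXON_CRIT_N7) {
  if (length(values_7) != 7L || any(!is.finite(values_7)))
    stop_param("dixon_q expects seven finite values")
  x <- sort(values_7)
  rng <- x[7] - x[1]
  if (rng == 0)
    return(structure(list(q_low = NA_real_, q_high = NA_real_,
                          q_max = NA_real_, confidence = "none"),
                     class = "q_test"))
  q_low <- (x[2] - x[1]) / rng
  q_high <- (x[7] - x[6]) / rng
  q_max <- max(q_low, q_high)
  lv <- c("90", "95", "99")
  passed <- lv[q_max > critical[lv]]
  conf <- if (length(passed)) passed[length(passed)] else "none"
  structure(list(q_low = q_low, q_high = q_high, q_max = q_max,
                 confidence = conf), class = "q_test")
}

#' @export
print.q_test <- function(x, ...) {
  cat(sprintf("Dixon Q (n=7): q_low=%.3f q_high=%.3f -> confidence %s\n",
              x$q_low, x$q_high, x$confidence))
  invisible(x)
}

.q_stars <- function(confidence)
  c(none = 0L, `90` = 1L, `95` = 2L, `99` = 3L)[[confidence]]

#' Assign reliability stars to one gene
#'
#' Combines the count-depth stars (computed on the raw counts) with the
#' Q-test outlier stars (computed on the normalized expression values, the
#' actual "expression data points"; 90/95/99\% confidence maps to 1/2/3
#' stars). A gene is a candidate when its total reaches `min_total`.
#'
#' @param expression_row the gene's seven early-stage normalized expression
#'   values.
#' @param counts_row the gene's seven early-stage raw counts.
#' @param min_total candidate threshold on the total stars (default 2).
#' @param critical Dixon critical values, see [dixon_q()].
#' @param q_on `"expression"` (default) or `"counts"` — which values the
#'   Q test is applied to.
#' @param aggregate tau-sigma aggregator, see [tau_sigma_stars()].
#' @return A one-row data.frame: `tau_sigma_stars`, `q_stars`, `q_max`,
#'   `q_confidence`, `total_stars`, `candidate`.
#' @export
assign_stars <- function(expression_row, counts_row, min_total = 2,
                         critical = DIXON_CRIT_N7,
                         q_on = c("expression", "counts"),
                         aggregate = c("min", "mean")) {
  q_on <- match.arg(q_on)
  if (length(expression_row) != length(counts_row))
    stop_param("expression and count rows are misaligned")
  tau <- tau_sigma_stars(counts_row, aggregate = match.arg(aggregate))
  q <- dixon_q(if (q_on == "expression") expression_row else counts_row,
               critical = critical)
  qs <- .q_stars(q$confidence)
  data.frame(tau_sigma_stars = tau, q_stars = qs, q_max = q$q_max,
             q_confidence = q$confidence, total_stars = tau + qs,
             candidate = (tau + qs) >= min_total)
}

#' Build the per-gene star table
#'
#' Runs the full reliability pipeline over a count matrix: low-count
#' filtering on the summed early-stage counts, tau-sigma stars on raw
#' counts, Dixon Q stars on per-million expression, and candidate flags.
#'
#' @param counts a [count_matrix()] including the early-stage columns.
#' @param stage_subset the seven early stages used for all statistics.
#' @param cutoff low-count filter threshold (default 16).
#' @param min_total candidate threshold on total stars (default 2).
#' @param ... passed to [assign_stars()].
#' @return A data.frame with one row per retained gene (`gene_id`,
#'   `total_count`, star columns, `candidate`), plus the filtered
#'   expression matrix as attribute `"expression"`.
#' @export
star_table <- function(counts, stage_subset = EARLY_STAGES,
                       cutoff = cutoff_count(25, 1), min_total = 2, ...) {
  stopifnot(inherits(counts, "count_matrix"))
  filtered <- filter_by_total(counts, stage_subset, cutoff)
  expr <- normalize_per_million(filtered)
  cnt <- filtered$counts[, stage_subset, drop = FALSE]
  ex7 <- expr[, stage_subset, drop = FALSE]
  rows <- lapply(seq_len(nrow(cnt)), function(i)
    assign_stars(ex7[i, ], cnt[i, ], min_total = min_total, ...))
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(gene_id = rownames(cnt),
                          total_count = rowSums(cnt),
                          stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  attr(out, "expression") <- expr
  out
}

#' Candidate expression matrix
#'
#' Convenience accessor: the per-million expression rows of the genes
#' flagged as candidates in a [star_table()].
#'
#' @param stars a [star_table()] result.
#' @param stage_subset columns to keep (default [EARLY_STAGES]).
#' @return A numeric matrix of candidate genes by stages.
#' @export
candidate_expression <- function(stars, stage_subset = EARLY_STAGES) {
  expr <- attr(stars, "expression")
  expr[stars$gene_id[stars$candidate], stage_subset, drop = FALSE]
}

#' Write a star table as tab-separated text
#' @param stars a [star_table()] result.
#' @param path output path.
#' @export
write_star_table <- function(stars, path) {
  write.table(stars, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
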