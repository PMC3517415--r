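# Cross-platform validation: qPCR relative series, internal-control-gene
# normalization of the sequencing expression, Pearson correlation and the
# strong/acceptable reliability classification.

#' Rescale a qPCR series to fold-changes over its lowest stage
#'
#' Divides by the minimum so the lowest expression level is exactly 1 and
#' the other stages read as fold-changes relative to it.
#'
#' @param raw_levels positive expression levels across stages.
#' @return Numeric vector with `min(.) == 1`.
#' @export
qpcr_relative <- function(raw_levels) {
  if (any(!is.finite(raw_levels)) || any(raw_levels <= 0))
    stop_param("qPCR levels must be positive and finite")
  raw_levels / min(raw_levels)
}

#' Normalize a sequencing expression series to internal control genes
#'
#' Divides the gene's per-stage expression by the geometric mean of the
#' internal control gene (ICG) expressions for that stage, then rescales so
#' the series minimum is 1 (the qPCR fold-change convention, making the two
#' platforms directly comparable). A sequencing series may contain exact
#' zeros (undetected stages); the rescaling then uses the smallest positive
#' value, so the smallest detected stage reads 1 and zeros stay 0. The
#' rescaling is a positive scalar and cannot change a Pearson correlation.
#'
#' @param gene_expression the gene's per-stage expression values.
#' @param icg_expressions ICG expression: a vector (one ICG) or matrix with
#'   ICGs as rows and the same stage columns; must be positive everywhere.
#' @return Numeric series with minimum 1.
#' @export
normalize_454_to_icg <- function(gene_expression, icg_expressions) {
  icg <- rbind(icg_expressions)
  if (ncol(icg) != length(gene_expression))
    stop_param("ICG series must cover the same stages")
  zero <- which(apply(icg <= 0, 2, any))
  if (length(zero)) {
    lab <- if (!is.null(colnames(icg))) colnames(icg)[zero] else zero
    stop_param("non-positive ICG expression at stage(s): ",
               paste(lab, collapse = ", "))
  }
  denom <- exp(colMeans(log(icg)))
  scaled <- gene_expression / denom
  pos <- scaled[scaled > 0]
  if (!length(pos)) stop_param("gene expression is zero at every stage")
  scaled / min(pos)
}

#' Pearson correlation and reliability class of two temporal series
#'
#' Computes the Pearson correlation coefficient between a sequencing-derived
#' series and its qPCR counterpart and classifies the gene's temporal
#' dynamic: `strong` when `r > strong`, `acceptable` when
#' `acceptable < r <= strong`, else `weak`. A constant series has no
#' defined correlation and is reported as `incomparable`.
#'
#' @param series_a,series_b numeric series of equal length (>= 3).
#' @param strong,acceptable classification thresholds (defaults 0.75, 0.6).
#' @return A one-row data.frame with `r` and `class`.
#' @export
pearson_and_classify <- function(series_a, series_b, strong = 0.75,
                                 acceptable = 0.6) {
  if (length(series_a) != length(series_b) || length(series_a) < 3)
    stop_param("series must have equal length >= 3")
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    return(data.frame(r = NA_real_, class = "incomparable",
                      stringsAsFactors = FALSE))
  r <- cor(series_a, series_b)
  cls <- if (r > strong) "strong" else if (r > acceptable) "acceptable"
         else "weak"
  data.frame(r = r, class = cls, stringsAsFactors = FALSE)
}

#' Concordance of a 454 expression matrix with a qPCR panel
#'
#' For each assayed gene: ICG-normalize its sequencing series, min-rescale
#' the qPCR series, correlate, classify.
#'
#' @param expr genes x stages per-million expression matrix.
#' @param qpcr data.frame `gene_id`, `stage`, `level` (as from
#'   [simulate_qpcr()] or a measured panel).
#' @param icg_ids internal control gene ids (rows of `expr`).
#' @param stages stage labels to compare (default [EARLY_STAGES]).
#' @param strong,acceptable classification thresholds.
#' @return A data.frame with one row per gene: `gene_id`, `r`, `class`.
#' @export
concordance_table <- function(expr, qpcr, icg_ids, stages = EARLY_STAGES,
                              strong = 0.75, acceptable = 0.6) {
  if (!all(icg_ids %in% rownames(expr)))
    stop_param("ICG id(s) missing from the expression matrix")
  icg <- expr[icg_ids, stages, drop = FALSE]
  genes <- setdiff(unique(qpcr$gene_id), icg_ids)
  rows <- lapply(genes, function(g) {
    q <- qpcr[qpcr$gene_id == g, ]
    q <- q[match(stages, q$stage), ]
    if (anyNA(q$level)) stop_param("qPCR panel misses stages for ", g)
    s454 <- normalize_454_to_icg(expr[g, stages], icg)
    cbind(data.frame(gene_id = g, stringsAsFactors = FALSE),
          pearson_and_classify(s454, qpcr_relative(q$level),
                               strong, acceptable))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize concordance results
#'
#' Counts and fractions of genes whose correlation exceeds the strong and
#' acceptable thresholds.
#'
#' @param results a [concordance_table()] result (or any data.frame with an
#'   `r` column).
#' @param strong,acceptable thresholds.
#' @return A list: `n`, `n_strong`, `n_acceptable`, `frac_strong`,
#'   `frac_acceptable`.
#' @export
concordance_summary <- function(results, strong = 0.75, acceptable = 0.6) {
  if (!nrow(results)) stop_param("empty result set")
  r <- results$r
  n <- length(r)
  list(n = n,
       n_strong = sum(r > strong, na.rm = TRUE),
       n_acceptable = sum(r > acceptable, na.rm = TRUE),
       frac_strong = sum(r > strong, na.rm = TRUE) / n,
       frac_acceptable = sum(r > acceptable, na.rm = TRUE) / n)
}
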