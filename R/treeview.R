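# Cluster 3.0 / Java TreeView interchange: CDT (ordered data table), GTR
# (gene tree) and ATR (array tree) writers plus a CDT reader for round trips.

.node_name <- function(code, leaf_prefix) {
  ifelse(code < 0, sprintf("%s%dX", leaf_prefix, -code - 1L),
         sprintf("NODE%dX", code))
}

# one tree as GTR/ATR lines: NODEiX  childA  childB  similarity
.tree_lines <- function(tree, leaf_prefix) {
  sim <- 1 - tree$height
  sprintf("NODE%dX\t%s\t%s\t%.6f", seq_len(nrow(tree$merge)),
          .node_name(tree$merge[, 1], leaf_prefix),
          .node_name(tree$merge[, 2], leaf_prefix), sim)
}

#' Write a clustered expression matrix in the Cluster 3.0 dialect
#'
#' Emits `<basename>.cdt` (the processed matrix with rows and columns in
#' tree leaf order, with GID/AID identifiers and GWEIGHT/EWEIGHT fields),
#' `<basename>.gtr` (gene tree) and, when a column tree is present,
#' `<basename>.atr` (array tree). Merge similarities are written as
#' `1 - height`. The files open directly in Java TreeView.
#'
#' @param model a `cluster_model` from [cluster_expression()], or a list
#'   with `processed`, `row_tree` and optionally `col_tree`.
#' @param basename output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_treeview <- function(model, basename) {
  m <- model$processed
  rt <- model$row_tree
  ct <- model$col_tree
  ro <- rt$order
  co <- if (!is.null(ct)) ct$order else seq_len(ncol(m))

  gtr <- paste0(basename, ".gtr")
  writeLines(.tree_lines(rt, "GENE"), gtr)
  paths <- gtr
  if (!is.null(ct)) {
    atr <- paste0(basename, ".atr")
    writeLines(.tree_lines(ct, "ARRY"), atr)
    paths <- c(paths, atr)
  }

  genes <- rownames(m)[ro]
  arrays <- colnames(m)[co]
  vals <- m[ro, co, drop = FALSE]
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", arrays),
                  collapse = "\t")
  lines <- header
  if (!is.null(ct))
    lines <- c(lines, paste(c("AID", "", "", "",
                              sprintf("ARRY%dX", co - 1L)), collapse = "\t"))
  lines <- c(lines, paste(c("EWEIGHT", "", "", "",
                            rep("1", length(arrays))), collapse = "\t"))
  body <- vapply(seq_along(ro), function(i)
    paste(c(sprintf("GENE%dX", ro[i] - 1L), genes[i], genes[i], "1",
            sprintf("%.17g", vals[i, ])), collapse = "\t"),
    character(1))
  cdt <- paste0(basename, ".cdt")
  writeLines(c(lines, body), cdt)
  invisible(c(cdt, paths))
}

#' Read a CDT file back into a matrix
#'
#' Parses a Cluster 3.0 CDT written by [write_treeview()] and returns the
#' ordered expression matrix (UNIQID as rownames, array labels as
#' colnames).
#'
#' @param path CDT file path.
#' @return A numeric matrix.
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  arrays <- header[-(1:4)]
  body <- parts[vapply(parts, function(p)
    !p[1] %in% c("GID", "AID", "EWEIGHT"), logical(1))]
  m <- t(vapply(body, function(p) as.numeric(p[-(1:4)]),
                numeric(length(arrays))))
  rownames(m) <- vapply(body, `[`, character(1), 2L)
  colnames(m) <- arrays
  m
}
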