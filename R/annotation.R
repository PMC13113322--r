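#' Depth-normalized log expression
#'
#' value(c, g) = ln(1 + count(c, g) * target_sum / total(c)). The default
#' `target_sum` is the median per-cell total, so a typical cell's values are
#' close to log1p of its raw counts. Exactly invariant to per-cell depth
#' scaling. Cells with zero total must be removed first (see [qc_filter]).
#'
#' @param m a [cell_matrix].
#' @param target_sum scaling target; `NULL` (default) = median per-cell total.
#' @return Object of class `normalized_matrix`: dense `values` (cells x
#'   genes, dimnames from `m`), `target_sum`, and `cell_meta` carried over.
#' @export
normalize_counts <- function(m, target_sum = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  tot <- Matrix::rowSums(m$counts)
  if (any(tot == 0))
    stopf("%d cell(s) have zero total counts; run qc_filter first",
          sum(tot == 0))
  if (is.null(target_sum)) target_sum <- stats::median(tot)
  vals <- log1p(as.matrix(m$counts) * (target_sum / tot))
  structure(list(values = vals, target_sum = target_sum,
                 cell_meta = m$cell_meta, gene_ids = m$gene_ids),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes, target_sum %.4g\n",
              nrow(x$values), ncol(x$values), x$target_sum))
  invisible(x)
}

#' Default marker panels for the aged liver section
#'
#' Canonical-marker panels used for cell-type scoring: zonated hepatocyte
#' markers (core plus periportal/pericentral genes), macrophage markers
#' (Vcam1, Cd74, H2-Ab1, ...), acute-phase injured-hepatocyte markers
#' (Saa1, Saa2) and the interferon-stimulated gene program (Rsad2, Ifit1,
#' Cmpk2, Ifit3).
#'
#' @return named list of character vectors.
#' @export
default_marker_panels <- function() {
  list(
    hepatocyte = c("Alb", "Ttr", "Apoa1", "Serpina1a",
                   "Sds", "Cyp2f2", "Glul", "Cyp2e1"),
    macrophage = c("Vcam1", "Cd74", "H2-Ab1", "Clec4f", "Adgre1", "Lyz2"),
    hepatocyte_injured = c("Saa1", "Saa2"),
    isg = c("Rsad2", "Ifit1", "Cmpk2", "Ifit3")
  )
}

#' Score cells against marker panels
#'
#' score(c, t) = mean normalized value of panel t's genes present in the
#' matrix. Panel genes absent from the matrix are ignored with a warning; a
#' panel with no present genes is an error.
#'
#' @param nm a [normalized_matrix].
#' @param panels named list of marker gene vectors.
#' @return cells x panels numeric matrix of scores.
#' @export
score_panels <- function(nm, panels) {
  stopifnot(inherits(nm, "normalized_matrix"), is.list(panels),
            length(panels) >= 1L)
  if (any(vapply(panels, length, 1L) == 0L)) stopf("empty marker panel")
  out <- matrix(0, nrow(nm$values), length(panels),
                dimnames = list(rownames(nm$values), names(panels)))
  for (t in names(panels)) {
    present <- intersect(panels[[t]], nm$gene_ids)
    absent <- setdiff(panels[[t]], nm$gene_ids)
    if (!length(present))
      stopf("no genes of panel '%s' are present in the matrix", t)
    if (length(absent))
      warnf("panel '%s': %d marker gene(s) absent and ignored", t,
            length(absent))
    out[, t] <- rowMeans(nm$values[, present, drop = FALSE])
  }
  out
}

#' Assign cell types from panel scores
#'
#' Each cell gets the argmax panel; exact ties or a top-minus-runner-up
#' margin below `min_margin` yield `"unassigned"`.
#'
#' @param scores cells x panels score matrix from [score_panels].
#' @param min_margin minimum lead of the top score, in normalized-expression
#'   units.
#' @return character vector of labels, one per cell.
#' @export
assign_types <- function(scores, min_margin = 0.1) {
  stopifnot(is.matrix(scores), all(is.finite(scores)))
  if (ncol(scores) == 1L) return(rep(colnames(scores), nrow(scores)))
  lab <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    o <- order(scores[i, ], decreasing = TRUE)
    margin <- scores[i, o[1]] - scores[i, o[2]]
    lab[i] <- if (margin < min_margin || margin == 0) "unassigned"
              else colnames(scores)[o[1]]
  }
  lab
}

#' Unsupervised clustering of cells (delegated route)
#'
#' PCA (prcomp) on the normalized values followed by Louvain community
#' detection on a k-nearest-neighbour graph. Mirrors the usual
#' cluster-then-annotate route; marker-panel scoring remains the primary,
#' ground-truth-testable annotation path. Deterministic given `seed`.
#'
#' @param nm a [normalized_matrix].
#' @param n_components number of principal components (reduced automatically
#'   if it reaches the number of cells or genes).
#' @param resolution Louvain resolution; larger = more clusters. The default
#'   0.1 yields a handful of coarse populations on matrices of a few
#'   thousand cells, matching the annotation granularity of the marker
#'   panels.
#' @param k neighbours per cell in the kNN graph.
#' @param seed RNG seed for the community detection.
#' @return integer vector of cluster ids (1-based), one per cell.
#' @export
cluster_cells <- function(nm, n_components = 20L, resolution = 0.1,
                          k = 15L, seed = 1L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  n <- nrow(nm$values)
  if (n < 2L) stopf("clustering needs at least 2 cells")
  if (n <= n_components)
    stopf("fewer cells (%d) than requested components (%d)", n, n_components)
  ncomp <- min(n_components, ncol(nm$values))
  pc <- stats::prcomp(nm$values, center = TRUE, scale. = FALSE,
                      rank. = ncomp)$x
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(pc))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(cl))
}
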