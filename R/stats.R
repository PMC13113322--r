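#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact null distribution (no ties, n_a + n_b <= 12), otherwise the normal
#' approximation with midranks, tie correction and continuity correction.
#' Identical values across both groups return p = 1.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  if (all(c(a, b) == c(a, b)[1])) return(1)
  has_ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !has_ties && (length(a) + length(b)) <= 12L
  stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param method "BH" (default) or "bonferroni".
#' @return adjusted p-values, in input order.
#' @export
bh_adjust <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = method)
}

#' Within-cell-type contrasts of niche groups
#'
#' For each cell type, two contrasts: p21-positive cells versus the
#' remaining cells of that type, and neighbor cells versus the remaining
#' cells of that type. Per gene: log2 fold change of group means of
#' normalized values with pseudocount `eps`, two-sided rank-sum p, BH
#' adjustment within each (type, contrast) family, and the significance rule
#' adjusted p < `alpha` with positive log2FC. Contrasts with fewer than
#' `min_cells` cells in either group are skipped with a recorded reason.
#'
#' @param nm a [normalized_matrix].
#' @param roles niche roles per cell (`p21_positive` / `neighbor` / `other`).
#' @param types cell-type labels per cell.
#' @param min_cells minimum group size per contrast.
#' @param alpha adjusted-p significance level.
#' @param eps pseudocount added to both group means.
#' @param adjust_method multiplicity correction passed to [bh_adjust].
#' @return Object of class `contrast_set`: list with `results` (one
#'   data.frame per tested (type, contrast): gene, log2fc, p, p_adj,
#'   significant) and `skipped` (data.frame of skipped pairs and reasons).
#' @export
run_contrasts <- function(nm, roles, types, min_cells = 3L, alpha = 0.05,
                          eps = 1e-9, adjust_method = "BH") {
  stopifnot(inherits(nm, "normalized_matrix"))
  n <- nrow(nm$values)
  if (length(roles) != n || length(types) != n)
    stopf("roles and types must have one entry per cell")
  bad <- setdiff(unique(roles), c("p21_positive", "neighbor", "other"))
  if (length(bad)) stopf("unknown niche role(s): %s", paste(bad, collapse = ", "))
  results <- list()
  skipped <- data.frame(cell_type = character(), contrast = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (ty in sort(unique(types))) {
    in_type <- types == ty
    for (ctr in c("p21_vs_rest", "neighbor_vs_rest")) {
      grp <- if (ctr == "p21_vs_rest") "p21_positive" else "neighbor"
      sel_a <- in_type & roles == grp
      sel_b <- in_type & roles != grp
      if (sum(sel_a) < min_cells || sum(sel_b) < min_cells) {
        skipped <- rbind(skipped, data.frame(
          cell_type = ty, contrast = ctr,
          reason = sprintf("group sizes %d vs %d below min_cells = %d",
                           sum(sel_a), sum(sel_b), min_cells),
          stringsAsFactors = FALSE))
        next
      }
      va <- nm$values[sel_a, , drop = FALSE]
      vb <- nm$values[sel_b, , drop = FALSE]
      log2fc <- log2((colMeans(va) + eps) / (colMeans(vb) + eps))
      p <- vapply(seq_len(ncol(va)),
                  function(j) rank_sum_test(va[, j], vb[, j]), numeric(1))
      p_adj <- bh_adjust(p, method = adjust_method)
      res <- data.frame(gene = nm$gene_ids, log2fc = log2fc, p = p,
                        p_adj = p_adj,
                        significant = p_adj < alpha & log2fc > 0,
                        stringsAsFactors = FALSE, row.names = NULL)
      attr(res, "cell_type") <- ty
      attr(res, "contrast") <- ctr
      attr(res, "n_a") <- sum(sel_a)
      attr(res, "n_b") <- sum(sel_b)
      results[[paste(ty, ctr, sep = ".")]] <- res
    }
  }
  structure(list(results = results, skipped = skipped),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("contrast_set: %d tested contrast(s), %d skipped\n",
              length(x$results), nrow(x$skipped)))
  for (nm in names(x$results))
    cat(sprintf("  %s: %d significant gene(s)\n", nm,
                sum(x$results[[nm]]$significant)))
  invisible(x)
}

#' Cumulative ISG score per cell
#'
#' Summarises the interferon-stimulated gene program as the mean (default)
#' or sum of normalized values over the panel genes present in the matrix.
#'
#' @param nm a [normalized_matrix].
#' @param panel ISG gene identifiers (default Rsad2, Ifit1, Cmpk2, Ifit3).
#' @param method "mean" or "sum".
#' @return numeric score per cell.
#' @export
isg_score <- function(nm, panel = c("Rsad2", "Ifit1", "Cmpk2", "Ifit3"),
                      method = c("mean", "sum")) {
  stopifnot(inherits(nm, "normalized_matrix"), length(panel) >= 1L)
  method <- match.arg(method)
  present <- intersect(panel, nm$gene_ids)
  if (!length(present)) stopf("no ISG panel genes present in the matrix")
  v <- nm$values[, present, drop = FALSE]
  if (method == "mean") rowMeans(v) else rowSums(v)
}

#' Call ISG status from scores
#'
#' Quantile mode (default): a cell is ISG-positive iff its score strictly
#' exceeds the `threshold_quantile` type-1 (inverse ECDF) quantile of all
#' scores, so on n distinct scores a quantile q marks exactly
#' `n - ceiling(q * n)` cells positive. Cluster mode: when `clusters` and
#' `isg_cluster` are supplied, status is membership of the dedicated ISG
#' cluster.
#'
#' @param scores numeric per-cell ISG scores.
#' @param threshold_quantile quantile in (0, 1).
#' @param clusters optional per-cell cluster ids.
#' @param isg_cluster optional id of the ISG cluster.
#' @return logical vector of ISG status per cell.
#' @export
isg_call <- function(scores, threshold_quantile = 0.98, clusters = NULL,
                     isg_cluster = NULL) {
  if (!is.null(clusters) && !is.null(isg_cluster)) {
    stopifnot(length(clusters) == length(scores))
    return(clusters == isg_cluster)
  }
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stopf("threshold_quantile must lie strictly between 0 and 1")
  thr <- stats::quantile(scores, threshold_quantile, type = 1, names = FALSE)
  scores > thr
}

#' Fisher's exact test on a 2x2 table, with the sample odds ratio
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (within relative tolerance 1e-7).
#' The odds ratio is the sample estimate (a*d)/(b*c) (`Inf` when b*c = 0 and
#' a*d > 0), not the conditional MLE. A zero margin yields p = 1 and a
#' missing odds ratio.
#'
#' @param tab 2x2 matrix (or length-4 vector, column-major) of counts
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("table entries must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p_value = 1, odds_ratio = NA_real_))
  p <- stats::fisher.test(tab)$p.value
  or <- if (b * cc == 0) {
    if (a * d > 0) Inf else NA_real_
  } else a * d / (b * cc)
  list(p_value = p, odds_ratio = or)
}

#' Replicate-wise overlap analysis of p21 and ISG status
#'
#' For every replicate, the 2x2 contingency table over (p21 status) x
#' (ISG status) with its Fisher exact test and sample odds ratio; plus a
#' pooled table reporting the percentage of all cells in each of the four
#' categories.
#'
#' @param p21 logical p21 status per cell.
#' @param isg logical ISG status per cell.
#' @param replicate replicate ids per cell.
#' @return list with `per_replicate` (data.frame: replicate, the four
#'   counts, p_value, odds_ratio) and `pooled` (data.frame: category, n,
#'   percent).
#' @export
overlap_analysis <- function(p21, isg, replicate = rep(1L, length(p21))) {
  stopifnot(length(p21) == length(isg), length(replicate) == length(p21))
  if (anyNA(p21) || anyNA(isg)) stopf("statuses must be defined for every cell")
  reps <- sort(unique(replicate))
  rows <- lapply(reps, function(r) {
    sel <- replicate == r
    if (!sum(sel)) {
      message(sprintf("overlap_analysis: replicate %s has no cells; skipped", r))
      return(NULL)
    }
    tab <- rbind(c(sum(p21[sel] & isg[sel]),  sum(p21[sel] & !isg[sel])),
                 c(sum(!p21[sel] & isg[sel]), sum(!p21[sel] & !isg[sel])))
    ft <- fisher_exact_2x2(tab)
    data.frame(replicate = as.character(r),
               p21_pos_isg_pos = tab[1, 1], p21_pos_isg_neg = tab[1, 2],
               p21_neg_isg_pos = tab[2, 1], p21_neg_isg_neg = tab[2, 2],
               p_value = ft$p_value, odds_ratio = ft$odds_ratio,
               stringsAsFactors = FALSE)
  })
  per_rep <- do.call(rbind, rows)
  n_tot <- length(p21)
  counts <- c(p21_pos_isg_pos = sum(p21 & isg),
              p21_pos_isg_neg = sum(p21 & !isg),
              p21_neg_isg_pos = sum(!p21 & isg),
              p21_neg_isg_neg = sum(!p21 & !isg))
  pooled <- data.frame(category = names(counts), n = as.integer(counts),
                       percent = 100 * counts / n_tot,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(per_replicate = per_rep, pooled = pooled)
}
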