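#' Assign niche roles from the contact graph
#'
#' Cells are partitioned into three mutually exclusive roles:
#' `p21_positive` (reporter-positive cells), `neighbor` (cells whose segment
#' boundary directly contacts at least one p21-positive segment and that are
#' not themselves p21-positive) and `other`. Neighborhood depth is one
#' (direct contact only).
#'
#' @param g a [neighbor_graph].
#' @param p21_ids integer vector of p21-positive segment ids (must be nodes
#'   of `g`).
#' @return data.frame with `segment_id` and `niche_role`.
#' @export
assign_roles <- function(g, p21_ids) {
  stopifnot(inherits(g, "neighbor_graph"))
  p21_ids <- as.integer(p21_ids)
  unknown <- setdiff(p21_ids, g$nodes)
  if (length(unknown))
    stopf("p21 id(s) not present in the graph: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  is_p21 <- g$nodes %in% p21_ids
  touch <- logical(length(g$nodes))
  if (nrow(g$edges)) {
    a <- g$edges[, 1]; b <- g$edges[, 2]
    ap <- a %in% p21_ids; bp <- b %in% p21_ids
    touched_ids <- unique(c(b[ap], a[bp]))
    touch <- g$nodes %in% touched_ids
  }
  role <- ifelse(is_p21, "p21_positive",
          ifelse(touch, "neighbor", "other"))
  data.frame(segment_id = g$nodes, niche_role = role,
             stringsAsFactors = FALSE)
}

#' Cell-type composition per niche role
#'
#' Counts and within-role fractions of every (role, type) combination; the
#' fractions of each role sum to 1.
#'
#' @param roles character vector of niche roles, one per cell.
#' @param types character vector of cell types, one per cell.
#' @return data.frame with `niche_role`, `cell_type`, `n` and `fraction`.
#' @export
composition_table <- function(roles, types) {
  stopifnot(length(roles) == length(types))
  tab <- as.data.frame(table(niche_role = roles, cell_type = types),
                       responseName = "n", stringsAsFactors = FALSE)
  tot <- stats::ave(tab$n, tab$niche_role, FUN = sum)
  tab$fraction <- ifelse(tot > 0, tab$n / tot, NA_real_)
  tab[order(tab$niche_role, tab$cell_type), , drop = FALSE]
}

#' p21 positivity rate per cell type and replicate
#'
#' ratio = p21-positive cells of the type / all cells of the type, computed
#' per replicate and pooled (replicate `"pooled"`). Types absent from a
#' replicate are emitted with `NA`.
#'
#' @param is_p21 logical vector, one per cell.
#' @param types character vector of cell types.
#' @param replicate replicate ids, one per cell (default: single replicate).
#' @return data.frame with `replicate`, `cell_type`, `n_cells`, `n_p21`,
#'   `ratio`.
#' @export
p21_rate_by_type <- function(is_p21, types, replicate = rep(1L, length(types))) {
  stopifnot(length(is_p21) == length(types),
            length(replicate) == length(types))
  one <- function(rep_label, sel) {
    tt <- sort(unique(types))
    n <- vapply(tt, function(t) sum(sel & types == t), 1L)
    k <- vapply(tt, function(t) sum(sel & types == t & is_p21), 1L)
    data.frame(replicate = rep_label, cell_type = tt, n_cells = n, n_p21 = k,
               ratio = ifelse(n > 0, k / n, NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  reps <- sort(unique(replicate))
  out <- do.call(rbind, lapply(reps, function(r)
    one(as.character(r), replicate == r)))
  rbind(out, one("pooled", rep(TRUE, length(types))))
}
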