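#' Nuclear seed set
#'
#' Seeds are single-pixel nuclear anchors detected as DAPI intensity peaks.
#' Ids are consecutive from 1, assigned in descending smoothed-intensity
#' order with ties broken by (y, x) lexicographic order. Coordinates are
#' 0-based integer pixel positions (x = column, y = row).
#'
#' @param seeds data.frame with columns `id`, `x`, `y`, `dapi_intensity`.
#' @param shape integer c(height, width) of the source image.
#' @return Object of class `seed_set`.
#' @export
seed_set <- function(seeds, shape) {
  stopifnot(is.data.frame(seeds),
            all(c("id", "x", "y", "dapi_intensity") %in% names(seeds)))
  n <- nrow(seeds)
  if (n && !identical(as.integer(seeds$id), seq_len(n)))
    stopf("seed ids must be consecutive integers starting at 1")
  if (n && (any(seeds$x < 0) || any(seeds$x >= shape[2]) ||
            any(seeds$y < 0) || any(seeds$y >= shape[1])))
    stopf("seed coordinates must lie within the image bounds")
  structure(list(seeds = seeds, shape = as.integer(shape)),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("seed_set: %d nuclear seeds on a %d x %d grid\n",
              nrow(x$seeds), x$shape[2], x$shape[1]))
  invisible(x)
}

#' Detect nuclear seeds as smoothed DAPI peaks
#'
#' The DAPI channel is Gaussian-smoothed, and strict local maxima (greater
#' than all 8 neighbours) with smoothed intensity >= `min_intensity` become
#' candidate seeds. Candidates closer than `min_distance_px` (Euclidean) to a
#' stronger accepted candidate are suppressed greedily in descending-intensity
#' order. When `min_intensity` is `NULL` it defaults to the Otsu threshold of
#' the smoothed image.
#'
#' @param dapi non-negative intensity matrix (rows = y, columns = x).
#' @param smooth_sigma Gaussian smoothing sigma in pixels (0 disables).
#' @param min_distance_px minimum separation between accepted seeds.
#' @param min_intensity minimum smoothed intensity, or `NULL` for Otsu.
#' @return A [seed_set]; `dapi_intensity` holds the smoothed peak value.
#' @export
detect_nuclei <- function(dapi, smooth_sigma = 2, min_distance_px = 4L,
                          min_intensity = NULL) {
  if (!is.matrix(dapi) || !length(dapi)) stopf("dapi must be a non-empty matrix")
  if (any(dapi < 0)) stopf("dapi intensities must be non-negative")
  if (smooth_sigma < 0) stopf("smooth_sigma must be >= 0")
  sm <- if (smooth_sigma > 0)
    EBImage::gblur(dapi, sigma = smooth_sigma, boundary = "replicate")
  else dapi
  if (is.null(min_intensity)) {
    rng <- range(sm)
    min_intensity <- if (rng[2] > rng[1])
      EBImage::otsu(EBImage::Image((sm - rng[1]) / (rng[2] - rng[1]))) *
        (rng[2] - rng[1]) + rng[1]
    else rng[2] + 1  # flat image: nothing can pass
  }
  nr <- nrow(sm); nc <- ncol(sm)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- sm
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  is_max <- rep(TRUE, nr * nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- pad[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx]
    is_max <- is_max & (core > nb)
  }
  cand <- which(is_max & (core >= min_intensity))
  if (!length(cand))
    return(seed_set(data.frame(id = integer(), x = integer(), y = integer(),
                               dapi_intensity = numeric()), dim(dapi)))
  cy <- (cand - 1L) %% nr          # 0-based row
  cx <- (cand - 1L) %/% nr         # 0-based col
  val <- sm[cand]
  o <- order(-val, cy, cx)
  cx <- cx[o]; cy <- cy[o]; val <- val[o]
  keep <- logical(length(o))
  min_d2 <- min_distance_px^2
  for (i in seq_along(o)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    acc <- which(keep[seq_len(i - 1L)])
    keep[i] <- all((cx[acc] - cx[i])^2 + (cy[acc] - cy[i])^2 >= min_d2)
  }
  seeds <- data.frame(id = seq_len(sum(keep)), x = cx[keep], y = cy[keep],
                      dapi_intensity = val[keep])
  seed_set(seeds, dim(dapi))
}

#' Segment label map
#'
#' Integer label image: 0 = background, k >= 1 = territory of seed k. Every
#' labeled pixel lies within `radius_px` (Euclidean, between pixel centers,
#' inclusive) of its seed.
#'
#' @param labels integer matrix of labels.
#' @param radius_px the radius cap used to grow the map, in pixels.
#' @return Object of class `segment_map`.
#' @export
segment_map <- function(labels, radius_px) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stopf("labels must be >= 0")
  structure(list(labels = labels, radius_px = as.numeric(radius_px)),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf(
    "segment_map: %d x %d px, %d segments, radius cap %.3g px\n",
    ncol(x$labels), nrow(x$labels), length(setdiff(unique(as.vector(x$labels)), 0L)),
    x$radius_px))
  invisible(x)
}

#' Grow radius-capped cell territories from nuclear seeds
#'
#' Implements distance-capped Voronoi expansion: each pixel receives the label
#' of its nearest seed (Euclidean distance between pixel centers) provided
#' that distance is at most `radius_px`; expansion is isotropic and stops
#' where neighbouring territories meet. Pixels equidistant from two seeds go
#' to the smaller seed id; pixels farther than `radius_px` from every seed
#' stay background (0). The default radius of 6 px corresponds to roughly
#' 15 um at 2.5 um/px, a hepatocyte-scale territory.
#'
#' @param seeds a [seed_set].
#' @param shape integer c(height, width) of the output grid; defaults to the
#'   seed set's source shape.
#' @param radius_px positive radius cap in pixels.
#' @return A [segment_map].
#' @export
grow_segments <- function(seeds, shape = seeds$shape, radius_px = 6) {
  stopifnot(inherits(seeds, "seed_set"))
  if (radius_px <= 0) stopf("radius_px must be > 0")
  s <- seeds$seeds
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (nrow(s)) {
    if (anyDuplicated(s[, c("x", "y")]))
      stopf("duplicate seed coordinates")
    if (any(s$x < 0 | s$x >= nc | s$y < 0 | s$y >= nr))
      stopf("seed outside the requested shape")
  }
  labels <- matrix(0L, nr, nc)
  if (!nrow(s)) return(segment_map(labels, radius_px))
  best <- matrix(Inf, nr, nc)
  off <- disc_offsets(radius_px)
  d2 <- off[, "dx"]^2 + off[, "dy"]^2
  # seeds processed in increasing id order; only a strictly smaller distance
  # displaces an earlier label, so ties resolve to the smaller id
  for (i in seq_len(nrow(s))) {
    px <- s$x[i] + off[, "dx"]
    py <- s$y[i] + off[, "dy"]
    ok <- px >= 0L & px < nc & py >= 0L & py < nr
    idx <- py[ok] + 1L + (px[ok]) * nr
    di <- d2[ok]
    upd <- di < best[idx]
    if (any(upd)) {
      ii <- idx[upd]
      best[ii] <- di[upd]
      labels[ii] <- i
    }
  }
  segment_map(labels, radius_px)
}

#' Boundary-contact graph between segments
#'
#' Two segments are connected iff some pixel of one lies within the chosen
#' pixel neighbourhood (4- or 8-connectivity) of a pixel of the other.
#' Background (label 0) creates no edges. 8-connectivity, the default, counts
#' corner contact as contact.
#'
#' @param seg a [segment_map].
#' @param connectivity 4 or 8.
#' @return Object of class `neighbor_graph`: list with `nodes` (sorted
#'   segment ids) and `edges` (2-column matrix of id pairs, a < b).
#' @export
contact_graph <- function(seg, connectivity = 8L) {
  stopifnot(inherits(seg, "segment_map"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  L <- seg$labels
  nr <- nrow(L); nc <- ncol(L)
  pairs <- list(
    cbind(as.vector(L[-nr, ]), as.vector(L[-1L, ])),   # vertical
    cbind(as.vector(L[, -nc]), as.vector(L[, -1L]))    # horizontal
  )
  if (connectivity == 8L) {
    pairs <- c(pairs, list(
      cbind(as.vector(L[-nr, -nc]), as.vector(L[-1L, -1L])),  # down-right
      cbind(as.vector(L[-nr, -1L]), as.vector(L[-1L, -nc]))   # down-left
    ))
  }
  e <- do.call(rbind, pairs)
  e <- e[e[, 1] > 0L & e[, 2] > 0L & e[, 1] != e[, 2], , drop = FALSE]
  if (nrow(e)) {
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- unique(e)
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  nodes <- sort(setdiff(unique(as.vector(L)), 0L))
  neighbor_graph(nodes, e)
}

#' Neighbor graph constructor
#'
#' @param nodes integer vector of segment ids.
#' @param edges 2-column matrix of unordered id pairs.
#' @return Object of class `neighbor_graph`.
#' @export
neighbor_graph <- function(nodes, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stopf("self-edges are not allowed")
    if (!all(edges %in% nodes)) stopf("edges reference unknown nodes")
  }
  structure(list(nodes = as.integer(nodes), edges = edges),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d nodes, %d contact edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write seeds as TSV
#' @param seeds a [seed_set].
#' @param path output path.
#' @export
write_seeds <- function(seeds, path) {
  stopifnot(inherits(seeds, "seed_set"))
  utils::write.table(seeds$seeds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
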