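`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_finite_coords <- function(x, y, what = "coordinates") {
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("non-finite %s supplied", what)
  invisible(TRUE)
}

# Integer lattice offsets (dx, dy) with dx^2 + dy^2 <= r^2, as a 2-column
# matrix. Used by segment growing and by the synthetic renderer.
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  keep <- g$dx^2 + g$dy^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}
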