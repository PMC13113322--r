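#' Control point pairs for image-to-array registration
#'
#' @param src 2-column matrix (or data.frame) of image coordinates.
#' @param dst 2-column matrix of array coordinates, same number of rows.
#' @return Object of class `control_points`.
#' @export
control_points <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L, nrow(src) == nrow(dst))
  assert_finite_coords(src[, 1], src[, 2], "control points")
  assert_finite_coords(dst[, 1], dst[, 2], "control points")
  if (anyDuplicated(src)) stopf("duplicated source control points")
  structure(list(src = unname(src), dst = unname(dst)),
            class = "control_points")
}

#' Read control points from TSV (columns x_img, y_img, x_arr, y_arr)
#' @param path TSV path.
#' @export
read_control_points <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("x_img", "y_img", "x_arr", "y_arr")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("control point file lacks column(s): %s",
                          paste(miss, collapse = ", "))
  control_points(d[, c("x_img", "y_img")], d[, c("x_arr", "y_arr")])
}

#' Fit a planar transform to control points
#'
#' Least-squares estimate of the map from image to array coordinates.
#' `model = "similarity"` (default) fits rotation + isotropic scale +
#' translation in closed form (no reflection); `model = "affine"` fits a
#' full 2x3 affine by QR least squares. Sequential imaging of one physical
#' section rarely needs shear, hence the similarity default.
#'
#' @param cp a [control_points] object (>= 2 pairs for similarity, >= 3
#'   non-collinear pairs for affine).
#' @param model "similarity" or "affine".
#' @return Object of class `planar_transform`: 2x3 coefficient matrix `A`
#'   (maps column vector (x, y, 1)), `model` and `rms_residual`.
#' @export
fit_transform <- function(cp, model = c("similarity", "affine")) {
  stopifnot(inherits(cp, "control_points"))
  model <- match.arg(model)
  src <- cp$src; dst <- cp$dst
  n <- nrow(src)
  if (model == "similarity") {
    if (n < 2L) stopf("similarity fit needs at least 2 control point pairs")
    z <- complex(real = src[, 1], imaginary = src[, 2])
    w <- complex(real = dst[, 1], imaginary = dst[, 2])
    zc <- z - mean(z); wc <- w - mean(w)
    denom <- sum(Mod(zc)^2)
    if (denom < 1e-12) stopf("degenerate control points: zero spread")
    a <- sum(wc * Conj(zc)) / denom
    t <- mean(w) - a * mean(z)
    A <- matrix(c(Re(a), -Im(a), Re(t),
                  Im(a),  Re(a), Im(t)), 2L, 3L, byrow = TRUE)
  } else {
    if (n < 3L) stopf("affine fit needs at least 3 control point pairs")
    X <- cbind(src, 1)
    q <- qr(X)
    if (q$rank < 3L) stopf("degenerate (collinear) control points for affine fit")
    A <- unname(t(qr.coef(q, dst)))  # rows (x', y'), cols (x, y, 1)
  }
  pred <- apply_transform(structure(list(A = A, model = model,
                                         rms_residual = 0),
                                    class = "planar_transform"), src)
  rms <- sqrt(mean(rowSums((pred - dst)^2)))
  structure(list(A = A, model = model, rms_residual = rms),
            class = "planar_transform")
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf("planar_transform (%s), rms residual %.4g px\n", x$model,
              x$rms_residual))
  print(x$A)
  invisible(x)
}

#' Apply a planar transform to points
#'
#' @param t a [planar_transform].
#' @param pts 2-column matrix of (x, y) coordinates.
#' @return matrix of transformed coordinates, same shape.
#' @export
apply_transform <- function(t, pts) {
  stopifnot(inherits(t, "planar_transform"))
  pts <- as.matrix(pts)
  assert_finite_coords(pts[, 1], pts[, 2])
  out <- cbind(pts, 1) %*% t(t$A)
  colnames(out) <- c("x", "y")
  out
}

#' Identity transform (images and array share a frame)
#' @export
identity_transform <- function() {
  structure(list(A = cbind(diag(2), c(0, 0)), model = "similarity",
                 rms_residual = 0), class = "planar_transform")
}

#' Serialize / deserialize a planar transform as YAML
#' @param t a [planar_transform].
#' @param path YAML file path.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "planar_transform"))
  yaml::write_yaml(list(model = t$model, matrix = as.list(as.data.frame(t$A)),
                        rms_residual = t$rms_residual), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  d <- yaml::read_yaml(path)
  A <- do.call(cbind, lapply(d$matrix, unlist))
  dimnames(A) <- NULL
  structure(list(A = A, model = d$model, rms_residual = d$rms_residual),
            class = "planar_transform")
}
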