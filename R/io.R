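#' Spatially resolved transcript table
#'
#' An `sdge_table` holds a spatial digital gene expression (sDGE) point cloud:
#' one record per captured transcript (or per identical-coordinate molecule
#' group), with sub-pixel x/y coordinates, a gene identifier and a positive
#' integer count. Coordinates are 0-based pixel units, origin at the top-left
#' corner, x = column, y = row.
#'
#' @param records data.frame with columns `x`, `y` (finite numerics), `gene`
#'   (non-empty character) and `count` (positive integers).
#' @param pixel_size_um micrometers per pixel (single positive number).
#' @return An object of class `sdge_table`: a list with elements `records`
#'   and `pixel_size_um`.
#' @export
sdge_table <- function(records, pixel_size_um) {
  stopifnot(is.data.frame(records))
  need <- c("x", "y", "gene", "count")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("sDGE records are missing column(s): %s", paste(miss, collapse = ", "))
  records <- records[, need, drop = FALSE]
  records$x <- as.numeric(records$x)
  records$y <- as.numeric(records$y)
  records$gene <- as.character(records$gene)
  records$count <- as.integer(records$count)
  if (nrow(records)) {
    assert_finite_coords(records$x, records$y, "sDGE coordinates")
    if (anyNA(records$count) || any(records$count < 1L))
      stopf("sDGE counts must be integers >= 1")
    if (any(!nzchar(records$gene)) || anyNA(records$gene))
      stopf("sDGE gene identifiers must be non-empty")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be a single positive number")
  structure(list(records = records, pixel_size_um = as.numeric(pixel_size_um)),
            class = "sdge_table")
}

#' @export
print.sdge_table <- function(x, ...) {
  cat(sprintf("sdge_table: %d transcript records, %d genes, %.3g um/px\n",
              nrow(x$records), length(unique(x$records$gene)), x$pixel_size_um))
  invisible(x)
}

#' Read an sDGE table from a delimited text file
#'
#' Expects a tab-separated file with a header naming at least the columns
#' `x`, `y`, `gene`, `count`. Malformed rows (non-numeric or non-finite
#' coordinates, counts below 1 or non-integral, empty gene ids) are rejected
#' individually and reported with their line numbers; they are returned in the
#' `rejects` attribute so that input rows = retained records + rejects.
#'
#' @param path path to the TSV file.
#' @param pixel_size_um micrometers per pixel of the coordinate system.
#' @param sep field separator, default tab.
#' @return An [sdge_table] with attribute `rejects` (data.frame of `line` and
#'   `reason`).
#' @export
read_sdge <- function(path, pixel_size_um, sep = "\t") {
  if (!file.exists(path)) stopf("sDGE file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("x", "y", "gene", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("sDGE file %s lacks required column(s): %s", path,
          paste(miss, collapse = ", "))
  n <- nrow(raw)
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  cnt <- suppressWarnings(as.numeric(raw$count))
  reason <- rep(NA_character_, n)
  bad_coord <- !is.finite(x) | !is.finite(y)
  reason[bad_coord] <- "non-numeric or non-finite coordinate"
  bad_count <- is.na(reason) & (!is.finite(cnt) | cnt < 1 | cnt != round(cnt))
  reason[bad_count] <- "count must be an integer >= 1"
  bad_gene <- is.na(reason) & (!nzchar(raw$gene) | is.na(raw$gene))
  reason[bad_gene] <- "empty gene identifier"
  keep <- is.na(reason)
  rejects <- data.frame(line = which(!keep) + 1L,  # +1 for the header line
                        reason = reason[!keep], stringsAsFactors = FALSE)
  if (nrow(rejects))
    warnf("read_sdge: rejected %d malformed row(s) (first at line %d: %s)",
          nrow(rejects), rejects$line[1], rejects$reason[1])
  rec <- data.frame(x = x[keep], y = y[keep], gene = raw$gene[keep],
                    count = as.integer(cnt[keep]), stringsAsFactors = FALSE)
  out <- sdge_table(rec, pixel_size_um)
  attr(out, "rejects") <- rejects
  out
}

#' Write an sDGE table as TSV
#'
#' @param sdge an [sdge_table].
#' @param path output file path.
#' @export
write_sdge <- function(sdge, path) {
  stopifnot(inherits(sdge, "sdge_table"))
  utils::write.table(sdge$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Multi-channel fluorescence stack
#'
#' Named list of co-registered 2-D non-negative intensity matrices (rows = y,
#' columns = x) of identical shape, e.g. DAPI, GFP and tdTomato channels, with
#' a common pixel size.
#'
#' @param channels named list of numeric matrices.
#' @param pixel_size_um micrometers per pixel.
#' @return Object of class `fluorescence_stack`.
#' @export
fluorescence_stack <- function(channels, pixel_size_um) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stopf("fluorescence channels must be named")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, TRUE)))
    stopf("each channel must be a matrix")
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d0), TRUE)))
    stopf("all channels must share the same shape")
  if (any(vapply(channels, function(m) any(m < 0), TRUE)))
    stopf("fluorescence intensities must be non-negative")
  structure(list(channels = channels,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "fluorescence_stack")
}

#' @export
print.fluorescence_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("fluorescence_stack: %s, %d x %d px, %.3g um/px\n",
              paste(names(x$channels), collapse = "/"), d[2], d[1],
              x$pixel_size_um))
  invisible(x)
}

# tiff::writeTIFF stores samples in [0, 1]; intensities are divided by a
# power-of-two scale >= their maximum (exact in binary floating point) and the
# scale is recorded in a YAML sidecar, so round-trip error is float32
# quantisation only (~1e-7 relative).
pow2_scale <- function(m) {
  mx <- max(m, 1e-12)
  2^ceiling(log2(max(mx, 1)))
}

#' Write / read a fluorescence stack as per-channel TIFF files
#'
#' Each channel is written to `<dir>/<channel>.tif` as 32-bit float TIFF,
#' scaled into \[0, 1\] by a per-channel power-of-two factor recorded in
#' `<dir>/channels.yml` together with the pixel size.
#'
#' @param stack a [fluorescence_stack].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fluorescence <- function(stack, dir) {
  stopifnot(inherits(stack, "fluorescence_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- lapply(stack$channels, pow2_scale)
  for (ch in names(stack$channels)) {
    tiff::writeTIFF(stack$channels[[ch]] / scales[[ch]],
                    file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 32L)
  }
  yaml::write_yaml(list(pixel_size_um = stack$pixel_size_um,
                        channels = scales),
                   file.path(dir, "channels.yml"))
  invisible(dir)
}

#' @rdname write_fluorescence
#' @export
read_fluorescence <- function(dir) {
  meta_path <- file.path(dir, "channels.yml")
  if (!file.exists(meta_path)) stopf("no channels.yml in %s", dir)
  meta <- yaml::read_yaml(meta_path)
  chans <- lapply(names(meta$channels), function(ch) {
    f <- file.path(dir, paste0(ch, ".tif"))
    if (!file.exists(f)) stopf("missing channel image: %s", f)
    tiff::readTIFF(f) * meta$channels[[ch]]
  })
  names(chans) <- names(meta$channels)
  fluorescence_stack(chans, meta$pixel_size_um)
}

#' Write / read a segment label map as 32-bit TIFF
#'
#' Labels (integers, 0 = background) are stored as float32 samples scaled by
#' 2^-24, which is exact for label values below 2^24. The growth radius is
#' recorded in a YAML sidecar `<path>.yml`.
#'
#' @param seg a [segment_map].
#' @param path output TIFF path.
#' @export
write_segment_map <- function(seg, path) {
  stopifnot(inherits(seg, "segment_map"))
  if (max(seg$labels) >= 2^24)
    stopf("label values >= 2^24 cannot be stored losslessly")
  tiff::writeTIFF(seg$labels / 2^24, path, bits.per.sample = 32L)
  yaml::write_yaml(list(radius_px = seg$radius_px), paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_segment_map
#' @export
read_segment_map <- function(path) {
  labels <- round(tiff::readTIFF(path) * 2^24)
  storage.mode(labels) <- "integer"
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  segment_map(labels, meta$radius_px)
}

#' Cell-by-gene count matrix with per-cell metadata
#'
#' @param counts cells x genes matrix of non-negative integer counts (dense
#'   matrix or any `Matrix` sparse class; stored as `dgCMatrix`).
#' @param cell_meta data.frame with one row per cell; must contain a
#'   `segment_id` column. Typical columns: `segment_id`, `x`, `y`, `area_px`,
#'   `replicate`, `reporter_class`, `cell_type`, `niche_role`.
#' @param gene_ids character vector of gene identifiers, one per column.
#' @return Object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta, gene_ids) {
  counts <- Matrix::Matrix(counts, sparse = TRUE) * 1  # force numeric cells
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  stopifnot(is.data.frame(cell_meta))
  if (!"segment_id" %in% names(cell_meta))
    stopf("cell_meta must contain a segment_id column")
  if (nrow(cell_meta) != nrow(counts))
    stopf("cell_meta rows (%d) must match matrix rows (%d)",
          nrow(cell_meta), nrow(counts))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ncol(counts))
    stopf("gene_ids length (%d) must match matrix columns (%d)",
          length(gene_ids), ncol(counts))
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  dimnames(counts) <- list(as.character(cell_meta$segment_id), gene_ids)
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta, gene_ids = gene_ids),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d genes, %d stored counts\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' Write a cell matrix as MatrixMarket triplets plus TSV sidecars
#'
#' Writes `matrix.mtx` (sparse triplets), `cells.tsv` (per-cell metadata) and
#' `genes.tsv` (ordered gene identifiers) into `dir`. The reader inverts the
#' writer exactly.
#'
#' @param m a [cell_matrix].
#' @param dir output directory (created if needed).
#' @export
write_cell_matrix <- function(m, dir) {
  stopifnot(inherits(m, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(m$cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = m$gene_ids),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  cells <- utils::read.table(file.path(dir, "cells.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  genes <- utils::read.table(file.path(dir, "genes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)$gene
  cell_matrix(counts, cells, as.character(genes))
}
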