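#' Aggregate transcripts into per-segment cells
#'
#' Each sDGE record is binned by truncation to its containing pixel and its
#' count credited to (segment at that pixel, gene). Records landing on
#' background (label 0) are tallied as unassigned; records falling outside
#' the image bounds are rejected and reported. Counts are conserved exactly:
#' matrix total + unassigned + rejected = input total.
#'
#' All segments present in the map receive a row, including segments that
#' captured no transcripts (their row is all zero); QC removes them later.
#'
#' @param sdge an [sdge_table].
#' @param seg a [segment_map].
#' @param replicate replicate identifier recorded in the cell metadata.
#' @return list with `matrix` (a [cell_matrix]), `unassigned_count`
#'   (total count on background) and `rejected_count` (total count out of
#'   bounds).
#' @export
assign_transcripts <- function(sdge, seg, replicate = 1L) {
  stopifnot(inherits(sdge, "sdge_table"), inherits(seg, "segment_map"))
  L <- seg$labels
  nr <- nrow(L); nc <- ncol(L)
  rec <- sdge$records
  px <- floor(rec$x); py <- floor(rec$y)
  inb <- px >= 0 & px < nc & py >= 0 & py < nr
  rejected <- sum(rec$count[!inb])
  if (rejected > 0)
    warnf("assign_transcripts: %d record(s) outside the image were rejected",
          sum(!inb))
  lab <- rep(0L, nrow(rec))
  lab[inb] <- L[cbind(py[inb] + 1L, px[inb] + 1L)]
  unassigned <- sum(rec$count[inb & lab == 0L])
  seg_ids <- sort(setdiff(unique(as.vector(L)), 0L))
  genes <- sort(unique(rec$gene))
  keep <- inb & lab > 0L
  counts <- Matrix::sparseMatrix(
    i = match(lab[keep], seg_ids),
    j = match(rec$gene[keep], genes),
    x = rec$count[keep],
    dims = c(length(seg_ids), length(genes))
  )
  # per-segment geometry from the label map
  idx <- which(L > 0L)
  lv <- L[idx]
  yy <- (idx - 1L) %% nr
  xx <- (idx - 1L) %/% nr
  area <- tabulate(lv, nbins = max(seg_ids, 0L))[seg_ids]
  cx <- rowsum(xx, lv)[, 1] / area
  cy <- rowsum(yy, lv)[, 1] / area
  meta <- data.frame(segment_id = seg_ids, x = cx, y = cy, area_px = area,
                     replicate = replicate,
                     reporter_class = NA_character_,
                     cell_type = NA_character_,
                     niche_role = NA_character_,
                     stringsAsFactors = FALSE)
  list(matrix = cell_matrix(counts, meta, genes),
       unassigned_count = unassigned,
       rejected_count = rejected)
}

#' QC configuration
#'
#' @param min_unique_features minimum number of distinct genes with nonzero
#'   count a cell must have to be retained (inclusive). Default 100.
#' @return Object of class `qc_config`.
#' @export
qc_config <- function(min_unique_features = 100L) {
  if (min_unique_features < 0) stopf("min_unique_features must be >= 0")
  structure(list(min_unique_features = as.integer(min_unique_features)),
            class = "qc_config")
}

#' Filter cells on unique feature count
#'
#' Retains exactly the cells whose number of genes with nonzero count is at
#' least `min_unique_features` (inclusive rule); cell order is preserved.
#' Idempotent.
#'
#' @param m a [cell_matrix].
#' @param qc a [qc_config].
#' @return Filtered [cell_matrix].
#' @export
qc_filter <- function(m, qc = qc_config()) {
  stopifnot(inherits(m, "cell_matrix"), inherits(qc, "qc_config"))
  nfeat <- Matrix::rowSums(m$counts > 0)
  keep <- nfeat >= qc$min_unique_features
  cell_matrix(m$counts[keep, , drop = FALSE],
              m$cell_meta[keep, , drop = FALSE], m$gene_ids)
}

#' Per-segment mean fluorescence
#'
#' For every segment and channel, the mean intensity over the segment's
#' pixels (or the maximum, with `summary = "max"`).
#'
#' @param seg a [segment_map].
#' @param stack a [fluorescence_stack] of the same shape.
#' @param summary "mean" (default) or "max".
#' @return data.frame with `segment_id` and one column per channel.
#' @export
quantify_fluorescence <- function(seg, stack, summary = c("mean", "max")) {
  stopifnot(inherits(seg, "segment_map"), inherits(stack, "fluorescence_stack"))
  summary <- match.arg(summary)
  L <- seg$labels
  if (!identical(dim(L), dim(stack$channels[[1]])))
    stopf("segment map and fluorescence stack shapes differ")
  idx <- which(L > 0L)
  lv <- L[idx]
  ids <- sort(unique(lv))
  out <- data.frame(segment_id = ids)
  for (ch in names(stack$channels)) {
    v <- stack$channels[[ch]][idx]
    out[[ch]] <- if (summary == "mean") {
      (rowsum(v, lv)[, 1]) / as.vector(table(factor(lv, levels = ids)))
    } else {
      vapply(split(v, lv), max, numeric(1))
    }
  }
  out
}

#' Default reporter thresholds from background fluorescence
#'
#' Per-channel threshold set to a high quantile (default 99.9th percentile)
#' of the intensities of pixels outside every segment.
#'
#' @param seg a [segment_map].
#' @param stack a [fluorescence_stack].
#' @param channels channels to threshold.
#' @param probs background quantile used as the threshold.
#' @return named numeric vector of thresholds.
#' @export
background_thresholds <- function(seg, stack,
                                  channels = c("GFP", "tdTomato"),
                                  probs = 0.999) {
  stopifnot(inherits(seg, "segment_map"), inherits(stack, "fluorescence_stack"))
  bg <- seg$labels == 0L
  if (!any(bg)) stopf("no background pixels to estimate thresholds from")
  vapply(channels, function(ch) {
    if (!ch %in% names(stack$channels)) stopf("unknown channel: %s", ch)
    stats::quantile(stack$channels[[ch]][bg], probs, names = FALSE)
  }, numeric(1))
}

#' Call p21 reporter classes from per-segment fluorescence
#'
#' A channel is positive iff its per-segment summary exceeds (strictly) its
#' threshold. The GFP/tdTomato positivity pair maps to the reporter classes
#' `none`, `gfp_only`, `tdtomato_only` and `double`. Under the default
#' `p21_rule = "or"` a cell is p21-positive iff either channel is positive;
#' `p21_rule = "tdtomato"` restricts positivity to the tdTomato-involved
#' classes (cells with a recombination readout).
#'
#' @param fluor data.frame from [quantify_fluorescence] with `GFP` and
#'   `tdTomato` columns.
#' @param thresholds named numeric vector with `GFP` and `tdTomato` entries.
#' @param p21_rule "or" or "tdtomato".
#' @return data.frame of reporter calls: `segment_id`, per-channel means and
#'   thresholds, `class` and `is_p21_positive`.
#' @export
call_reporter <- function(fluor, thresholds, p21_rule = c("or", "tdtomato")) {
  p21_rule <- match.arg(p21_rule)
  stopifnot(all(c("segment_id", "GFP", "tdTomato") %in% names(fluor)),
            all(c("GFP", "tdTomato") %in% names(thresholds)))
  if (any(thresholds < 0)) stopf("thresholds must be >= 0")
  gfp_pos <- fluor$GFP > thresholds[["GFP"]]
  tdt_pos <- fluor$tdTomato > thresholds[["tdTomato"]]
  cls <- ifelse(gfp_pos & tdt_pos, "double",
         ifelse(gfp_pos, "gfp_only",
         ifelse(tdt_pos, "tdtomato_only", "none")))
  p21 <- if (p21_rule == "or") gfp_pos | tdt_pos else tdt_pos
  data.frame(segment_id = fluor$segment_id,
             gfp_mean = fluor$GFP, tdtomato_mean = fluor$tdTomato,
             gfp_threshold = thresholds[["GFP"]],
             tdtomato_threshold = thresholds[["tdTomato"]],
             class = cls, is_p21_positive = p21,
             stringsAsFactors = FALSE)
}
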