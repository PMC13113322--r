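#' Default gene expression profiles for the synthetic liver section
#'
#' Per-cell-type gene weight vectors over a shared gene universe:
#' housekeeping genes, hepatocyte core genes, periportal and pericentral
#' zonation markers, macrophage markers, acute-phase injury markers
#' (Saa1/Saa2), SASP chemokines (Gpnmb, Cxcl9, Cxcl10, Ccl8, Mmp3),
#' interferon-stimulated genes (Rsad2, Ifit1, Cmpk2, Ifit3), Cdkn1a (p21),
#' reporter transcripts (EGFP, tdTomato) and 200 low-weight background genes
#' that give cells realistic unique-feature counts.
#'
#' Hepatocyte zonation weight is split between the periportal and
#' pericentral blocks at generation time according to each cell's position
#' along the lobule axis; the weights returned here carry the full zonation
#' block under `"zonation_pp"` / `"zonation_pc"` placeholders resolved by
#' [generate_tissue()].
#'
#' @return named list: `genes` (gene universe), `panels` (named marker gene
#'   groups) and `profiles` (per-type base weights).
#' @export
default_expression_profiles <- function() {
  panels <- list(
    housekeeping = c("Actb", "Gapdh", "B2m", "Rplp0", "Eef1a1"),
    hep_core     = c("Alb", "Ttr", "Apoa1", "Serpina1a"),
    periportal   = c("Sds", "Cyp2f2", "Hal", "Arg1"),
    pericentral  = c("Glul", "Cyp2e1", "Oat", "Cyp1a2"),
    macrophage   = c("Vcam1", "Cd74", "H2-Ab1", "Clec4f", "Adgre1", "Lyz2"),
    injury       = c("Saa1", "Saa2"),
    sasp         = c("Gpnmb", "Cxcl9", "Cxcl10", "Ccl8", "Mmp3"),
    isg          = c("Rsad2", "Ifit1", "Cmpk2", "Ifit3"),
    senescence   = "Cdkn1a",
    reporter     = c("EGFP", "tdTomato"),
    background   = sprintf("Bg%03d", 1:200)
  )
  genes <- unlist(panels, use.names = FALSE)
  w <- function(...) {
    v <- stats::setNames(numeric(length(genes)), genes)
    args <- list(...)
    for (nm in names(args)) v[panels[[nm]]] <- args[[nm]] / length(panels[[nm]])
    v
  }
  profiles <- list(
    hepatocyte = list(base = w(housekeeping = 0.10, hep_core = 0.26,
                               senescence = 0.001, background = 0.50),
                      zonation = 0.14),
    macrophage = list(base = w(housekeeping = 0.10, macrophage = 0.275,
                               sasp = 0.10, senescence = 0.001,
                               background = 0.50),
                      zonation = 0),
    hepatocyte_injured = list(base = w(housekeeping = 0.10, hep_core = 0.12,
                                       injury = 0.26, senescence = 0.001,
                                       background = 0.50),
                              zonation = 0.02),
    isg_override = list(base = w(housekeeping = 0.10, isg = 0.30,
                                 hep_core = 0.08, senescence = 0.001,
                                 background = 0.50),
                        zonation = 0.02)
  )
  list(genes = genes, panels = panels, profiles = profiles)
}

#' Configuration for the synthetic zonated liver section
#'
#' Defaults emulate an aged mouse liver section profiled at micrometer
#' resolution: 512 x 512 px at 2.5 um/px (so the 6 px segmentation radius is
#' about 15 um), 2000 cells, a periportal-to-pericentral zonation gradient
#' along x, rare (about 1.6% overall) p21-reporter-positive cells split 60/40
#' between double-positive and tdTomato-only classes, SASP genes upregulated
#' `sasp_fold`-fold in p21+ macrophages, and a focal aggregate of
#' ISG-expressing cells.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um micrometers per pixel.
#' @param n_cells number of cells to place.
#' @param type_proportions named fractions per cell type (sum to 1).
#' @param p21_fraction_by_type named per-type probability that a cell is
#'   reporter-positive.
#' @param reporter_class_probs probabilities of the `double` and
#'   `tdtomato_only` classes among reporter-positive cells.
#' @param isg_focus list with `center` (0-based c(x, y)), `radius` (px) and
#'   `n_cells` (cap on focus membership; `Inf` = all cells inside).
#' @param mean_counts_per_cell Poisson mean of transcripts emitted per cell.
#' @param sasp_fold fold-increase of SASP gene weights in p21+ macrophages.
#' @param fluor_snr peak blob amplitude / background noise scale.
#' @param nuclear_radius_px nuclear blob radius; cells are placed with
#'   minimum spacing `2 * nuclear_radius_px + 1`.
#' @param expression expression model from [default_expression_profiles()].
#' @param rng_seed integer seed; the whole section is reproducible from it.
#' @return Object of class `tissue_config`.
#' @export
tissue_config <- function(width_px = 512L, height_px = 512L,
                          pixel_size_um = 2.5, n_cells = 2000L,
                          type_proportions = c(hepatocyte = 0.80,
                                               macrophage = 0.12,
                                               hepatocyte_injured = 0.08),
                          p21_fraction_by_type = c(hepatocyte = 0.012,
                                                   macrophage = 0.05,
                                                   hepatocyte_injured = 0.02),
                          reporter_class_probs = c(double = 0.6,
                                                   tdtomato_only = 0.4),
                          isg_focus = list(center = c(128, 128), radius = 40,
                                           n_cells = Inf),
                          mean_counts_per_cell = 450,
                          sasp_fold = 4,
                          fluor_snr = 10,
                          nuclear_radius_px = 3,
                          expression = default_expression_profiles(),
                          rng_seed = 42L) {
  if (n_cells < 1L) stopf("n_cells must be >= 1")
  if (abs(sum(type_proportions) - 1) > 1e-9)
    stopf("type_proportions must sum to 1")
  if (any(type_proportions < 0) || any(type_proportions > 1))
    stopf("type_proportions must lie in [0, 1]")
  bad <- setdiff(names(p21_fraction_by_type), names(type_proportions))
  if (length(bad)) stopf("p21 fraction for unknown type(s): %s",
                         paste(bad, collapse = ", "))
  if (any(p21_fraction_by_type < 0) || any(p21_fraction_by_type > 1))
    stopf("p21 fractions must lie in [0, 1]")
  if (abs(sum(reporter_class_probs) - 1) > 1e-9)
    stopf("reporter_class_probs must sum to 1")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 type_proportions = type_proportions,
                 p21_fraction_by_type = p21_fraction_by_type,
                 reporter_class_probs = reporter_class_probs,
                 isg_focus = isg_focus,
                 mean_counts_per_cell = mean_counts_per_cell,
                 sasp_fold = sasp_fold, fluor_snr = fluor_snr,
                 nuclear_radius_px = nuclear_radius_px,
                 expression = expression, rng_seed = as.integer(rng_seed)),
            class = "tissue_config")
}

# Random sequential (dart-throwing) Poisson-disc sampling with a bucket grid.
# Returns n x 2 matrix of (x, y), all pairwise distances >= min_dist, all
# points at least `margin` from the border.
poisson_disc <- function(n, width, height, min_dist, margin,
                         max_attempts = 400L * n) {
  cell <- min_dist / sqrt(2)
  gx <- max(1L, ceiling((width - 2 * margin) / cell))
  gy <- max(1L, ceiling((height - 2 * margin) / cell))
  grid <- matrix(0L, gy, gx)
  px <- numeric(n); py <- numeric(n)
  placed <- 0L; attempts <- 0L
  d2min <- min_dist^2
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- stats::runif(1, margin, width - margin)
    y <- stats::runif(1, margin, height - margin)
    cx <- min(gx, 1L + floor((x - margin) / cell))
    cy <- min(gy, 1L + floor((y - margin) / cell))
    ok <- TRUE
    for (jx in max(1L, cx - 2L):min(gx, cx + 2L)) {
      for (jy in max(1L, cy - 2L):min(gy, cy + 2L)) {
        k <- grid[jy, jx]
        if (k > 0L && (px[k] - x)^2 + (py[k] - y)^2 < d2min) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      px[placed] <- x; py[placed] <- y
      grid[cy, cx] <- placed
    }
  }
  if (placed < n)
    stopf(paste("could not place %d cells with spacing %.1f px in a %d x %d",
                "area; reduce n_cells or the spacing"),
          n, min_dist, width, height)
  cbind(x = px, y = py)
}

# Add an isotropic Gaussian blob to an intensity image (in place value).
add_blob <- function(img, cx, cy, sigma, amp, support = ceiling(3 * sigma)) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(0L, floor(cx) - support); x1 <- min(nc - 1L, floor(cx) + support)
  y0 <- max(0L, floor(cy) - support); y1 <- min(nr - 1L, floor(cy) + support)
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  gx <- exp(-((xs - cx)^2) / (2 * sigma^2))
  gy <- exp(-((ys - cy)^2) / (2 * sigma^2))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amp * outer(gy, gx)
  img
}

#' Generate a synthetic liver section with ground truth
#'
#' Places `n_cells` nuclei by Poisson-disc sampling (minimum spacing twice
#' the nuclear radius plus one pixel), assigns cell types, zonation weights
#' (periportal fraction decaying along x), rare reporter-positive cells, and
#' an ISG-expressing focus; emits per-cell Poisson transcript clouds
#' localised to a cytoplasmic annulus around each nucleus; and renders DAPI /
#' GFP / tdTomato channels as Gaussian nuclear or cytoplasmic blobs over
#' half-normal background noise scaled by `fluor_snr`. Fully reproducible
#' from `cfg$rng_seed`.
#'
#' @param cfg a [tissue_config].
#' @return list with `sdge` ([sdge_table]; attribute `source_cell` maps every
#'   record to its emitting cell), `stack` ([fluorescence_stack] with DAPI,
#'   GFP, tdTomato) and `truth` (data.frame: per-cell id, centroid, type,
#'   reporter class, ISG status, p21 status).
#' @export
generate_tissue <- function(cfg) {
  stopifnot(inherits(cfg, "tissue_config"))
  set.seed(cfg$rng_seed)
  W <- cfg$width_px; H <- cfg$height_px
  n <- cfg$n_cells
  rnuc <- cfg$nuclear_radius_px
  min_dist <- 2 * rnuc + 1
  margin <- 2 * rnuc + 2
  cents <- poisson_disc(n, W, H, min_dist, margin)

  types <- sample(names(cfg$type_proportions), n, replace = TRUE,
                  prob = cfg$type_proportions)
  # periportal weight decays along the lobule (x) axis; mild sharpening keeps
  # the gradient monotone but not razor thin
  wpp <- 1 - cents[, "x"] / W
  s_pp <- wpp^2 / (wpp^2 + (1 - wpp)^2)

  # ISG focus membership
  d2 <- (cents[, "x"] - cfg$isg_focus$center[1])^2 +
        (cents[, "y"] - cfg$isg_focus$center[2])^2
  isg <- d2 <= cfg$isg_focus$radius^2
  if (is.finite(cfg$isg_focus$n_cells) && sum(isg) > cfg$isg_focus$n_cells) {
    inside <- which(isg)
    isg[] <- FALSE
    isg[inside[order(d2[inside])][seq_len(cfg$isg_focus$n_cells)]] <- TRUE
  }

  # reporter classes
  pfrac <- cfg$p21_fraction_by_type[types]
  pfrac[is.na(pfrac)] <- 0
  p21 <- stats::runif(n) < pfrac
  cls <- rep("none", n)
  if (any(p21))
    cls[p21] <- sample(names(cfg$reporter_class_probs), sum(p21),
                       replace = TRUE, prob = cfg$reporter_class_probs)

  ex <- cfg$expression
  genes <- ex$genes
  panels <- ex$panels
  n_counts <- stats::rpois(n, cfg$mean_counts_per_cell)

  # per-cell profiles
  prof_weights <- function(i) {
    key <- if (isg[i]) "isg_override" else types[i]
    p <- ex$profiles[[key]]
    wv <- p$base
    if (p$zonation > 0) {
      wv[panels$periportal] <- wv[panels$periportal] +
        p$zonation * s_pp[i] / length(panels$periportal)
      wv[panels$pericentral] <- wv[panels$pericentral] +
        p$zonation * (1 - s_pp[i]) / length(panels$pericentral)
    }
    if (p21[i]) {
      wv[panels$senescence] <- wv[panels$senescence] * 8
      if (cls[i] == "double") wv[c("EGFP", "tdTomato")] <- 0.008
      if (cls[i] == "tdtomato_only") wv["tdTomato"] <- 0.008
      if (types[i] == "macrophage")
        wv[panels$sasp] <- wv[panels$sasp] * cfg$sasp_fold
    }
    wv
  }

  gene_idx <- vector("list", n)
  for (i in seq_len(n)) {
    if (n_counts[i] == 0L) { gene_idx[[i]] <- integer(); next }
    gene_idx[[i]] <- sample.int(length(genes), n_counts[i], replace = TRUE,
                                prob = prof_weights(i))
  }
  src <- rep.int(seq_len(n), n_counts)
  gi <- unlist(gene_idx, use.names = FALSE)
  m <- length(src)
  # cytoplasmic annulus between nuclear radius and twice the nuclear radius
  rr <- sqrt(stats::runif(m, rnuc^2, (2 * rnuc)^2))
  th <- stats::runif(m, 0, 2 * pi)
  tx <- pmin(pmax(cents[src, "x"] + rr * cos(th), 0), W - 1e-6)
  ty <- pmin(pmax(cents[src, "y"] + rr * sin(th), 0), H - 1e-6)
  sdge <- sdge_table(data.frame(x = tx, y = ty, gene = genes[gi],
                                count = 1L, stringsAsFactors = FALSE),
                     cfg$pixel_size_um)
  attr(sdge, "source_cell") <- src

  # fluorescence rendering
  amp <- stats::runif(n, 0.6, 0.85)
  noise_scale <- mean(c(0.6, 0.85)) / cfg$fluor_snr
  dapi <- matrix(0, H, W)
  gfp <- matrix(0, H, W)
  tdt <- matrix(0, H, W)
  for (i in seq_len(n))
    dapi <- add_blob(dapi, cents[i, "x"], cents[i, "y"], rnuc / 2, amp[i])
  cyto_sigma <- rnuc  # reporter fluorescence fills the cytoplasm
  for (i in which(cls == "double"))
    gfp <- add_blob(gfp, cents[i, "x"], cents[i, "y"], cyto_sigma, amp[i])
  for (i in which(cls %in% c("double", "tdtomato_only")))
    tdt <- add_blob(tdt, cents[i, "x"], cents[i, "y"], cyto_sigma, amp[i])
  dapi <- dapi + abs(stats::rnorm(H * W, 0, noise_scale))
  gfp <- gfp + abs(stats::rnorm(H * W, 0, noise_scale))
  tdt <- tdt + abs(stats::rnorm(H * W, 0, noise_scale))
  stack <- fluorescence_stack(list(DAPI = dapi, GFP = gfp, tdTomato = tdt),
                              cfg$pixel_size_um)

  truth <- data.frame(cell_id = seq_len(n),
                      x = cents[, "x"], y = cents[, "y"],
                      cell_type = types,
                      periportal_weight = s_pp,
                      reporter_class = cls,
                      is_p21_positive = p21,
                      is_isg = isg,
                      n_transcripts = n_counts,
                      stringsAsFactors = FALSE)
  list(sdge = sdge, stack = stack, truth = truth, config = cfg)
}

#' Write a simulated tissue to disk
#'
#' Writes the sDGE TSV, the fluorescence TIFF stack, the ground-truth TSV
#' (including per-transcript source cells as `sdge_sources.tsv`) and the
#' configuration as YAML.
#'
#' @param sim result of [generate_tissue()].
#' @param dir output directory.
#' @export
write_tissue <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sdge(sim$sdge, file.path(dir, "sdge.tsv"))
  write_fluorescence(sim$stack, file.path(dir, "fluorescence"))
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(source_cell = attr(sim$sdge, "source_cell")),
                     file.path(dir, "sdge_sources.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  yaml::write_yaml(list(width_px = cfg$width_px, height_px = cfg$height_px,
                        pixel_size_um = cfg$pixel_size_um,
                        n_cells = cfg$n_cells,
                        type_proportions = as.list(cfg$type_proportions),
                        p21_fraction_by_type = as.list(cfg$p21_fraction_by_type),
                        mean_counts_per_cell = cfg$mean_counts_per_cell,
                        sasp_fold = cfg$sasp_fold,
                        fluor_snr = cfg$fluor_snr,
                        rng_seed = cfg$rng_seed),
                   file.path(dir, "config.yml"))
  invisible(dir)
}
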