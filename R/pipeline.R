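#' Pipeline run configuration
#'
#' Either a synthetic [tissue_config] (the demo/benchmark route) or a set of
#' input paths (sDGE TSV + fluorescence directory, with an optional
#' control-point file for registration) — exactly one of the two.
#'
#' @param synthetic a [tissue_config], or `NULL`.
#' @param sdge_path path to an sDGE TSV, or `NULL`.
#' @param fluorescence_dir directory with channel TIFFs + channels.yml.
#' @param control_points_path optional TSV of control point pairs mapping
#'   image to array coordinates; `NULL` = identity registration.
#' @param registration_model "similarity" or "affine".
#' @param pixel_size_um pixel size for file inputs.
#' @param radius_px segmentation radius cap (default 6 px, about 15 um at
#'   2.5 um/px).
#' @param connectivity contact-graph connectivity (4 or 8).
#' @param min_unique_features QC cutoff on unique features (default 100).
#' @param threshold_quantile background quantile for reporter thresholds.
#' @param p21_rule "or" or "tdtomato" (see [call_reporter]).
#' @param panels marker panels for annotation.
#' @param isg_panel ISG gene panel.
#' @param isg_quantile ISG-positivity quantile.
#' @param min_margin annotation margin (see [assign_types]).
#' @param replicate replicate id recorded for this section.
#' @param out_dir output directory.
#' @param seed seed for any stage randomness (the synthetic generator uses
#'   its own `rng_seed`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, sdge_path = NULL,
                       fluorescence_dir = NULL, control_points_path = NULL,
                       registration_model = "similarity",
                       pixel_size_um = 2.5,
                       radius_px = 6, connectivity = 8L,
                       min_unique_features = 100L,
                       threshold_quantile = 0.999,
                       p21_rule = "or",
                       panels = default_marker_panels(),
                       isg_panel = c("Rsad2", "Ifit1", "Cmpk2", "Ifit3"),
                       isg_quantile = 0.98,
                       min_margin = 0.1,
                       replicate = 1L,
                       out_dir = tempfile("senoniche_run_"),
                       seed = 1L) {
  has_synth <- !is.null(synthetic)
  has_files <- !is.null(sdge_path) || !is.null(fluorescence_dir)
  if (has_synth == has_files)
    stopf("supply exactly one of: a synthetic tissue_config, or input paths")
  if (has_synth) stopifnot(inherits(synthetic, "tissue_config"))
  if (has_files) {
    for (p in c(sdge_path, fluorescence_dir, control_points_path))
      if (!is.null(p) && !file.exists(p)) stopf("input does not exist: %s", p)
  }
  structure(list(synthetic = synthetic, sdge_path = sdge_path,
                 fluorescence_dir = fluorescence_dir,
                 control_points_path = control_points_path,
                 registration_model = registration_model,
                 pixel_size_um = pixel_size_um,
                 radius_px = radius_px, connectivity = as.integer(connectivity),
                 min_unique_features = as.integer(min_unique_features),
                 threshold_quantile = threshold_quantile,
                 p21_rule = p21_rule, panels = panels,
                 isg_panel = isg_panel, isg_quantile = isg_quantile,
                 min_margin = min_margin, replicate = replicate,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full senescent-niche pipeline
#'
#' Stages, in order: ingest or simulate -> register -> segment (DAPI seed
#' detection + radius-capped growth) -> quantify (transcript assignment, QC,
#' fluorescence, reporter calls) -> annotate (normalize + marker panels) ->
#' niche (contact graph, roles, composition, rates) -> stats (contrasts, ISG
#' score/status, replicate overlap). All intermediates are written under
#' `cfg$out_dir` in the package's standard formats, and a manifest records
#' the configuration hash, seeds and per-stage counts. Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param cfg a [run_config].
#' @param quiet suppress stage messages.
#' @return the manifest, invisibly (list; also written as `manifest.yml`).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s (artifacts kept in %s)",
            name, conditionMessage(e), cfg$out_dir))
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  # --- ingest / simulate ---------------------------------------------------
  sim <- NULL
  inp <- stage("ingest", {
    if (!is.null(cfg$synthetic)) {
      sim <- generate_tissue(cfg$synthetic)
      write_tissue(sim, file.path(cfg$out_dir, "tissue"))
      list(sdge = sim$sdge, stack = sim$stack)
    } else {
      list(sdge = read_sdge(cfg$sdge_path, cfg$pixel_size_um),
           stack = read_fluorescence(cfg$fluorescence_dir))
    }
  })

  # --- registration --------------------------------------------------------
  trans <- stage("register", {
    if (!is.null(cfg$control_points_path)) {
      cp <- read_control_points(cfg$control_points_path)
      fit_transform(cp, cfg$registration_model)
    } else identity_transform()
  })
  write_transform(trans, file.path(cfg$out_dir, "transform.yml"))

  # --- segmentation --------------------------------------------------------
  seeds <- stage("segment", detect_nuclei(inp$stack$channels$DAPI))
  seg <- grow_segments(seeds, radius_px = cfg$radius_px)
  write_seeds(seeds, file.path(cfg$out_dir, "seeds.tsv"))
  write_segment_map(seg, file.path(cfg$out_dir, "segments.tif"))

  # --- quantification ------------------------------------------------------
  q <- stage("quantify", {
    sdge <- inp$sdge
    if (!is.null(cfg$control_points_path)) {
      mapped <- apply_transform(trans, as.matrix(sdge$records[, c("x", "y")]))
      sdge$records$x <- mapped[, 1]; sdge$records$y <- mapped[, 2]
    }
    assign_transcripts(sdge, seg, replicate = cfg$replicate)
  })
  qc <- qc_filter(q$matrix, qc_config(cfg$min_unique_features))
  fluor <- quantify_fluorescence(seg, inp$stack)
  thr <- background_thresholds(seg, inp$stack, probs = cfg$threshold_quantile)
  calls <- call_reporter(fluor[fluor$segment_id %in% qc$cell_meta$segment_id, ],
                         thr, p21_rule = cfg$p21_rule)
  qc$cell_meta$reporter_class <-
    calls$class[match(qc$cell_meta$segment_id, calls$segment_id)]
  write_cell_matrix(qc, file.path(cfg$out_dir, "cell_matrix"))
  write_tsv(calls, file.path(cfg$out_dir, "reporter_calls.tsv"))

  # --- annotation ----------------------------------------------------------
  ann <- stage("annotate", {
    nm <- normalize_counts(qc)
    scores <- score_panels(nm, cfg$panels)
    list(nm = nm, types = assign_types(scores, cfg$min_margin))
  })
  qc$cell_meta$cell_type <- ann$types

  # --- niche ---------------------------------------------------------------
  niche <- stage("niche", {
    g <- contact_graph(seg, cfg$connectivity)
    keep <- qc$cell_meta$segment_id
    g_qc <- neighbor_graph(intersect(g$nodes, keep),
                           g$edges[g$edges[, 1] %in% keep &
                                   g$edges[, 2] %in% keep, , drop = FALSE])
    p21_ids <- calls$segment_id[calls$is_p21_positive]
    roles <- assign_roles(g_qc, intersect(p21_ids, g_qc$nodes))
    roles
  })
  qc$cell_meta$niche_role <-
    niche$niche_role[match(qc$cell_meta$segment_id, niche$segment_id)]
  write_tsv(qc$cell_meta, file.path(cfg$out_dir, "cell_metadata.tsv"))
  comp <- composition_table(qc$cell_meta$niche_role, qc$cell_meta$cell_type)
  rates <- p21_rate_by_type(qc$cell_meta$niche_role == "p21_positive",
                            qc$cell_meta$cell_type, qc$cell_meta$replicate)
  write_tsv(comp, file.path(cfg$out_dir, "composition.tsv"))
  write_tsv(rates, file.path(cfg$out_dir, "p21_rates.tsv"))

  # --- stats ---------------------------------------------------------------
  st <- stage("stats", {
    contrasts <- run_contrasts(ann$nm, qc$cell_meta$niche_role,
                               qc$cell_meta$cell_type)
    scores <- isg_score(ann$nm, cfg$isg_panel)
    isg <- isg_call(scores, cfg$isg_quantile)
    overlap <- overlap_analysis(qc$cell_meta$niche_role == "p21_positive",
                                isg, qc$cell_meta$replicate)
    list(contrasts = contrasts, scores = scores, isg = isg, overlap = overlap)
  })
  flat <- do.call(rbind, lapply(names(st$contrasts$results), function(nm) {
    r <- st$contrasts$results[[nm]]
    cbind(data.frame(cell_type = attr(r, "cell_type"),
                     contrast = attr(r, "contrast")), r)
  }))
  if (is.null(flat))
    flat <- data.frame(cell_type = character(), contrast = character(),
                       gene = character(), log2fc = numeric(), p = numeric(),
                       p_adj = numeric(), significant = logical())
  write_tsv(flat, file.path(cfg$out_dir, "contrasts.tsv"))
  if (nrow(st$contrasts$skipped))
    write_tsv(st$contrasts$skipped,
              file.path(cfg$out_dir, "contrasts_skipped.tsv"))
  write_tsv(data.frame(segment_id = qc$cell_meta$segment_id,
                       isg_score = st$scores, is_isg = st$isg),
            file.path(cfg$out_dir, "isg_scores.tsv"))
  write_tsv(st$overlap$per_replicate, file.path(cfg$out_dir, "overlap.tsv"))
  write_tsv(st$overlap$pooled, file.path(cfg$out_dir, "overlap_pooled.tsv"))

  # --- manifest ------------------------------------------------------------
  cfg_yaml <- file.path(cfg$out_dir, "run_config.yml")
  yaml::write_yaml(serialize_run_config(cfg), cfg_yaml)
  manifest <- list(
    package_version = as.character(utils::packageVersion("senoniche")),
    config_hash = unname(tools::md5sum(cfg_yaml)),
    seed = cfg$seed,
    synthetic_seed = if (!is.null(cfg$synthetic)) cfg$synthetic$rng_seed,
    counts = list(
      seeds_detected = nrow(seeds$seeds),
      cells_segmented = nrow(q$matrix$cell_meta),
      transcripts_unassigned = q$unassigned_count,
      transcripts_rejected = q$rejected_count,
      cells_passing_qc = nrow(qc$cell_meta),
      p21_positive = sum(qc$cell_meta$niche_role == "p21_positive"),
      neighbors = sum(qc$cell_meta$niche_role == "neighbor"),
      isg_positive = sum(st$isg),
      contrasts_tested = length(st$contrasts$results),
      contrasts_skipped = nrow(st$contrasts$skipped)
    )
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yml"))
  say("pipeline complete: %s", cfg$out_dir)
  invisible(manifest)
}

# plain-list view of a run_config for hashing/serialization
serialize_run_config <- function(cfg) {
  s <- cfg[setdiff(names(cfg), c("synthetic", "panels"))]
  s$panels <- cfg$panels
  if (!is.null(cfg$synthetic)) {
    sc <- cfg$synthetic
    s$synthetic <- list(width_px = sc$width_px, height_px = sc$height_px,
                        pixel_size_um = sc$pixel_size_um,
                        n_cells = sc$n_cells,
                        type_proportions = as.list(sc$type_proportions),
                        p21_fraction_by_type = as.list(sc$p21_fraction_by_type),
                        reporter_class_probs = as.list(sc$reporter_class_probs),
                        isg_focus = lapply(sc$isg_focus, function(v)
                          if (is.numeric(v) && any(!is.finite(v))) "Inf" else v),
                        mean_counts_per_cell = sc$mean_counts_per_cell,
                        sasp_fold = sc$sasp_fold, fluor_snr = sc$fluor_snr,
                        nuclear_radius_px = sc$nuclear_radius_px,
                        rng_seed = sc$rng_seed)
  }
  s$out_dir <- NULL  # the output location is not part of the run identity
  s
}
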