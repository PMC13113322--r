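# The default synthetic section and the full analysis chain over it are
# expensive; build them once per test run and share across files.
.chain_cache <- new.env(parent = emptyenv())

run_chain <- function(cfg) {
  sim <- generate_tissue(cfg)
  seeds <- detect_nuclei(sim$stack$channels$DAPI)
  seg <- grow_segments(seeds, radius_px = 6)
  q <- assign_transcripts(sim$sdge, seg)
  qc <- qc_filter(q$matrix)
  nm <- normalize_counts(qc)
  panels <- default_marker_panels()
  types <- assign_types(score_panels(nm, panels))
  fluor <- quantify_fluorescence(seg, sim$stack)
  thr <- background_thresholds(seg, sim$stack)
  calls <- call_reporter(fluor, thr)
  g <- contact_graph(seg)
  keep <- qc$cell_meta$segment_id
  g_qc <- neighbor_graph(intersect(g$nodes, keep),
                         g$edges[g$edges[, 1] %in% keep &
                                 g$edges[, 2] %in% keep, , drop = FALSE])
  p21_ids <- calls$segment_id[calls$is_p21_positive &
                              calls$segment_id %in% g_qc$nodes]
  roles_df <- assign_roles(g_qc, p21_ids)
  roles <- roles_df$niche_role[match(keep, roles_df$segment_id)]
  mt <- match_seeds(seeds$seeds, sim$truth, max_dist = 3)
  seg2true <- ifelse(mt$matched, mt$nearest, NA)
  # expected annotation: planted type, except ISG-focus cells which express
  # the ISG program and should score as "isg"
  expected_all <- ifelse(sim$truth$is_isg, "isg", sim$truth$cell_type)
  expected <- expected_all[seg2true[match(keep, seeds$seeds$id)]]
  list(cfg = cfg, sim = sim, seeds = seeds, seg = seg, q = q, qc = qc,
       nm = nm, types = types, fluor = fluor, thr = thr, calls = calls,
       graph = g_qc, roles = roles, match = mt, seg2true = seg2true,
       expected_type = expected)
}

default_chain <- function() {
  if (is.null(.chain_cache$default))
    .chain_cache$default <- run_chain(tissue_config())
  .chain_cache$default
}
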