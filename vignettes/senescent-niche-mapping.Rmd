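---
title: "Mapping senescent-cell niches in spatial transcriptomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping senescent-cell niches in spatial transcriptomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Micrometer-resolution spatial transcriptomics platforms capture individual
transcripts with sub-cellular coordinates but no cell boundaries. When the
same tissue section also carries fluorescence readouts — DAPI for nuclei and
a p21 (Cdkn1a) dual reporter in which promoter activity drives GFP and
permanently switches on tdTomato — one can ask single-cell questions about
rare senescent cells and their immediate tissue neighborhood: which lineages
activate p21 in the aged liver, what do the cells in direct physical contact
with them express, and how does the senescence program relate to focal
interferon-stimulated gene (ISG) activation.

`senoniche` implements that workflow end to end: nuclear-anchored
segmentation, transcript-to-cell assignment, fluorescence-based reporter
calling, marker-panel annotation, boundary-contact niche analysis, and the
statistical layer (within-type rank-sum contrasts, ISG scoring, and
replicate-wise Fisher tests of p21/ISG overlap). A synthetic tissue
generator with complete ground truth makes every stage testable without any
external data.

# Segmentation model

Nuclei are reduced to single-pixel seeds: the DAPI channel is smoothed with
a Gaussian (default `smooth_sigma = 2` px), strict local maxima above a
threshold (default: Otsu on the smoothed image) become candidates, and
candidates closer than `min_distance_px = 4` to a stronger candidate are
suppressed. These defaults are package choices for a well-sampled nuclear
stain; they are tunable and the threshold can be set explicitly for
low-contrast images.

Cell territories are the *distance-capped Voronoi partition* of the seeds:
a pixel belongs to its nearest seed (Euclidean distance between pixel
centers) if that distance is at most `radius_px`, else it stays background.
The default cap of 6 px corresponds to roughly 15 µm at the 2.5 µm/px scale
of the data this package targets — a deliberate compromise for hepatocyte-
sized cells. Two conventions make the partition exactly testable:

* distances are measured between pixel centers and the cap is inclusive, so
  a single seed at radius 6 owns exactly the 113 integer lattice points with
  dx² + dy² ≤ 36;
* pixels equidistant from two seeds go to the smaller seed id. Expansion
  "until neighboring regions meet" does not define a winner at ties; a
  deterministic rule is required for reproducibility and oracle testing.

The test suite checks `grow_segments()` against a brute-force nearest-seed
scan, label by label, on randomized instances. The method intentionally does
not model cell-size variability: every territory has the same radius cap,
which under-segments large cells and merges tightly packed small ones. That
limitation is part of the approach being implemented, not an artifact.

Boundary contact (`contact_graph()`) uses 8-connectivity by default, so
corner contact counts as contact; 4-connectivity is available by flag.

# Quantification and reporter calling

Transcripts carry fractional pixel coordinates; each record is binned by
truncation to its containing pixel (0-based, origin top-left, x = column)
and credited to the segment there. Counts are conserved exactly: matrix
total + background-unassigned + out-of-bounds-rejected = input total. QC
retains cells with at least `min_unique_features = 100` distinct genes; the
rule is *inclusive* at the cutoff (a cell with exactly 100 unique features
is kept) — the source procedure states the cutoff but not strictness, and
the inclusive reading is documented here as the package's convention.

Reporter calling summarizes each segment's GFP and tdTomato by the mean over
its pixels (max available by flag) and compares against per-channel
thresholds, by default the 99.9th percentile of background (outside-segment)
pixels — no positivity threshold is inherited from elsewhere, so a
data-driven default is used. The class comes from the positivity pair:
`double`, `gfp_only`, `tdtomato_only`, `none`. Under the default rule a cell
is p21-positive iff *either* channel is positive; because the biological
readout of interest is sometimes restricted to classes with a recombination
record (tdTomato involved), `p21_rule = "tdtomato"` implements that
restriction. Whether GFP-only cells should count as p21-positive is
genuinely ambiguous in the source description; both behaviors are provided
and only the "or" rule is used in the shipped defaults.

# Annotation

Counts are depth-normalized as ln(1 + count × target_sum / total), with
`target_sum` defaulting to the median per-cell total. This replaces
variance-stabilizing regression and multi-sample anchor integration, which
are external tools' internals; a per-replicate batch covariate is carried in
the metadata instead. The transform is exactly invariant to per-cell depth
scaling, which the tests assert.

Cell types are assigned by marker-panel scoring: the score of type *t* for
cell *c* is the mean normalized value over panel *t*'s genes, and the label
is the argmax provided it leads the runner-up by `min_margin` (default 0.1
normalized-log units; ties are always unassigned). Marker scoring is the
primary annotation path because it can be validated against planted ground
truth. The cluster-then-annotate route is also provided
(`cluster_cells()`: PCA + Louvain on a kNN graph, deterministic given a
seed). Its default resolution of 0.1 is calibrated to the coarse,
well-separated populations this package's matrices contain — a handful of
lineages in a few thousand cells; finer resolutions begin to split the
continuous hepatocyte zonation gradient into arbitrary slices.

# Niche definition and contrasts

Neighbors are cells whose segment boundary directly contacts a p21-positive
segment (graph depth 1, no µm-band extension). Roles are mutually
exclusive: `p21_positive` takes precedence, so a p21⁺ cell touching another
p21⁺ cell is never a "neighbor". Roles are computed on QC-passing cells
only.

For each cell type, two contrasts: p21⁺ versus the remaining cells of that
type, and neighbors versus the remaining cells of that type ("remaining" =
the complement within the type, so the neighbor contrast's reference
includes the type's few p21⁺ cells — about 1.7% contamination at the default
prevalence). Per gene: two-sided Wilcoxon rank-sum p (exact enumeration when
both groups together have ≤ 12 observations and no ties, otherwise the
normal approximation with midranks, tie correction and continuity
correction), log2 fold change of group means of normalized values with
pseudocount 1e−9, Benjamini–Hochberg adjustment *within each (type,
contrast) family* (the alternative — adjusting across types — is stricter
but conflates families of very different size; Bonferroni is available),
and significance = adjusted p < 0.05 with positive log2FC. Groups smaller
than 3 cells are skipped with a recorded reason.

The "cumulative ISG score" is implemented as the mean normalized value over
the ISG panel (Rsad2, Ifit1, Cmpk2, Ifit3), with a sum variant by flag; the
phrase names a summary, not a formula, so this is an interpretation and is
documented as such. ISG status is either a strict-threshold call at a score
quantile or membership of a dedicated ISG cluster; the quantile uses the
type-1 (inverse-ECDF) definition so that quantile q on n distinct scores
marks exactly n − ⌈qn⌉ cells positive.

Overlap between p21 and ISG status is tested per biological replicate with
Fisher's exact test on the 2×2 table. The two-sided p follows the
probability-mass rule (sum of hypergeometric probabilities no greater than
the observed table's, within relative tolerance 1e−7). The reported odds
ratio is the sample estimate (ad)/(bc) — infinite when bc = 0 with ad > 0 —
rather than the conditional MLE, because the raw cross-product is what the
2×2 percentages display.

# The synthetic section: what it emulates, and what it does not

`generate_tissue()` builds a 512 × 512 px (2.5 µm/px) section with 2000
cells. Its defaults are the study conditions for all recovery tests:

* **Placement.** Poisson-disc (dart-throwing) sampling with minimum spacing
  7 px (twice the 3-px nuclear radius, plus one) keeps nuclei resolvable;
  the radius-6 cap then makes segmentation recovery well-posed.
* **Types.** hepatocyte 0.80, macrophage 0.12, injured (Saa1/Saa2-high)
  hepatocyte 0.08. Hepatocyte zonation is a *continuous* gradient: a cell at
  position x carries periportal weight s(w) = w²/(w² + (1−w)²) with
  w = 1 − x/width, splitting a fixed zonation weight between periportal
  (Sds, Cyp2f2, Hal, Arg1) and pericentral (Glul, Cyp2e1, Oat, Cyp1a2)
  markers. The mild sharpening keeps the periportal marker fraction strictly
  decreasing across x-bins without making mid-lobule cells ambiguous.
* **Counts.** Each cell emits Poisson(450) transcripts — chosen so the mean
  unique-feature count (~150 of 231 genes, anchored by 200 low-weight
  background genes) sits comfortably above the 100-feature QC cutoff, at a
  per-cell depth comparable to the few hundred unique transcripts such
  sections yield. Transcripts land uniformly in a 3–6 px cytoplasmic
  annulus around the nucleus, reproducing cytoplasmic localization.
* **Reporters.** Per-type p21 fractions (hepatocyte 0.012, macrophage 0.05,
  injured 0.02) give ≈ 1.7% reporter-positive cells overall — the rare-
  minority regime of aged tissue. Positives split 60% double-positive / 40%
  tdTomato-only (both observed classes; the split itself is a package
  choice, configurable). p21⁺ cells get 8× Cdkn1a weight plus reporter
  transcripts.
* **SASP.** Macrophages express the SASP panel (Gpnmb, Cxcl9, Cxcl10, Ccl8,
  Mmp3) at a baseline weight of 0.02 per gene — a robustly-expressed
  chemokine level for activated aged-liver macrophages — and p21⁺
  macrophages at 4× that. The baseline matters: a 4× fold on a gene with
  mean ≈ 2 counts is statistically invisible to a rank-sum test with ~10
  positive cells, whereas at mean ≈ 9 counts the planted program is
  reliably recoverable, which is the point of planting it.
* **ISG focus.** Cells within 40 px of a focal point (~1.9% of cells)
  switch to an ISG-dominated profile (30% panel weight) with reduced
  hepatic markers, emulating a focal aggregate of ISG-expressing
  hepatocyte-like cells. Their ground-truth lineage stays "hepatocyte";
  annotation is expected to label them by the ISG panel, mirroring
  cluster-level annotation of such cells in real data.
* **Fluorescence.** DAPI renders each nucleus as a Gaussian blob (σ = 1.5
  px, amplitude U(0.6, 0.85)); GFP/tdTomato render cytoplasm-scale blobs
  (σ = 3 px) only at reporter-positive cells of the corresponding class.
  All channels add half-normal noise with scale = mean amplitude /
  `fluor_snr` (default SNR 10).

The generator is deliberately idealized: no point-spread function, no
channel bleed-through, no 3-D overlap of cells, no segmentation-breaking
cell-size variation, no empty (cell-free) regions, and background genes are
uniform rather than structured. Passing recovery tests therefore
demonstrates correctness of the computations under favorable, known
conditions — not performance on real sections, where nuclear crowding,
autofluorescence and diffusion of transcripts degrade every stage.

# Numerical and format choices

* Coordinates are 0-based pixel indices, origin top-left, x = column;
  transcripts bin by truncation. All public APIs share this convention.
* Label maps are stored as float32 TIFF scaled by 2⁻²⁴ (exact for labels
  below 2²⁴); intensity channels are stored scaled by a per-channel
  power-of-two recorded in a YAML sidecar, so the only round-trip error is
  float32 quantisation (~1e−7 relative). The cell × gene matrix uses
  MatrixMarket triplets with TSV sidecars and round-trips exactly.
* Seed ids are ordered by descending smoothed intensity with (y, x)
  tie-breaks; Voronoi ties go to the smaller id; BH is the stock step-up
  procedure; all RNG flows from a single configuration seed per section.

# Problem sizes

The shipped tests and the acceptance script run the full chain on the
default 2000-cell section (about 900k transcripts), check the segmentation
oracle on 50 random ≤ 128 × 128 instances, the rank-sum and Fisher
enumerations on 200 random cases each, and the permutation calibration on
20 label shuffles — sizes chosen so the whole suite completes in a few
minutes on one CPU while leaving every statistical check well-powered.

# Known limitations

* One radius cap for all cell types; densely packed small cells merge.
* Marker-panel annotation needs panels that discriminate at the granularity
  you care about; it will not discover unexpected populations (use
  `cluster_cells()` exploratively for that).
* The neighbor definition is purely topological (direct boundary contact);
  paracrine ranges beyond one cell diameter are out of scope.
* Contrasts treat cells as exchangeable within a type; there is no
  pseudobulk or mixed-model layer, so replicate-level confounding must be
  inspected via the per-replicate metadata.

```{r demo}
library(senoniche)
cfg <- run_config(synthetic = tissue_config(), out_dir = "senoniche_demo")
manifest <- run_pipeline(cfg)
manifest$counts
```
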