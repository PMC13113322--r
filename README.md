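# senoniche

Fluorescence-guided spatial single-cell analysis of senescent-cell niches.

Micrometer-resolution spatial transcriptomics captures individual
transcripts with coordinates but no cell boundaries. When the section also
carries DAPI and a p21 (Cdkn1a) dual fluorescence reporter — promoter
activity drives GFP, and Cre permanently switches on tdTomato — rare
senescent cells and their immediate neighbors become addressable at
single-cell resolution. `senoniche` implements that workflow for aged-liver
sections:

1. **Segmentation** — DAPI intensity peaks become nuclear seeds; each seed
   grows an isotropic territory up to a radius cap *r* (default 6 px ≈ 15 µm
   at 2.5 µm/px), stopping where territories meet. Formally, pixel *p* gets
   label *k* iff `d(p, s_k) = min_j d(p, s_j) ≤ r` (Euclidean, ties to the
   smaller id) — a distance-capped Voronoi partition.
2. **Quantification** — transcripts bin by truncation into segments,
   yielding a cells × genes matrix; cells need ≥ 100 unique features to
   pass QC; per-segment GFP/tdTomato means against background-percentile
   thresholds give the reporter classes `double`, `gfp_only`,
   `tdtomato_only`, `none`, and p21 positivity.
3. **Annotation** — depth-normalized log expression
   `ln(1 + c·T/total)`, marker-panel scores (panel means), argmax-with-
   margin type labels; PCA + Louvain clustering as the exploratory route.
4. **Niche** — the segment contact graph (8-connectivity) defines
   neighbors: cells whose boundary directly touches a p21⁺ segment.
5. **Statistics** — per cell type, Wilcoxon rank-sum contrasts (p21⁺ vs
   rest, neighbors vs rest) with Benjamini–Hochberg control and the rule
   *significant ⇔ adjusted p < 0.05 and log2FC > 0*; a cumulative ISG score
   (panel mean of Rsad2, Ifit1, Cmpk2, Ifit3); and replicate-wise Fisher
   exact tests of p21 × ISG overlap.

A synthetic zonated-liver generator with complete ground truth (cell
positions, types, reporter classes, ISG focus, per-transcript source cells)
makes every stage testable offline; see the methods vignette
(`vignettes/senescent-niche-mapping.Rmd`) for the model and all design
choices.

## Worked example

```r
library(senoniche)
cfg <- run_config(synthetic = tissue_config(), out_dir = "senoniche_demo")
manifest <- run_pipeline(cfg, quiet = TRUE)
str(manifest$counts)
#> List of 10
#>  $ seeds_detected        : int 2000
#>  $ cells_segmented       : int 2000
#>  $ transcripts_unassigned: int 53261
#>  $ transcripts_rejected  : int 0
#>  $ cells_passing_qc      : int 2000
#>  $ p21_positive          : int 35
#>  $ neighbors             : int 116
#>  $ isg_positive          : int 40
#>  $ contrasts_tested      : int 6
#>  $ contrasts_skipped     : int 4
```

All 2000 planted nuclei are detected and segmented; 35 cells (1.8%) are
called reporter-positive and 116 cells touch one of them. The p21⁺
macrophage contrast recovers the planted senescence program — reporter
transcripts, Cdkn1a, and the 4×-upregulated SASP genes:

```r
ct <- read.delim(file.path(cfg$out_dir, "contrasts.tsv"))
mac <- subset(ct, cell_type == "macrophage" & contrast == "p21_vs_rest" & significant)
head(mac[order(mac$p_adj), c("gene", "log2fc", "p_adj")], 8)
#>      gene    log2fc        p_adj
#>  tdTomato 7.1042395 1.330792e-40
#>      EGFP 5.5431674 1.212203e-08
#>      Ccl8 0.5661609 7.397025e-05
#>    Cxcl10 0.5604445 7.397025e-05
#>     Cxcl9 0.6421786 7.397025e-05
#>      Mmp3 0.6250073 7.397025e-05
#>     Gpnmb 0.6340000 7.794776e-05
#>    Cdkn1a 1.8427578 1.927112e-03
```

The replicate-wise overlap table shows what independence looks like: p21⁺
and ISG⁺ cells co-occur no more than chance predicts (Fisher p = 0.51):

```r
read.delim(file.path(cfg$out_dir, "overlap.tsv"))
#>  replicate p21_pos_isg_pos p21_pos_isg_neg p21_neg_isg_pos p21_neg_isg_neg
#>          1               1              34              39            1926
#>   p_value odds_ratio
#>  0.509945   1.452489
```

A thin CLI wraps the same functions
(`inst/cli/senoniche simulate|run|segment|de|isg|overlap`).

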