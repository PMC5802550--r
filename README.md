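# orgcyto

Quantitative analysis of cellular organization in cerebral-organoid
sections and of coexpression networks in progenitor transcriptomes, for
researchers comparing control and disease (e.g. schizophrenia-derived)
organoids.

Cerebral organoids form rosettes — a lumen wrapped by ventricular (VZ),
intermediate (IZ) and cortical (CZ) zones. orgcyto measures how that
architecture degrades:

* **MST dispersion.** Proliferating (Ki67+) cell centroids in each ROI
  are summarized by their Euclidean minimum spanning tree; edge lengths
  are binned into half-open 5 px bins ([0, 5), [5, 10), ...) and
  phenotypes compared by a two-way ANOVA (phenotype x distance bin,
  Type II SS, ROIs as replicates). Scattering of cells out of the VZ
  shifts the edge-length distribution toward longer bins and shows up
  as a phenotype-by-bin interaction.
* **Interneuron morphometry.** Segmented calretinin+ cells are measured
  for total skeleton length (body plus neurites; 50 px = 18 um at the
  default 0.36 um/px calibration) and for the deviation angle, folded
  into [0, 90] degrees, between each cell's long axis (second-moment
  principal axis) and the tangent of a cortical-surface curve. Groups
  are compared with the two-sample Kolmogorov–Smirnov test on the raw
  values.
* **ROI intensity and colocalization.** Background subtraction, 8-bit
  conversion, per-ROI mean intensity over pixels whose centers fall in
  the polygon, random placement of fixed-area square ROIs, percent of
  DAPI nuclei positive for a second marker, and greedy double-label
  matching between channels.
* **Coexpression networks.** Gene filters (expressed in all samples;
  |FC| >= 1.5 with q <= 0.05), pairwise Pearson correlation within a
  condition, signed graphs thresholded at |r| > 0.9, top-200 most
  connected subgraphs, and deconstruction metrics (edge, component and
  degree ratios) between conditions.

A synthetic-data generator (`simulation_config()`,
`simulate_rosette_points()`, `simulate_interneurons()`,
`simulate_expression()`, `render_channel()`) emulates all the inputs
with known ground truth, so the full pipeline is testable without
microscope or sequencing data.

All user-facing functions take data frames first and return tibbles;
fitted comparisons support `tidy()` and `glance()`; `plot_*()` helpers
cover the standard figures (rosette maps, MST bin histograms, CDF
curves, correlation histograms, circular network graphs).

## Worked example

```r
library(orgcyto)

# 17 control vs 20 disease ROIs, 40 proliferating cells each
cohort <- simulate_dispersion_cohort(seed = 1)
tab    <- dispersion_experiment(cohort)
rs     <- attr(tab, "roi_stats")
tapply(rs$mean_edge_px, rs$group, mean)
#>  control  disease
#> 21.49955 40.61188
tidy(compare_dispersion(tab))
#> # A tibble: 3 x 5
#>   term      statistic    df   df2   p.value
#>   <chr>         <dbl> <dbl> <dbl>     <dbl>
#> 1 group           0       1  1190 1   e+  0
#> 2 bin            93.4    33  1190 0
#> 3 group:bin      25.0    33  1190 1.34e-112
```

Control ROIs average ~21 px between neighbouring proliferating cells,
disease ROIs ~41 px, and the phenotype-by-bin interaction is
overwhelming — the disease pattern is dispersed. (The `group` main
effect is empty by construction: every ROI contributes the same number
of MST edges.)

```r
# orientation morphometry at study scale: 770 vs 547 cells
ctrl <- simulate_interneurons(
  simulation_config(seed = 1, phenotype = "control", n_interneurons = 770),
  min_separation_px = 0)
dis  <- simulate_interneurons(
  simulation_config(seed = 2, phenotype = "disease", n_interneurons = 547),
  min_separation_px = 0)
tidy(compare_morphology(ctrl$true_deviation_deg, dis$true_deviation_deg))
#> # A tibble: 1 x 5
#>   term  statistic    df   df2 p.value
#>   <chr>     <dbl> <dbl> <dbl>   <dbl>
#> 1 D         0.730    NA    NA       0
```

Tangent-aligned control cells against uniformly oriented disease cells
give a KS distance of ~0.73 — far beyond any plausible chance level.

```r
# coexpression network formation and deconstruction
ex    <- simulate_expression(seed = 1)   # 3 planted modules of 10 genes
corr  <- pairwise_correlation(ex$values,
          samples = ex$samples$sample_id[ex$samples$condition == "NCC"])
decor <- pairwise_correlation(ex$values,
          samples = ex$samples$sample_id[ex$samples$condition == "NPC"])
connectivity_metrics(build_graph(corr), build_graph(decor))$per_graph
#> # A tibble: 2 x 6
#>   graph n_edges n_connected_genes n_components mean_degree largest_component
#>   <chr>   <dbl>             <int>        <dbl>       <dbl>             <dbl>
#> 1 a         135                30            3         2.7                10
#> 2 b           0                 0            0         0                   0
```

The correlated condition forms exactly the three planted modules as
connected components; the decorrelated condition has no edge above the
0.9 threshold — the network is fully deconstructed.

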