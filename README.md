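# heartscape

Single-nucleus RNA-seq analysis of heart tissue, for researchers studying
cardiomyocyte states in injury and regeneration models. The package
reimplements a complete snRNA-seq pipeline as tested, reusable R
functions:

* **QC & normalization** — barcode/nucleus filtering (500/30,000 UMI
  bounds, 5%/25% mitochondrial caps, 200-gene minimum), log-normalization
  to counts-per-10,000, covariate-regressed scaling;
* **autoencoder embedding** — a three-layer autoencoder minimizing
  `E = (1/N)Σᵢ‖xᵢ − yᵢ‖² + 0.001‖W‖² + Q` that maps cells from the
  ≥1,000-UMI gene space into a 10-dimensional embedded layer;
* **projection & clustering** — seeded UMAP to 2-D, the 30th-nearest
  distance curve with automated elbow selection of ε, and DBSCAN
  (minpts = 30, ε = 0.3 by convention) with cluster-by-group composition
  tables, profile-based cluster merging, and marker-panel annotation
  (e.g. cardiomyocytes via ACTC1/MYH7);
* **marker genes** — per-cluster selection by Fisher exact p < 10⁻⁶,
  detection in ≥50% of cluster cells, and ≥1.3-fold mean abundance, with
  genome-percentage and marker-sharing summaries;
* **gene-program scoring** — a soft-margin linear model
  (min `½|w| + CΣεᵢ` s.t. `yᵢ(wxᵢ + b) + εᵢ ≥ 1`) fit on positive/negative
  reference cell groups restricted to a program's genes; every cell gets a
  score `y = wx + b` and a high/middle/low call at the ±1 margins, with
  odds-ratio contrasts between clusters;
* **transition analysis** — semisupervised self-training scores in [0, 1]
  splitting an unlabeled cluster into two reference-like subpopulations,
  differential genes between them, and the co-expression arithmetic
  linking subpopulation fractions to cluster proportions;
* **cluster similarity** — the binary detection-pattern distance
  `Σⱼ(sign(xⱼ) − sign(yⱼ))²` averaged over 1,000 sampled cell pairs;
* **immunofluorescence quantification** — co-stain segmentation
  (green > 10), three-scenario background baselines, mean adjusted signal
  intensity, and Wilcoxon rank-sum group comparisons.

A synthetic-data module (`synthetic_design()`, `generate_counts()`,
`generate_if_image()`) plants clusters, markers, program gradients,
library-size variation, mitochondrial content, and stain images with known
truth, so the whole pipeline is testable without external data.

## Worked example

```r
library(heartscape)

design <- study_design(seed = 7)        # 6 clusters x 4 groups, 3,000 cells
sim <- generate_counts(design)

filtered <- filter_cells(sim$matrix)
norm <- scale_regress(lognormalize(filtered))
genes <- select_input_genes(filtered, min_total_umi = 1000)
X <- norm$scaled[match(genes, norm$gene_ids), ]

ae <- fit_autoencoder(X, ae_config(activation = "linear", epochs = 300, seed = 1))
coords <- project_2d(encode(ae, X), n_neighbors = 30, min_dist = 0.3, seed = 2)

kd <- estimate_epsilon(coords, k = 30)
kd
#> <kdist_curve> k = 30, elbow epsilon = 0.4067

labels <- density_cluster(coords, cluster_params(minpts = 30, epsilon = kd$epsilon))
table(labels)
#> labels
#>   0   1   2   3   4   5   6
#>   5 500 499 497 500 499 500
```

The elbow of the 30th-nearest-distance curve suggests ε ≈ 0.41 for this
layout, and DBSCAN recovers the six planted clusters (label 0 is noise —
5 cells). Composition and markers:

```r
head(composition_table(labels, filtered$group), 4)
#> # A tibble: 4 x 5
#>   cluster group      n_cells proportion percent
#> 1 1       ctl            500      0.5      50
#> 2 2       ctl            499      0.499    49.9
#> 3 3       injury_p28     497      0.497    49.7
#> 4 4       injury_p28     500      0.5      50

head(find_markers(filtered, labels, 1), 3)
#> # A tibble: 3 x 5
#>   gene      expressing_fraction  fold odds_ratio   p_value
#> 1 gene00018               0.912  4.91      102.  1.32e-303
#> 2 gene00001               0.924  5.23      108.  5.47e-303
#> 3 gene00002               0.908  4.56       93.8 2.43e-297
```

Each group splits 50/50 across its two planted clusters, and the top
markers of cluster 1 are planted cluster-1 marker genes (`gene00001`–`20`)
at ~5-fold enrichment with detection in >90% of the cluster — the effect
sizes the design planted. `plot_cell_map(coords, labels)`,
`autoplot(kd)`, and the `tidy()`/`glance()` methods give the matching
figures and model summaries.

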