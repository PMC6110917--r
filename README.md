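# soilscape

Multi-scale analysis of how edaphic pH and electrical-conductivity (EC)
gradients structure soil bacterial community diversity and composition, for
nested sampling designs of the kind used in polar-desert soil ecology:
lake-basin watersheds (regional scale), patterned-ground soil polygons
within basins (basin scale), and radial transects from the polygon trough
to its centre (local scale). The intended users are microbial ecologists
analysing OTU count tables against per-sample edaphic metadata.

## What it computes

Starting from an OTU table (samples × OTUs with phylum taxonomy) and
per-sample metadata (basin, polygon, distance from trough, coordinates,
pH, EC in µS/cm):

* **Rarefaction and diversity** — subsampling without replacement to a
  common depth (default 500 reads); observed species S, inverse Simpson
  1/Σp², Good's coverage 1 − singletons/reads; Bray–Curtis and binary
  Jaccard distance matrices.
* **Permutation matrix tests** — Mantel r (Spearman on off-diagonal
  entries), partial Mantel r_AB·C = (r_AB − r_AC r_BC)/√((1−r_AC²)(1−r_BC²))
  controlling for spatial distance, a multivariate Mantel correlogram over
  equal-frequency distance classes, ANOSIM
  R = (r̄_between − r̄_within)/(n(n−1)/4), and PERMANOVA with sequential
  (Type I) partitioning of the Gower-centred −D²/2 — per-term R² plus
  residual sums to 1. All permutation p-values follow the add-one rule;
  exhaustive enumeration is available for small n.
* **Canonical correspondence analysis** — chi-square residual matrix
  Q̄ = D_r^(−1/2)(P − rcᵀ)D_c^(−1/2) projected onto the constraint space;
  total inertia ΣQ̄² = χ²/N; permutation test of the model pseudo-F.
* **Sliding-window LMG model** — windows of 10 samples slid one sample at
  a time along each edaphic gradient; within each window the regression
  R² of richness on pH + EC is decomposed into non-negative per-predictor
  LMG shares (exact average of sequential R² gains over all predictor
  orderings); shares are normalized onto fixed-width bins (0.05 pH units,
  5 µS/cm) and summarized as dominance intervals with a crossover
  estimate.
* **Cohort statistics** — Kruskal–Wallis with rank-based Tukey post hoc
  letters, Spearman correlation grids with Benjamini–Hochberg correction,
  and phylum-vs-phylum regressions along transects.
* **A synthetic-landscape generator** whose defaults encode the nested
  3-basin × 8-polygon × 5-position design (120 samples), basin pH means
  8.77/10.03/9.57 and EC means 361/144/788 µS/cm, a local pH gradient only
  in the Bonney-like basin, a strong local EC gradient only in the
  Fryxell-like basin, signed phylum responses to EC, and a richness
  decline with EC — so the whole pipeline is testable without sequencing
  data.

## Worked example

```r
library(soilscape)
cfg <- default_config(seed = 42)
frame <- generate_landscape(cfg)
community <- generate_community(frame, cfg)
rar <- rarefy(community, depth = 500, seed = 1)
ids <- rownames(rar$counts)
meta <- as.data.frame(frame)[ids, ]
meta$observed_species <- observed_species(rar)[ids]

kruskal_wallis(meta$ph, meta$basin)
#> Kruskal-Wallis: chi2 = 91.26, df = 2, p = <2e-16
#> letters: Bonney=a, Fryxell=b, Hoare=c

anosim_test(beta_distances(rar, "bray_curtis"), meta$basin,
            n_perm = 999, seed = 2)
#> ANOSIM: R = 0.474, p = 0.001 (n_perm = 999)

permanova(beta_distances(rar, "jaccard"), meta,
          c("basin", "ec", "ph", "dist_from_trough"), n_perm = 999, seed = 3)
#> PERMANOVA (sequential):
#>              term Df        SS     R2     F     p
#>             basin  2 3.6843334 0.0918 5.571 0.001
#>                ec  1 0.7450040 0.0186 2.253 0.001
#>                ph  1 0.3397501 0.0085 1.027 0.306
#>  dist_from_trough  1 0.3062742 0.0076 0.926 0.775
#> Residual: df = 106, R2 = 0.8735

prof <- sliding_windows(meta, "ec", window_size = 10)
occ <- subset(normalize_profile(prof, bin_width = 5), n_windows > 0)
mean(occ$mean_share_ec > occ$mean_share_ph)
#> [1] 0.9708
```

Reading: the three basins differ sharply in pH (every basin gets its own
post hoc letter); basin identity separates the communities (ANOSIM
R = 0.474 with p at the permutation floor); the sequential PERMANOVA
attributes ~9% of community variance to basin and ~2% to EC entered next,
with pH and transect position adding little once those are in; and along
the EC gradient the windowed LMG decomposition makes EC the dominant
predictor of richness in ~97% of occupied 5 µS/cm bins.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
landscape and write tables under `results/`:

```sh
Rscript analysis/01_simulate_landscape.R   # metadata + OTU table
Rscript analysis/02_diversity.R            # rarefaction, alpha, distances
Rscript analysis/03_matrix_tests.R         # Mantel/ANOSIM/PERMANOVA, 3 scales
Rscript analysis/04_ordination.R           # CCA regional + per basin
Rscript analysis/05_sliding_window.R       # LMG importance profiles
Rscript analysis/06_taxon_patterns.R       # Spearman grid, phylum regressions
```

`run_scales()` orchestrates the same battery programmatically and
`write_report()` emits a replayable JSON summary (every statistic with its
permutation count and substream seed).

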