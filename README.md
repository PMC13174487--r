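# stemniche

Analysis toolkit for the CD8⁺ T cell compartment of the clear cell renal
cell carcinoma (ccRCC) immune microenvironment. Stem-like (progenitor)
CD8⁺ T cells — TCF7/IL7R/CXCR5-high — sustain the anti-tumor response and
give rise to terminally exhausted TOX/HAVCR2/CXCL13-high cells; their
spatial organization into stromal immune aggregates (up to tertiary
lymphoid structure–like niches) tracks with outcome. `stemniche`
implements the quantitative machinery for this biology:

- **State scoring** — control-gene signature scores per cell; a
  *transition score* `t = ecdf_rank(exhausted − stem) ∈ [0, 1]` ordering
  CD8 cells along the stem→exhausted axis; margin-argmax state labels.
- **Expression programs** — consensus NMF (`X ≈ WH`, HALS restarts,
  outlier-filtered consensus clustering of loadings, NNLS usage refit,
  stability-based choice of k); gene rankings by cosine similarity of
  loading profiles to the CXCL13 and CXCR5 anchors; weighted
  Kolmogorov–Smirnov running-sum enrichment (ES/NES, permutation p, BH
  FDR) and hypergeometric over-representation analysis.
- **Spatial niches** — DBSCAN-style immune aggregate detection;
  Quiescent / Stimulated / Lymphoid classification from chemokine
  co-expression and exhausted-CD8 content (requiring ≥ 20% T cells);
  stromal-area-normalized densities; Moran's I with permutation tests;
  transition-score ECDFs with bootstrap bands; rank-based aggregate-size
  contrasts; stromal localization tests.
- **Clonotypes** — paired-αβ TCR string clonotypes; the fraction of
  expanding clones (≥ 3 cells) containing multiple stem-like cells;
  clone-level CXCL13 / stem-fraction association.
- **Association models** — Kendall tau-b, zero-inflated negative
  binomial regression by EM with LRT, quadratic-vs-linear model
  comparison, rank-based differential expression.
- **Synthetic data** — a seeded generator for all of the above with
  recoverable ground truth: a CD8 differentiation continuum, clone-size
  laws with controlled stem content, and tissue maps with planted
  aggregates of the three classes.

## Worked example

The `analysis/` scripts run the full study workflow on the synthetic
cohort (`Rscript analysis/01_simulate.R` … `06_association_models.R`,
outputs under `results/`). Condensed, with the numbers they print:

```r
library(stemniche)

cfg <- sim_preset("well_separated", seed = 2026, n_cells = 2000)
sim <- simulate_cd8_counts(cfg)                       # counts + ground truth
st  <- score_state_table(sim$counts,
         label_map = c(stem = "stem-like", cytotoxic = "effector",
                       exhausted = "exhausted"))
mean(st$state_label == sim$truth$state)               # 0.960
cor(sim$truth$u, st$transition, method = "spearman")  # 0.918
```

The cNMF anchor rankings recover the program structure: genes covarying
with CXCL13 are the exhaustion markers (running-sum enrichment of the
exhausted set: ES 0.82, FDR 0.003; stem set depleted, ES −0.89), while
CXCR5's top covarying genes are LEF1, CCR7, TCF7, IL7R (stem set ES 1.00,
FDR 0.005). Spatially:

```r
tis  <- simulate_tissue(cfg)
aggs <- classify_aggregates(detect_aggregates(tis$map), tis$map, tis$expr)
aggs$aggregates$class_label      # "Quiescent" "Stimulated" "Lymphoid"
```

Membership ARI against the planted aggregates is 0.962; chemokine
Moran's I is 0.57 (CXCL13) and 0.53 (CXCR5) against a null expectation of
−0.002 (permutation p = 0.002); Lymphoid-aggregate CD8 cells sit lower on
the transition axis than Stimulated ones (mean transition 0.34 vs 0.68,
KS = 0.58). At the clonotype level, 89/196 = 45.4% of expanding clones
carry ≥ 2 stem-like cells (generator target 47.7%), and clone-mean CXCL13
anti-correlates with clone stem fraction (Kendall tau = −0.50).

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch against
the installed package — simulating the cohort, scoring states, fitting
the consensus NMF with both anchor rankings and enrichment, detecting and
classifying aggregates, building clonotypes and fitting the association
models — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All quantitative guarantees (oracle equivalence of the clustering,
enrichment, Moran and Kendall primitives; planted-structure recovery;
ZINB calibration) live in `tests/testthat/test-acceptance.R`.
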