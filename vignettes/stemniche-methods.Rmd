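---
title: "Methods: CD8 state scoring, expression programs and spatial immune niches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CD8 state scoring, expression programs and spatial immune niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemniche)
```

# Scope

`stemniche` re-implements, as tested and reusable components, the
computational core of a tumor immune-microenvironment analysis in clear
cell renal cell carcinoma (ccRCC): scoring CD8⁺ T cells along a
stem-to-exhausted axis, consensus non-negative matrix factorization (cNMF)
of expression programs with CXCL13/CXCR5 anchor-similarity rankings and
running-sum enrichment, density-based detection and classification of
stromal immune aggregates, clonotype-level stem-content statistics, and
the supporting association models (Kendall correlation, zero-inflated
negative binomial regression, quadratic-versus-linear comparison). Because
the original patient tissue and the underlying public single-cell cohorts
are not bundled here, every procedure is exercised end to end on synthetic
data with recoverable ground truth; the generator is itself first-class,
tested code.

This vignette records the models, the tunable parameters, the numerical
choices, and the open design decisions the package had to settle.

# The synthetic world

## CD8 differentiation continuum

Each simulated CD8 cell carries a latent differentiation coordinate
$u \in [0,1]$ (stem-like at 0, terminally exhausted at 1). A cell first
draws a discrete state from `state_mixture`, then $u$ uniformly from that
state's interval (`state_u`). Gene means are
`baseline * archetype_multiplier(class, u, marker_amp)` with marker
amplitude 8× baseline by default (the generative model is the package's
own choice; the source study reports no generative model):

* **stem markers** (TCF7, IL7R, CCR7, CXCR5, SELL, LEF1, BACH2) decay
  linearly from `marker_amp` at $u=0$ to 1 at $u=1$;
* **exhaustion markers** (TOX, HAVCR2, PDCD1, CXCL13, LAG3, TIGIT,
  ENTPD1) mirror them;
* **cytotoxic markers** (GZMB, GZMA, PRF1, NKG7, IFNG, KLRG1) form a
  Gaussian peak at $u=0.5$ (width 0.12) — effector function rises and
  then wanes with terminal exhaustion;
* **proliferation markers** (MKI67, TOP2A, PCNA, STMN1, MCM2, CDK1,
  TYMS, RRM2) form a narrow burst at $u=0.70$ (width 0.07), i.e. in the
  effector-to-exhausted transition rather than inside any discrete state.
  An earlier, wider bump centered inside the effector interval made
  effector cells systematically mis-assign to "proliferating"; the burst
  placement is therefore a deliberate separability decision, not a claim
  about biology;
* 30 flat "housekeeping" genes cycle through baselines 0.2–10 so that
  expression-bin-matched control-gene sampling has non-trivial bins.

Counts are negative binomial with dispersion `nb_dispersion` (θ; variance
$\mu + \mu^2/\theta$), Poisson in the $\theta \to \infty$ limit, with
independent dropout (`zero_inflation`). All randomness flows through one
seeded generator; identical configurations are byte-identical.

The `"well_separated"` preset — narrowed state intervals
(stem 0.02–0.18, effector 0.42–0.58, exhausted 0.82–0.98), θ = 10, no
dropout — is the regime in which the recovery guarantees are stated. A
green recovery test establishes that the pipeline recovers planted
structure *when the structure is recoverable*; it does not establish
performance on noisy, batch-affected real tissue.

## Clonal structure

Clone sizes follow a geometric law (`clone_size_law`, default p = 0.6).
Each expanding clone (≥ 3 cells) is declared "stem-maintained" with
probability `frac_expanding_with_stem` (default 0.477, echoing the
fraction reported in the motivating study) and is then seeded with at
least two stem-like cells; "exhaustion-dominant" clones draw from the
non-stem pool. The realized fraction is therefore binomial around the
target, which is exactly what the recovery test asserts. Clonotype keys
are surrogate `TRA:<id>|TRB:<id>` strings: the statistic depends only on
exact string identity, so realistic CDR3 sequences would add nothing.

## Tissue maps

Tumor regions are a thresholded Gaussian random field (white noise on a
25 µm grid, separable Gaussian smoothing, threshold at the
`tumor_area_frac` quantile); stroma is the remainder. Background immune
cells follow a homogeneous Poisson process over the stroma. Each planted
aggregate is a 2-D Gaussian cluster (σ = 40 µm) centered in stroma, with
centers re-sampled (up to 200 times) if they fall closer than
`min_center_sep_um` to another center or if more than 5% of the simulated
footprint lands on tumor. Default composition classes:

| class | T fraction | B fraction | exhausted CD8 | chemokine level |
|---|---|---|---|---|
| Quiescent | 0.70 | 0.10 | 0.10 | 1× |
| Stimulated | 0.70 | 0.10 | 0.60 | 1× |
| Lymphoid | 0.45 | 0.35 | 0.15 | 8× |

CD8 cells in the tissue also carry a latent $u$ consistent with their
state label, so transition-score ECDFs can be compared across detected
classes. The generator emits cells directly; bin-to-cell segmentation of
spot-level data is deliberately out of scope, so pseudocell-construction
choices of the original platform are not modeled.

# State scoring

`score_signature()` re-implements the standard control-gene scoring
scheme: genes are ranked by population average expression into `n_bins`
equal-count bins (default 25); each signature gene is compared with
`n_ctrl` (default 50, capped at bin size) control genes sampled from its
own bin, and a cell's score is the mean over signature genes of
(expression − mean control expression). Scores are computed on
library-size-normalized (10⁴ per cell), log1p-transformed counts; the
source methods are silent on normalization, so this common default is
stated explicitly. Adding a constant to every gene leaves scores
unchanged — a property the tests assert.

**Transition score.** The study describes a stem-to-exhausted "transition
score" without a formula. The package defines: raw = exhausted score −
stem score; transition = mid-rank empirical-CDF position of raw among
scored cells, $(r - 0.5)/n$. This is monotone in the raw contrast,
scale-free, and uniform on $[0,1]$ over the scored population by
construction. A pseudotime-based alternative was considered and rejected
to avoid importing a trajectory-inference stack; on the synthetic
continuum the rank-normalized contrast correlates with the latent
coordinate at Spearman ≥ 0.9, which is the property that matters
downstream.

**Discrete states.** The original analysis used graph clustering with
majority-vote annotation. The package instead assigns the argmax
signature, requiring it to beat the runner-up by `margin` (default 0,
with "other" only on exact ties) — transparent, deterministic, and
testable against ground truth (≥ 0.9 accuracy on the well-separated
preset).

# Consensus NMF and anchor rankings

For each candidate k, `n_restarts` (default 30; 10–15 suffice on the
synthetic panels) HALS fits of $X \approx WH$ are run from seeded random
initializations. Loading rows are L2-normalized and pooled; factors whose
nearest-neighbor cosine distance exceeds 0.3 are dropped as outliers; the
rest are clustered into k groups by average linkage on cosine distance;
consensus loadings are the component-wise median of each cluster
(re-normalized), and usages are refit by nonnegative least squares
(active-set). Per-k stability is the mean silhouette of that consensus
clustering.

**Choosing k.** The specification of this component was ambiguous: the
operation contract said "elbow of the reconstruction-error curve," its
acceptance property said "stability-based selection." Both rules are
implemented; the default (`"stability"`) selects the *smallest k that is
stable (silhouette ≥ 0.98) and reaches near-minimal reconstruction error
among stable candidates (within 5% relative)*. The two-sided rule matters:
below the true k restarts agree on merged programs (stable, poor fit);
above it they either disagree on splits (unstable) or split without
improving the fit. Pure max-silhouette reliably under-selects and pure
largest-stable-k occasionally over-selects by one. The published
configuration for the full-scale cohorts is pinned as
`cnmf_paper_preset()` with k = 13.

**Anchor similarity.** A gene's program profile is its column of the
consensus loadings; genes are ranked by cosine similarity to the anchor
gene's column (CXCL13 and CXCR5 are each run as their own anchor,
matching the two published panels), descending, ties broken
lexicographically so rankings are reproducible.

**Enrichment.** The ranked list is tested with the weighted
Kolmogorov–Smirnov running sum (weight $|s|^p$, p = 1): up-steps
proportional to hit weights, down-steps $1/(N-m)$; ES is the signed
maximum deviation. The null is `n_perm` gene-label permutations; NES
divides ES by the mean |null ES| of the same sign and p is the same-sign
tail with the +1 correction; FDR is Benjamini–Hochberg across the
supplied set family. ES/NES/FDR were named but not defined in the source;
these are the GSEA-standard choices. A set covering the whole ranking is
degenerate (no misses) and returns ES = 0. Over-representation analysis
is the one-sided hypergeometric tail with BH correction, reporting
overlap counts and the fraction of module genes covered.

# Spatial niches

**Detection** is DBSCAN-style: a core cell has ≥ `min_samples` neighbors
(excluding itself — the convention is stated because the spec wording was
ambiguous) within `eps_um`; clusters are connected core components plus
border cells attached to the lowest-id reachable core cluster; noise is
dropped, as are clusters below `min_size`. Defaults eps = 50 µm,
min_samples = 10, min_size = 20 are package choices (the study reports
none) and are config-exposed; neighbor search uses eps-sized grid
binning, and the implementation is required by test to be
partition-identical to a brute-force reference.

**Classification** is a decision list with quantile thresholds so it is
invariant to uniform rescaling of expression: (1) T-cell fraction < 0.20
→ Unclassified (the study's ≥ 20% T-cell rule); (2) both aggregate-mean
CXCL13 and CXCR5 at or above the cohort 75th-percentile of
aggregate-level means → co-expressing → Lymphoid; (3) exhausted-CD8
fraction ≥ 0.4 → Stimulated; (4) otherwise Quiescent. The co-expression
quantile (0.75) and exhaustion cut (0.4) quantify the study's qualitative
descriptions; with fewer than two aggregates the quantiles are
meaningless and fixed expression cutoffs are used (logged).

**Statistics.** Stromal area uses a 50 µm occupancy grid (tiles
containing ≥ 1 stromal cell), trading boundary bias for image-free
reproducibility; the grid-size sensitivity is itself tested against a
disk of known area. Moran's I uses row-standardized k-nearest-neighbor
weights (k = 6, distance ties broken by cell index) with permutation
p-values and the exact $-1/(n-1)$ null expectation. Transition-score
ECDFs are compared per class with pointwise 5–95% bootstrap bands
(display aids; the KS statistics are computed from the raw scores).
Aggregate-size contrasts report the median difference with an exact
Wilcoxon rank-sum p when both groups are small and tie-free, a
permutation rank-sum p otherwise. Per-aggregate stromal localization is a
two-sided binomial test against the slide-wide stromal fraction of immune
cells. Multiple aggregates are not multiplicity-corrected by default,
matching the source's reporting; BH is available via `p.adjust` on the
returned columns.

# Clonotypes

Clones are exact string matches of the paired-chain key; cells without a
TCR are excluded and counted. "Expanding" means ≥ 3 cells; "multiple
stem-like cells" means ≥ 2 (configurable) — the stem-like label comes
from the state-scoring module, since the source does not fully specify
its clone-level stem definition. With no expanding clones the statistic
is returned explicitly as not computable rather than as NaN. The
clone-level CXCL13/stem-fraction association uses Kendall's tau-b.

# Association models

**Kendall tau-b** uses the tie-corrected denominator, with exact
permutation enumeration for n ≤ 8 and the tie-corrected normal
approximation otherwise; it is test-verified against both brute-force
pair enumeration and `stats::cor.test`.

**ZINB.** $y \sim \pi\,\delta_0 + (1-\pi)\,\mathrm{NB}(\mu, \theta)$,
$\mu = \exp(X\beta)$, NB2 variance, shared scalar π (a covariate-
dependent π via a logistic link was considered and left out: nothing in
scope needs it). Fitting is EM: the E-step computes the posterior
probability that each observed zero is structural; the M-step updates π
in closed form and (β, log θ) by warm-started BFGS on the weighted NB
log-likelihood, accepting only improvements, so the observed-data
log-likelihood is non-decreasing — asserted at every iteration in the
tests. Convergence is |ΔL| < 1e-6 or 500 iterations; non-convergence
flags the fit rather than erroring. Covariate association is a χ² LRT
against the intercept-only null.

**Quadratic vs linear.** OLS for $y \sim x$ and $y \sim x + x^2$, both
R², and the large-sample LRT $n \log(\mathrm{RSS}_1/\mathrm{RSS}_2)$ on
1 df (F-test available). When the linear fit is already essentially
perfect (RSS below 1e-10 of total variance) the LRT is defined as 0: the
ratio of two floating-point zeros is noise, not evidence.

**Rank DE** (two-sided Mann–Whitney per gene, log2 ratio of means + 1,
BH) is explicitly a plumbing substitute for the model-based differential
expression used in the source; its gene lists are not expected to match
model-based output, and it exists so the Lymphoid-versus-surrounding
contrast can be exercised end to end.

# Pipeline and reproducibility

`run_pipeline()` executes score → cNMF → niches → clones → assoc, writes
every table as CSV/JSON, and records an MD5 per file in `manifest.json`.
One global seed is expanded to per-stage seeds by a fixed polynomial hash
of the stage name, so adding a stage never perturbs earlier ones. Stage
parameters are looked up with exact-name indexing (a partial-name lookup
once silently matched `k` to `k_grid`; the regression is covered by the
determinism test). Configuration is an R list serialized as JSON; no YAML
dependency is available in the target environment and JSON carries the
same structure.

# Known limitations

* The generator's continuum is one-dimensional and noise is independent
  across genes; real CD8 data carry correlated technical noise, batch
  structure and doublets that none of the guarantees here speak to.
* Aggregate classification thresholds (0.75 quantile, 0.4 exhaustion
  cut) are calibrated to the synthetic world's contrast; on real tissue
  they are starting points to be tuned against histology.
* The stability rule for k assumes the error curve flattens after the
  true rank; on data without a clean low-rank structure (most real
  expression matrices) "selected k" is a modeling choice, not an
  estimate.
* Tissue simulation is 2-D and cell-resolved; segmentation error and 3-D
  effects are out of scope.
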