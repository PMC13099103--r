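---
title: "Models and design choices in spatplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in spatplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spatplex)
```

`spatplex` analyses segmented hyperplexed-imaging data: one row per cell,
centroid coordinates in pixels (0.45 µm/pixel by default), and a mean 8-bit
intensity for each of ~78 markers. This vignette explains each model the
package fits, the assumptions behind it, the parameters that matter, and
the places where the design was genuinely open and a choice had to be made.

## The synthetic tissue generator

Every stage of the package is exercised against simulated samples with
known ground truth, because public hyperplexed datasets rarely ship
re-analyzable single-cell matrices. The generator (`synthetic_spec()`,
`generate_sample()`, `generate_cohort()`) emulates the features of the real
data that the downstream statistics actually consume, and nothing more:

* **Abundances** are a multinomial draw over the declared type fractions.
* **Spatial modes** per type: `poisson` (complete spatial randomness,
  uniform over the field), `clustered` (a Thomas-style parent–offspring
  process with Gaussian dispersion `cluster_sd`), and `coupled` (each cell
  displaced from a random partner cell of another type by an isotropic
  Gaussian of sd `displacement_sd`; the radial displacement is therefore
  Rayleigh, and on sparse fields the median nearest-neighbor distance to
  the partner type is close to `displacement_sd * sqrt(pi/2)`). Points
  landing outside the field are redrawn, so per-type counts are exact.
* **Marker intensities** come from a two-component lognormal mixture per
  (type, marker): a bright "expressed" component and a background
  component, mixed by a positive fraction. Values are clipped to [0, 255]
  after exponentiation and rounded to 8-bit integers last, mirroring
  mean-intensity extraction from 8-bit images.
* **Zones** are named polygons; membership is point-in-polygon on the cell
  centroid and everything else is `"interstitial"`.
* `plant_colocalization()` relocates an exact count
  (`round(fraction * n_b)`) of one type uniformly into discs around random
  cells of another, giving a known-positive spatial association.

What the generator does **not** emulate: segmentation errors, staining
artifacts, marker spillover, spatially varying background, cell shapes and
sizes (cells are points), or realistic marker correlation structure beyond
the type labels. Passing tests therefore demonstrate that the algorithms
recover the structure they are designed for — not that real tissue will be
as clean.

Reference conditions used by the test bench (`bench_*_spec()`): a 2 × 2,000
cell CSR pair on a 2,000 px field for null calibration; a dense background
(3,000 cells) plus four 300-cell focal types on 2,250 px for the spatial
statistics — the background matters because it makes each focal type's
interaction area small relative to the tissue area, which is the regime the
overlap null assumes in densely packed tissue; 3-type and 6-subtype marker
panels for the clustering stages. The light-chain condition plants
kappa/lambda plasma-cell fractions at a 1.5 abundance ratio, the balance
reported for normal lymphoid tissue.

## Lognormal shrinkage

`fit_shrinkage()` fits, per marker, a 1-D Gaussian mixture on
`log(1 + intensity)` with `modelNames = "V"` (unequal variances), selecting
the component count by BIC over 1..`G_i` and then dropping components of
weight below `weight_tol` (1e-3). `G_i` (default 20) is an upper bound, not
a target: it should be chosen so that the converged `G_f` stays strictly
below it for every marker (very large samples may need ~28). The log offset
of 1 admits the zeros that 8-bit data contain; the exact offset is a
convention, not a fitted quantity.

`apply_shrinkage()` contracts each value toward the mean of its
maximum-responsibility component: `x' = mu_k + (1 - lambda) * (x - mu_k)`.
Contracts tested rather than trusted: `lambda = 0` is the exact identity on
`log1p`; `lambda = 1` collapses to component means and is idempotent;
within-component order is preserved for `lambda < 1`; outputs stay inside
the hull of the inputs. The default `lambda = 0.8` is a configuration
constant, deliberately exposed — the method's value is the contract, and
the test suite asserts the benefit (chance-corrected agreement with ground
truth after clustering does not drop when contraction is on, under the
bench conditions with fixed seeds) instead of any magic value. Across
random seeds the improvement holds in the large majority of runs and in
the mean; occasional inversions occur when contraction crystallizes a
spurious mixed cluster, which the noise bucket would otherwise absorb —
worth knowing when tuning `lambda` on real panels. Ties in component assignment go to the lower-mean component,
making the transform deterministic.

Per-cell marker positivity — needed only for the "expressed in ≥30% /
≥70% of cells" reporting conventions, since the pipeline never gates
intensities — is defined from the same mixture: a cell is positive when its
assigned component's mean exceeds the marker's weight-averaged grand mean.
This is deterministic and threshold-free; it was an open design point and
is intentionally decoupled from significance testing.

## Embedding and density clustering

`embed_and_cluster()` runs UMAP (via `uwot`, 2-D, defaults
`n_neighbors = 15`, `min_dist = 0.1`, seeded, single-threaded SGD so runs
are bit-reproducible) followed by DBSCAN on the embedding. No
hierarchical-density implementation is available in this dependency stack,
so the package carries a standard DBSCAN (radius queries via `RANN`,
components of the core graph via `igraph`); the noise label −1 plays the
same garbage-collector role. `eps` defaults to 3× the median
`min_pts`-th-neighbor distance on the embedding — a knee-style heuristic
that tracks the embedding's within-cluster scale; it is a parameter, and
recorded with every result.

Cluster-size floor: clusters smaller than
`max(min_cluster_size, 20, 0.005% of n)` are dissolved into noise.
`min_cluster_size` (default 200, useful range ~100–300 for 1e5-cell
samples) trades granularity against the size of the unclear bucket.
Because embeddings are stochastic across library versions, all recovery
guarantees are stated in terms of cluster-to-truth purity, never label
identity.

`nested_classify()` implements the two-level scheme: preprocessing once,
global clustering on the global panel, an explicit `broad_map` from global
clusters to broad types (supervision is an input — in real use an expert
decision, in tests a ground-truth majority vote via `majority_map()`), then
an independent re-clustering of each broad type on its subpanel only.
Global noise and unmapped clusters never enter subclass runs; a subclass
−1 is reported as `"average <type>"` because at that level it means a
typical cell of the type, not junk. Subclass runs derive their seeds as
`seed + 1000 * k`, which makes the single-type reduction exactly equal to a
direct `embed_and_cluster()` call — a contract the tests hold.

`characterize_cluster()` uses Welch's *t*-test per marker (inside vs
outside the cluster, Bonferroni over markers, α = 0.05 by default) and a
robust effect size: difference of medians over the pooled MAD
(`sqrt((mad_in^2 + mad_out^2)/2)`). The published pipelines this follows
describe "a robust measure of effect size" without printing the formula;
the choice here is documented, configurable in spirit (the ranking
contract, not the constant, is what the tests pin down), and the profile
keeps only significantly *over*-expressed markers, ranked by decreasing
effect, since depleted markers do not characterize a phenotype.

## Profiling conventions

`band_marker_frequencies()` recounts, per (type, marker), the fraction of
the type's clusters where the marker is significant, with inclusive band
edges at 0.70, 0.50 and 0.30 and omission below 0.30.
`top_ranked_markers()` takes the median of the marker's positions in the
per-cluster ranked lists; clusters where the marker is absent contribute no
rank (the alternative — imputing rank m+1 — is available as
`absent = "m_plus_1"`). Markers with median rank 1–5 are reported. Both are
verified against brute-force recounts on randomized profiles.
`light_chain_ratio()` is plain count arithmetic per sample with cohort mean
and SD; a sample without lambda-positive cells reports an undefined ratio
rather than a number.

## The neighborhood test

For focal type *i* and radius *r* (10 and 20 µm → 22 and 44 px via
truncation at 0.45 µm/px; `radius_in_pixels()` is the single conversion
point), cells other than *i* are near iff within *r* of any *i* cell
(centroid Euclidean distance). Fisher's exact test (two-sided — depletion
is as reportable as enrichment) is applied to near/far × (*j*/other), and
the reported enrichment is the ratio of proportions near vs far, the
statistic the worked 20%/5% → 4 example defines; the classical odds ratio
is also emitted. Self-pairs are supported by excluding the focal cell
itself from its own neighborhood. Degenerate margins are flagged (`p = NA`
with no far or no near cells) or resolved by convention (no *j* anywhere →
ratio 0, p = 1; *j* only near → ratio +Inf with an exact p).

Consensus is deliberately harsh: a pair is significant only when *every*
(sample containing both types) × (radius) test falls at or below α/m — the
max-p rule. It is monotone (more samples can only remove calls) and its
false-positive rate under CSR is far below nominal, which the suite
measures. `m` defaults to the number of evaluable ordered pairs and is
always logged with the threshold, because a printed threshold is only
reproducible together with its m: at the package's default α = 0.05, for
example, m = 6177 yields 8.0945e-06.

## The overlap test

Discs of radius *r* around every cell are rasterized on the native pixel
grid (a pixel belongs to a disc when its center is at distance ≤ *r* from
the cell's pixel-snapped center; ties included; field-border truncation).
The tissue area *A* is the union of discs over *all* cells of the sample —
so "tissue" is wherever cells are, and border effects are ignored on the
assumption that any one type's area *a* satisfies *a* ≪ *A*. The
rasterizer is compiled (row-span difference arrays) and is checked
bit-for-bit against an exhaustive per-pixel oracle on small fields.

Cross-type: o_ij is the Jaccard index of the two coverage sets, compared
with `K ~ Binomial(min(n_i, n_j), max(a_i, a_j)/A)` through the strict
upper tail at `floor(o_ij * min(n_i, n_j))`. The null treats each pixel hit
as a Bernoulli trial; it is conservative under CSR (the suite asserts the
empirical type-I rate stays below nominal rather than at it).

Same-type: the observed statistic is the fraction of covered pixels hit at
least twice; its null expectation is the binomial tail ratio
`P(K > 1)/P(K > 0)` with `p = a_single/A`, and significance comes from
bootstrap placements of n_i cells uniformly on the tissue support (pixels
with coverage ≥ 1, not the bounding box — an open point resolved toward
the more faithful null). `n_boot` defaults to 1,000 and is configurable;
the bootstrap seed is part of the call.

## Zonal analysis

Regions arrive as polygons or as an integer label mask (mask wins when
both are given; a cell on a boundary belongs to the region containing its
centroid pixel). Interstitial cells are excluded as a region but retained
in every test's outside-region margin. Per (region, type, sample) a Fisher
test on in/out × type/other; aggregation demands a consistent log-odds
sign across all qualifying samples *and* the max-p Bonferroni rule, with
m = #regions × #types as its own family, separate from the pairwise
analyses (the shared-m alternative is a one-line configuration). Sample
log odds ratios use the Haldane–Anscombe 0.5 correction only when a cell
of the 2×2 is zero, so sign consistency is always defined. The two
descriptive matrices are row- (type across regions, pooled cells) and
column-normalized (region composition, averaged over the samples that
contain the region).

## Numerical and reproducibility choices

* All µm↔px conversion goes through `radius_in_pixels()` (truncation).
* Every stochastic stage takes an explicit seed; `with_seed()` isolates
  RNG state so library calls never perturb user streams. Identical
  (spec, seed) inputs give bit-identical samples, embeddings and labels.
* Output files written by `run_pipeline()`/`write_bundle()` carry a
  `.meta.yaml` sidecar with the config hash and seed.
* Degenerate inputs fail loudly and early (empty clusters, zero-variance
  markers, zero tissue area, unknown junk ids), with the failing stage
  named by `run_pipeline()`.

## Problem sizes in the test bench

The suite and the reproduction script run, by design, at desk scale:
cohorts of six samples with 1,200–4,200 cells each, 100–200 null cohorts
for calibration (reported rates are percentages of consensus decisions),
20–50 planted cohorts for recovery, clustering runs at 3,000–6,000 cells.
These sizes were chosen so each property is measured with useful precision
while a full run stays in the minutes range; they are simulation-design
choices, and anyone scaling them up should expect the same qualitative
behavior with tighter Monte-Carlo error.

## Known limitations

* The density-clustering stage is DBSCAN, not HDBSCAN: a single `eps`
  scale per run. On embeddings with strongly varying cluster density the
  noise bucket grows and `eps_factor` may need adjusting.
* The overlap null ignores border effects and within-type clumping of the
  background; it is conservative rather than exact.
* Cluster-to-type naming across samples is the caller's responsibility
  (`broad_map`, `type_map`); the package never invents a nomenclature.
* Per-cell positivity is mixture-based; for markers whose mixture is
  genuinely unimodal the positive call degenerates to "above the grand
  mean", which is the intended, documented behavior.
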