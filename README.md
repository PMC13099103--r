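# spatplex

Cell classification and spatial statistics for hyperplexed tissue imaging.

Cyclic immunofluorescence methods stain one tissue section with ~78 antibody
markers and segment it into millions of cells, each described by its centroid
(x, y, in pixels at 0.45 µm/pixel) and a mean 8-bit intensity per marker.
`spatplex` implements the downstream analysis such data needs, end to end, for
people studying tissue architecture (the motivating case is the human lymph
node): preprocessing that sharpens phenotype clusters, nested two-level
clustering into cell types, cluster-to-type marker profiling, and a set of
spatial statistics that ask which cell types sit next to which, how strongly,
and where in the tissue. A synthetic tissue generator with known ground truth
makes every stage testable without any imaging data.

## Methods at the core

**Lognormal shrinkage.** Per marker, a 1-D Gaussian mixture is fitted to
log(1 + intensity) with at most *G*<sub>i</sub> components (default 20; the
converged count *G*<sub>f</sub> ≤ *G*<sub>i</sub>). Each value *x* is assigned
to its maximum-responsibility component with mean µ<sub>k</sub> and contracted,

> x′ = µ<sub>k</sub> + (1 − λ)(x − µ<sub>k</sub>),  λ ∈ [0, 1] (default 0.8),

which pulls within-mode variation out before embedding and improves cluster
recovery (asserted on synthetic data in the test suite).

**Nested clustering.** UMAP embedding plus density clustering (DBSCAN with a
noise bucket: label −1 collects outliers) on a global panel; clusters are
mapped to broad types (B cells, T cells, …) by explicit supervision; each
broad type is then re-clustered on its own subpanel of markers. At the
subclass level −1 means "an average cell of that type", not junk. Artifact
clusters can be excluded by id; excluded cells leave every downstream
statistic but stay in the table.

**Cluster profiles.** Per cluster, a Welch *t*-test of each marker inside vs
outside the cluster (Bonferroni over markers) with a robust effect size
(median difference / pooled MAD); significant over-expressed markers are
ranked by decreasing effect. Types are then summarised by marker frequency
bands (significant in 70–100% / 50–69% / 30–49% of the type's clusters) and
by the markers whose median rank across clusters is 1st–5th.

**Neighborhood test.** For a focal type *i*, every other cell is *near* if it
lies within *r* of any *i* cell (r = 10 and 20 µm → 22 and 44 px). Fisher's
exact test on near/far × (type *j* / other); the enrichment is the ratio of
the proportion of *j* among near cells to the proportion among far cells
(20% vs 5% → 4). A pair is significant only if **every** sample at **both**
radii passes the Bonferroni-corrected threshold α/m (the max-p rule; m is
logged with every result).

**Overlap test.** Every cell projects an interaction disc of radius *r*;
discs are rasterized on the native pixel grid. With *A* the tissue area
(union of discs over all cells) and a<sub>i</sub> a type's covered area, the
pair statistic is the Jaccard index o<sub>ij</sub> = |a<sub>i</sub> ∩
a<sub>j</sub>| / |a<sub>i</sub> ∪ a<sub>j</sub>|, tested against
K ~ Binomial(min(n<sub>i</sub>, n<sub>j</sub>), max(a<sub>i</sub>,
a<sub>j</sub>)/A) via P[K > ⌊o<sub>ij</sub>·min(n<sub>i</sub>,
n<sub>j</sub>)⌋]. Same-type aggregation uses the double-coverage ratio with a
binomial/bootstrap null. Consensus follows the same max-p rule.

**Zones.** Per (region, type, sample) a Fisher test of in-region vs outside
(cells in no region are "interstitial": never a region themselves, always
part of the outside margin); enrichment calls require a consistent sign in
every sample plus the max-p Bonferroni rule, and two descriptive matrices
give each type's distribution across regions (rows sum to 100%) and each
region's composition (columns sum to 100%).

## Worked example

Six synthetic samples: a dense background population plus four sparse types,
with 80% of `T2` cells planted within 8 µm of `T1` cells.

```r
library(spatplex)

spec <- bench_background_spec()
cohort <- generate_cohort(spec, n_samples = 6, base_seed = 42)
cohort <- lapply(seq_along(cohort), function(i)
  plant_colocalization(cohort[[i]], "T1", "T2",
                       radius_um = 8, fraction = 0.8, seed = 100 + i))
names(cohort) <- sprintf("S%d", 1:6)

nb <- neighborhood_analysis(cohort, types = paste0("T", 1:4))
subset(nb$consensus, significant)
#>    i  j n_tests_used    max_p mean_log_ratio significant
#> 1 T2 T1           12 1.28e-40        1.97527        TRUE
#> 4 T1 T2           12 7.64e-70        2.85972        TRUE

ov <- overlap_analysis(cohort, types = paste0("T", 1:4))
subset(ov$consensus, significant)
#>    i  j n_tests_used    max_p significant
#> 1 T1 T2           12 1.52e-05        TRUE

median_nearest_distance(cohort$S1, "T1", "T2")
#> [1] 7.574816
```

Reading: the planted pair — and only the planted pair — survives the
consensus rule in both statistics, in both directions for the neighborhood
test (`mean_log_ratio` 2.86: near `T1` cells, `T2` is e^2.86 ≈ 17 times more
frequent than far from them; 12 tests = 6 samples × 2 radii all below
α/m = 0.05/12). The planted median nearest-neighbor distance, 7.6 µm, sits
inside the 8 µm planting radius.

The full pipeline (shrinkage → nested clustering → profiling → all spatial
statistics, with per-file provenance sidecars) runs through `run_pipeline()`;
a thin CLI over the same functions lives in `inst/cli/spatplex.R`.

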