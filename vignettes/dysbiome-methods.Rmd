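---
title: "Models and methods behind dysbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dysbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbiome)
```

`dysbiome` analyses two-group 16S rRNA gut microbiome cohorts — a test
group (for instance celiac patients on a gluten-free diet, labelled CD)
against healthy controls (HC) — from a filtered feature table to
group-level findings. This vignette explains the models, the parameters
that matter, the synthetic-data generator the test suite is built on,
and the numerical choices made where the design was genuinely open. It
states no empirical result that the package's tests do not themselves
compute.

## The data model

The central object is a `feature_table`: a taxa × samples matrix of
non-negative integer read counts, each taxon carrying a 7-rank
Greengenes-style lineage string. Counts stay integers through the whole
pipeline; operations that need proportions (`rel_abundance()`) take a
per-sample closure view that is never written back. Sample metadata is a
two-column tibble (`sample_id`, `group`) with exactly two group levels
for all two-group operations; phylogenetic metrics consume a rooted
`ape::phylo` tree whose leaves cover the table's taxa. Missing branch
lengths are set to 0 with a warning rather than rejected, since exported
trees occasionally omit root edges.

## Filtering and rarefaction

Contaminants are removed by case-insensitive lineage substring match
(defaults `"mitochondri"`, `"chloroplast"`). Ultra-rare taxa are removed
when **either** prevalence < 5 samples **or** total count < 20 reads.
The union reading treats the two clauses as two separately named removal
classes; both thresholds are strict, so a taxon in exactly 5 samples
with exactly 20 reads survives, and the operation is idempotent. An
intersection variant is available (`rule = "and"`).

Rarefaction subsamples each retained sample **without replacement**
(multivariate hypergeometric, via `vegan::rrarefy`) to exactly the
target depth — 10,000 reads by default — excluding and reporting
shallower samples. The hypergeometric choice matches the behaviour of
the standard 16S toolchains; the test suite verifies the marginal
expectation depth × count/total by Monte-Carlo. Stage order is fixed:
contaminants → ultra-rare → rarefy.

## Diversity

Shannon entropy and Pielou's evenness use log base 2 (the convention of
the standard 16S pipelines; `base` is a parameter). Faith's PD sums the
branch lengths of every edge with at least one observed descendant,
which includes the path to the root. Both UniFrac variants are computed
branch-wise from one shared primitive — an edge × tip incidence matrix
built by postorder accumulation:

* unweighted UniFrac = (branch length unique to one sample) / (branch
  length observed in either);
* weighted UniFrac = Σ bᵢ·|pᵢᴬ − pᵢᴮ| over edges, with pᵢ the relative
  abundance of the subtree below edge i — **unnormalized** by default,
  matching the common `weighted_unifrac` default; a normalized variant
  is a flag.

Both variants are validated against a brute-force per-branch oracle
(independent descendant enumeration) on hundreds of random trees with up
to 8 leaves, to 1e-9.

Group testing corrects by Benjamini–Hochberg **within the declared
family**: the alpha metrics form one family, the beta metrics another,
mirroring how such results are usually tabulated. PERMANOVA is delegated
to `vegan::adonis2` under a seeded permutation stream; its p-value
carries the +1 correction, so 999 permutations bound p below by 0.001.
PCoA uses classical (Gower-centred) scaling; negative eigenvalues are
reported but excluded from the proportion-explained denominator, with no
correction by default (Cailliez behind a flag) because corrections
change the visual geometry without changing the test decisions made
upstream.

## Compositional differential abundance

**ANCOM.** For every ordered taxon pair (i, j) the group difference of
log((cᵢ+1)/(cⱼ+1)) is tested with a Mann–Whitney test
(normal approximation with tie correction); p-values are BH-adjusted
within each taxon's family of m−1 tests and Wᵢ counts rejections at
α = 0.05. Detection uses the common 0.7·(m−1) heuristic; raw W is
always reported because detection thresholds are the least standardized
part of the method. Direction of enrichment is the sign of the mean CLR
difference.

**CLR-lasso** CLR-transforms pseudocounted, closed compositions and fits
an L1-penalized logistic model over the glmnet path, choosing the
smallest penalty yielding at most `max_taxa` (default 20) nonzero
coefficients — reading the "search for a maximum of 20 discriminant
taxa" instruction as a hard per-method cap. The reported score is a
cross-validated AUC at the chosen penalty.

**Coda-lasso** fits the log-contrast model: penalized logistic
regression on log-pseudocounted abundances with the zero-sum constraint
on coefficients. No packaged constrained-lasso solver fit this
environment, so the package ships a small accelerated proximal-gradient
solver whose proximal step — soft-thresholding restricted to the
zero-sum hyperplane — is solved exactly by locating the root of a
piecewise-linear function of the Lagrange multiplier. Coefficients
therefore sum to zero to machine precision. The path stops once the
support saturates (all features, or more than the cap).

**Selbal-style balance search** greedily builds a two-part balance
B = √(kₙk_d/(kₙ+k_d)) · (mean log numerator − mean log denominator),
initialized at the best cross-validated pair and grown while
cross-validated AUC improves, capped at `max_taxa` total taxa.
Candidate scoring uses the CV AUC of the univariate balance itself
(orientation learned on training folds, rank-based AUC on pooled
held-out scores): for a univariate monotone score this ranks candidates
identically to fitting per-fold logistic models and is far cheaper.
Ties break to the lowest taxon index, numerator side first, for
determinism. Because greedy search overfits on noise, a null cohort
typically stops well before the cap with a modest AUC, and the test
suite checks exactly that property over replicate null cohorts rather
than a single draw.

**Consensus** tallies which methods selected each taxon and its
direction, and can collapse taxa sharing a lineage prefix at a chosen
rank when counting distinct taxonomies — the rank is a parameter because
reported collapses rarely state it.

## ALDEx2-style effect sizes

For a pathway (or any feature) count table: each of `n_mc = 128`
Monte-Carlo instances draws per-sample compositions from
Dirichlet(counts + 0.5) and CLR-transforms them. Per instance,
min(n₁, n₂) random cross-group pairings give between-group differences;
within-group differences come from a cyclic shift of a per-group
permutation (never pairing a sample with itself), and the dispersion is
the pairing-wise maximum of the two groups' absolute differences. The
effect is the median of difference/dispersion over all instances and
pairings. The sign convention is second group level minus first, and is
declared in the result's attributes. All pairings derive from **one
global sample permutation per instance**, so swapping the group labels
mirrors the pairings exactly and the effect negates exactly — a
property the tests assert identically, not approximately. The 0.5 / 1 /
1.5 absolute-effect ladder gives nested feature lists.

## Dysbiosis against a healthy reference

**Median-distance test.** A test sample's statistic is its median
Bray–Curtis distance to all reference samples. The wording "the 90%
quantile of the distance distribution within the reference set" is
ambiguous between the pooled pairwise distribution and the distribution
of per-sample medians; the default uses the **leave-one-out median**
distribution so that cutoff and statistic are the same functional — by
construction ~10% of reference samples then exceed their own cutoff
(exactly 3 of 30 under type-7 interpolation with distinct values),
which the tests assert. The pooled variant is a flag. Quantiles are
linear (type-7).

**DOC.** For each sample pair, overlap O = ½ Σ_{i∈S}(xᵢ + yᵢ) over the
shared taxon set S, and dissimilarity D = the root Jensen–Shannon
divergence (natural log, so D ∈ [0, √log 2]) of the two compositions
renormalized over S. A LOWESS curve (span 0.3) summarizes the cloud;
the slope (linear fit) and Spearman correlation are computed within the
high-overlap region — pairs above the median overlap by default — and a
bootstrap over **samples** (not pairs, to respect pair dependence)
gives confidence bands. The region statistic is smoother-free, so the
choice of smoother is cosmetic.

**CLOUD.** For each of 100 random reference subsets of the chosen
fraction (5/15/30%; a fraction of 1 is a single deterministic draw),
the test sample's neighbourhood diameter is its mean distance to its k
nearest subset members, and r is that diameter divided by the mean
leave-one-out diameter of the subset members; the reported r averages
over draws. k defaults to max(3, ⌈0.05·n_ref⌉). The empirical p-value
is the +1-corrected fraction of reference samples whose own
leave-one-out r is at least the test sample's. Reference r scores
average ≈1 by construction.

## The synthetic cohort generator

The generator's defaults are the study conditions every statistical
test in the suite assumes:

* 46 test + 30 reference samples over 100 taxa;
* sparse overdispersed compositions from a Dirichlet-multinomial with a
  skewed gamma(0.35) concentration vector — the standard microbiome
  null; sparsity comes from small concentrations rather than structural
  zeros, keeping compositional operations well-defined after
  pseudocounting;
* per-sample read totals from a log-normal law with meanlog
  = log(16,841) and sdlog = log(23,273/13,210)/(2·Φ⁻¹(0.75)) ≈ 0.42,
  i.e. median ≈ 16.8k and quartiles ≈ 13.2k/23.3k, which places roughly
  one sample in ten below the 10,000-read rarefaction cutoff;
* planted group-differential taxa specified as (taxon, log2 fold-change,
  group); under the default concentration vector a planted taxon is
  first reset to the **median** background concentration, because a
  fold-change planted on a taxon whose drawn concentration is ~0 does
  not exist in the realized data and no method could (or should) detect
  it;
* planted dysbiotic outliers: a sample's composition is permuted across
  taxa and sharpened (weights raised to the power `strength`) before
  redrawing counts at the original depth.

The universality generator (`simulate_universal_dynamics()`) gives each
sample a uniformly random subset of taxa and log-normal noise around
one shared steady-state profile, with the noise scale proportional to
(n_taxa/k − 1): samples hosting nearly the whole community sit at the
shared attractor, samples missing many taxa deviate from it. That is a
deliberate, minimal emulation of the ecological mechanism behind the
dissimilarity–overlap signature; with universality off, every sample
gets an independent profile and constant noise, and the DOC flattens.
Counts are deterministic largest-remainder quantizations so that the
zero-noise case yields exactly zero dissimilarity. What these cohorts do
**not** emulate: real taxon co-occurrence structure, phylogenetic
signal in abundances, batch effects, and compositional correlations
beyond the Dirichlet's. Passing tests therefore demonstrate calibration
and power under a clean, standard null — not robustness to every
real-data pathology.

The pathway generator draws log-normal pathway abundances with
within-group log-sd 1 and plants CLR-scale shifts expressed in
within-group standard deviations; with 20 samples per group the
sampling noise of realized group means makes a small share of null
effects exceed 0.5 in magnitude, which is inherent to the effect-size
definition, not an artifact.

## Problem sizes and numerical choices

The test suite runs its statistical checks at the design points above:
500 replicate null cohorts for type-I calibration of Kruskal–Wallis and
PERMANOVA (band 0.05 ± 0.02, a two-sigma binomial band at 500
replicates), 50 replicates for planted-taxon power at m = 20 taxa and a
fixed 10,000-read depth, 200 random trees for the UniFrac oracle, 20
seeds for the DOC separation, and 20 replicates for effect-size
recovery. These sizes were chosen so that each check's sampling error
is small relative to its acceptance band while the whole suite stays
desk-scale.

Numerical conventions: pseudocount 1 before log-ratios (ANCOM and
selectors; 0.5 Dirichlet prior in the effect-size module, its reference
default); Mann–Whitney always uses the normal approximation for
determinism under ties; permutation p-values carry the +1 correction;
quantiles are type-7; the coda-lasso proximal step is exact and its
FISTA iterations stop at a 1e-5 coefficient-change tolerance; all
randomized operations take an explicit integer seed and restore the
caller's RNG state (`withr::with_seed`), and the pipeline derives
per-stage seeds from one global seed by fixed offsets, making the run
report byte-identical across reruns.

## Known limitations

* ANCOM's pairwise Mann–Whitney formulation costs O(m²) tests; beyond a
  few hundred taxa it becomes the slowest stage.
* The selbal score is the AUC of a balance selected on the same data;
  like the reference procedure, it is optimistically biased and should
  be read as a ranking device, not an unbiased performance estimate.
* The DOC bootstrap band resamples samples, which is conservative for
  small cohorts (< 20 samples).
* Weighted UniFrac is unnormalized by default and therefore not bounded
  by 1; comparisons across trees with different total branch length
  should use the normalized flag.
* The pipeline consumes a pathway count table as-is; inferring pathway
  content from 16S profiles is out of scope.
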