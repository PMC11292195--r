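---
title: "ecmnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecmnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmnet)
```

`ecmnet` analyses extracellular-matrix (matrisome) and integrin-adhesome
profiles of tumour proteome matrices: which proteins form coregulated
networks, how network activity relates to grade, subtype and survival,
and whether gene-set level scores (such as a proteoglycan score) carry
independent prognostic information. This vignette explains the
statistical machinery, the tunable parameters, and the choices made
where the design was genuinely open. Everything quantitative stated here
is computed by the package's test suite or by `scripts/acceptance.R`;
nothing is quoted from external sources.

## Input model

The central object is a plain numeric matrix of log2-normalised protein
intensities, proteins in rows, samples in columns, `NA` for missing
measurements. Statistical operations use observed values only; the
missing-data policies per operation are described below. Clinical data
travel as a data frame keyed by `sample_id` with survival endpoints as
`<label>_time` / `<label>_event` column pairs, where the label set is
closed (`OS`, `LRFS`, `MFS`, `DSS`) so that endpoint typos fail loudly.

## Annotation filtering

Matrisome and adhesome catalogs are tables of `gene, division,
category`. A gene listed in both a matrisome division and the adhesome
is resolved by the precedence matrisome > adhesome and keeps an
`in_adhesome` flag, so division counts partition the catalog while
adhesome composition breakdowns remain possible. Matching is exact and
case-sensitive by default (`ignore_case` opts into case folding); no
alias expansion is attempted, because alias maps depend on the catalog
release. The bundled `matrisome_adhesome_snapshot.csv` is a miniature
example snapshot (~115 genes with plausible assignments), not a copy of
any licensed catalog release; analyses of real data should supply the
user's own catalog export.

## Differential abundance

Group contrasts use Welch's t-test on observed log2 values, per
protein. A protein is "upregulated" at the default thresholds when its
Benjamini–Hochberg q-value is below 0.01 and its mean log2 difference is
at least 1 (fold change of 2 or more, inclusive at the boundary).
"Uniquely upregulated" means flagged in exactly one eligible group's
one-vs-rest contrast; eligibility defaults to groups with at least 20
samples. Proteins with fewer than half of values observed in either arm
(or fewer than two observations) are excluded and reported, because
their variance estimates are unstable. Welch rather than a pooled or
moderated test: log-intensity proteomics is plausibly normal after
normalisation, group variances differ in practice, and moderated
(empirical-Bayes) testing is an explicit non-goal.

Tumour-content robustness checks use Kruskal–Wallis per protein across
content strata plus one test of the per-sample global median; strata
with fewer than two samples merge into the adjacent stratum.

### SAM

The two-class SAM statistic is d = (mean_A − mean_B) / (s + s0) with
the pooled-variance standard error s and a fudge factor s0 that damps
the inflated d of low-variance proteins. `s0_strategy` offers `"median"`
(median of all s, the default: robust and assumption-light), `"zero"`
(plain t-like behaviour), and `"percentile"` (a coefficient-of-variation
scan over s percentiles). The null is built from group-label
permutations — enumerated exhaustively when there are at most
`n_permutations` distinct assignments (e.g. all 20 for 3 vs 3),
otherwise a seeded random subset. For each threshold delta on |d| the
estimated FDR is the median permutation exceedance count divided by the
observed count, clipped to [0, 1]. Exhaustive mode is deterministic;
subset mode is reproducible given the seed.

## Coregulated networks

Protein–protein similarity is pairwise-complete Pearson correlation.
Pairs with fewer than `min_pairs = 10` joint observations are masked —
below that, r estimates are too unstable to cluster on — and
zero-variance proteins are masked whole rather than propagating NaN.

Consensus clustering follows the Monti resampling scheme: in each of
`n_resamples` iterations (default 1000), 80% of items are drawn without
replacement and clustered by average-linkage hierarchical clustering —
on 1 − r distances for similarity input, Euclidean distances for
feature input — and the consensus matrix records how often each pair
co-clusters among its co-sampled iterations. Both input modes exist
because clustering the correlation matrix and clustering the raw
profiles are both defensible and give the user the choice.

### Choosing k

PAC (proportion of ambiguous clustering: off-diagonal consensus values
in (0.1, 0.9)) measures stability, but its plain minimum is degenerate
in a common case: when the structure at the true k is clean, a coarser
k often merges two whole clusters *consistently*, making PAC zero for
the coarse and the true k alike, and the minimum then lands on the
coarser k. The package therefore selects k in two steps: restrict to
"stable" k with PAC ≤ `pac_stable` (0.1); among those keep the k whose
relative gain in the area under the consensus-value CDF over k−1 is at
least `delta_min` (0.1) — the classical delta-area signal that the
finer partition explains genuinely more co-clustering — and choose the
largest such k. When no k is stable the PAC minimum is used as a
fallback and the result is flagged `no_stable_structure` whenever the
minimum PAC exceeds `stable_pac_max` (0.2). A `fixed_k` mode skips
selection for reproduction-style analyses. On 3-block synthetic
correlation data (3 × 60 proteins, within-block r ≈ 0.8, 120 samples)
this selects k = 3 with adjusted Rand index 1.0 in 10/10 seeds; for
exactly duplicated profiles any sub-split of a tie group is ill-posed,
and the k = 2 consensus values are exactly {0, 1} as forced by the ties.

In the end-to-end pipeline, network discovery is restricted to proteins
that have at least one correlate with |r| ≥ `min_abs_cor` (0.4).
Uncorrelated items are outliers under average linkage — each cut is
spent peeling off a noise singleton, and genuine programs merge — so
proteins that correlate with nothing are reported as unassigned rather
than forced into a network. At 300 samples the largest spurious |r|
among independent proteins is about 0.2, so the default separates
cleanly.

### Cluster significance

`sigclust()` tests a 2-cluster split against a single-Gaussian null:
the statistic is the 2-means cluster index (within-cluster sum of
squares over total), and the null simulates Gaussians with diagonal
covariance equal to the sample-covariance eigenvalues hard-thresholded
from below at a background variance estimated by the MAD of all
(median-centred) data values. Known limitation: because the null's
eigenvalues are estimated from the same data that produces the observed
index, the test is conservative — datasets that split easily also
generate stretchier nulls. Measured over 800 null replicates (300 items
× 2 features), rejection at nominal 5% is about 2.6%, and small
item-to-feature ratios are far more conservative. The test never
over-rejects in these checks, so a significant result is trustworthy;
borderline non-significance is not evidence of homogeneity. p-value
resolution is 1/`n_sim`; fewer than 100 simulations draw a warning.

Cluster activity per sample is the median of observed member-protein
abundances. Grade associations use two-sided Mann–Whitney tests (grade
2 vs 3, desmoid cases excluded, since that entity is not graded on the
same scale); subtype associations use Kruskal–Wallis with Dunn's
pairwise z-tests, BH-adjusted — BH because the Dunn stage is a
screening step, not a confirmatory family.

## Enrichment

`ssgsea()` implements the rank-weighted running-sum score: genes are
ranked by value, descending, ties broken by gene symbol for
determinism; rank weights are |r|^alpha with alpha = 0.75; the score is
the sum over ranks of the difference between the weighted in-set ECDF
and the unweighted out-set ECDF. Matrix scoring optionally normalises
by the *global* score range over all samples and sets. An earlier
per-sample range variant was rejected after it provably cancelled
between-group signal with two-set collections. Note the compositional
caveat of any rank-based score: strongly shifting one gene set in some
samples displaces the scores of other sets in those samples; the tests
demonstrate this on constructed data.

Overrepresentation uses the upper-tail hypergeometric distribution with
the universe defaulting to the quantified proteins, not the genome —
proteomics detection bias makes the genome universe anti-conservative.
Hallmark-style screens apply a one-way pooled-variance ANOVA to ssGSEA
scores across subgroups with BH correction at q < 0.05; scores computed
on the full, unfiltered matrix so that enrichment reflects the whole
measured proteome.

## Survival

Kaplan–Meier estimation, the log-rank test and Cox proportional-hazards
models delegate to the `survival` package (Efron tie handling by
default, Breslow selectable) behind this package's interface; the test
suite cross-checks them against independent oracles: a hand
product-limit computation, a direct O/E/hypergeometric-variance
tabulation, and a one-dimensional partial-likelihood grid search.
Refusals are explicit: constant covariates, more covariate terms than
events, negative times; perfect separation is reported per-term as
non-estimable rather than returned as a finite estimate. Wald 95%
intervals are exp(coef ± 1.96 se).

Score stratification uses inclusive cutoffs (score ≤ cutoff goes low)
for both the median and the tertile rule, so ties at the cutoff are
assigned deterministically; `combine_upper` merges the intermediate and
high tertiles to express lowest-tertile-versus-rest contrasts. The
choice of ≤ at the boundary is a convention; it is configurable at the
data level by nudging scores, and recorded in the returned cutoffs so
an assignment can always be reproduced.

## Gene-set prognostic screening

`prognostic_screen()` is a two-stage filter. Stage 1 scores every set
per patient (observed-member median by default; ssGSEA as the
orthogonal rule), splits the cohort at the median score, and runs a
log-rank test per endpoint; a set passes if any endpoint gives p <
0.05. Raw p-values are used at stage 1 by design — the screen is a
filter, not a confirmatory family — with a BH option for stricter use.
Stage 2 refits each passing set × endpoint as a multivariable Cox model
containing the high/low stratum indicator plus clinical covariates, by
default preselected by univariable significance (p < 0.05) per
endpoint; rare factor levels (< 5 cases) are lumped into "other" before
fitting because singleton levels produce monotone likelihoods. A set is
retained when its stratum term stays significant in the adjusted model.
Endpoints missing for more than 20% of samples are skipped with a
warning.

On synthetic cohorts (n = 300) where the hazard depends on one latent
program (log-HR −0.7 per SD), the program-tracking set is retained in
100/100 simulations with the protective direction (high-stratum HR < 1),
and background decoy sets are retained in ≤ 10% (measured 4%) — the
decoy simulations screen the causal endpoint only, since each
additional screened endpoint multiplies a null set's family-wise
stage-1 pass rate by roughly (1 − alpha)⁻¹.

## Migration metrics

A track is an ordered series of (t minutes, x µm, y µm). Total distance
is the sum of consecutive Euclidean steps (gaps bridged by straight
segments, the usual tracker convention), net distance the start-to-end
displacement, directionality index DI = net/total ∈ [0, 1] (defined as 0
for a motionless track), and speed = total distance / elapsed time —
the path-length definition rather than mean frame displacement, because
it is invariant to dropped frames on irregular sampling. DI is invariant
to rigid motions and speed scales linearly with spatial units; both are
property-tested. Condition comparisons use Mann–Whitney for two
conditions and Kruskal–Wallis plus BH-adjusted Dunn tests otherwise,
with tracks pooled across experiments and conditions under 3 tracks
excluded.

## IHC scoring

H-score bins per-cell DAB optical densities at 0.14 / 0.18 / 0.23 OD
with intervals closed on the left (a cell exactly at a cutpoint takes
the higher bin — a deterministic convention, since only the cutpoints
themselves are given) and computes 100·(weak + 2·moderate + 3·strong).
Positive-pixel fractions use an inclusive 0.15 OD threshold. TIL
densities divide each replicate count by its section-preservation
fraction, exclude replicates under 50% preservation, average, and
multiply by the area-normalisation constant 1.274 (treated as an opaque
protocol constant, configurable per marker panel). Per-case mean scores
are clustered into low/intermediate/high groups by a univariate
three-component Gaussian mixture with unequal variances fitted with
`mclust` — the established tool for this step — whose model-based
hierarchical initialisation makes the fit deterministic for a given
dataset; recovery of means {50, 150, 250} (sd 10, n = 300) is within
±5 with >95% assignment accuracy.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not mass-spectrometry physics. Each expression program is a
single-factor block: per-sample activity a ~ N(µ_subtype + µ_grade, 1);
a member protein is offset + √ρ·a + √(1−ρ)·ε with protein offsets
N(25, 2) on the log2 scale, so the within-block correlation converges
to ρ (checked at n = 1000 within ±0.02). Background proteins are
i.i.d. noise. Defaults mirror a realistic sarcoma cohort: 300 samples;
11 subtypes at proportions LMS 0.25, UPS 0.17, SS 0.13, DDLPS 0.12,
DES 0.12, AS 0.09, ES 0.05, RT 0.04 and 1% each for the three rare
entities; grades 2/3/unknown at 35.8/43.3/20.9%; three programs of 60
proteins at ρ = 0.8 (a grade-linked proteoglycan-like program, an
LMS-shifted basement-membrane-like program, a UPS-shifted
protease-like program) plus 120 background proteins; 10% missing at
random. Survival is exponential with baseline hazard 0.02/month,
log-HR −0.7 per SD of the proteoglycan-like program's activity, and
independent exponential censoring at 0.005/month (roughly 20%
censoring); the same hazard model generates OS, LRFS and MFS
independently. Exponential rather than Weibull keeps hazard-ratio
recovery analytically checkable; the generator's truth record (latent
activities, standardised driver, memberships) suffices to compute every
recovery metric without hidden state.

What the generator does *not* emulate: intensity-dependent missingness,
batch structure, heavy-tailed measurement error, between-program
correlation, and non-proportional hazards. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to those real-data phenomena.

Tracks come from a persistent random walk: headings evolve by
wrapped-normal increments with standard deviation 1/√κ (κ = ∞ gives
straight lines with DI exactly 1; κ = 0 redraws a uniform heading each
step, the diffusive regime with mean DI below 0.3 at 36 steps), step
lengths are Rayleigh(σ), and doubling σ doubles speed while leaving the
DI distribution unchanged. IHC tables draw per-cell ODs from lognormal
mixtures.

## Pipeline and reproducibility

`run_full_analysis()` executes acquisition → annotation filtering →
subtype-unique differential expression → networks → prognostic screen →
survival tables from one configuration (list or YAML), with every
source of randomness derived from a single seed. Stage results are
cached under `out_dir/cache`, keyed by content hashes of their inputs:
reruns with unchanged inputs skip completed stages, a changed seed
invalidates everything downstream, and a cache file that does not match
its manifest hash stops the run with a provenance error instead of
silently recomputing or reusing corrupt state. Repeated runs with the
same seed are byte-identical across output files.

## Problem sizes used by the checks

The acceptance checks run at sizes chosen to finish comfortably on one
CPU while keeping each statistical claim meaningful: oracle comparisons
at 100 random profiles (ssGSEA), all hypergeometric configurations to
universe 30, 1000 BH vectors, ten 20-subject Cox toys; type-I checks at
200 replicates each (null binomial band [4, 16] at α = 0.05); recovery
at 10 consensus seeds (180 proteins × 120 samples, 100 resamples), 100
Cox cohorts of n = 300, and 100 screening cohorts of n = 300; the
end-to-end run at the full default cohort with 150 consensus resamples.

## Known limitations

- The SigClust variant is conservative under the null (measured above);
  use it to confirm splits, not to certify homogeneity.
- Rank-based enrichment scores are compositional across sets within a
  sample.
- Consensus k-selection cannot distinguish nested partitions of exact
  tie groups; such data are reported at the coarser stable k via the
  duplicate-collapse behaviour of the resampling, and `fixed_k` exists
  for reproduction runs.
- The screen's stage-1 raw-p design controls nothing family-wise by
  default; that is intentional for a filter, and the BH option exists
  when the screened collection is large.
- The survival module fits proportional hazards without diagnostics;
  time-varying effects and competing risks are out of scope.
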