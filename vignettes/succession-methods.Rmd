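---
title: "Models and design choices in microsucc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in microsucc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

microsucc analyses longitudinal 16S OTU tables from birth-cohort designs:
the same animals sampled densely from day 0 to adulthood, with per-sample
metadata (animal, day of life, diet period, delivery mode). This vignette
records the statistical models, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the methodology was genuinely open and a choice had to be made.

## Presence, prevalence and the core

Every occupancy statistic uses one presence convention: an OTU is present
in a sample when its (by default rarefied) count is ≥ 1. Core membership
collapses samples by animal first — presence in an animal means presence
in at least one of its samples — and then applies an inclusive prevalence
threshold (default 0.8: "at least 80 % of animals"). Because occupancy
depends on sequencing depth, the default workflow rarefies to a common
depth (10,000 reads) before any presence-based statistic; both rarefied
and raw tables are accepted, as the literature is usually silent on which
was used.

Rarefaction is subsampling **without replacement** (`vegan::rrarefy`)
with an explicit seed; samples below the target depth cannot be rarefied
and are dropped with a warning rather than silently kept at lower depth.

## Time bins

Sampling in such designs is front-loaded (daily in week one, then weekly,
then monthly), so fixed-width bins would leave late bins nearly empty.
`assign_time_bins` builds equal-frequency bins over the pooled sampling
days: ties (all samples taken on the same day) never straddle an edge, the
largest guaranteed minimum occupancy is found by binary search, edges are
placed greedily at each bin's fair share of the remaining samples subject
to tail feasibility, and a local boundary polish maximises the minimum
occupancy, then minimises the maximum. Bins are half-open `[lo, hi)`
intervals indexed from 0; bin assignment is a pure, monotone function of
day of life, and the edges are emitted to the run log so a binning is
always reproducible. Explicit edges can be supplied instead (the original
studies used a fixed 58-bin mapfile that is not generally available).

## Permutation tests

All permutation p-values use the add-one estimator `p = (b + 1)/(B + 1)`,
so they live on the grid `{1/(B+1), …, 1}` and are never zero. Specifics:

* **Diet breadth** shuffles each OTU's presence vector across samples
  independently (the row-wise reading of the classic procedure),
  preserving occupancy while randomising time and diet. "Most diets"
  means a strict majority of the diet codes present in the table.
* **First appearance** draws `|core|` OTUs from the non-core pool and
  compares mean pooled first-presence days; the lower tail is the
  interesting one (core arriving early).
* **Arrival rate** shuffles the sample-to-bin labels and refits the OLS
  slope of per-bin new-OTU counts on the bin index. The regressor is the
  bin index by default (`regressor = "midpoint"` uses the mean day per
  bin; the sources do not say which was used). The two-sided p counts
  permutations at least as far from the null mean as the observed slope.
* **Persistence ratio** permutes the day-of-life labels across samples
  globally and recomputes each OTU's span; a `within_animal` mode is
  provided for sensitivity analysis. OTUs seen in a single sample have no
  defined ratio and are excluded.
* **IndVal** permutes group labels at the **animal** level by default:
  samples of one animal are not exchangeable, so moving whole animals is
  the defensible unit. `level = "sample"` reproduces the literal classic
  behaviour, and `exact = TRUE` enumerates all label assignments (used
  when groups are small enough, e.g. 4+4 samples → 70 assignments),
  making the p-value exact rather than Monte-Carlo.
* **PERMANOVA** is vegan's `adonis2` with sequential (Type-I) sums of
  squares in the order given (age, diet, age×diet by convention here).
  Age enters as the numeric bin index rather than a 58-level factor:
  with diet being a step function of age, a saturated age factor would
  alias the diet term completely. An optional `blocks` argument permutes
  whole animals (via `permute::Plots`) because repeated measures violate
  exchangeability; the default is unrestricted, matching common practice.

## Persistence

Persistence is `Δ = last − first` observed day, pooled across animals
("first appearance in any animal"), since that is the only reading under
which a cohort-level curve is defined; a per-animal mode exists in
`build_arrival_table`'s per-animal matrices. The observation window
(default 600 days) is applied as a cap `min(Δ, 600)` rather than an
exclusion — a window within which appearance was "measured" — and OTUs
first appearing after day 430 are discarded because late time points are
sampled too sparsely to estimate a span. The stringency sweep
(`min_samples` ∈ {5, 10, 20, 30}) drops OTUs seen in few samples.

## Centre of mass

The COM of an OTU is its abundance-weighted mean sampling day,
`Σ RA_t·Day_t / Σ RA_t`. The legacy formula printed in parts of the
literature divides by `Σ Day_t` instead; that quantity is not a day (a
single observation at day 10 with abundance 0.5 has "COM" 0.5) and is not
shift-equivariant. Both variants are computed everywhere (`com_weighted`,
`com_printed`); the weighted mean is the default for inference and the
as-printed variant is emitted for literal replication. The weighted mean
is shift-equivariant, invariant to rescaling abundances, and always lies
inside the observed day range — these are tested properties. The K-means
shift analysis uses seeded multi-restart `stats::kmeans` (best inertia
kept) and an unpaired two-sided Welch t-test; identical COM vectors short-
circuit to `t = 0, p = 1` because the Welch statistic is undefined there.

## The temporal mixed model

For focal taxon `j` the model is

```
y_t = β₀ + Σ_{k=1..p} α_k y_{t−k} + g + ε,
g ~ N(0, σ²_g K),  ε ~ N(0, σ²_e I)
```

where `y` is relative abundance and `K` is the temporal kinship: each
sample's feature vector is the column-standardised concatenation of its
animal's quantile-binned community state (deciles by default; zeros in
bin 0) at the previous `q` time points, `K = FFᵀ/m` rescaled to unit mean
diagonal. The focal taxon is excluded from its own kinship features, an
intercept is always included, and only taxa with ≥ 10 % prevalence are
fitted. Variance components come from REML profiled over
`δ = σ²_e/σ²_g`, optimised in 1-D after one eigendecomposition of `K`
(the EMMA trick); a coarse grid over `log δ ∈ [−12, 12]` brackets the
optimum before `optimize`. Numerical guards: eigenvalues are clamped at
zero; rank-deficient fixed effects are dropped by pivoted QR; an
(essentially) noise-free fit short-circuits to OLS with `σ²_g = 0` to
avoid a degenerate likelihood.

Each animal's model rows are split sequentially into thirds: candidates
(default `(p,q) ∈ {(1,1),(1,2),(2,1),(2,2)}`) are fitted on the training
third, selected by out-of-sample Pearson correlation on the validation
third (ties, within 10⁻⁶, go to the earliest — most parsimonious —
candidate), refitted on train+validation, and scored on the test third by
best linear unbiased prediction conditioned on the train+validation
observations; lagged fixed effects use the actual earlier observations,
so no prediction sees its own future (a tested property).

**Calling rule.** The sources report autoregressive taxa against a
random-predictor-set baseline but leave the per-taxon rule unstated. The
choice here: at each null iteration a random focal taxon is drawn, its
series permuted within animal (destroying temporal structure while
keeping the marginal distribution and the overfitting geometry), and the
default model fitted with a kinship built from `set_size` random
predictor taxa. A taxon is called autoregressive when its observed test
correlation exceeds the null's 95th percentile (`threshold` exposed).

## Sequencing-error QC

Errors per read are Poisson with `λ = rate × read_length` (defaults
0.0024 and 250 nt). `poisson_error_prob` reports `P(X ≥ d)` and the
per-sample scaling `min(1, P × read_length)`; `repeated_error_prob(k)` is
`rate^k`, the probability the same single-nucleotide error recurs in `k`
samples. Without raw sequences the minor/major split cannot use edit
distance; minors are OTUs whose table-wide total is below 1 % of their
dominant co-occurring OTU (the count-ratio proxy). The error null for an
OTU's total count is Poisson with mean
`parent_total × p_div / ((1 − p_div) × children)` where
`p_div = 1 − (1 − rate)^read_length` is the per-read any-error
probability and `children` the number of error variants a parent can
spawn; the `(1 − p_div)` factor corrects for the parent's own observed
depletion. OTUs that fail to reject this null after BH (or Bonferroni)
adjustment are flagged as possibly spurious. Note the flip side: genuinely
rare taxa with totals below the error-expectation scale cannot reject and
will be flagged — the screen bounds what the data can rule out, it does
not certify taxa as artefacts.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort` plants the design its statistics assume: 45 animals
(18 C-section), sampled daily over days 0–7, twice to day 15, weekly to
day 220 and monthly to day 830, with a third of the cohort followed for
the full period and the rest to day 240, ~20 % of visits missed, and
weekly/monthly days jittered by a few days (real sampling is never
grid-aligned; this also makes equal-frequency binning meaningful). This
yields ≈ 1,650 samples. Read depths are negative binomial (mean 33,000,
size 3, matching a heavily overdispersed amplicon run); rarefaction to
10,000 then drops a realistic tail of shallow samples.

Abundances follow a log-space latent process per OTU — baseline + diet
offset + age trend + delivery offset + a stochastic term that is AR(1)
with a lagged community-score term for the planted autoregressive taxa —
pushed through a softmax over the OTUs present and realised by one
multinomial draw per sample. Presence is governed by planted arrival days
and dwell times: core taxa arrive within days 0–140 (exponential, mean
8 d, so mass on days 0–10) in every animal and reside for life (so their
persistence saturates any observation window); non-core taxa invade the
shared environment at a cohort-level epoch (uniform over the study) and
colonise each animal with probability 0.3 after a short exponential lag,
residing ~200 days. Dwell is a per-OTU species trait — one draw shared
across animals — because pooled first-to-last spans would otherwise be
dominated by the maximum of many independent dwells. The community score
driving AR taxa is computed from the **non-AR** core taxa so the coupled
latent system cannot feed back on itself and diverge. Delivery effects
are a log-abundance offset in the associated mode plus a group-restricted
colonisation pool, and C-section dynamics are advanced by 30 days
(arrivals and age trends), planting the earlier-arrival/lower-COM
signature. Effect sizes are config-exposed choices made once for
well-powered recovery tests, not estimates of any real cohort.

Not emulated: phylogenetic structure (taxonomy strings are decorative),
strain-level variation, chimeras, batch effects, true compositional
interactions beyond the single community score, and any fit to real
deposited data. A green recovery test therefore establishes that the
statistics detect the signals they claim to detect at realistic size and
noise — not that any biological effect size is correct.

## Degenerate inputs and tie-breaks

* Zero-total samples error in `to_relative_abundance` and
  `bray_curtis_matrix`; zero-total OTUs are dropped (with a warning in
  `indval`).
* `pcoa` drops negative-eigenvalue axes and errors when more axes are
  requested than positive eigenvalues exist.
* Pielou evenness is `NA` at richness < 2; dispersion is `NA` for groups
  of one sample.
* Kernel densities are renormalised on their reported grid (R's FFT
  evaluation is only ~10⁻⁴ accurate); bandwidth is Silverman's rule on
  the count-expanded day values.
* `balance_cohorts` breaks ties between equally good animal picks with
  the supplied seed.
* Spearman ordering tests use the tie-corrected asymptotic p
  (`exact = FALSE`); constant vectors error.

## Limitations

The PERMANOVA F statistics, IndVal counts and autoregressive totals of
any real cohort depend on that cohort's depth and design and are not
reproduced here; the package's claims are about the correctness and
calibration of the procedures (type-I error of the PERMANOVA wrapper,
exactness of the IndVal enumeration, recovery of planted core/AR/dwell
structure), which is what the test suite computes. The MTV-LMM here is an
independent implementation of the model class, not a numerical clone of
any released software. Runtime scales with `n_perm × cost(statistic)`;
the defaults in `pipeline_config` are desk-scale and should be raised for
production analyses.
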