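---
title: "Quantifying assembly kinetics from pulse-labeled affinity pulldowns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying assembly kinetics from pulse-labeled affinity pulldowns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karma)
library(dplyr)
```

## The measurement and its logic

KARMA (kinetic analysis of incorporation rates in macromolecular assemblies)
infers the order in which subunits join a large complex from the *age* of the
protein copies that co-purify with an affinity-tagged bait. A growing culture
is switched to medium containing heavy lysine at time 0; every protein made
after the switch carries the heavy label. At a series of post-labeling time
points (here 30, 60 and 90 min, three biological replicates, plus a time-0
control taken just before the switch), complexes are affinity purified and
quantified by DIA mass spectrometry at the fragment-ion level in both
channels. The fractional labeling of a precursor,

$$\mathrm{FL} = \frac{H}{H + L},$$

is the heavy share of its summed fragment intensities and proxies the mean
age of the purified population: a bait that binds only newly made assemblies
pulls down subunits with FL far above the bulk of the proteome, whereas
subunits that join after the bait has left show delayed labeling.

Nuclear transport receptors serve as the in-assay reference for bulk protein:
their pore interactions are fast and unselective with respect to age, so
their labeling follows pure growth dilution, $1 - 2^{-t/T_d}$ for doubling
time $T_d$ (`bulk_labeling()`).

## The labeling-quantification cascade

`quantify_labeling()` chains four stages, each exported on its own:

1. **Fragment filters** (`filter_fragments()`): quality-flagged rows are
   dropped, then only proteotypic y-type fragment ions with exactly one
   lysine that were found in both channels are retained. Only lysine-bearing
   y ions discriminate heavy from light peptides under lysine-only labeling,
   and a single lysine makes the mass offset unambiguous. "Found in both
   channels" is evaluated over the whole experiment by default — a fragment
   is kept when it has any detection in each channel anywhere — because the
   criterion describes library-level retention; the stricter per-sample
   reading is available as `both_channels = "per_sample"`. Detection always
   means intensity strictly above the detection threshold (default 0), and
   empty cells are read as intensity 0.
2. **Precursor aggregation** (`aggregate_precursors()`): fragment
   intensities are summed per precursor, sample and channel (`sum_all`).
   The targeted-acquisition convention of summing only the 3 most intense
   fragments per channel is available as `top3`.
3. **Presence filter** (`presence_filter()`): a precursor must be detected
   in at least `min_reps` replicates at *every* post-labeling time point
   (default 2 of 3; the relaxed `min_reps = 1` variant suits degron time
   courses where depletion thins coverage). Time-0 samples never enter the
   criterion.
4. **Protein summary with RMSE pruning** (`protein_labeling()`): per sample
   the median FL over the protein's precursors is computed (pass 1); each
   precursor is scored by the root-mean-square deviation of its FL from
   those medians across the post-labeling samples where it has a value (no
   imputation — imputing zeros for missing samples would bias the score);
   the `floor(n * discard_fraction)` precursors with the highest RMSE
   (default: the worst half) are discarded and the per-sample median over
   the survivors is the protein trajectory. One prune pass is performed;
   the pass-1 medians are not recomputed iteratively, matching the
   procedure's narrative description. With an odd precursor count the floor
   rule retains the larger half. RMSE ties are broken by retaining the more
   intense precursor (summed H+L over post-labeling samples), then by
   lexicographic precursor id, so results are deterministic.

Two conventions were genuinely open and are fixed as follows. Replicates are
aggregated by the median per protein, condition and time point before bait
normalization (`normalize_to_bait()`), reflecting how such trajectories are
usually reported. The manual, blinded exclusion of visibly noisy
trajectories that human analysts perform is not implementable as such; an
optional automated surrogate (`trajectory_noise_filter()`, a threshold on
the maximum within-time-point replicate SD) is provided but off by default,
and logs what it removes when enabled.

`treatment_ratio()` compares two arms (e.g. degron induction versus solvent
control) by pairing replicates and time points, reporting the per-protein
mean ratio ± SEM with the pair count; pairs with zero control labeling are
dropped with a warning, and a single surviving pair yields a missing SEM
rather than a fabricated one.

## Label-free tier enrichment

The screen that surfaces transient assembly factors compares a protein's
abundance in pulldowns of early-tier baits against late-tier baits.
`lf_precursor_intensities()` keeps proteotypic, unflagged precursors and
sums their fragments; `median_normalize()` divides by each sample's median
over detected precursors and rescales by the grand median of the sample
medians — after the transform all sample medians are equal while the data
keep their original intensity scale, so absolute thresholds stay meaningful.
`top3_protein_intensity()` averages the 3 most intense detected precursors
per sample, requiring at least 3 (precursors not found in all replicates of
a bait are omitted first; a variant requires completeness across all baits).
`tier_enrichment()` then takes replicate medians per bait and reports

$$\mathrm{fold} = \frac{\mathrm{median}_{\text{early baits}}}{\mathrm{median}_{\text{late baits}}}.$$

A protein never detected with any late-tier bait cannot be ranked by a
finite fold; it is reported as `Inf` with an `absent_in_late` flag rather
than silently dropped. Known complex members and transport receptors can be
flagged out of the ranking via `exclude_ids` (a user-supplied list, not
hard-coded gene names). The method ranks; it does not test — no p-values are
attached.

## Lysate intermixing

Mixing a heavy-grown untagged lysate with a light-grown tagged lysate before
purification measures how much bait-bound subunits exchange during the
procedure. `intermixing_extent()` reuses the labeling cascade with two extra
filters suited to the low signal of this end-point assay: precursors with
summed H+L below 100 (configurable; the channel scope of the published
threshold is unstated, so the channel-summed reading is used) are treated as
undetected, and only proteins with more than three precursor ions are
considered. Each subunit's FL is normalized to the mean FL of all
co-purified proteins outside the subunit set (the bait itself can be
excluded via `exclude_from_reference`; whether the published reference
includes the bait is unstated, and it is excluded here by default). A
subunit with no heavy signal at all cannot pass the both-channels filter;
that is the no-exchange case and is reported as extent 0 rather than
dropped.

## The three-state kinetic state model

The inaccessible-pool statistic asks: what share of a subunit's cellular
copies can the bait not capture? The forward model used here is a linear
compartment chain at steady-state abundances in an exponentially growing
culture (dilution $\mu = \ln 2 / T_d$, no degradation — turnover in budding
yeast is growth-dominated):

$$\text{free} \xrightarrow{k_a} \text{accessible} \xrightarrow{k_m}
\text{inaccessible},$$

with all synthesis heavy after $t = 0$. Writing $a = k_a + \mu$ and
$b = k_m + \mu$, the labeled share of the bait-visible (accessible) pool is

$$\mathrm{FL}_{\mathrm{AP}}(t) = 1 - \frac{a e^{-bt} - b e^{-at}}{a - b},$$

with the limit $1 - (1 + at)e^{-at}$ as $b \to a$, and the steady-state
share of the assembled pool beyond the bait's reach is

$$\varphi = \frac{k_m}{k_m + \mu}.$$

The exact published variant of this model lives in external material not
bundled with the article text, so the package defines its own concrete
parameterization and exposes it behind `ksm_params()` / `ksm_forward()`;
a different variant can be swapped in without touching the fitting code.
Faster maturation out of reach ($k_m$ up) makes the accessible pool younger
and its labeling faster at every $t > 0$ — the model's expression of the
observation that assembly-factor pulldowns label faster than bulk. A
capture weight for the free state (`w_free`, default 0) covers baits that
also pull down unassembled subunits.

The closed form is verified in the test suite against an independent
Runge–Kutta integration of the same ODE system (deSolve) to $10^{-8}$ on
random parameter draws.

**Fitting and identifiability.** `fit_inaccessible_pool()` minimizes squared
error over $(k_a, k_m)$ with bounded Levenberg–Marquardt (minpack.lm) from
10 multistarts drawn deterministically from the seed. The forward curve is
invariant under exchanging $a$ and $b$, so the pair is only identifiable up
to that swap; the fit is restricted to the $k_a \ge k_m$ branch (entry into
bait reach at least as fast as maturation out of it), which is the
physically sensible branch for assemblies probed on sub-doubling-time
grids and makes $\varphi$ unique. Non-convergence is reported through a
flag, never as an exception. Because $\varphi \ge 0$ sits on a boundary,
noisy data inflate near-zero estimates one-sidedly: with FL noise of 0.02
the null case averages $\hat\varphi \approx 0.03$–0.04 rather than 0. This
is a property of any bounded least-squares estimator, not of the
implementation; noiseless null trajectories are recovered at exactly 0, and
the recovery study in the test suite (truth 0–0.6, noise sd 0.02, 3
replicates, 20 seeds) stays within ±0.1 of the truth in the mean.

Default doubling time is 120 min, typical for budding yeast in synthetic
medium; it is an input, measured per strain, not a fitted quantity by
default.

## Fluorescence statistics

- `frap_normalize()` computes $(I_{bl} - I_{bg}) / (I_{total} - I_{bg})$
  per frame and rescales the mean pre-bleach level to 1. The anchor is not
  part of the published normalization but makes the mobile-fraction
  definition well posed; it is applied uniformly and documented in the
  output.
- `fit_frap_recovery()` fits $y(t) = y_0 + A(1 - 2^{-t/\tau_{1/2}})$ — a
  single-exponential recovery in half-time parameterization, the simplest
  model consistent with reported half-times — and derives the mobile
  fraction $(y_0 + A - y_{bleach})/(y_{pre} - y_{bleach})$ clipped to
  $[0, 1]$.
- `profile_sd_filter()` excludes envelope intensity profiles whose sample
  standard deviation (the $n-1$ denominator reading of "standard
  variation") exceeds 200 a.u., removing contours dominated by bright foci.
- `profile_pearson()` is the sample Pearson correlation between two channel
  profiles; constant profiles raise an error because the coefficient is
  undefined there. Manual exclusion of cells with strong background cannot
  be emulated and is not.
- `fit_profile_peak_distances()` measures membrane spacings: local maxima
  seed Gaussian least-squares refinements in windows of ±3 initial sigmas
  (sigma seeded from the half-max width); when windows overlap the peaks
  are refined jointly as a multi-Gaussian model with shared baseline.
  Centers are unbiased on symmetric noiseless peaks to solver tolerance.

## What the simulators emulate — and what they do not

`simulate_karma_dataset()` reproduces the data *structure* the analyses
assume: the 0/30/60/90-min grid with three replicates; per-class labeling
kinetics (an early-tier class with $\varphi = 0.4$ and fast assembly, an
intermediate class, a slow late class, bulk-like transport-receptor and
background classes); a deterministic fragment intensity ladder per
precursor; independent multiplicative log-normal noise per fragment and
channel (log-sd `noise_sigma`, median 1 — the standard heavy-tailed model
for MS intensities; median-1 noise pairs naturally with the pipeline's
median-based summaries, which are then centred on the truth); Bernoulli
missingness per fragment and sample; and decoy fragments (non-proteotypic,
b-series, two-lysine, quality-flagged, heavy-only) carrying deliberately
corrupted labeling so that a missing filter produces a wrong number, not a
silent pass. Heavy-label incorporation is assumed complete (lysine-only
labeling). `simulate_labelfree_dataset()` adds a designed early:late
abundance factor for an assembly-factor protein over a constant background;
`simulate_intermixing_dataset()` ties subunit labeling to
`mixing_fraction × heavy share`; `simulate_frap_trace()` renders the
recovery model back to raw intensities with Gaussian frame noise.

Real DIA data differ in ways the simulators deliberately do not model:
missingness is intensity-dependent rather than independent (an optional
logistic link would be the extension point), interference and co-elution
corrupt fragment intensities non-multiplicatively, protein inference is not
one-to-one, and labeling chases have arginine-conversion-style artifacts
under other labeling schemes. Passing recovery tests therefore validates
the *computations* under the stated generative assumptions — not the
upstream extraction, nor robustness to structured interference.

## Numerical and reproducibility choices

- All nonlinear fits use bounded Levenberg–Marquardt (minpack.lm) with
  `ftol`/`ptol` near machine precision and fixed, seed-derived starts;
  fits are bitwise reproducible given the seed.
- Exported functions that draw random numbers restore the caller's RNG
  state.
- The orchestrator (`karma_run()`) expands one run seed into per-stage
  seeds by a fixed counter (`seed + 1000 × stage index`), so any stage can
  be reproduced in isolation; reruns are byte-identical and manifests
  record config, seed, stage counts and output checksums.
- Degenerate inputs have defined behaviour rather than NaNs: FL is missing
  when $H + L = 0$; a single precursor survives pruning (floor rule); a
  flat FRAP trace yields mobile fraction 0 with a convergence flag; ties
  in RMSE and in peak ordering are broken deterministically.
- Test problem sizes: oracle equivalence uses 100 random instances of at
  most 5 proteins × 6 precursors × 9 samples; Monte-Carlo recovery studies
  use 10–20 seeds at the study's replicate counts. These sizes give
  standard errors well below the asserted tolerances while keeping the
  default suite fast.

## Known limitations

- The kinetic model is this package's concrete stand-in for the published
  three-state formulation; parameter *recovery* on its own forward
  simulations is the validated surface, not numerical agreement with
  published per-protein estimates.
- $\hat\varphi$ near 0 is upward-biased under noise (boundary effect,
  quantified above).
- The intermixing statistic is a single end-point extent; exchange kinetics
  over incubation time are out of scope.
- Protein inference, identification FDR and spectral extraction are
  upstream of this package and assumed done.
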