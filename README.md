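# karma

Quantitative analysis of **K**inetic **A**nalysis of incorporation **R**ates
in **M**acromolecular **A**ssemblies (KARMA) experiments: pulse-SILAC
metabolic labeling combined with affinity-purification mass spectrometry to
infer the order in which subunits join a large complex — and whether a bait
sees all of a subunit's cellular pool — from the *age* of the protein copies
it pulls down.

The package is aimed at proteomics analysts working with fragment-level DIA
exports of heavy/light pulldown experiments (nuclear pore complex assembly
being the motivating system), and at anyone who wants a fully testable,
simulation-backed implementation of the underlying statistics.

## What it computes

- **Fractional labeling trajectories.** For each precursor,
  FL = H / (H + L); per protein, a reproducible filter cascade:
  quality-flag removal → proteotypic single-lysine y-ion selection with
  both-channel detection → per-precursor fragment summation → replicate
  presence filter (≥ 2 of 3 replicates at every post-labeling time point;
  relaxed ≥ 1 variant) → two-pass median with RMSE-based pruning of the
  worst half of precursors (`quantify_labeling()` and friends).
- **Assembly-tier enrichment.** Median-normalized top-3 label-free protein
  intensities across baits, and the early-tier / late-tier median fold
  difference that flags transient assembly factors (`tier_enrichment()`).
- **Intermixing extent.** From heavy/light lysate-mixing pulldowns, subunit
  exchange during purification as subunit FL normalized to the mean FL of
  co-purified bulk proteins (`intermixing_extent()`).
- **Inaccessible pool φ.** A three-state kinetic compartment model
  (free → accessible → inaccessible, growth dilution μ = ln 2 / T_d, heavy
  synthesis after t = 0). The bait-visible pool labels as
  FL(t) = 1 − (a e^(−bt) − b e^(−at)) / (a − b) with a = k_a + μ,
  b = k_m + μ, and φ = k_m / (k_m + μ) is the steady-state share of the
  assembled pool the bait cannot capture (`ksm_forward()`,
  `fit_inaccessible_pool()`).
- **Fluorescence statistics.** FRAP normalization
  (I_bl − I_bg)/(I_total − I_bg) and half-time recovery fits with mobile
  fractions; intensity-profile SD filtering and cross-channel Pearson
  correlation; Gaussian peak fitting for membrane-spacing measurements.
- **Synthetic data with known ground truth** for every assay type
  (`simulate_karma_dataset()` etc.), including the decoy fragments the
  filters must remove — the basis of the package's end-to-end validation.

## Worked example

Simulate a pulldown time course under realistic noise, run the cascade, and
fit the inaccessible pool:

```r
library(karma)
library(dplyr)

d <- sim_design(noise_sigma = 0.05, missing_rate = 0.05, n_precursors = 10)
sim <- simulate_karma_dataset(d, seed = 42)
prof <- quantify_labeling(sim$records, min_reps = 2, discard_fraction = 0.5)

prof %>%
  group_by(protein_id, time_min) %>%
  summarise(FL = median(FL), .groups = "drop") %>%
  tidyr::pivot_wider(names_from = time_min, values_from = FL,
                     names_prefix = "t") %>%
  left_join(select(sim$truth, protein_id, class, phi), by = "protein_id") %>%
  filter(protein_id %in% c("EARLY_NUP_01", "NTR_REFERENCE_01",
                           "LATE_NUP_01"))
#>         protein_id t0    t30    t60   t90         class phi
#> 1     EARLY_NUP_01  0 0.2125 0.4091 0.557     early_nup 0.4
#> 2      LATE_NUP_01  0 0.0297 0.0958 0.184      late_nup 0.0
#> 3 NTR_REFERENCE_01  0 0.1594 0.2941 0.408 ntr_reference 0.0
```

Three of the simulated proteins are shown, joined with their ground truth.
The early-tier protein labels *faster* than the transport-receptor
reference (0.21 vs 0.16 at 30 min) — the signature of a bait that binds
young assemblies — while the late joiner lags far behind. Fitting the
kinetic model:

```r
ksm_fit_profiles(prof, T_d = 120, seed = 1) %>%
  filter(protein_id %in% c("EARLY_NUP_01", "NTR_REFERENCE_01",
                           "LATE_NUP_01"))
#>         protein_id    phi     k_a      k_m      rss converged
#> 1     EARLY_NUP_01 0.3982 0.19719 0.003823 1.33e-04      TRUE
#> 2      LATE_NUP_01 0.1018 0.00615 0.000655 1.49e-05      TRUE
#> 3 NTR_REFERENCE_01 0.0217 1.00000 0.000128 3.96e-05      TRUE
```

The early protein's inaccessible pool is recovered at φ̂ = 0.398 against a
ground truth of 0.4: about 40% of its copies sit in mature complexes the
bait no longer binds. Near-zero pools carry a small upward noise bias
(boundary effect; see the methods vignette).

A thin command-line front-end over the same functions is included:

```sh
Rscript inst/cli/karma.R simulate --out out/ --seed 3
Rscript inst/cli/karma.R quantify-labeling --report out/fragment_report.tsv --out out/
```

## Documentation

The methods vignette (`vignettes/karma-methods.Rmd`) describes the models
and their assumptions, every tunable threshold with its default and
rationale, the simulators' generative model and its deliberate
simplifications, numerical choices, and known limitations.
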