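---
title: "Modeling memory effects in forest NEE: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling memory effects in forest NEE: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Monthly net ecosystem exchange (NEE, gC m^-2 d^-1; negative = net CO2
uptake) at a forest site is driven partly by the weather and canopy state of
that month, and partly by *memory*: carbon fixed in earlier months and years
returns to the atmosphere through respiration, and disturbance or drought
years leave multi-year imprints. `fluxmem` implements a complete, testable
pipeline for quantifying how much of NEE variability a dynamic sequence
model can recover from climate and surface-reflectance histories, and at
which time scales, using a factorial set of ablations that selectively
destroy temporal information in the predictors.

Because multi-site eddy-covariance/satellite compilations are access
restricted, every experiment here runs on a synthetic multi-site dataset
whose memory structure is known and controllable. The pipeline is the
contribution; the generator defines the ground truth against which its
behavior is verified.

## The synthetic data generator

`generator_config()` + `generate_dataset()` produce, per site:

* **Climate** — air temperature and global radiation as latitude-dependent
  sinusoids plus stationary AR(1) noise (lag-1 coefficient 0.5); the
  seasonal phase flips by six months south of the equator. VPD is a
  monotone exponential function of temperature plus noise; precipitation is
  lognormal around a seasonal mean, so it stays positive; `rpot` is the
  closed-form daily-mean top-of-atmosphere radiation from latitude and
  mid-month solar declination, noise free.
* **Vegetation** — a latent greenness in [0, 1] with PFT-dependent seasonal
  amplitude (deciduous 0.45 > mixed 0.30 > savanna 0.33 > evergreen 0.12),
  month-scale AR(1) noise (sd 0.03), and a year-scale anomaly term
  (sd 0.06, AR(1) across years with coefficient 0.3) that emulates drought
  and high-productivity years. A disturbance event (per-site probability
  0.25) removes half of greenness and recovers exponentially with a
  36-month time constant. Six optical bands are affine in greenness plus
  Gaussian noise (sd 0.008), clipped to [0, 1]; the thermal band tracks air
  temperature. The band noise is set so that every band keeps a
  signal-to-noise ratio comfortably above sqrt(3); below that threshold no
  gap-filling method can beat half of the band's temporal standard
  deviation, because the band's own noise is unpredictable.
* **NEE** — `GPP = epsilon * Rg * G * f_T(T) * f_W(VPD)` with smooth logistic
  temperature and dryness scalars; a single carbon pool
  `C_t = (1 - lambda) C_{t-1} + gamma GPP_{t-1}` feeds respiration
  `Reco = r_b exp(k T) C`, so respiration remembers past productivity with
  half-life `log(2)/-log(1 - lambda)` months (3.1 months at the default
  `lambda = 0.2`). `NEE = Reco - GPP + noise` (sd 0.3). `r_b = 0.085` makes
  long-run respiration about 75% of GPP — a typical forest carbon-use
  ratio — which matters for the ablation experiments: if respiration
  balanced GPP exactly, vegetation anomalies would cancel out of annual NEE
  and no model could detect them.
* **Observation model** — NEE exists only inside a per-site measurement
  window (3--12 years, placed uniformly in 2000--2015, so the "at least
  three complete years" anomaly filter has bite); a monthly quality
  fraction is drawn from Beta(18, 1) and months at or below 0.8 are later
  masked; each reflectance band is withheld per month with probability 0.3
  (times 2.5 at tropical sites, emulating cloud cover); an auxiliary
  reflectance table (a stand-in for a coarser-resolution satellite record)
  covers 2000 onward.

One carbon pool, rather than several, keeps the memory horizon a single
interpretable number, which the altered-forcings experiment needs. Random
streams are split hierarchically (master seed, then site, then variable),
so enlarging a configuration never perturbs existing sites.

What the generator does *not* emulate: spatially correlated cloud fields,
atmospheric contamination that correlates across bands, non-Gaussian EC
error structure (the Gaussian choice is a modeling convenience, not a claim
about flux-tower errors), sub-monthly dynamics, or species-level ecology.
Passing tests therefore demonstrate that the pipeline recovers memory
structure *of this kind*; they cannot certify performance on real FLUXNET
data.

## Preprocessing

* `qc_filter()` keeps a month's NEE only when its quality fraction is
  strictly greater than 0.8.
* `gapfill_stage1()` fills reflectance gaps inside the auxiliary-coverage
  period with a per-site, per-band random forest trained on months where
  band and auxiliaries are both observed (global fallback when a site has
  fewer than 12 overlap months); `gapfill_stage2()` fills everything that
  remains, over the full period, from climate + `rpot` + latitude + cyclic
  month encoding + one-hot PFT. Provenance columns partition every cell
  into observed / stage1 / stage2, and observed values are never rewritten.
  Feature screening is available as `select_features()`, a
  shadow-feature (Boruta-type) procedure re-implemented directly: each
  candidate is duplicated as a within-column permutation, and candidates
  must beat the best shadow in at least 80% of 20 repeats.
* `downscale_climate()` fits linear, kernel-ridge (Gaussian-process) and
  neighbor-mean models on the overlap between a gappy site series and three
  neighbor series, selecting by highest NSE on a held-out 20% — except for
  precipitation, which is selected by lowest RMSE. Candidates are always
  scored in a fixed canonical order, so the chosen family cannot depend on
  how the caller lists them.

## The sequence model

A single-layer LSTM (standard sigmoid gates and tanh candidate, zero
initial states) maps the 11 monthly predictors (7 bands + Tair, P, Rg, VPD)
to NEE at every timestep; a linear unit reads the hidden state out. The
loss is the mean squared error over *observed* months only, so the network
trains on full 20--34 year sequences while being graded only inside each
site's measurement window. Backpropagation through time and Adam are
implemented in compiled code; the analytic gradients are verified against
central finite differences in the test suite (relative error below 1e-5).

Training details, chosen where the underlying procedure leaves them open:

* one *iteration* is one full-batch pass over the training sites (no batch
  size is prescribed anywhere, and full batch makes early stopping
  deterministic);
* 20% of training *sites* (not months) are held out as the evaluation set
  for early stopping, preventing within-site leakage into the stopping
  decision; training stops when the evaluation loss has not improved for
  `patience` consecutive iterations and the best-iteration weights are
  returned;
* dropout (0 or 0.5) acts on the hidden-to-output connection during
  training only — a placement choice, made configurable;
* predictors and target are z-standardized with training-fold statistics
  (a learning rate of 0.1 is unusable on raw flux scales); the test suite
  asserts the pipeline never uses test-fold statistics;
* the hyperparameter grid (learning rate 0.1/0.01, hidden units 10/20/30,
  dropout 0/0.5) is searched once per cross-validation fold on that fold's
  training portion, preserving test-fold independence; exact ties resolve
  to the smaller network;
* ensembles re-train the same configuration from different initialization
  seeds (50 in the full-scale `"paper"` profile; 5 in the desk-scale
  experiments here), sharing
  one evaluation split, and report member mean and spread.

The static baseline (`train_static_baseline()`) is a 200-tree random forest
on the same 11 predictors month by month, with an internally canonicalized
row order so that training is invariant to how rows are supplied.

## Factorial set-ups and experiments

`make_setup()` materializes the five variants: full LSTM; `LSTM_perm` (one
seeded permutation of timesteps applied jointly to predictors, target and
mask within each site — instantaneous links survive, order dies);
`LSTM_msc` (each band replaced by its mean seasonal cycle; climate
untouched); `LSTM_annual` (each band replaced by its calendar-year mean);
and the static RF. Permutation is within site, because sequences are per
site and a cross-site permutation would also destroy the instantaneous
site-identity link the variant is supposed to keep.

`run_cross_validation()` assigns entire sites to K folds (balanced to one
site), fits standardizer + (optionally) grid search + ensemble on K-1
folds and predicts the held-out fold, recording per-fold training-site
provenance. `run_altered_forcings()` then takes each site's *test-fold*
ensemble and predicts the site after replacing the predictors of the n
preceding years (n = 1..5; bands, climate, or both) by their mean seasonal
cycle — if the model uses no information from those years, the predictions
cannot move. Target years are restricted to those with max(n) preceding
years on the panel so every n is measured on the same months; deviations
are summarized per hemisphere-aligned calendar month and forest type with
the ensemble spread, and the between-member sd of unaltered predictions is
reported as the noise floor.

## Evaluation

`decompose()` splits aligned (obs, pred) pairs into four scales: the raw
monthly series (*seasonal cycle*), per-site seasonal anomalies (value minus
that site's calendar-month mean, observations and predictions each centered
on their own means), interannual anomalies (complete-year annual means,
site-centered), and across-site variability (one site-mean pair per site).
Anomalies use only sites with at least three complete years of observations
(a year is complete when all 12 months survive the quality filter); strata
with no eligible site report NA, never zero. `stratified_report()` computes
NSE, R^2, RMSE and MAE per scale and stratum, metric-per-member first and
then mean +/- sd across members (the metrics of the ensemble-mean prediction
are emitted alongside). `residual_seasonal_curve()` implements the
site-centered residual
`(obs_ij - mean_i(obs)) - (pred_ij - mean_i(pred))`, averaged by
hemisphere-aligned month.

## Problem sizes and numerical choices

The canonical study fixture (`fixture_config()`) uses 40 sites on 20-year
panels (1996--2015) with `lambda = 0.2`, no reflectance gaps (gap-filling
is exercised separately on gappy configurations, so the sequence-model
experiments are not confounded with fill error), 2-fold entire-site CV,
5-member ensembles, and a fixed configuration (learning rate 0.01, 10
hidden units, no dropout, patience 50, 300 iterations) instead of the full
grid. These sizes keep a complete factorial replicate to roughly a minute
on one core while leaving the headline contrasts (dynamic vs static, actual
vs mean-seasonal vegetation, altered-forcings plateau at the pool
half-life) clearly resolved; `run_profile("desk")` and
`run_profile("paper")` scale folds, grid, ensemble and site count back up,
the latter mirroring 185 sites / 10 folds / 50 members and running for
hours.

Other numerical choices: weight initialization is uniform Glorot with the
forget-gate bias at +1; Adam uses the conventional (0.9, 0.999, 1e-8)
moments; standard-deviation floors of 1e-8 guard degenerate standardizers;
NSE refuses zero-variance observations rather than returning a number; the
permutation variant re-materializes byte-identically from its seed; and
grid-search seeds derive from hyperparameter *values*, so duplicated grid
entries train identically and ties genuinely resolve by the documented
order.

## Known limitations

* The generator's memory enters only through one respiration pool; real
  lag mechanisms (soil moisture carry-over, phenological priming, delayed
  mortality) are richer and partly predictor-visible.
* Interannual-anomaly metrics at 40 sites are intrinsically noisy; the
  dynamic-vs-MSC contrast is a small positive signal on top of that noise,
  which mirrors how marginal the corresponding contrast is on real data.
* The LSTM is single layer and unidirectional by design; no attention or
  multi-layer variants.
* Entire-site cross-validation means the model never learns site-specific
  offsets, which bounds across-site skill.
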