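# fluxmem

Memory effects of climate and vegetation on forest net ecosystem CO₂
exchange (NEE): a tested, fully synthetic pipeline for memory-attribution
analysis of monthly eddy-covariance flux data.

## The problem

Monthly forest NEE (gC m⁻² d⁻¹; negative = net uptake) responds to the
current month's radiation, temperature, dryness and canopy state — but also
to *past* states: carbon fixed months or years ago returns through
respiration, and disturbances leave multi-year recovery trajectories. How
much of NEE variability does that memory explain, and at which scales?

`fluxmem` answers this with a factorial modeling experiment:

* a **single-layer LSTM** maps monthly predictor sequences (7 surface
  reflectance bands + air temperature, precipitation, global radiation,
  VPD) to NEE, trained with a **masked MSE loss** (gradients flow only
  through months with observations), Adam, site-wise early stopping and a
  multi-initialization ensemble — backpropagation through time is
  hand-implemented and verified against finite differences;
* **ablation set-ups** that selectively destroy temporal information:
  `LSTM_perm` (timesteps permuted within site — instantaneous links kept,
  order destroyed), `LSTM_msc` (reflectance replaced by its mean seasonal
  cycle — no interannual vegetation signal), `LSTM_annual` (reflectance
  replaced by annual means — no seasonal vegetation signal), and a static
  random-forest baseline;
* **entire-site k-fold cross-validation** (a site's months never split
  across folds), with nested grid search and per-fold standardization;
* a **counterfactual altered-forcings experiment**: predict with the
  trained model after replacing the n preceding years of predictors by
  their mean seasonal cycle — if predictions don't move, the model wasn't
  using those years;
* a **four-scale evaluation**: Nash–Sutcliffe efficiency
  (NSE = 1 − Σ(pred−obs)²/Σ(obs−mean obs)²), R², RMSE and MAE on the raw
  seasonal cycle, per-site seasonal anomalies, interannual anomalies
  (≥ 3 complete years required), and across-site means, stratified by
  forest type, climate class and stand age.

Because multi-site flux/satellite compilations are access restricted,
everything runs on a seeded **synthetic data generator** whose memory is
known by construction: NEE = Reco − GPP where respiration draws on a carbon
pool `C_t = (1−λ)C_{t−1} + γ·GPP_{t−1}` with half-life `ln 2 / −ln(1−λ)`
months (3.1 months at the default λ = 0.2). Site records, seasonal climate,
disturbance/recovery, cloud-driven reflectance gaps and quality-filtered
measurement windows all mirror the structure of a global forest
eddy-covariance compilation. See the methods vignette
(`vignettes/memory-effects-methods.Rmd`) for the model, the generator and
every design decision.

## Worked example

The numbered scripts under `analysis/` run the full study at desk scale
(40 sites, 20-year panels, 2-fold entire-site CV, 5-member ensembles;
about 5 minutes on one core):

```sh
Rscript analysis/01_generate.R 1        # synthetic dataset -> results/dataset
Rscript analysis/02_preprocess.R 1      # QC + two-stage gap-filling demo
Rscript analysis/03_cross_validation.R 1
Rscript analysis/04_altered_forcings.R
Rscript analysis/05_report.R
```

`03_cross_validation.R` prints, per set-up, the held-out NSE at each scale
(seed 1; ensemble-member means):

```
LSTM         NSE  seasonal 0.880 | across-site 0.965 | seas-anom 0.359 | interann 0.180
LSTM_perm    NSE  seasonal 0.391 | across-site 0.771 | seas-anom -0.302 | interann -0.312
LSTM_msc     NSE  seasonal 0.848 | across-site 0.942 | seas-anom 0.257 | interann -0.141
LSTM_annual  NSE  seasonal 0.806 | across-site 0.952 | seas-anom -0.023 | interann -0.338
RF           NSE  seasonal 0.368 | across-site 0.691 | seas-anom -0.127 | interann -0.521
```

Reading: the dynamic model beats everything that cannot see temporal order
(`LSTM_perm`, `RF`) by ~0.5 NSE on the seasonal cycle — that gap *is* the
memory effect, here dominated by respiration lagging productivity. Replacing
reflectance with its mean seasonal cycle (`LSTM_msc`) barely hurts the
seasonal cycle but erases interannual-anomaly skill, because disturbance and
drought-year signals live in the interannual part of the bands.

`04_altered_forcings.R` prints the counterfactual deviations: altering one
preceding year moves monthly predictions by 0.110 gC m⁻² d⁻¹, and altering
2–5 years changes that by at most 8.6 % — the model's usable memory
plateaus within a year, consistent with the generator's 3.1-month pool
half-life. Altering only climate moves predictions less (0.068) than
altering reflectance (0.086) or both (0.110).

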