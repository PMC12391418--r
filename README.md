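# sersquant

Label-free quantification of sweat metabolites — uric acid, lactate and
tyrosine — from surface-enhanced Raman (SERS) spectra, for researchers
building or evaluating wearable sweat-sensing pipelines. The package
covers the whole computational chain around a chrono-sampling SERS patch:

* **Simulation** of labeled SERS mixture spectra: Lorentzian band models
  per analyte (primary bands at 635, 859 and 1353 cm⁻¹ for uric acid,
  lactate and tyrosine), chemically diverse sweat backgrounds, a
  41-combination × 36-replicate mixture design, and a seeded
  per-measurement noise model (multiplicative gain, baseline drift,
  white noise).
* **Preprocessing**: interpolation onto a uniform 457–1674 cm⁻¹ grid of
  1321 points, per-spectrum min–max normalization to [0, 1], reference
  background subtraction, peak-height and signal-to-noise utilities.
* **Quantification** with a semi-supervised autoencoder: a symmetric
  encoder/decoder around a 2-D latent plus one logistic prediction head
  per metabolite, trained with Adam on the total loss

  `total = MSE(decoder(encoder(x)), x) + λ · MSE(head(encoder(x)), y)`

  where `y` are min–max-scaled concentrations. Predictions are read off
  the latent "concentration axes" and inverse-scaled to physical units.
* **Explanation**: expected-gradients SHAP values of the encoder,
  squared and averaged across samples into a per-wavenumber importance
  profile.
* **Evaluation**: repeated random-subsampling cross-validation (10× with
  75/25 splits), R², RMSE in physical units, Bland–Altman agreement
  (bias ± 1.96 sd), per-level quartile boxes.
* **Chrono-sampling arithmetic**: chamber fill intervals (volume /
  flow rate), patch capacity, sweat-rate estimation, and time-resolved
  concentration profiles with one-standard-deviation error bars.

See `vignettes/sersquant-methods.Rmd` for the model, its assumptions,
all tunable parameters and the package's design choices.

## Worked example

```r
library(sersquant)

## synthetic study-condition data at desk scale: the full 41-combination
## design, 6 replicates, 300-point grid
g       <- wn_grid(457, 1674, 300)
lib     <- default_library()
design  <- default_design(replicates = 6)
spectra <- generate_dataset(lib, design, noise_model(seed = 1), g)
spectra
#> <spectrum_set> 246 spectra x 300 points (457..1674 cm^-1)
#>   labels: uric_acid, lactate, tyrosine

## cross-validated autoencoder quantification (2-D latent)
cfg <- quantifier_config(input_dim = 300, hidden_layers = 2, hidden_width = 200,
                         latent_dim = 2, max_epochs = 400, lr_initial = 3e-3,
                         lr_late = 3e-4, schedule_epoch = 200,
                         early_stop_patience = 40, seed = 1)
cv <- cross_validate(spectra, cfg, n_repeats = 3)
cv
#> <cv_result> 3 repeats
#>   uric_acid  R2 0.87-0.90 (mean 0.89), RMSE mean 4.48
#>   lactate    R2 0.89-0.93 (mean 0.91), RMSE mean 2.26
#>   tyrosine   R2 0.75-0.82 (mean 0.77), RMSE mean 32.8
```

Per metabolite and repeat, `cv$metrics` holds the held-out R² and the
RMSE in that metabolite's physical units (µM for uric acid and tyrosine,
mM for lactate): here, for example, uric acid is recovered with a mean
error of ≈ 4.5 µM over its 0–40 µM physiological range. `eval_report(cv)`
adds Bland–Altman agreement and per-level box summaries.

Chrono-sampling of a concentration transient (80 → 10 → 20 µM inlet):

```r
rec <- simulate_chrono_injection(
  data.frame(concentration = c(80, 10, 20), duration = c(13, 11, 12)),
  flow_rate = 0.25, chamber_volume = 0.5, n_chambers = 17)
head(rec, 3)
#>   index volume fill_start fill_end concentration
#> 1     1    0.5          0        2            80
#> 2     2    0.5          2        4            80
#> 3     3    0.5          4        6            80

sampling_interval(0.5, 0.25)  # 2 (minutes per chamber)
patch_capacity(17, 0.5)       # 8.5 (µL)
```

Each chamber is labeled with the volume-weighted mean inlet
concentration over its 2-minute fill window; `step_tracking_error()`
shows that 0.5 µL chambers track the step with a smaller worst-case
error than 1.5 µL chambers.

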