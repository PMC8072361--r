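# mbfdecon

Quantification of myocardial blood flow (MBF) from first-pass
contrast-enhanced cardiac MR perfusion curves, by constrained (Fermi) and
nonparametric Bayesian deconvolution, with the digital phantom machinery
needed to validate both against ground truth.

Under the indicator-dilution model the tissue concentration-time curve is a
convolution of the arterial input function (AIF) with a flow-scaled residue
function,

    C_t(t) = MBF · (C_a(· − τ_d) ⊗ R)(t),     R(0) = 1, R decaying,

and MBF (ml/min/g) is recovered by deconvolution. The package implements:

* **Fermi constrained deconvolution** (`fermi_fit()`): the residue is the
  sigmoid-shouldered exponential `A / (1 + exp((t − τ0) k))`, optionally with
  a causal bolus-arrival delay `τ_d` ("Fermi-δ"), fitted by
  Levenberg-Marquardt on the first-pass window with 20-fold oversampled
  Fourier-domain convolution; MBF is the maximum of the fitted residue.
* **Bayesian model-independent deconvolution** (`bayes_deconv()`): a
  free-form residue pinned to 1 at contrast arrival (Dirac prior) with a
  second-difference smoothness prior; residue and noise level are
  marginalised analytically (Student-type evidence) and the posterior over
  (flow, delay, smoothness) is integrated on a deterministic grid. Returns
  posterior-mean MBF, delay, the residue with a 95% credible band, mean
  transit time and blood volume. `bayes_batch()` vectorises the whole grid
  across thousands of curves.
* **A digital perfusion phantom** (`phantom_spec()`, `build_phantom()`):
  dual-Gaussian AIF calibrated to clinical stress features (peak
  5.86 mmol/L), 10 × 10 tiles of two-compartment-exchange tissue curves over
  flows 0.48–3.9 ml/min/g and plasma volumes 0.04–0.1 ml/g, frame-multiple
  bolus delays and centered Gaussian noise at three clinically measured
  scales.
* **Wild-bootstrap precision** (`bootstrap_precision()`,
  `representative_curve()`): Rademacher sign-flipped residual resampling
  with optional HC2/HC3 leverage weighting; the SD of replicate MBFs is the
  quoted precision.
* **Agreement statistics** (`regression_stats()`, `lin_ccc()`,
  `relative_error_summary()`, `measure_bat_10pct()`, `mbf_histogram()`,
  `compile_comparison_tables()`) and a one-call orchestration of the whole
  simulate → estimate → evaluate → report pipeline (`run_pipeline()`,
  `reproduce_study()`).

See the methods vignette (`vignettes/mbf-deconvolution-methods.Rmd`) for the
models, priors, numerical choices and known limitations.

## Worked example

```r
library(mbfdecon)

aif <- synthesize_aif(aif_params())                  # clinical-feature AIF
ct  <- generate_tissue_curve(aif, kinetic_params(Fp = 2, Vp = 0.08),
                             delay = 2.8, time_dilation = 60)

fit <- fermi_fit(ct, aif, variant = "fermi_delta")
summary(fit)
#> Fermi constrained deconvolution (fermi_delta)
#>   MBF:       1.9339 ml/min/g
#>   SSE:       1.856e-09 (window end 26.6 s)
#>   converged: TRUE after 1 iterations
#>        A        k     tau0    tau_d
#>  1.93395  0.91128 36.59820  2.80000

est <- bayes_deconv(ct, aif)
est
#> <bayes_deconv> posterior-mean estimates
#>   MBF   2.090 ml/min/g
#>   delay 2.80 s
#>   MTT   46.8 s
#>   MBV   1.6290 ml/g, eps 0.0001
```

A tissue curve generated with true flow 2 ml/min/g and a 2.8 s arrival delay
is recovered by both estimators: the delay-managed Fermi fit reads
MBF ≈ 1.93 with `tau_d` = 2.8 s, and the Bayesian posterior mean is
MBF ≈ 2.09 with the delay estimated at 2.80 s (the ~4% discrepancies are the
methods' own smoothing/shape biases on a noiseless curve). Plain
`fermi_fit(ct, aif, variant = "fermi")` on the same curve returns
1.50 ml/min/g — the delay-induced underestimation that makes delay
management necessary.

`plot(est, "residue")` draws the posterior-mean residue with its credible
band; `plot(fit)` overlays the Fermi fit and the first-pass window on the
data.

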