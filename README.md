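# blinkHMM

Bayesian hidden Markov analysis of single-molecule fluorescence blinking.

## What problem this solves

Single fluorophores (here: ATTO655-labeled DNA, where the dark state is a
charge-separated radical configuration) blink: they alternate between an
emitting ON state and a non-emitting OFF state. The measurement is a
photon-count trajectory — the number of detected photons `I_n` in each time
bin of width `Δ` (0.5 ms at the reference conditions). Shot noise,
background and detector noise blur the two levels, so naive thresholding
corrupts the dwell-time statistics that carry the photophysics (the OFF
dwell measures the charge-recombination time).

`blinkHMM` infers the hidden ON/OFF sequence with a two-state
Gaussian-emission hidden Markov model fitted by blocked Gibbs sampling:

* the full state sequence `S` is drawn *exactly* each sweep by
  forward-filtered backward sampling (forward weights
  `f_kn ∝ N(I_n | μ_k, λ_k⁻¹) Σ_ℓ A_kℓ f_ℓ,n−1`, per-step normalized;
  backward draws with weights `η_kn ∝ f_kn A_ℓk`);
* emission means/precisions `(μ_k, λ_k)` are drawn from conjugate
  Gauss-Gamma conditionals, the initial distribution `π` and each *column*
  of the transition matrix `A` (`A_kℓ = P(k | ℓ)`) from conjugate
  Dirichlets;
* counts are standardized to zero mean, unit variance for fitting and
  parameters are de-standardized to counts/bin for reporting.

From the inferred sequences the package computes blinking statistics:
dwell-time probability densities `p(τ_k) = n_k / (N_e Δτ)`, exponential
relaxation-time fits `p(τ) = s⁻¹ exp(−τ/s)`, transition-matrix relaxation
times `τ_k = Δ / (1 − Ā_kk)`, two-Gaussian photon-count-histogram models
with a bimodality score, bin-width diagnostics, QC flags, and a
mean-variance (Poisson) check `σ² ≈ μ`. A synthetic generator (bin-level
Markov chains and photon-level arrival streams) provides ground-truth data
for validation.

## Worked example

```r
library(blinkHMM)

# 5 s reference trajectory: tau_on = 17.6 ms, tau_off = 7.8 ms,
# 20 counts per ON bin, Poisson noise, 0.5 ms bins
sim <- simulate_blinking(default_scenario(seed = 1))
fit <- blink_hmm(sim$trace, seed = 2)   # 1000 sweeps, burn-in 100
summary(fit)
```

```
Blinking HMM posterior summary -- sim
  10000 bins of 0.5 ms; 1000 sweeps (burn-in 100), objective stable from sweep 20
  emission means (counts/bin): ON 19.964 (0.055)  OFF 0.989 (0.018)
  emission variances        : ON 20.515 (0.346)  OFF 1.070 (0.028)
  A_on,on = 0.9698 (0.0020), A_off,off = 0.9328 (0.0046)
  relaxation times: tau_on = 16.55 ms, tau_off = 7.45 ms
  occupancy w_on = 0.690; mean objective -0.3671 nats/sample
  QC: pass
```

The emission block recovers the generating intensities (20 and 1
counts/bin, variances ≈ means, i.e. Poissonian); the self-transition
probabilities translate through `τ = Δ/(1 − A_kk)` into the relaxation
times printed below them; the occupancy matches the stationary value
`τ_on/(τ_on+τ_off) ≈ 0.69`; and the surrogate objective (nats/sample) sits
above the −1.4189 baseline that separates informative fits from
unidentifiable ones.

```r
d <- extract_dwells(fit)
fit_exponential(d$on)
fit_exponential(d$off)
```

```
Exponential dwell fit (ON, mle): s = 16.596 ms +/- 1.151 ms (N_e = 208)
Exponential dwell fit (OFF, mle): s = 7.442 ms +/- 0.516 ms (N_e = 208)
```

Both dwell constants agree with the generating 17.6 / 7.8 ms within the
quoted standard errors, and with the transition-matrix route above — the
two independent readings of the same relaxation time.

## Package tour

| Area | Functions |
| --- | --- |
| Synthetic data | `blink_scenario()`, `default_scenario()`, `simulate_state_chain()`, `simulate_trace()`, `simulate_arrivals()`, `simulate_blinking()` |
| Containers | `photon_trace()`, `standardize()`, `count_histogram()`, `rebin()` |
| Model + sampler | `blink_prior()`, `blink_hmm()` (+ `summary`, `coef`, `plot`, `simulate`, `residuals` methods), `forward_filter()`, `backward_sample()`, `surrogate_loglik()`, conjugate-update functions |
| Blinking statistics | `extract_dwells()`, `dwell_pdf()`, `fit_exponential()`, `relaxation_from_transition()`, `pool_dwells()` |
| Diagnostics | `model_histogram()`, `bimodality_report()`, `qc_flag()`, `mean_variance_table()`, `convergence_sweep()` |
| I/O + pipeline | `read_trace()`, `write_trace()`, `write_dwells()`, `run_pipeline()` |

The methods vignette (`vignettes/blinking-analysis.Rmd`) documents the
model, the sampler's stabilizers (warm start, canonical component order),
the dwell and histogram conventions, what the generator does and does not
emulate, and known limitations.
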