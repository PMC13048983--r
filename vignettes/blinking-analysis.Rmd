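---
title: "Hidden Markov analysis of fluorescence blinking trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden Markov analysis of fluorescence blinking trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkHMM)
```

## The problem

A surface-anchored fluorophore under continuous excitation alternates between
an emitting (ON) state and a dark (OFF) state — for dye-labeled DNA the dark
state is a charge-separated radical configuration, so the OFF dwell length
measures the lifetime of charge separation. The raw observable is a
photon-count trajectory: the number of detected photons $I_n$ in each time
bin of width $\Delta$ (typically 0.5 ms here). Shot noise, background and
detector noise blur the two intensity levels, so thresholding the raw counts
misclassifies bins and corrupts the dwell-time statistics that the
experiment is after.

`blinkHMM` treats the ON/OFF label of each bin as a hidden state of a
two-state hidden Markov model and infers the full posterior over label
sequences and model parameters by blocked Gibbs sampling.

## Model

Counts are standardized to zero mean and unit variance (population standard
deviation, so the realized series has exactly unit variance). Conditional on
its hidden state $k$, a standardized count is Gaussian with mean $\mu_k$ and
precision $\lambda_k$ ($\sigma_k^2 = 1/\lambda_k$). Photon counting is
Poisson at heart; at $\sim$20 counts per ON bin the Gaussian is an accurate
approximation, and the mean–variance diagnostic below checks it after the
fact. The hidden sequence is a first-order Markov chain: the initial label
is drawn from $\boldsymbol\pi$ and each transition from the columns of a
$K\times K$ matrix $A$, with $A_{k\ell} = P(\text{state } k \mid
\text{previous state } \ell)$ — columns are the normalized axis, because
each column must be a conditional distribution over destinations. $K = 2$
throughout (the types are $K$-generic, but no model selection beyond two
states is provided).

Priors are conjugate: a Gauss-Gamma prior on each $(\mu_k, \lambda_k)$ pair
(hyperparameters $\nu, m, a, b$; Gamma in shape–rate form), a Dirichlet
prior on $\boldsymbol\pi$, and an independent Dirichlet prior on each
*column* of $A$. The reference settings are $(\nu, m, a, b) = (1, 0, 1, 1)$
on the standardized scale, $\boldsymbol\alpha = (1,1)$ and an all-ones
transition concentration — all deliberately weak.

## Sampler

Each Gibbs sweep draws, in this order:

1. **The full hidden sequence**, exactly, by forward-filtered backward
   sampling. The forward weights obey
   $f_{kn} \propto \mathcal N(I_n \mid \mu_k, \lambda_k^{-1})
   \sum_\ell A_{k\ell} f_{\ell,n-1}$; they are renormalized at every step
   with the log-normalizer stored, because the unnormalized recursion
   underflows for $N \gtrsim 10^3$. Backward sampling needs only the
   normalized filter and $A$: the last bin is drawn from the final filter
   row, and bin $n$ from weights $\eta_{kn} \propto f_{kn} A_{\ell k}$ where
   $\ell$ is the sampled state at $n+1$. The backward *message* is never
   materialized — the sampling conditional provably does not require it.
2. **Emission parameters** from the Gauss-Gamma conditionals
   ($\hat\nu_k, \hat m_k, \hat a_k, \hat b_k$ accumulate the per-state
   sufficient statistics).
3. **The initial distribution** from $\text{Dirichlet}(\alpha + s_1)$.
4. **The transition columns** from
   $\text{Dirichlet}(\hat\beta_{\cdot\ell})$, where $\hat\beta_{k\ell}$
   counts observed $\ell \to k$ transitions plus the prior.

Two stabilizers:

* **Warm start.** For the first 10 sweeps the transition concentration is
  replaced by a sticky matrix ($20N$ on the diagonal, 1 off-diagonal). Early
  sweeps otherwise assign labels almost at random, and a transition matrix
  fitted to random labels can trap the chain in a fast-switching mode.
* **Canonical component order.** Whenever an emission draw would make the
  "ON" component dimmer than the "OFF" one, the two components (and the
  current labels) are swapped. The ON state is the bright state *by
  definition*, and enforcing the order at every sweep — rather than
  relabelling once after the run — keeps posterior averages meaningful even
  if the sampler visits both labelings; a run whose labels oscillate in more
  than 10% of retained sweeps triggers a warning, since that indicates the
  components are not really distinguishable.

Initialization: precisions and $\boldsymbol\pi$ are drawn from their priors,
$A$ from the warm-start Dirichlet, and the emission means are anchored at
the 80th/20th percentiles of the standardized trace. A pure prior draw
($m = 0$ for both components) makes the components exchangeable and symmetry
breaking needlessly slow; the quantile anchor starts the bright component
bright without biasing the eventual posterior.

The default run is 1000 sweeps with a burn-in of 100 retained for averages.
Convergence of the per-sample surrogate log-likelihood (emission + initial +
transition terms, nats/sample) is typically reached within 20–30 sweeps on
bimodal data; the burn-in is set an order of magnitude above that and also
swallows the warm-start phase, whose sticky prior would otherwise leak into
the averaged $A$. Convergence is monitored (`convergence_sweep()`), not
enforced — the sweep count is fixed, never adapted to the data.

The monitoring objective has a useful stationary approximation: replacing
the emission quadratic by its expectation and dropping the initial term
gives $\tfrac12\sum_k w_k \ln\lambda_k - \tfrac{1+\ln 2\pi}{2} + \sum_\ell
w_\ell \sum_k A_{k\ell}\ln A_{k\ell}$ with occupancies $w_k$. The constant
$-(1+\ln 2\pi)/2 = -1.4189$ is the value the emission term takes when the
fitted precisions are 1, i.e. when splitting the standardized trace into two
components explains none of its variance — which is why a post-burn-in mean
objective *below* that baseline is one of the two QC triggers.

## Downstream statistics

* **Dwells.** The per-bin posterior ON frequency is binarized at 0.5 (a tie
  resolves to OFF — conservative against false ON events); maximal constant
  runs become dwells of length (bins $\times\,\Delta$). Boundary runs are
  truncated by the observation window; they are *included* by default
  (`"censor"` drops them). The dwell-time density is a histogram on the grid
  $\tau_k = k\,\Delta\tau$ (default $\Delta\tau = 1$ ms) with the half-open
  convention $[\tau_{k-1}, \tau_k)$, normalized so
  $\sum_k p(\tau_k)\Delta\tau = 1$.
* **Relaxation times, two routes.** (i) An exponential density
  $p(\tau) = s^{-1} e^{-\tau/s}$ fitted to the dwell sample — the default
  estimator is the MLE (the sample mean; standard error $s/\sqrt{N_e}$),
  which is the estimator the density form implies; a histogram
  least-squares fit is provided for comparison since curve-fitting the
  histogram is common practice. (ii) Inversion of the averaged transition
  matrix, $\tau_k = \Delta / (1 - \bar A_{kk})$, the continuous-time reading
  of the geometric dwell law. Agreement between the two routes is a
  self-consistency check the test suite enforces.
* **Histogram model and QC.** The count histogram $h(n)$ is compared with
  the fit-implied mixture $h_{\rm model}(n) = N_{\rm eve}\,
  [w_{\rm ON}\,\mathcal N(n \mid \mu_{\rm ON}, \sigma^2_{\rm ON}) +
  w_{\rm OFF}\,\mathcal N(n \mid \mu_{\rm OFF}, \sigma^2_{\rm OFF})]$.
  Modality is quantified by the separation score
  $d = (\mu_{\rm ON}-\mu_{\rm OFF})/(\sigma_{\rm ON}+\sigma_{\rm OFF})$:
  bimodal for $d \ge 1$ (boundary inclusive), shoulder for $0.5 \le d < 1$,
  unimodal below. The thresholds were chosen once so that well-separated,
  partially overlapping and indistinguishable synthetic mixtures land in
  the three classes; they are a reproducible stand-in for visual judgement
  of histogram shape. A trajectory is QC-flagged when its classification is
  unimodal *or* its mean objective falls below $-1.4189$; flags are
  reported, never auto-dropped.
* **Mean–variance.** Per molecule and state, $(\mu, \sigma^2)$ with the
  ratio $\sigma^2/\mu$; Poisson-dominated detection keeps the ratio near 1,
  and rows outside $[0.5, 2]$ are flagged.

## The synthetic generator

`default_scenario()` encodes the reference conditions: mean dwells
$\tau_{\rm ON} = 17.6$ ms and $\tau_{\rm OFF} = 7.8$ ms, about 20 detected
photons per ON bin at $\Delta = 0.5$ ms, Poisson count noise, 5 s traces.
Two values are deliberate implementation choices rather than measured
quantities: the OFF level (1 count/bin — a nonzero background so that no
state ever has zero variance, which would break standardization and the
Gamma updates; the true background level is not separately characterized)
and the default duration (5 s, comfortably above the
$10\times\max(\tau)$ rule of thumb for stable dwell statistics while
keeping a fit to a few seconds of compute).

State chains are simulated at the bin level with
$A_{kk} = 1 - \Delta/\tau_k$, the first-order discretization of exponential
dwells; discrete-time dwells are then geometric with mean $\tau_k/\Delta$
bins, which is exactly the law the transition-matrix relaxation-time formula
inverts. Counts are Poisson (or rounded, zero-clipped Gaussian — traces are
always valid integer count data). A photon-level generator
(`simulate_arrivals()`) produces a rate-switching Poisson process with
exponential dwells in *continuous* time, quantized to the 80 ns detector
tick, for studying bin-width effects via `rebin()`.

What the generator does and does not emulate: it reproduces two-state
Markov switching, exponential/geometric dwells, shot noise and a constant
background — the features the inference relies on. It does **not** model
triplet states, photobleaching, power-law blinking, intensity drift or
diffusion through the focal volume. Passing tests therefore demonstrate
correctness of the inference machinery under the model's own assumptions,
not robustness to every artifact of real recordings. One consequence worth
knowing: bin-level chain simulation produces no bins that straddle a state
switch, so dwell recovery looks slightly *better* on chain-simulated data
than on arrival-simulated (or real) data, where sub-3-bin dwells are
systematically washed out. The test suite probes that effect with the
arrival-level generator, which is why the minimum reliable dwell is quoted
as $\approx 3\Delta$.

## Numerical choices and edge cases

* Per-step filter normalization with stored log-normalizers (underflow-proof
  for arbitrary $N$); a fully underflowed step raises an error rather than
  returning NaNs.
* A forbidden-but-required transition in backward sampling (zero Dirichlet
  draw) raises an error naming the bin.
* $\hat b_k \le 0$ in the emission update — possible only when a constant
  data segment collides with a degenerate prior — raises a dedicated error.
* A trace with zero spread is refused (standardization undefined).
* $\bar A_{kk} = 1$ yields an infinite relaxation time with a warning, not a
  crash.
* Consensus-sequence ties (ON marginal exactly 0.5) resolve to OFF.
* Rebinning from counts requires an integer bin-width multiple and drops the
  trailing partial window (keeping bins identically distributed); rebinning
  from arrivals accepts any width.

## Reported study sizes

The validation studies run by the test suite and the acceptance script use:
5 s traces (10,000 bins) at the reference conditions for single-fit checks,
a 20 s trace for dwell-census checks, 20 seeded replicates for the
parameter-recovery study, and 11 molecules spanning ON brightness 10–40
counts/bin for the mean–variance study. Exhaustive-enumeration oracles use
$N \le 8$ bins ($2^N$ paths) with $10^5$ backward-sampling draws. These
sizes keep every Monte-Carlo standard error several times smaller than the
corresponding acceptance tolerance.

## Known limitations

* Gaussian emissions mis-specify very dim states (Poisson with mean
  $\lesssim 3$ is visibly skewed); the OFF state at 1 count/bin is fitted
  adequately in practice, but a Poisson-emission variant is out of scope.
* The weak reference prior is not scale-free on the standardized axis: for a
  component whose standardized variance is very small (a dim OFF state under
  a bright ON state), the Gamma rate $b = 1$ and the prior mean $m = 0$
  together inflate the posterior of that component's variance by several
  percent on traces of a few seconds. The effect shrinks as $1/N$; it is a
  property of the prescribed prior, not of the sampler, and mostly concerns
  the OFF-state variance read from short traces.
* When the ON and OFF intensity distributions coincide, the sampler does not
  return "no structure": it splits the single count distribution into two
  overlapping pseudo-components with rapidly switching labels (mean pseudo-
  dwells of roughly 2–4 bins in our experiments — far below any genuine
  dwell, but not below 2 bins in every run). This is the identifiability
  limit, and it is exactly what the QC flag detects: such fits sit below the
  $-1.4189$ objective baseline.
* Dwells shorter than $\sim 3\Delta$ are under-detected on continuous-time
  data; choose $\Delta$ small enough that the dwells of interest span
  several bins, but large enough that the count histogram is bimodal.
* The surrogate objective is a monitoring statistic, not a marginal
  likelihood; it supports convergence checks and QC, not model comparison.

## A short worked example

```{r example, eval = FALSE}
library(blinkHMM)

sim <- simulate_blinking(default_scenario(seed = 1))
fit <- blink_hmm(sim$trace, seed = 2)
summary(fit)

d <- extract_dwells(fit)
fit_exponential(d$on)   # ~17.6 ms
fit_exponential(d$off)  # ~7.8 ms
relaxation_from_transition(fit$posterior$A, fit$trace$delta)

plot(fit, "trace")
plot(fit, "objective")
```
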