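---
title: "Sampling-based inference in spiking ring networks: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling-based inference in spiking ring networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurosampler)
```

This vignette is the package's own account of the science it
implements: the generative models, the sampling circuits, the
parameters that matter, the numerical conventions, and what the test
suite does and does not establish.

## The code and its generative models

All latents live on a ring of length `L = 360` degrees. A population of
`n_e` excitatory neurons (default 180) has preferred stimuli evenly
spaced on `(-180, 180]` and Gaussian log-tuning of width `a_deg`
(default 40 degrees): `h_j(s) = -d(s, θ_j)²/(2a²)` with `d` the
minimal-arc difference. A feedforward input is one vector of
independent Poisson counts with rates `U_f exp[h_j(s)]`. Because the
log-tuning is quadratic in `s`, each draw encodes an exactly Gaussian
likelihood: mean `μ_f` (the activity-weighted mean of preferred
stimuli) and precision `Λ_f = n_f/a²`, with `n_f` the total count.

Two priors connect this code to multi-latent inference:

* the **hierarchical** model couples the stimulus `s` to a uniformly
  distributed stimulus parameter `z` through `s|z ~ N(z, 1/Λ_s)`; the
  joint posterior of `(s, z)` is Gaussian with mean `(μ_f, μ_f)` and
  precision `[[Λ_f + Λ_s, -Λ_s], [-Λ_s, Λ_s]]`;
* the **parallel** model puts an improper pairwise prior
  `∝ exp[-Λ_s(s₁-s₂)²/2]` on two stimuli with uniform marginals; each
  stimulus drives its own feedforward input, and the posterior
  precision is the likelihood precision plus the singular prior
  precision matrix.

Wrapped Gaussians on a ring are only approximately Gaussian; all
formulas use minimal-arc differences and the validated regime keeps
posterior standard deviations well below 30 degrees, where the wrap
error is negligible. At `Λ_s = 0` the hierarchical posterior is
degenerate in `z`; the package returns an explicitly flagged degenerate
object rather than pseudo-inverting.

## Sampling circuits

`run_chain()` is the reference Gibbs sampler: it alternates the exact
conditionals (stimulus given input and parameter, then parameter given
stimulus; network 1 then network 2 in the parallel model) and is the
algorithmic oracle all spiking results are compared against. The
initialisation (`z = μ_f`, respectively `s_m = μ_fm`) is a package
convention — it starts the chain in the high-density region, matching
the input-driven network — and burn-in defaults to 10% of the chain
with a floor of 100 samples; the strong conditionals mix within tens of
steps, so these choices are conservative.

`simulate_e_only()` is the excitatory-only theory network: a fixed
input vector is presented at every step, the recurrent input is
`w_E r_{t-1}` from self-connections only, corrupted by Gaussian noise
whose variance equals its rectified mean (mimicking Poisson
variability), and spikes are independent Poisson draws from the
rectified rate. One decoded sample is emitted per step: the spike
population vector is the stimulus sample and the recurrent-input
position is the stimulus-parameter sample. At
`w_E* = Λ_s/(Λ_f + Λ_s)` this is a Gibbs chain for the hierarchical
posterior. Negative rates are treated as zero spiking probability; the
unrectified rate is still logged. A stability guard aborts when the
summed rate exceeds ten times the feedforward-only rate — runaway
excitation lies outside the theory's regime.

`simulate_ei()` is the full excitatory-inhibitory ring: a
time-discretized Hawkes process (Euler step 0.1 ms) with exponential
synaptic filtering (`τ_d = 2` ms), a 2 ms refractory period, untuned
inhibitory neurons, `1/√N` weight scaling, E-to-E connectivity decaying
as a wrapped Gaussian of preferred-stimulus distance (footprint 40
degrees, rows normalised to `n_e·w_ee`), and unstructured E-I, I-E and
I-I blocks with `w_I/w_E = 5`. The feedforward drive is a Poisson spike
stream with tuning width `√2·a` (the broader of the two tuning
conventions that appear in the theory; the narrower `a` form is
available through `input_width_deg`) and the inhibitory population
receives a flat drive scaled by `w_if = 0.8` to keep excitation and
inhibition balanced. Spikes are decoded with a population vector in
non-overlapping 20 ms windows. `simulate_coupled()` couples two such
rings by excitatory projections onto both E and I cells of the partner,
with no within-ring E-to-E connections (the uniform marginal prior
requires none) and no recurrent noise.

Magnitude parameters that the underlying theory leaves open are package
conventions chosen once for stable, cortical-range activity: peak
feedforward drive 50 Hz and reference weight `w_e = 0.1`, giving
excitatory rates of roughly 10–20 Hz. With these magnitudes the
uncoupled ring's decoded sampling precision is proportional to the
decoded likelihood precision across input rates (ratio ≈ 0.35) rather
than equal to it; equality additionally requires the network's spike
count per window to dominate the feedforward count, i.e. a higher
recurrent gain than these defaults produce.

## Decoding conventions

The population vector is computed in two passes: the circular resultant
locates the activity bump wrap-safely, and the linear mean of
minimal-arc deviations about it reproduces the activity-weighted mean
exactly. The two-pass form matters: the likelihood mean encoded by a
Poisson input draw is the *linear* weighted mean, and the pure circular
resultant can differ from it by a degree or more when stray spikes land
on the flanks, which would masquerade as a bias of the sampling
distribution. Away from the wrap point the decoder equals the linear
formula; at the wrap point (equal masses at ±179 degrees) it correctly
returns 180 rather than 0. Windows with no spikes are skipped and
counted — a conditional sample is undefined when no spikes are emitted.
The generator's default peak input `U_f = 5` counts per draw
(`n_f ≈ 250`) keeps the likelihood SD near 2.5 degrees.

Sampling distributions are summarised by circular-aware first and
second moments (covariances of minimal-arc deviations, `n-1`
denominator) before any Gaussian comparison; higher-moment mismatch is
deliberately not folded into the KL.

## Information accounting

`kl_gaussian()` computes `D_KL[p‖q]` — true posterior against
approximation, the direction in which the divergence equals the lost
mutual information — in bits. `mutual_info_bound()` implements the
closed-form bivariate bound and satisfies `I = I_q + D_KL` to 1e-9
bits. Two degenerate cases get exact special forms rather than ad-hoc
regularisation: when the prior precision is zero the true posterior
factorises into a Gaussian over `s` and a uniform over `z`, and the KL
against a joint Gaussian approximation is computed for that product
density (a network with no recurrent input represents exactly the
uniform, so only the `s` marginals differ); conversely, when the
approximation has no `z` representation but the posterior is proper,
the missing axis is scored as a uniform readout — a large, finite
penalty, so weight scans penalise under-coupling honestly.

`linear_fisher_information()` is the standard bias-corrected empirical
estimator — `(2T-N-3)/(2T-2)` on the quadratic form and a
`2N/(Tδs²)` subtraction — with silent neurons removed before inverting
the covariance and 50 bootstrap resamples for error bars by default.

## Differential correlations

Two variance decompositions quantify sampling signatures. With a fixed
input, the rate-position variance `V(s̄|u^f)` equals `a²n_f⁻¹w_E*` at
the optimal weight; with the input redrawn per trial the variance gains
the inherited term `a²/n_f`. Both are measured by
`differential_correlations()` on the theory network. A structural
point the implementation makes explicit: in the *self-connected*
theory network the position wander is carried entirely by amplified
per-neuron variance — instantaneous spike counts are uncorrelated
across neurons — which is precisely how the chain keeps the correct
posterior marginal. The collective covariance signature
(`f'f'ᵀ` structure with its anti-symmetric quadrant pattern) appears in
the laterally connected E-I ring, and `diff_corr_fit()` extracts it
from windowed counts by jointly fitting the differential (`f'f'ᵀ`) and
amplitude-fluctuation (`ffᵀ`) components on the off-diagonal of the
noise covariance; the diagonal is excluded because it carries private
Poisson noise.

## What the tests show — and what they do not

The synthetic-data generator *is* the study design: all tests run on
data drawn from the stated generative models, so they validate the
implementation and the internal consistency of the theory, not its fit
to biological recordings. Three further caveats:

* **Finite input draws.** With one fixed Poisson input the spike-stage
  sampling variance scales with that draw's realised profile second
  moment, not `a²` (relative SD ≈ `√(2/n_f)`, about 9% at the default
  rates). Expectation-level claims (the `a²n_f⁻¹w_E*` law) are
  therefore tested as averages over independent input draws at fixed
  total step count; single-draw checks (posterior matching, weight
  scans) inherit this realisation noise, and a weight-scan argmin can
  shift by about one grid step for an unlucky draw.
* **Problem sizes.** Chains of 1e4–1e5 samples, 2000-trial information
  estimates, and 4–20 s of E-I simulation keep the full suite near two
  minutes on one core while leaving Monte-Carlo error comfortably
  inside the stated tolerances; these are the sizes at which the
  reported properties were verified.
* **E-I magnitudes.** The E-I simulator's rate and weight magnitudes
  are package conventions (see above); quantitative E-I claims that
  depend on those magnitudes — notably the identity between sampling
  precision and likelihood precision — are tested as proportionality,
  and the optimal-weight and posterior-matching laws are verified on
  the excitatory-only network and the Gibbs oracle where the theory
  pins every constant.

## Degenerate inputs and error policy

Empty feedforward inputs are flagged and refuse to decode; empty
decode windows are skipped and counted; zero or negative total
recurrent input yields no stimulus-parameter sample for that step;
`Λ_s = 0` returns degenerate posteriors and uniform `z` draws;
unstable simulations abort with the step at which the guard tripped;
all-identical chains return zero covariance with a degeneracy flag.
Every simulator and experiment is bit-reproducible given its seed, and
chains, inputs, configs and experiment specs round-trip through
CSV/YAML with JSON metadata sidecars.
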