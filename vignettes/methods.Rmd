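---
title: "Models and methods behind bsscult"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bsscult}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsscult)
```

This vignette explains the generative model, the estimators, and the design
choices in `bsscult`, in the spirit of a methods section: what is assumed,
what each tunable parameter means, and where the genuinely open decisions
were made.

## The stimulation design

Two hidden binary sources $u_1(t), u_2(t) \in \{0,1\}$ are drawn i.i.d.
Bernoulli($\rho$) per one-second event, $t = 1,\dots,256$ within a trial.
Thirty-two stimulation channels receive probabilistic copies: channel $i \le
16$ copies $u_1$ with probability $a$ (otherwise $u_2$), channels 17–32 have
the roles swapped, equivalent to a binary process with intensity $A u(t)$
for the $32 \times 2$ mixing matrix $A$ with rows $(a, 1-a)$ and $(1-a, a)$.
Defaults are $\rho = 1/2$ and $a = 3/4$. One realized pattern is delivered
identically on all 100 trials — a consequential feature: within a culture,
the mixing randomness never averages out across trials, only the response
noise does. Analyses that target design-level expectations (such as the
$a/(1-a)$ conditional-mean ratio of a channel-driven unit) must therefore
replicate over schedules, not trials; `stim_params()` exposes the seed so
this is cheap.

## The synthetic culture

`simulate_culture()` implements a two-layer linear-rate model. Per event,
the two-dimensional population response is
$$\tilde x(t) = W \tilde s(t) + \xi(t), \qquad \xi \sim N(0, \Sigma_\xi),$$
where $\tilde s(t)$ holds the two channel-group means of the delivered
pattern. Each electrode's expected evoked count is
$$\lambda_i(t) = \max\!\big(0,\; b + c_i s_i(t) + \tilde x_{g(i)}(t)\big),$$
with baseline $b$, nearest-channel gain $c_i$ (electrode $i$ listens to
channel $i$ for $i \le 32$; this reproduces the stimulated/non-stimulated
contrast of the recordings), and group assignment $g(i)$ (electrodes 1–16
carry $\tilde x_1$, 17–32 carry $\tilde x_2$, electrodes 33–64 are
unstimulated and weakly coupled to the mean population rate). Counts are
Poisson; rates are rectified at zero before drawing because counts cannot
be negative. Between trials the connectivity is updated by the
state-dependent Hebbian rule
$$\Delta W = \eta \sum_{u \ne (0,0)} \beta_u \, z^u, \qquad
  z^u = \sum_{t:\,u(t)=u} (\tilde x(t) - \langle\tilde x\rangle)
        (\tilde s(t) - \langle\tilde s\rangle)^T,$$
with $\beta_{(1,0)} = \beta_{(0,1)} = \beta_1$, $\beta_{(1,1)} = \beta_2$,
and $\beta_{(0,0)} = 0$ (no activity, no activity-dependent plasticity).
Centering means are within-trial empirical means, and the update is applied
once per trial, matching the per-trial granularity of all estimators.

### Default parameters and why

| parameter | default | units | rationale |
|---|---|---|---|
| $\rho$, $a$ | 1/2, 3/4 | — | the trained-condition design values |
| $W_0$ | $[1.5\; 0.25; 0.25\; 1.5]$ | spike/event | see below |
| $\Sigma_\xi$ | $0.1\,I$ | (spike/event)² | response s.d. ≈ 0.3, modest relative to rates of 1–3 |
| $b$ | 0.3 | spike/event | low spontaneous rate; keeps unstimulated electrodes below the availability threshold most of the time |
| $c_i$ | 1 | spike/event | direct responses comparable to the population component |
| $\eta\beta_1$ | 4×10⁻⁴ | — | total diagonal connectivity change of order +1 over 100 trials |
| $\beta_2/\beta_1$ | 0.271 | — | the trained-condition efficacy ratio; the quantity the recovery study re-estimates |

Responses and connectivity magnitudes were set once to the scales of the
experimental figures (conditional means of 1–3 spike/event, connectivity of
order 1–2 spike/event). The paperless free parameters (baseline, gains,
noise) are realistic choices, not calibrated claims.

**Initial connectivity.** The study conditions require that, under the
state-dependent rule with $\beta_2/\beta_1 = 0.271$, within-group
connections strengthen while between-group connections do not. A
first-order analysis of the expected update at $\rho = 1/2$, $a = 3/4$
(so each source state occupies ≈ 64 of 256 events, and the pure-state
population-input deviations are $\pm 1/4$) gives an expected off-diagonal
drift per trial proportional to
$$\beta_1\big[-8(W_{11} - W_{12}) + 1.5\,W_{12}\big] +
  16\,\beta_2 (W_{11} + W_{12}),$$
which is negative precisely when
$8(W_{11}-W_{12}) - 1.5 W_{12} > 16 (\beta_2/\beta_1)(W_{11}+W_{12})$.
A diagonally dominant start such as $W_0 = [1.5\; 0.25; 0.25\; 1.5]$
satisfies this with margin (9.6 vs 7.6), and the margin widens as training
strengthens the diagonal. Diagonal dominance at trial 1 is also what the
recordings show: response preference and nonzero source divergence are
present before training. With a weakly dominant start the joint-state term
wins and between-group connections grow instead — the α-model regime.

### What the simulator does and does not emulate

It emulates: the mixing design and its per-state statistics; evoked-count
scales; the stimulated/unstimulated electrode contrast; trial-to-trial
plasticity with state-dependent efficacy; an NMDA-blockade analogue
(`apv_mode`, all efficacies zero, connectivity bitwise frozen); partial
training (resting trials with no stimulation and frozen connectivity); and,
optionally, 25 kHz raw voltage traces with stimulation artifacts for
exercising the spike-detection path.

It does not emulate: biophysical neuron or electrode-field dynamics;
bursting and other non-stimulus-locked population events; development or
drift of the background noise; spike waveform diversity (no spike sorting);
or any constraint on total synaptic strength. Two consequences are worth
stating plainly, because they bound what passing tests show about real
recordings:

* **Internal energy.** In this generative family the analysis residual
  $\Sigma_\xi$ is background noise plus Poisson sampling noise, and neither
  shrinks with learning — the Poisson part in fact grows slightly with the
  rates. The expected internal energy $\langle U\rangle = 1 + \log 2\pi +
  \tfrac12 \log|\Sigma_\xi|$ is therefore flat-to-slightly-increasing on
  synthetic cultures, whereas real cultures show a decrease, presumably
  because their response reliability improves with training in a way a
  fixed-noise linear model cannot express. The free-energy decrease on
  synthetic cultures is carried by the entropy increase alone.
* **γ-norms.** `gamma_norm()` computes $(\sum_{ij} |W_{ij}|^\gamma)^{1/\gamma}$
  and `culture_fep()` tracks it per trial, but on the unconstrained
  simulator every norm grows with the diagonal entries; the empirical
  observation that $\gamma = 2$–$4$ norms stay flat in real data reflects a
  constraint on total synaptic strength that the simulated rule does not
  impose.

## Estimators

**Conditional statistics.** $x_i^u(l)$ is the per-trial mean count over
events in state $u$ — the ML estimate of the Poisson mean. Availability
requires the four all-trial conditional means to average at least 1
spike/event; preference is G1/G2 when the pure-state means differ by at
least ±0.5 spike/event. States absent from a trial propagate as missing
values, never as zeros.

**Poisson KLD.** The divergence between the pure-state response
distributions is evaluated in closed form,
$D_{KL} = (\log\lambda_1 - \log\lambda_2)\lambda_1 - \lambda_1 + \lambda_2$
(nats). Limit conventions: $\lambda_1 = 0$ gives $\lambda_2$ (the
continuous limit); for trajectories, a zero $\lambda_2$ is floored at one
pseudo-count over the whole recording, $1/(256 \times 100)$, keeping curves
finite while preserving order. Change-from-trial-1 summaries are clipped to
$[-10, 10]$.

**Connectivity.** Per trial,
$\mu^W = (\sum_t \tilde x \tilde s^T)(\sum_t \tilde s \tilde s^T)^{-1}$,
the minimizer of the summed prediction-error energy; the input moment
matrix is rejected as singular above condition number $10^8$ (a constant
pattern across events cannot identify $W$). $\Sigma_\xi$ is the pooled
residual second moment over the trial's events. The defining moments are
written per source state but a single $\Sigma_\xi$ enters the energy, so
pooling is the default; conditional (per-state) residual moments are
available behind a flag without endorsement.

**Free-energy decomposition.** $\langle U\rangle$ uses the closed Gaussian
form above; $H$ is the plug-in entropy $-\frac1{256}\sum_t \log q(\tilde
x(t))$ of a four-component Gaussian mixture whose components are labelled
by the known source state (conditional sample moments; no EM), with equal
weights 1/4; $F = \langle U\rangle - H$ exactly, omitting the
parameter-entropy term, which is constant over trials. Component
covariances receive a $10^{-9}\cdot\mathrm{tr}/2$ diagonal regularization
before inversion so degenerate trials stay evaluable; mixture densities are
evaluated by log-sum-exp.

**Learning rule.** The per-trial connectivity change is taken as the
endpoint slope $(W(100) - W(1))/100$ for all trials — trial differences of
$\mu^W$ are noisy and saturate late. The α-model regresses it on
$z^{10}+z^{01}+z^{11}$ with one efficacy; the β-model on
$(z^{10}+z^{01},\, z^{11})$ with two. Both are closed-form least squares on
a Gaussian residual model with a single variance shared across all four
matrix entries. The printed $z$ definition repeats the row index on the
input factor; it is read as the outer product $(\tilde x_i - \langle\tilde
x_i\rangle)(\tilde s_j - \langle\tilde s_j\rangle)$, since $z$ is a $2
\times 2$ cross-product statistic. Centering is per-trial (the sums
defining $z$ run within one trial); all-trial centering is available behind
`centering = "all"`.

**BIC.** $\mathrm{BIC} = k \ln n + 2\,\mathrm{NLL}$ with $n = 400$ residual
entries (100 trials × 4 matrix entries), the ML plug-in variance, and $k$
counting efficacies plus the variance (2 vs 3). Whether the variance is
counted is a convention; either choice preserves the one-parameter penalty
difference that the model comparison rests on.

## Numerical and preprocessing conventions

* Evoked window $[10, 30)$ ms half-open — the printed integral bounds are
  closed, but half-open counting avoids double-counting at boundaries.
* Band-pass: the recordings specify only the 500–2000 Hz band; a zero-phase
  Butterworth design (order-2 forward–backward, effective 4th order) is
  used and fixed here.
* Detection: $\mu, \sigma$ per non-overlapping 1 s block; local minima with
  $v - \mu < -5\sigma$; discrete-sample minimum test `v[k] < v[k-1] &&
  v[k] <= v[k+1]` (ties broken leftward); within 0.25 ms only the deepest
  valley is kept.
* RNG: one master seed with named substreams (sources, mixing, noise,
  counts) so components can be varied in isolation while whole runs stay
  bit-reproducible.

## Problem sizes in the test suite

The shipped tests validate estimators on reduced designs chosen for quick
iteration: directional group-level checks use 20 training and 9
plasticity-blocked cultures at the full 100 × 256 design; efficacy-ratio
recovery uses 23 full-design cultures at the population level, with a
60-trial variant for the bias and model-selection studies; oracle
equivalences run on single trials or toy arrays. Monte-Carlo oracles use
$10^5$ samples.

## Known limitations

Beyond the two simulator gaps above: preference labels are all-trial
averages, so electrodes whose preference emerges only late contribute
diluted population series; the recognition density fixes four components
even when states coincide (the entropy then degenerates gracefully to a
single Gaussian); and the efficacy estimators regress a constant endpoint
slope on per-trial statistics, which attenuates estimates when regressor
noise is large relative to the mean Hebbian statistics — at the default
noise this bias is within the Monte-Carlo error of the recovery studies.
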