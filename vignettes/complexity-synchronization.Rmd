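---
title: "Measuring complexity synchronization with diffusion entropy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring complexity synchronization with diffusion entropy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdea)
```

## The problem

Physiological organ networks — the brain, the heart, the lungs — emit
continuous signals whose *temporal complexity* varies over time. A useful
summary of that complexity is the scaling index $\delta$ of the diffusion
process built from the signal's *crucial events*: if $X(t)$ is self-similar,
its probability density obeys
$$P(x,t) = \frac{1}{t^{\delta}}\,F\!\left(\frac{x}{t^{\delta}}\right),$$
and the Shannon entropy $S(t) = -\int P \ln P \, dx$ of that density grows as
$$\Delta S(t) = S(t) - S_{\mathrm{ref}} = \delta \ln t ,$$
regardless of the (generally unknown) shape of $F$. $\delta = 0.5$ is
ordinary Gaussian diffusion; $\delta > 0.5$ signals superdiffusive,
crucial-event dynamics. *Complexity synchronization* is the covariation over
time of the $\delta(t)$ series of different signals — detectable by
cross-correlating $\delta(t)$ traces even when the raw signals themselves
are uncorrelated. This package implements the full chain: signal
conditioning, the modified diffusion entropy analysis (MDEA) estimator of
$\delta$, sliding-window $\delta(t)$ extraction, index conversions, and the
cross-correlation analysis, together with synthetic generators that make
every stage testable without access to clinical recordings.

## The MDEA estimator

Each data slice is processed as follows:

1. **Normalization.** The slice is projected onto $[0,1]$: subtract the
   minimum, divide by the resulting maximum (`normalize_unit()`). A constant
   slice cannot be normalized and is flagged degenerate (its $\delta$ is
   missing downstream, never fabricated).
2. **Stripes.** The unit interval is partitioned into equal stripes of width
   $s$ (default $s = 0.01$, i.e. 100 stripes). A sample belongs to stripe
   $\lfloor x/s \rfloor$; a value exactly on a boundary belongs to the upper
   stripe and $x = 1$ is clamped into the top stripe.
3. **Events.** A *crucial event* is recorded whenever consecutive samples
   fall in different stripes (`extract_events()`). Sub-stripe fluctuations —
   the non-crucial events that contaminate plain diffusion entropy analysis —
   generate no events by construction. The first sample never carries an
   event.
4. **Diffusion.** The cumulative event count is the diffusion trajectory
   $x(t)$ (`diffusion_trajectory()`).
5. **Ensemble.** For each window size $w$, every event origin $t_e$ with
   $t_e + w$ inside the record contributes the displacement
   $x(t_e + w) - x(t_e)$ (`displacement_ensemble()`). All events are used as
   origins; windows are overlapping.
6. **Entropy.** $S(w)$ is the Shannon entropy of the unit-bin histogram of
   the integer displacements (`shannon_entropy()`). With the bin width fixed
   at one count, the discretization offset of the differential entropy is
   independent of $w$: it shifts the intercept $S_{\mathrm{ref}}$, never the
   slope.
7. **Fit.** $\delta$ is the ordinary-least-squares slope of $S(w)$ against
   $\ln w$ over a configurable window range (`fit_delta()`), with $r^2$
   always reported so the linearity of the fit is auditable.

`mdea_slice()` composes the chain and returns a `scaling_fit`; invalidity
(degenerate slice, too few events, too few usable window sizes, poor
linearity, $\delta \notin (0, 1.5)$) is a *value* with a reason code, not an
exception.

## Index conversions

For a renewal process whose waiting times follow
$\psi(\tau) \propto \tau^{-\mu}$ the scaling index, the waiting-time index
$\mu$, the spectral index $\beta$ of $S(f) \propto f^{-\beta}$ and the
fractal dimension $D$ are tied together:

| relation | branch |
|---|---|
| $\mu = 1 + \delta$ | non-ergodic, $1 \le \mu \le 2$ (infinite mean wait) |
| $\mu = 1 + 1/\delta$ | asymptotically ergodic, $2 \le \mu \le 3$ |
| $\delta = 0.5$ | $\mu \ge 3$ (ordinary diffusion) |
| $\beta = 3 - \mu$ | $\mu = 2$ is the $1/f$ point, $\beta = 1$ |
| $D = 2 - \delta$ | self-affine record |

`delta_to_mu()` takes the branch as an explicit argument (default
`"ergodic"`, the regime of the physiological $\delta < 1$ discussion);
automatic branch inference from data is deliberately out of scope. Results
outside the branch's range are returned with a warning, never clipped.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `stripe_size` | 0.01 | fraction of signal range | 100 stripes; the standard operating point of the protocol |
| `w_grid` | 30 log-spaced, 10..min(3000, n/10) | samples | even coverage per decade; capped so the largest window retains many origins |
| `w_lo`, `w_hi` | 10, 1000 | samples | default fit range; see "numerical choices" for when to widen it |
| `min_events` | 200 | events/slice | below this the entropy curve is dominated by shot noise; $\delta$ is reported missing |
| `min_origins` | 50 | origins/window | window sizes with fewer usable origins are dropped from the curve |
| `r2_min` | 0.9 | — | fits with worse linearity are flagged invalid |
| `L_sec`, `step_sec` | 60 s, 20 s | s | the sliding-window protocol: 60 s slices stepped by 20 s |
| `max_lag` | 10 steps (200 s) | window steps | lag range scanned by the cross-correlation |

## The sliding protocol and the CS report

`sliding_delta()` applies `mdea_slice()` to half-open sample windows
$[k \cdot \mathrm{step} \cdot f_s,\ k \cdot \mathrm{step} \cdot f_s + L f_s)$
and reports window-center times (centers keep cross-correlation lags
symmetric). Invalid windows propagate as missing values at exactly their
position. `cs_report()` averages the EEG-group series per window (skipping
missing channels; a window is missing only if every channel is missing),
then computes the maximum lagged Pearson cross-correlation for EEG-mean vs
ECG, EEG-mean vs RESP, and ECG vs RESP, with pairwise deletion per lag and
ties broken toward the smallest lag magnitude (negative first). Both the
lag-maximized and the zero-lag coefficients are reported, because either
convention is defensible; the headline value is the maximum.

Confidence intervals use the Fisher $z$ transform with half-width
$1.96/\sqrt{n-3}$. Because 60 s windows stepped by 20 s overlap, successive
$\delta(t)$ values are autocorrelated and the nominal interval is
anti-conservative; `use_effective_n = TRUE` substitutes the AR(1)-corrected
effective sample size $n(1-\rho_1\rho_2)/(1+\rho_1\rho_2)$. It is off by
default so the default output matches the common uncorrected convention.

## Signal conditioning

The acquisition pipeline the package mirrors: EEG/ECG high-passed at 1 Hz,
respiration low-passed at 2 Hz, all with zero-phase FIR filters; EEG
re-referenced to the average of the EEG group; everything decimated from
2048 Hz to 512 Hz. Numerical choices, documented because no tap counts are
standard:

* FIR kernels come from `signal::fir1` with length $3 f_s/f_c$ rounded up to
  odd, re-normalized to exactly unit passband gain (DC for low-pass, Nyquist
  for high-pass); the filter is applied forward and backward, which squares
  the magnitude response and cancels the phase exactly.
* Edges are handled by odd-reflection padding of one kernel length, trimmed
  after filtering, so the first MDEA slice is not contaminated by filter
  transients.
* Decimation (`downsample()`) low-passes at $0.45\times$ the *new* Nyquist
  rate before keeping every $k$-th sample — a deliberately conservative
  anti-alias margin, irrelevant to the $\le 2$ Hz physiological passbands.
* Artifact removal (ICA) is out of scope; readers assume cleaned input.

## The synthetic generators

`sample_waiting_times()` draws from the regularized hyperbolic density
$$\psi(\tau) = \frac{(\mu-1)\,T^{\mu-1}}{(T+\tau)^{\mu}},$$
which has the $\tau^{-\mu}$ tail of a crucial-event process but no
divergence at $\tau = 0$, plus closed forms (mean $T/(\mu-2)$ for $\mu > 2$,
survival $(T/(T+\tau))^{\mu-1}$) that serve as independent test oracles.
`events_from_waiting_times()` rounds cumulative waits onto the sample grid
(collisions merge); `signal_from_events()` synthesizes a piecewise-constant
signal jumping between stripe centers whose stripe crossings reproduce the
planted events *exactly* — consecutive distinct stripe centers remain more
than one stripe width apart after re-normalization, so the round trip
`extract_events(normalize_unit(x))` is an identity on the indicator.

`generate_cs_ensemble()` emulates the synchronized multichannel setting:
every channel is a renewal train whose waiting times are drawn with the
shared instantaneous index
$\mu(t) = \mu_{\mathrm{base}} + A \sin(2\pi t/P)$, frozen at each draw's
start (a piecewise-renewal approximation, valid while $\mu(t)$ changes
slowly relative to the mean wait; draws are batched in 2 s chunks).

The ensemble defaults were chosen once, to make the planted synchronization
actually resolvable by the 60 s / 20 s protocol, and are worth explaining:

* **`fs = 512` Hz.** The estimator works in samples, so the rate simply sets
  the slice size: 60 s windows of 30720 samples give per-window $\delta$
  noise of about 0.02. At coarse rates (tens of Hz) a 60 s window holds only
  a couple thousand samples, the noise reaches ~0.07, and the modulation
  drowns; 512 Hz is also the acquisition rate of the recordings this
  ensemble emulates.
* **$\mu(t) = 2.7 + 0.5\sin(2\pi t/400\,\mathrm{s})$.** The modulation spans
  $\mu \in [2.2, 3.2]$. The lower edge stays well clear of $\mu = 2$: closer
  to the non-ergodic boundary a single waiting time can span a measurable
  fraction of the record and blank out whole stretches of windows. The span
  produces a per-window $\delta$ response of ~0.13 against ~0.02 noise.
* **$T = 0.5$ samples.** Keeps thousands of events in every 60 s window so
  no window falls under `min_events`.
* **Period 400 s $> 2L$** so the sliding protocol resolves the oscillation.

With `synchronized = FALSE` the drivers are made *incoherent*: independent
initial phases, independent periods (factor $U(0.3, 0.9)$ of the base
period), and slow phase diffusion (0.1 rad/$\sqrt{\mathrm{s}}$). Randomizing
phases alone would not do: two equal-period sinusoids with any phase offset
are re-aligned by some lag within a $\pm$half-period scan, so a lag-maximized
correlation would be high by construction no matter how the phases are drawn.

`gaussian_random_walk()` (the $\delta = 0.5$ diffusive control) and
`fbm_control()` (fractional Brownian motion via exact-covariance
circulant-embedding synthesis of fractional Gaussian noise) provide the
Gaussian branches.

## Numerical choices and degenerate inputs

* Stripe ids use plain `floor(x/s)` in double precision; values exactly on a
  boundary belong to the upper stripe up to floating-point representation.
  A stripe size not dividing 1 gets one extra remainder stripe, with a
  warning.
* Displacements use closed windows on the trajectory: the count in
  $(t_e, t_e + w]$, both endpoints read from the cumulative trajectory.
* The entropy histogram bins are the integers $0..w$; empty bins contribute
  nothing.
* Degenerate cases (constant slice, event-free slice, all window sizes
  dropped, sub-4-point fits) produce invalid fits with reason codes
  `degenerate-normalization`, `too-few-events`, `empty-entropy-curve`,
  `too-few-points`.
* Lag-scan ties take the smallest $|$lag$|$, then the negative lag.
* All generators take explicit integer seeds and restore the global RNG
  state on exit.

## Convergence: what the fit window measures

The scaling relations above are *asymptotic*. For Lomax waits with $T = 5$
samples the standard deviation of the event count grows like $w^{0.6}$
across $w \in [10, 1000]$ even at $\mu = 3.5$ (where the asymptote is
$w^{0.5}$); the asymptotic slope only dominates for $w \gtrsim 10^4$. We
verified this against a direct renewal-count simulation that shares no code
with the estimator, so it is a property of the process, not of the
implementation. Consequences:

* Fits over the default $[10, 1000]$ window on heavy-tailed renewal input
  measure the *pre-asymptotic* exponent (e.g. ~0.60 at $\mu = 3.5$, $T=5$).
* Recovery studies in this package therefore use an *asymptotic protocol*:
  $T = 0.5$ samples (so a 500k-sample record holds as many renewals as
  possible), windows up to 50000 samples, fit over $[100, 10000]$
  (`analysis/02_fit_scaling.R`). Under it the medians over 10 seeds are
  accurate to $\pm 0.01$ at $\mu = 2.5$, $\pm 0.05$ at $\mu \in \{2.8, 3.5\}$.
* For $\mu \le 2.2$ the tail is so heavy that a 500k-sample record
  truncates it: medians sit roughly 0.08 *below* the branch value
  ($0.62$ vs $0.70$ at $\mu = 1.7$; $0.76$ vs $0.83$ at $\mu = 2.2$), and no
  fit window repairs this — larger windows make it worse by thinning the
  origin ensemble. Recovering those regimes to better than $\pm 0.07$
  needs records well beyond $10^6$ samples. We report this bias rather than
  hide it; the corresponding recovery assertions in the test suite document
  the shortfall.

## What the generators do and do not emulate

The synthetic ensembles reproduce the *statistical* skeleton of the
multichannel setting: renewal crucial events with inverse-power-law waits, a
shared slowly varying complexity driver, stripe-quantized continuous
signals. They do **not** emulate waveform morphology (QRS complexes, alpha
rhythms, breathing cycles), artifacts, volume conduction between EEG
channels, non-renewal memory, or the mixture of crucial and non-crucial
events present in real recordings (real signals rely on the stripes to
filter the non-crucial component; the synthetic signals contain crucial
events only). Passing the pipeline tests therefore demonstrates that the
estimator chain is correct and that planted synchronization is recovered
and its absence rejected — not that any particular physiological dataset
will show these effects.

## Problem sizes used by the checks

The bundled studies run at: 300k samples for the diffusive control; 500k
samples and 10 seeds per $\mu$ for recovery; 3600 s at 512 Hz, 10 channels,
for the synchronized ensemble; 20 seeded desynchronized runs of 3 channels
for the null. These sizes put the medians' sampling error well inside the
effect sizes being checked while keeping a full run in the minutes range.

## Known limitations

* Branch selection for $\delta \to \mu$ is the caller's assertion; data do
  not identify the branch.
* The Fisher intervals ignore window overlap unless `use_effective_n` is
  set (see above).
* The EDF reader covers plain continuous EDF with a common sampling rate
  across signals; EDF+ annotations and discontinuous records are out of
  scope.
* Original (unit-step-per-sample) diffusion entropy analysis, multifractal
  spectra and surrogate-data significance testing are deliberately not
  implemented.
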