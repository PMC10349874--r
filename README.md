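# csdea — complexity synchronization via modified diffusion entropy analysis

`csdea` measures the *temporal complexity* of continuous biosignals (EEG,
ECG, respiration) and how that complexity co-varies across signals. It is
aimed at physiologists and time-series researchers who want a working,
tested implementation of modified diffusion entropy analysis (MDEA) and of
the cross-correlation analysis of time-resolved scaling indices known as
complexity synchronization (CS).

## The method

For a self-similar process the probability density scales as
P(x,t) = t^−δ F(x/t^δ), and its Shannon entropy grows as

    S(w) = S_ref + δ ln w

independently of the shape of F. MDEA estimates δ from a single record:

1. normalize the record (or a 60 s slice of it) onto [0,1];
2. partition [0,1] into stripes of width 0.01; mark a **crucial event**
   whenever the signal crosses from one stripe to another;
3. accumulate events into a diffusion trajectory x(t);
4. for each window size w, collect the displacements x(t_e + w) − x(t_e)
   over all event origins t_e, histogram them with unit bins, and take the
   Shannon entropy S(w);
5. δ is the OLS slope of S(w) against ln w (r² is always reported).

δ = 0.5 is ordinary Gaussian diffusion; δ > 0.5 signals crucial-event
dynamics. For renewal waits ψ(τ) ∝ τ^−μ the indices interconvert:
μ = 1 + 1/δ (ergodic, 2 ≤ μ ≤ 3), μ = 1 + δ (non-ergodic, 1 ≤ μ ≤ 2),
β = 3 − μ (power spectrum; μ = 2 is the 1/f point), D = 2 − δ (fractal
dimension). Sliding 60 s windows stepped by 20 s yield δ(t) per channel;
CS is quantified by the maximum lagged cross-correlation between δ(t)
series (EEG-mean vs ECG, EEG-mean vs RESP, ECG vs RESP) with Fisher 95%
confidence intervals.

## Worked example

Generate a synchronized 10-channel ensemble (8 EEG-like channels + ECG +
RESP driven by one slowly oscillating waiting-time index μ(t)) and run the
full pipeline:

```r
library(csdea)
rec <- generate_cs_ensemble(n_eeg = 8, duration_sec = 3600, seed = 7)
cs_report(rec)
#> <cs_report> maximum lagged cross-correlations of delta(t) series
#>            pair  r_max lag r_zero_lag ci_low ci_high   n
#>    Ave. EEG-ECG 0.8747   0     0.8747 0.8334  0.9063 166
#>  Ave. EEG-Resp. 0.8634   0     0.8634 0.8205  0.8966 178
#>       ECG-Resp. 0.7921   0     0.7921 0.7276  0.8428 166
```

All three δ(t) pairs correlate strongly at lag 0 — the planted shared
driver is recovered. The same pipeline on a desynchronized control
(independent per-channel drivers, `synchronized = FALSE`) yields r_max of
0.13–0.20. A single-slice estimate on a diffusive control:

```r
fit <- mdea_slice(gaussian_random_walk(300000, seed = 1)$values)
fit
#> <scaling_fit> delta = 0.5149 (intercept 0.628, r2 0.9994, w in [10, 1000], 24 pts)
```

δ ≈ 0.5, the Gaussian value, with an almost perfectly linear entropy curve.

## The analysis scripts

The `analysis/` directory holds the study drivers, each a thin narrative
script over the package that writes its tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | builds the synthetic inputs and checks their moments against closed forms |
| `02_fit_scaling.R` | δ-recovery study across μ ∈ {1.7, 2.2, 2.5, 2.8, 3.5} (10 seeds each) |
| `03_sliding_delta.R` | δ(t) extraction for a synchronized ensemble, per-channel driver correlations |
| `04_cs_report.R` | the CS cross-correlation table for synchronized and desynchronized ensembles |

Note the recovery study reports the heavy-tail regimes honestly: at 500k
samples the μ ≤ 2.2 estimates sit ~0.08 below their asymptotic branch
values (record-length truncation of the waiting-time tail), while
μ ∈ {2.5, 2.8, 3.5} are recovered to within ±0.05.

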