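# ssvepds

Dynamic reference-electrode selection for SSVEP detection in multichannel
EEG.

Steady-state visual evoked potentials (SSVEPs) — periodic EEG responses
at the frequency of a flickering stimulus — are the workhorse of
high-throughput brain-computer interfaces. EEG is only defined as a
potential difference, so the reference electrode shapes every statistic;
the usual choices (`Cz`, the common average, the linked mastoids) are
static. This package implements the *dynamic selection* scheme: all
electrodes are treated as active, a narrowband SNR statistic is summed
over the whole montage, and the reference electrode maximizing that sum
is selected per stimulus frequency by exhaustive scan. It is aimed at
BCI researchers who want a self-contained, reproducible implementation of
the statistic, the scan, the threshold-calibrated detector, and the
simulation machinery behind them.

## The statistic at the core

For channel *m* and target frequency *f* on a zero-padded
rectangular-window FFT grid,

    R_fm = P_fm / mean{ P_gm : g in [f-1, f+1] }        (relative power)
    R_f  = sum over active electrodes of R_fm           (sum relative-power)
    G_f  = SR_f (evoked epoch) / R_f (spontaneous)      (SSVEP gain)

The optimum reference for *f* is the electrode *r* maximizing `R_f`
computed with every channel re-referenced to *r* (the reference itself is
excluded from the sum). Detection on 2 s segments (padded to 4 s,
0.25 Hz bins) compares `R_f` against per-frequency thresholds calibrated
so that 90% of spontaneous segments fall strictly below; a segment is
accepted when the first (or, where recorded, second) harmonic of the true
frequency exceeds its threshold while all competing stimulus frequencies
stay below theirs.

The mechanism is made explicit by a sinusoid field model: with
per-channel amplitudes `A_i` and phases `Phi_i` against an ideal
reference, the per-cycle mean sum power under reference *r* is
`sum_{i != r} (A_i^2 + A_r^2 - 2 A_i A_r cos(Phi_i - Phi_r)) / 2`; a
100,000-trial Monte-Carlo draw with the source amplitude forced maximal
shows the source reference strictly wins in about 98% of comparisons —
which is why scanned optimum references cluster at the occipital source.

## Worked example

Six evoked epochs (one per stimulus frequency, 100 s, 129 channels) and
one spontaneous epoch are simulated, the model is fitted, and detection
is run on the 12.5 Hz epoch's fifty 2 s segments:

```r
library(ssvepds)
plan <- frequency_plan()       # 33.33, 25, 16.67, 12.5, 8.33, 6.25 Hz
evoked <- lapply(plan$stimulus_freqs, function(f)
  synthesize_evoked(forward_model(f), duration = 100, seed = round(f * 100)))
spont <- synthesize_spontaneous(forward_model(12.5), 100, seed = 1)
fit <- ds_ssvep(evoked, spont, plan)
fit
#> Dynamic reference-selection fit
#>   stimuli: 33.33, 25, 16.67, 12.5, 8.33, 6.25 Hz
#>   optimum references: 33.33 Hz -> 86, 25 Hz -> 86, 16.67 Hz -> 86,
#>     12.5 Hz -> 86, 8.33 Hz -> 86, 6.25 Hz -> 86
#>   schemes calibrated: optimum, cz, avg, mastoid (specificity 0.90, 50 segments)
round(fit$gains["12.5", , ], 2)
#>        scheme
#> freq    optimum   cz  avg mastoid
#>   33.33    1.07 1.17 0.99    1.12
#>   25      11.18 2.90 3.11    2.54
#>   16.67    1.08 1.00 1.00    0.77
#>   12.5    23.30 3.83 4.13    6.52
#>   8.33     0.96 1.07 0.99    0.70
#>   6.25     1.00 0.98 1.00    0.55
```

Channel 86 is the simulator's occipital source: the scan recovers it for
every stimulus. In the 12.5 Hz epoch the gain at the stimulus frequency
is 23.3 under the dynamic reference versus 3.8 under `Cz` (the 25 Hz row
is the second harmonic; the remaining rows are noise gains, near 1 under
the dynamic reference). Detection follows the same ordering:

```r
predict(fit, evoked[[4]], rule = "h1h2", scheme = "optimum")$overall
#> [1] 0.24
predict(fit, evoked[[4]], rule = "h1h2", scheme = "cz")$overall
#> [1] 0.08
monte_carlo_reference_advantage(seed = 42)
#> P(source-referenced sum power > alternative) = 0.9816 (MC se 6.9e-05)
#>   129 channels, 100000 trials, comparison: all_m
```

Accuracies are far from 1 because the simulated source is deliberately
weak (1 µV in 10 µV RMS background; see the methods vignette) and a
correct detection also requires every competing frequency to stay below
threshold.

A command-line front end over the same functions lives in
`inst/cli/ds_ssvep.R` (subcommands `simulate`, `compare`, `montecarlo`),
and `vignettes/dynamic-reference-selection.Rmd` documents the model,
parameter choices and limitations.

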