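# earesn

Attention-state classification from two-channel in-ear EEG with a leaky echo
state network (ESN).

## What this package is for

Wearable, earphone-style EEG devices record two channels from the ear canals
at modest signal quality. `earesn` implements a complete offline pipeline for
deciding, every 0.5 s, whether the wearer is in an *attentive* or a *resting*
state during a visual vigilance task (runs of 8 self-paced trials with
6 ± 2 s pre-stimulus fixation intervals, followed by 48 s rest blocks):

1. **Synthetic sessions** — labeled two-channel recordings with the
   statistical structure the analysis assumes: 1/f background noise,
   band-limited oscillations whose amplitudes shift with state (alpha up at
   rest; theta and gamma up under attention), per-subject variability, and
   reaction times containing false starts and lapses. Everything downstream
   is testable without any data download.
2. **Features** — 0.5 s epochs (125 samples at 250 Hz), 1–50 Hz zero-phase
   6th-order Butterworth filtering (designed and run in second-order
   sections), and per channel and canonical band (delta 1–4, theta 4–8,
   alpha 8–13, beta 13–30, gamma 30–50 Hz): the band-mean square root of the
   STFT power spectral density, plus mean amplitude, SD, peak-to-peak,
   skewness and kurtosis of the band-filtered window — 60 features per
   two-channel epoch, z-scored on training data and rescaled to [−1, 1].
3. **Classifier** — a leaky ESN:
   `x(t) = (1 − α) x(t−1) + α tanh(W_in u(t) + W x(t−1))`, with a fixed
   sparse reservoir `W` rescaled to spectral radius λ, and a linear readout
   `y(t) = W_out (u(t), x(t))` trained by ridge regression (β = 1e-8).
   Positive readouts classify attentive (+1), negative resting (−1); a
   causal moving average over 1–12 outputs (0.5–6 s) smooths the readout.
4. **Evaluation** — reaction-time trial exclusion (false start < 100 ms,
   lapse > mean + 3 SD), grid search of α ∈ (0, 1] and λ ∈ (0, 2] in 0.1
   steps (200 combinations, 10 reservoirs each), reservoir size/connectivity
   sweeps, and three cross-validation protocols: within-subject
   (leave-one-run-out), cross-subject (leave-one-subject-out) and pooled
   10-fold.

See `vignettes/attention-esn-methods.Rmd` for the model, the generator's
assumptions, and every numerical choice.

## Worked example

```r
library(earesn)

cfg  <- session_config(n_runs = 4, seed = 42)         # 4 runs x 8 trials + rests
rec  <- simulate_session(subject_profile("s01"), cfg)
rec
#> <labeled_recording> subject s01: 2 channel(s) x 111965 samples @ 250 Hz (447.9 s)
#>   labels: attentive=51965, none=12000, rest=48000
#>   32 trials with reaction times

feats <- extract_features(rec) |>                     # 60 features per 0.5 s epoch
  filter_attended(rec$reaction_times)                 # drop false starts / lapses

cv <- within_subject_cv(feats,
                        grid_search_spec(c(0.3, 0.8), c(0.6, 0.9, 1.2), repeats = 2),
                        seed = 1)
tidy(cv)
#>    fold n_train n_test leaking_rate spectral_radius train_accuracy test_accuracy
#> 1     1     547    182          0.3             0.9          1             0.989
#> 2     2     560    169          0.3             0.9          0.998         0.959
#> 3     3     533    196          0.3             0.6          1             0.990
#> 4     4     547    182          0.3             0.9          1             0.973
glance(cv)
#>   scheme         n_folds mean_train_accuracy mean_test_accuracy sem_test_accuracy n_test
#> 1 within_subject       4               1.000              0.977           0.00745    729
smoothing_curve(cv, c(1, 6, 12))
#>   window accuracy
#> 1      1    0.977
#> 2      6    0.985
#> 3     12    0.985
```

Each fold holds out one run (its attention stream plus its rest block),
fits the feature standardizer and hyperparameters on the remaining runs,
and reports held-out accuracy; `smoothing_curve()` re-thresholds the stored
readout traces after causal moving-average smoothing (window 12 = 6 s) —
here smoothing repairs most of the isolated misclassified epochs.
`autoplot(cv)` shows the per-fold accuracies; `run_pipeline(pipeline_config(...))`
chains simulation, extraction and all three protocols with a run manifest.

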