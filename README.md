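# betatrack

Temporal response function (TRF) analysis of word-onset tracking in the
beta-band (12–30 Hz) envelope of basal ganglia local field potentials
(LFPs), for electrophysiologists working with deep-brain-stimulation
(DBS) electrode recordings during two-speaker ("cocktail party")
listening.

## The model

Each speech stream is reduced to a binary word-onset train
$s_f(t) \in \{0,1\}$ (attended and unattended; the first attended onset
is the target word). A forward encoding model predicts the Hilbert
envelope $y(t)$ of the band-passed (12–30 Hz) LFP from time-lagged
onsets over 0–700 ms:

$$\hat{y}(t) = \sum_f \sum_{\ell=0}^{L} w_f(\ell)\, s_f(t-\ell) + b$$

The kernels $w_f$ are estimated by closed-form ridge regression
($\lambda = 1$ on the standardized problem); performance is the Pearson
correlation between predicted and actual envelopes under five-fold,
trial-wise cross-validation. Inference per contact is non-parametric: a
100-replicate trial bootstrap describes the variability of real
tracking, a 500-replicate shuffle that permutes inter-onset intervals
(preserving their multiset exactly) while redrawing the train offset
provides the null, and the empirical p-value is the add-one-corrected
rank of the observed mean r in the null. Contacts are counted
significant at uncorrected p < 0.05, with cohort percentages rounded to
integer percent.

Because no recordings are distributed for this problem, the package
ships a synthetic-session generator with known ground-truth kernels
(96 trials, 2 kHz, 4 monopolar contacts per hemisphere, gamma-distributed
onset intervals with mean/SD 353/134 ms and 411/137 ms for the two
streams, 81% behavioral accuracy), used for parameter-recovery and
calibration testing. See `vignettes/word-onset-tracking.Rmd` for the
full methods account.

## Worked example

```r
library(betatrack)

cfg <- sim_config(n_trials = 24, seed = 7)        # noisy 24-trial session
res <- run_tracking_analysis(config = cfg, n_boot = 50, n_null = 100,
                             per_stream = FALSE, seed = 7)
res
```

```
<tracking_result> 6 contacts, 6 significant at alpha = 0.05
 contact n_trials mean_r_observed    p_joint significant
   L0-L1       20       0.7295002 0.00990099        TRUE
   L1-L2       20       0.6559581 0.00990099        TRUE
   L2-L3       20       0.4988386 0.00990099        TRUE
   R0-R1       20       0.7379076 0.00990099        TRUE
   R1-R2       20       0.6459355 0.00990099        TRUE
   R2-R3       20       0.5020330 0.00990099        TRUE
```

Each row is one bipolar contact (adjacent-contact derivation, three per
hemisphere). `mean_r_observed` is the 5-fold cross-validated correlation
between the predicted and actual beta envelope; `p_joint` is its
empirical p against the interval-preserving shuffle null (with
`n_null = 100`, the smallest attainable p is 1/101 ≈ 0.0099). Here every
contact tracks word onsets, as it should at this simulated
signal-to-noise ratio; 20 of 24 trials survived artifact and
correctness screening. The numbered scripts under `analysis/` run the
same stages at full scale (100 bootstrap / 500 null replicates) and
write their tables under `results/`.

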