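#!/usr/bin/env Rscript
# Multitaper time-frequency analysis of one representative contact:
# 2 s Slepian windows, 4 tapers, percent change from the -1..0 s
# pre-audio baseline, uncorrected t-test mask (visualization only).

library(betatrack)

epochs <- readRDS("scratch/epochs_default.rds")
epochs <- retained_epochs(epochs)
epochs <- decimate_epochs(epochs, 10)      # 2 kHz -> 200 Hz

mt <- multitaper_power(epochs, fmin = 12, fmax = 30, window_s = 2,
                       n_tapers = 4, step_s = 0.05)
tfr <- percent_change(mt, baseline_window = c(-1.56, -0.56))
mask <- baseline_ttest_mask(tfr, alpha = 0.05)

ch <- 2                                    # representative contact L1-L2
speech <- tfr$times > 0 & tfr$times < 2.9
base <- tfr$times >= -1.56 & tfr$times <= -0.56
summary <- data.frame(
  contact = epochs$channels[ch],
  mean_pct_change_speech = mean(tfr$pct[ch, , speech]),
  mean_pct_change_baseline = mean(tfr$pct[ch, , base]),
  frac_masked_speech = mean(mask[ch, , speech]),
  frac_masked_baseline = mean(mask[ch, , base]))
write.table(summary, "results/03_tfr_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Beta-band percent change, contact", epochs$channels[ch], "\n")
print(summary, row.names = FALSE)

# full trial-averaged map of that contact for plotting elsewhere
map <- data.frame(
  time_s = round(rep(tfr$times, each = length(tfr$freqs)), 3),
  freq_hz = rep(tfr$freqs, times = length(tfr$times)),
  pct_change = round(as.vector(tfr$pct[ch, , ]), 2),
  masked = as.vector(mask[ch, , ]))
write.table(map, "results/03_tfr_map_L1-L2.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
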