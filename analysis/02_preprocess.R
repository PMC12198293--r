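#!/usr/bin/env Rscript
# Preprocess the simulated session: bipolar re-referencing (0-1, 1-2, 2-3
# per hemisphere), epoching at (-1.56, 3.18) s around the target word,
# z >= 6 artifact flagging, correct-trial retention. Writes the QC report.

library(betatrack)

session <- readRDS("scratch/session_default.rds")
bip <- make_bipolar(session$recording)
epochs <- epoch_recording(bip, session$events)
epochs <- reject_artifact_trials(epochs, z_threshold = 6)
epochs <- keep_correct_trials(epochs)

qc <- qc_report(epochs)
write.table(qc, "results/02_qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Trials: %d total, %d artifact-flagged, %d incorrect, %d retained\n",
            nrow(qc), sum(qc$rejected), sum(!qc$correct),
            sum(qc$retained)))
saveRDS(epochs, "scratch/epochs_default.rds")
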