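#!/usr/bin/env Rscript
# Spectral screening of component time courses: 57 low-frequency "signal"
# components against 18 flat-spectrum noise components, using the
# low-frequency power fraction (< 0.1 Hz) with the 0.6 threshold.
library(brainstates)

seed <- 1
out <- file.path("results", "analysis")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

raw <- generate_noise_components(57, n_frames = 297, seed = derive_seed(seed, "signal"))
signal <- raw
signal$values <- apply(raw$values, 2, lowpass, cutoff_hz = 0.1, tr = 2)
colnames(signal$values) <- sprintf("net%02d", 1:57)
noise <- generate_noise_components(18, n_frames = 297, seed = derive_seed(seed, "noise"))

verdicts <- screen_components(list(signal, noise), tr = 2)
write.csv(verdicts, file.path(out, "component_screening.csv"), row.names = FALSE)

cat("component screening verdicts:\n")
print(table(verdicts$verdict))
cat(sprintf("signal components: low-frequency ratio %.2f-%.2f\n",
            min(verdicts$low_freq_ratio[1:57]), max(verdicts$low_freq_ratio[1:57])))
cat(sprintf("noise components:  low-frequency ratio %.2f-%.2f (flat spectrum ~0.4)\n",
            min(verdicts$low_freq_ratio[58:75]), max(verdicts$low_freq_ratio[58:75])))
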