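#!/usr/bin/env Rscript
# Strict-clock root-age estimation: fits the penalized least-squares clock to
# the simulated noisy tree using calibrations at three internal nodes (truth-
# centered, sigma 5% of age) and reports the fitted rate, root age, and a
# calibration-aware bootstrap interval, compared against the known 900 Ma
# truth. Also demonstrates the six shipped fossil calibrations.

suppressPackageStartupMessages(library(hgtrace))
tr <- ape::read.tree("results/simulated/clock_tree.nwk")
cal <- read.delim("results/simulated/clock_calibrations.tsv")
ct <- calibrated_tree(tr, cal)
fit <- fit_strict_clock(ct)
print(fit)
ci <- root_age_interval(fit, ct, reps = 200, seed = 1,
                        resample_calibrations = TRUE)
cat(sprintf("root age %.1f Ma (95%% bootstrap interval %.1f-%.1f); truth 900\n",
            fit$root_age, ci[1], ci[2]))
out <- data.frame(rate = fit$rate, root_age_ma = fit$root_age,
                  ci_low = ci[1], ci_high = ci[2], true_root_age = 900)
write.table(out, "results/clock_fit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nshipped fossil calibrations (deepest to shallowest):\n")
print(default_calibrations())
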