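#!/usr/bin/env Rscript
# CDK1 biosensor FLIM-FRET stage: simulate a two-population lifetime stack at
# 500 photons/pixel (untreated ~2.6 ns, drug-responding ~2.0 ns), rebuild the
# lifetime map with background masking, set the midpoint threshold from
# population ROI lifetimes, and classify cells as CDK1-high/low.

suppressMessages(library(stromaquant))
dir.create("results", showWarnings = FALSE)
set.seed(20260921)

# two-region field: left half responding (short lifetime), right untreated
tf <- matrix(0, 48, 96)
tf[, 1:48] <- 2.0
tf[, 49:96] <- 2.6
stack <- gen_flim_stack(tf, photons_per_pixel = 500, bg_photons = 5,
                        seed = 101)
map <- fit_lifetime_map(stack, background = 10)

rec <- data.frame(
  region = c("treated", "untreated"),
  tau_true_ns = c(2.0, 2.6),
  tau_median_ns = c(median(map$tau_ns[, 1:48], na.rm = TRUE),
                    median(map$tau_ns[, 49:96], na.rm = TRUE)),
  tau_sd_ns = c(sd(map$tau_ns[, 1:48], na.rm = TRUE),
                sd(map$tau_ns[, 49:96], na.rm = TRUE)),
  n_pixels = c(sum(!is.na(map$tau_ns[, 1:48])),
               sum(!is.na(map$tau_ns[, 49:96])))
)
rec$rel_err_pct <- 100 * (rec$tau_median_ns - rec$tau_true_ns) / rec$tau_true_ns
write.csv(rec, "results/flim_recovery.csv", row.names = FALSE)

# per-cell classification: ROI lifetimes drawn from the two populations
untreated <- rnorm(200, 2.6, 0.1)
treated <- rnorm(200, 2.1, 0.1)
thr <- midpoint_threshold(untreated, treated)
cls <- data.frame(
  group = c("untreated", "treated"),
  fraction_cdk1_high = c(classify_cdk1(untreated, thr)$fraction_high,
                         classify_cdk1(treated, thr)$fraction_high),
  threshold_ns = as.numeric(thr)
)
write.csv(cls, "results/cdk1_classification.csv", row.names = FALSE)

message(sprintf(
  "Lifetime recovery: %.3f ns (true 2.0), %.3f ns (true 2.6); threshold %.3f ns.",
  rec$tau_median_ns[1], rec$tau_median_ns[2], as.numeric(thr)))
message(sprintf(
  "CDK1-high fractions: untreated %.2f, treated %.2f.",
  cls$fraction_cdk1_high[1], cls$fraction_cdk1_high[2]))
message("Wrote results/flim_recovery.csv and results/cdk1_classification.csv")
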