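#!/usr/bin/env Rscript
# Cohort planning for the orthotopic injection experiment: how many mice per
# group are needed to resolve a drop in local-invasion incidence from ~75%
# to ~25% (SD 20%) at alpha = 0.05 and 80% power, and how power moves with n.

suppressMessages(library(stromaquant))
dir.create("results", showWarnings = FALSE)

n_req <- sample_size(delta = 75 - 25, sd = 20, alpha = 0.05,
                     target_power = 0.80)
tab <- data.frame(n_per_group = 2:10)
tab$power <- vapply(tab$n_per_group, ttest_power, numeric(1),
                    delta = 50, sd = 20, alpha = 0.05)
tab$meets_target <- tab$power >= 0.80
write.csv(tab, "results/power_planning.csv", row.names = FALSE)

message("Smallest cohort reaching 80% power: ", n_req, " mice per group ",
        sprintf("(power %.1f%% at that n).", 100 * tab$power[tab$n_per_group == n_req]))
message("Wrote results/power_planning.csv")
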