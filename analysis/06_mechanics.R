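#!/usr/bin/env Rscript
# Matrix mechanics stage: Hertz spherical-indentation fits of AFM force
# curves over a soft-to-stiff modulus grid (three areas x ten indentations
# per condition, as acquired), and LVE storage modulus from strain sweeps.

suppressMessages(library(stromaquant))
dir.create("results", showWarnings = FALSE)
set.seed(20260921)

afm <- do.call(rbind, lapply(c(soft = 1e3, intermediate = 5e3, stiff = 2e4),
                             function(E) {
  fmax <- max(gen_force_curve(E, noise_sd_pN = 0, seed = 1)$data$force_pN)
  fits <- vapply(1:30, function(i) {
    fc <- gen_force_curve(E, noise_sd_pN = 0.05 * fmax,
                          seed = sample.int(2^31 - 2, 1))
    fit_hertz(fc)$E_pa
  }, numeric(1))
  data.frame(E_true_pa = E, E_mean_pa = mean(fits), E_sd_pa = sd(fits),
             rel_rmse_pct = 100 * sqrt(mean((fits / E - 1)^2)), n_curves = 30)
}))
afm$condition <- rownames(afm)
write.csv(afm, "results/afm_hertz.csv", row.names = FALSE)

rheo <- do.call(rbind, lapply(c(fl_matrix = 120, mt_matrix = 310),
                              function(g0) {
  sweeps <- vapply(1:3, function(i) {
    sw <- gen_strain_sweep(g0, gamma_onset_pct = 1.2, decay_rate = 2,
                           noise_sd = g0 * 0.01,
                           seed = sample.int(2^31 - 2, 1))
    as.numeric(lve_storage_modulus(sw))
  }, numeric(1))
  data.frame(g0_true_pa = g0, gprime_mean_pa = mean(sweeps),
             gprime_sd_pa = sd(sweeps), n_sweeps = 3)
}))
rheo$condition <- rownames(rheo)
write.csv(rheo, "results/rheology_lve.csv", row.names = FALSE)

message(sprintf(
  "Hertz recovery: %.0f/%.0f/%.0f Pa fitted for 1/5/20 kPa truth (worst RMSE %.1f%%).",
  afm$E_mean_pa[1], afm$E_mean_pa[2], afm$E_mean_pa[3],
  max(afm$rel_rmse_pct)))
message(sprintf(
  "LVE storage moduli: %.0f Pa vs %.0f Pa (stiffer remodeled matrix).",
  rheo$gprime_mean_pa[1], rheo$gprime_mean_pa[2]))
message("Wrote results/afm_hertz.csv and results/rheology_lve.csv")
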