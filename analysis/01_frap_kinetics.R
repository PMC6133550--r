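#!/usr/bin/env Rscript
# FRAP binding-kinetics analysis on simulated traces.
#
# Each construct's published dissociation rate and mobile fraction serve as
# ground truth for the simulator; 200 noisy traces per construct are pushed
# through the normalization + fitting pipeline and summarized as mean +/- SEM,
# which shows how faithfully the pipeline recovers fast (N fragment, seconds)
# and slow (full-length, minutes) exchange regimes from realistic data.

suppressPackageStartupMessages(library(axokin))
dir.create("results", showWarnings = FALSE)
seed_base <- 20260101L

constructs <- list(
  # frame_interval / n_post chosen so each curve spans ~2.5 recovery
  # half-lives of its regime
  map7_n  = list(k = 0.27,   A = 74, dt = 1, nf = 60),
  map7_fl = list(k = 0.0062, A = 38, dt = 5, nf = 81),
  map7_dc = list(k = 0.012,  A = 50, dt = 5, nf = 81),
  kif5c_1_560   = list(k = 0.08, A = 65, dt = 1, nf = 120),
  kif5c_335_560 = list(k = 0.14, A = 65, dt = 1, nf = 60)
)

rows <- list()
for (name in names(constructs)) {
  cc <- constructs[[name]]
  fits <- vapply(1:200, function(i) {
    cfg <- frap_sim_config(k_off_true = cc$k, mobile_fraction_true = cc$A,
                           frame_interval = cc$dt, n_post_frames = cc$nf,
                           noise_sd = 0.03 * 1000 * 0.8,
                           seed = seed_base + i)
    fit <- fit_recovery(normalize_trace(simulate_frap_trace(cfg)))
    c(fit$k_off, fit$total_recovery, fit$t_half)
  }, numeric(3))
  k <- mean_sem(fits[1, ]); A <- mean_sem(fits[2, ])
  rows[[name]] <- data.frame(
    construct = name, k_off_true = cc$k, recovery_true = cc$A,
    k_off_fit = k$mean, k_off_sem = k$sem,
    recovery_fit = A$mean, recovery_sem = A$sem,
    t_half_fit = t_half_from_koff(k$mean), n = 200
  )
  seed_base <- seed_base + 1000L
  cat(sprintf("%-14s k_off %.4g (true %.4g)  recovery %.1f%% (true %.0f%%)\n",
              name, k$mean, cc$k, A$mean, cc$A))
}
fit_table <- do.call(rbind, rows)
write.csv(fit_table, "results/frap_fits.csv", row.names = FALSE)

# the half-life identity t1/2 = ln2 / k_off on the published values
ident <- data.frame(
  construct = c("map7_n", "map7_fl", "map7_dc", "kif5c_1_560",
                "kif5c_335_560"),
  published = c("k_off 0.27 1/s", "t_half 112.6 s", "t_half 59.0 s",
                "t_half 9 s", "t_half 5 s"),
  derived = c(round(t_half_from_koff(0.27), 1),
              signif(log(2) / 112.6, 2), signif(log(2) / 59.0, 2),
              signif(log(2) / 9, 1), signif(log(2) / 5, 2))
)
write.csv(ident, "results/frap_kinetic_identities.csv", row.names = FALSE)
cat(sprintf("full-length vs N half-life ratio: %.1f-fold\n", 112.6 / 2.6))
cat("wrote results/frap_fits.csv and results/frap_kinetic_identities.csv\n")
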