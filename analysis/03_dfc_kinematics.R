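#!/usr/bin/env Rscript

# Dorsal forerunner cell migration kinematics on synthetic track sets.
#
# Emulates 3 h live recordings (from 50% epiboly) of a converging,
# vegetal-ward migrating DFC group in a control-like and a
# mutant-like condition (slower drift, weaker convergence), then
# quantifies convergence ratio, migration speed and the migration index.

suppressPackageStartupMessages(library(lrflow))
dir.create("results", showWarnings = FALSE)

conditions <- list(
  control_like = list(drift = 1.0, conv = 0.004, noise = 1.0),
  mutant_like  = list(drift = 0.6, conv = 0.001, noise = 1.0)
)

cat("== DFC migration kinematics (3 h at 3 min intervals, 20 cells) ==\n")
rows <- list()
for (cond in names(conditions)) {
  cfg <- conditions[[cond]]
  # three replicate embryos per condition
  for (emb in 1:3) {
    tr <- simulate_dfc_tracks(n_cells = 20, drift_speed = cfg$drift,
                              convergence_strength = cfg$conv,
                              noise_sd = cfg$noise, duration = 180, dt = 3,
                              seed = 100L * emb + match(cond, names(conditions)))
    ratio <- convergence_ratio(tr)
    speed <- migration_speed(tr)$mean_speed
    # net vegetal-ward displacement of the group centroid as a fraction of a
    # 1000 um embryo axis, starting from the 50%-epiboly position (500 um)
    y_net <- mean(tr$y[tr$t == max(tr$t)]) - mean(tr$y[tr$t == 0])
    idx <- migration_index(min(max(500 + y_net, 0), 1000), 1000)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, embryo = emb, convergence_ratio = ratio,
      migration_speed = speed, migration_index = idx)
    write_track_table(tr, sprintf("results/dfc_%s_embryo%d.csv", cond, emb),
                      time_unit = "minutes")
  }
}
kin <- do.call(rbind, rows)
write.csv(kin, "results/dfc_kinematics.csv", row.names = FALSE)

for (cond in names(conditions)) {
  sub <- kin[kin$condition == cond, ]
  cat(sprintf("  %-12s convergence %.2f +/- %.2f   speed %.2f +/- %.2f um/min   index %.1f%%\n",
              cond, mean(sub$convergence_ratio), sd(sub$convergence_ratio),
              mean(sub$migration_speed), sd(sub$migration_speed),
              mean(sub$migration_index)))
}
cat("\nThe control-like condition converges roughly two-fold over the recording\n")
cat("while the mutant-like condition barely compacts and drifts more slowly,\n")
cat("the pattern the kinematics functions are built to quantify.\n")
cat("\nWrote results/dfc_kinematics.csv and per-embryo track tables\n")
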