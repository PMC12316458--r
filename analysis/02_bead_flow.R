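#!/usr/bin/env Rscript

# Kupffer's-vesicle flow analysis on synthetic imaging data.
#
# Simulates the two bead-motion regimes the organizer exhibits (directed
# vortex flow in a functional vesicle; confined Brownian motion in a
# collapsed one), renders the directed regime into a fluorescence stack,
# runs the full detect -> link -> MSD -> classify -> speed pipeline, and
# writes track tables, MSD curves and a flow summary under results/.

suppressPackageStartupMessages(library(lrflow))
dir.create("results", showWarnings = FALSE)

cat("== Simulating bead regimes (4 Hz, 8 s tracks) ==\n")
flow_tr <- simulate_bead_tracks("directed", n_beads = 200,
                                tangential_speed = 0.96, seed = 11)
still_tr <- simulate_bead_tracks("confined", n_beads = 200,
                                 confinement_radius = 5, seed = 12)
cat(sprintf("  directed: %d beads, ground-truth tangential speed 0.96 um/s\n",
            length(unique(flow_tr$track_id))))
cat(sprintf("  confined: %d beads in a 5 um disc\n",
            length(unique(still_tr$track_id))))
write_track_table(flow_tr, "results/beads_directed_truth.csv")
write_track_table(still_tr, "results/beads_confined_truth.csv")

cat("\n== Rendering and re-tracking the directed regime (SNR 10) ==\n")
ren <- render_image_stack(flow_tr, seed = 11)
cat(sprintf("  stack: %d x %d px, %d frames\n",
            dim(ren$stack$frames)[1], dim(ren$stack$frames)[2],
            dim(ren$stack$frames)[3]))
dets <- detect_spots(ren$stack)
cat(sprintf("  detections: %d (size gate 0.75-1.25 um, top-1%% brightness)\n",
            nrow(dets)))
linked <- link_detections(dets)
cat(sprintf("  linked: %d trajectories (2.5 um gate)\n",
            length(unique(linked$track_id))))
write_track_table(linked, "results/beads_directed_tracked.csv")

sp_true <- mean_bead_speed(flow_tr)
sp_tracked <- mean_bead_speed(linked)
cat(sprintf("  mean bead speed: ground-truth tracks %.5f um/s, pipeline %.5f um/s\n",
            sp_true$mean_speed, sp_tracked$mean_speed))

cat("\n== Ensemble MSD and motion classification (1-8 s tracks) ==\n")
summaries <- list()
for (regime in c("directed", "confined")) {
  tr <- if (regime == "directed") flow_tr else still_tr
  cu <- ensemble_msd(tr)
  cl <- classify_motion(cu)
  sp <- mean_bead_speed(tr)
  cat(sprintf("  %-8s verdict %-9s alpha %.2f  v %.3f um/s  L %.2f um  mean speed %.5f um/s\n",
              regime, cl$verdict, cl$alpha, cl$v, cl$L, sp$mean_speed))
  write.csv(cu, sprintf("results/msd_%s.csv", regime), row.names = FALSE)
  summaries[[regime]] <- data.frame(
    regime = regime, verdict = cl$verdict, alpha = cl$alpha,
    v_fit = cl$v, D_fit = cl$D, L_fit = cl$L, tau_fit = cl$tau,
    mean_speed = sp$mean_speed, n_tracks = sp$n_tracks)
}
flow_summary <- do.call(rbind, summaries)
flow_summary$pipeline_speed <- c(sp_tracked$mean_speed, NA)
write.csv(flow_summary, "results/flow_summary.csv", row.names = FALSE)

cat("\nA functional-organizer regime classifies as directed transport; the\n")
cat("MSD directed-model fit v recovers the imposed tangential speed, while\n")
cat("raw step speeds run slightly higher (they fold in the diffusive step).\n")
cat("The collapsed regime classifies as confined with a fitted size L at the\n")
cat("confinement radius; its raw step speed is mostly Brownian jitter.\n")
cat("\nWrote results/beads_*.csv, results/msd_*.csv, results/flow_summary.csv\n")
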