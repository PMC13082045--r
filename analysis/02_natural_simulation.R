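#!/usr/bin/env Rscript
# Stage 2: muscle-driven tracking simulation of natural (unassisted)
# running at 4 m/s. Solves the half-gait-cycle symmetric tracking problem
# and reports the average energetic cost that the design sweep uses as
# its baseline.

suppressMessages(library(exotendon))

seed <- 1
out_dir <- "results/natural"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

model <- build_default_model()
reference <- generate_reference_gait(model, speed = 4,
                                     stride_duration = 0.7,
                                     n_samples = 31, seed = seed)
cfg <- ocp_config(mesh = 10, n_harm_pelvis = 3, maxiter = 60,
                  seed = seed)

ocp <- build_tracking_problem(model, reference, NULL, cfg)
cat(sprintf("tracking problem: %d mesh intervals, %d decision variables\n",
            ocp$mesh, ocp$n_par))
sol <- solve_tracking(ocp)
print(sol)
cat(sprintf("peak pelvis residual %.0f (N or N m), peak reserve %.0f N m\n",
            sol$peak_pelvis_residual, sol$peak_reserve))

tr <- sol$trajectories
write_sto_mot(timeseries_table(tr$time, tr$coords),
              file.path(out_dir, "states.sto"), name = "coordinates")
write_sto_mot(timeseries_table(tr$time, tr$activations),
              file.path(out_dir, "activations.sto"), name = "activations")
write_sto_mot(timeseries_table(tr$time,
                               cbind(grf_r_x = tr$grf_r[, 1],
                                     grf_r_y = tr$grf_r[, 2],
                                     grf_l_x = tr$grf_l[, 1],
                                     grf_l_y = tr$grf_l[, 2])),
              file.path(out_dir, "grf.mot"), name = "grf")
jsonlite::write_json(list(
  cost_wkg = sol$cost_wkg, cost_gross_wkg = sol$cost_gross_wkg,
  objective = sol$objective, converged = sol$converged,
  peak_pelvis_residual = sol$peak_pelvis_residual,
  peak_reserve = sol$peak_reserve),
  file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
write_manifest(file.path(out_dir, "manifest.json"), "natural_simulation",
               seed, cfg[setdiff(names(cfg), "seed")])
cat("wrote", out_dir, "\n")
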