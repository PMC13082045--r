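#!/usr/bin/env Rscript
# Stage 3: the exotendon design-space sweep. Simulates assisted running
# across the 5 x 5 stiffness x slack-length grid, each design at several
# stride durations (keeping the energetically best), and writes the
# Table-1-style percent-change matrix plus per-design summaries.
#
# At the default mesh this stage solves (25 designs + 1 natural) x
# |stride_scales| tracking problems; with the settings below expect on
# the order of an hour of compute. Reduce `stride_scales` or the grid
# for a quicker pass.

suppressMessages(library(exotendon))

seed <- 1
out_dir <- "results/sweep"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

model <- build_default_model()
reference <- generate_reference_gait(model, speed = 4,
                                     stride_duration = 0.7,
                                     n_samples = 31, seed = seed)
cfg <- ocp_config(mesh = 10, n_harm_pelvis = 3, maxiter = 60,
                  seed = seed)
grid <- design_grid(stride_scales = c(0.90, 0.95, 1.00, 1.05))

sw <- run_sweep(model, reference, grid, cfg, verbose = TRUE)

cat(sprintf("\nnatural baseline: %.3f W/kg (best stride scale %.2f)\n",
            sw$baseline$cost_wkg, sw$baseline$best_scale))
rk <- rank_designs(sw)
cat("predicted-optimal design:\n")
print(rk$optimal[, c("design", "stiffness", "slack_pct", "pct_change",
                     "peak_tension")])
cat("named experimental presets:\n")
print(rk$presets[, c("design", "stiffness", "slack_pct", "pct_change",
                     "peak_tension")])

write_sweep_csv(sw, file.path(out_dir, "percent_change.csv"))
write_sweep_csv(sw, file.path(out_dir, "percent_change_gross.csv"),
                gross = TRUE)
utils::write.csv(sw$table, file.path(out_dir, "sweep_table.csv"),
                 row.names = FALSE)
prof <- do.call(cbind, sw$profiles)
utils::write.csv(data.frame(pct_gait_cycle = seq(0, 100, length.out = 101),
                            prof, check.names = FALSE),
                 file.path(out_dir, "tension_profiles.csv"),
                 row.names = FALSE)
jsonlite::write_json(list(
  baseline = sw$baseline[c("cost_wkg", "cost_gross_wkg", "best_scale")],
  optimal = as.list(rk$optimal),
  presets = rk$presets), file.path(out_dir, "summary.json"),
  auto_unbox = TRUE, digits = NA, na = "null")
write_manifest(file.path(out_dir, "manifest.json"), "design_sweep", seed,
               list(grid = grid[c("stiffness", "slack_pct",
                                  "stride_scales")],
                    mesh = cfg$mesh))
cat("wrote", out_dir, "\n")
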