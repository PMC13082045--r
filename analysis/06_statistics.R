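#!/usr/bin/env Rscript
# Stage 6: paired statistical analyses. In-lab family: each exotendon
# condition vs natural running (Shapiro-Wilk on the differences, paired
# t, Bonferroni over four comparisons). Track family: 5-km time, mean
# heart rate and cadence, exotendon vs natural, Bonferroni over three.

suppressMessages(library(exotendon))

seed <- 1
out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tab_path <- "results/experiment/metabolics_by_trial.csv"
if (!file.exists(tab_path)) {
  stop("run analysis/05_synthetic_experiment.R first", call. = FALSE)
}
tab <- utils::read.csv(tab_path)

inlab <- inlab_stats(tab)
cat("in-lab net-cost comparisons (Bonferroni m = 4):\n")
for (r in inlab) print(r)
write_stats_json(inlab, file.path(out_dir, "inlab_stats.json"))

sessions <- generate_track_sessions(n_runners = 10, seed = seed)
utils::write.csv(sessions, file.path(out_dir, "track_sessions.csv"),
                 row.names = FALSE)
trk <- track_session_compare(sessions)
cat("\n5-km track comparisons (Bonferroni m = 3):\n")
for (r in trk) print(r)
write_stats_json(trk, file.path(out_dir, "track_stats.json"))

write_manifest(file.path(out_dir, "manifest.json"), "statistics", seed,
               list(inlab_m = 4, track_m = 3, alpha = 0.05))
cat("wrote", out_dir, "\n")
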