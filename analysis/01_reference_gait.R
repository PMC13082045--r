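#!/usr/bin/env Rscript
# Stage 1: build the synthetic reference running gait at 4 m/s that the
# tracking simulations follow, and write it out as coordinate/GRF tables.
# The generator produces periodic sagittal-plane kinematics whose contact
# forces (from the model's own smoothed Hunt-Crossley spheres) balance
# body weight over the stride, with the pelvis path integrated from those
# forces so the whole-body center of mass obeys Newton's second law.

suppressMessages(library(exotendon))

seed <- 1
out_dir <- "results/reference"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

model <- build_default_model()
cat(sprintf("model: %d coordinates, %.1f kg, leg length %.2f m\n",
            n_coords(model), model$mass, model$leg_length))

ref <- generate_reference_gait(model, speed = 4, stride_duration = 0.7,
                               n_samples = 101, seed = seed)
w <- diff(ref$time)
wts <- c(w[1] / 2, (w[-1] + w[-length(w)]) / 2, w[length(w)] / 2)
imp <- sum(wts * (ref$grf_r[, 2] + ref$grf_l[, 2]))
cat(sprintf("stride %.2f s at %.1f m/s; duty factor %.2f\n",
            ref$stride_duration, ref$speed, ref$duty_factor))
cat(sprintf("vertical impulse / (m g T) = %.4f; peak vGRF %.0f N (%.2f BW)\n",
            imp / (ref$mass * 9.80665 * ref$stride_duration),
            max(ref$grf_r[, 2]),
            max(ref$grf_r[, 2]) / (ref$mass * 9.80665)))

write_reference(ref, file.path(out_dir, "coordinates.sto"),
                file.path(out_dir, "grf.mot"))
write_model_yaml(model, file.path(out_dir, "model.yaml"))
write_manifest(file.path(out_dir, "manifest.json"), "reference_gait",
               seed, list(speed = 4, stride_duration = 0.7,
                          n_samples = 101))
cat("wrote", out_dir, "\n")
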