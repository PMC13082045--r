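#' Synthetic reference running gait
#'
#' Generates the periodic sagittal-plane joint-coordinate and ground
#' reaction force (GRF) trajectories that the tracking optimization
#' follows, standing in for marker-derived treadmill reference data. The
#' construction works in task space: a pelvis path with exact average
#' forward speed, a stance/swing ankle path built from C2-smooth periodic
#' windows (foot stationary and at ground height during stance), planar
#' two-link inverse kinematics for hip and knee, a prescribed foot-pitch
#' profile for the ankle angle, and a single-peak `sin^2` vertical GRF
#' whose analytic impulse equals body weight times stride duration
#' exactly. Left-leg trajectories are the right-leg trajectories shifted
#' by half a stride.
#'
#' @name reference_gait
NULL

# C2 periodic "swing progress": 0 over stance [0, duty], rising 0 -> 1
# over the swing with zero first/second derivative at both ends
swing_progress <- function(phi, duty) {
  u <- pmin(pmax((phi - duty) / (1 - duty), 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

swing_window <- function(phi, duty) {
  u <- pmin(pmax((phi - duty) / (1 - duty), 0), 1)
  sin(pi * u)^2
}

# smooth monotone 0 -> 1 ramp over [start, start + width], C2 at the ends
smooth_ramp <- function(phi, start, width) {
  u <- pmin(pmax((phi - start) / width, 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

# C1 bump supported on [start, start + width]
bump <- function(phi, start, width) {
  u <- pmin(pmax((phi - start) / width, 0), 1)
  sin(pi * u)^2
}

#' Reference data container
#'
#' @param time strictly increasing time grid, s.
#' @param coords matrix of tracked coordinate trajectories (rows = time,
#'   named columns), rad / m.
#' @param grf_r,grf_l per-foot GRF matrices (columns fore-aft, vertical),
#'   N.
#' @param speed running speed, m/s.
#' @param stride_duration natural stride duration, s.
#' @param mass subject/model mass, kg.
#' @param duty_factor stance fraction of the stride.
#' @return a `reference_data` object.
#' @export
reference_data <- function(time, coords, grf_r, grf_l, speed,
                           stride_duration, mass, duty_factor = NA_real_) {
  if (any(diff(time) <= 0)) stopf("reference time grid must increase")
  if (nrow(coords) != length(time) || nrow(grf_r) != length(time) ||
      nrow(grf_l) != length(time)) {
    stopf("reference trajectories must share the time grid")
  }
  if (any(grf_r[, 2] < 0) || any(grf_l[, 2] < 0)) {
    stopf("vertical GRF must be non-negative")
  }
  structure(list(time = time, coords = coords, grf_r = grf_r,
                 grf_l = grf_l, speed = speed,
                 stride_duration = stride_duration, mass = mass,
                 duty_factor = duty_factor),
            class = "reference_data")
}

#' Generate a synthetic reference running gait
#'
#' @param model a `skeleton_model` (segment lengths and mass are read
#'   from it).
#' @param speed target running speed, m/s (> 0).
#' @param stride_duration stride duration, s (> 0).
#' @param duty_factor stance fraction per leg (default 0.30; chosen so a
#'   0.92 m leg can span the stance hip travel at 4 m/s without
#'   over-extension).
#' @param n_samples samples over one stride (first sample = right heel
#'   strike).
#' @param seed integer seed; with `jitter > 0` it perturbs the shape
#'   harmonics deterministically, emulating subject-to-subject
#'   variability. The generator is a pure function of its arguments.
#' @param jitter relative amplitude of the seeded shape perturbation.
#' @return a [reference_data()] object; attribute `"phase"` holds the
#'   stride phase of each sample.
#' @export
generate_reference_gait <- function(model, speed = 4, stride_duration = 0.7,
                                    duty_factor = 0.30, n_samples = 101,
                                    seed = 0, jitter = 0) {
  if (speed <= 0 || stride_duration <= 0) {
    stopf("speed and stride duration must be positive")
  }
  Tst <- stride_duration
  phi <- seq(0, 1, length.out = n_samples)
  time <- phi * Tst
  nq <- n_coords(model)
  cn <- coord_names(model)
  Q <- matrix(0, n_samples, nq, dimnames = list(NULL, cn))

  mass <- model$mass
  L1 <- model$segments$length[model$segments$name == "thigh_r"]
  L2 <- model$segments$length[model$segments$name == "shank_r"]
  hip_dy <- model$joints$loc_y[model$joints$name == "hip_r"]
  foot_h <- -model$points$y[model$points$name == "heel_r"]
  ankle_h <- foot_h + 0.035          # sphere bottoms touch the ground

  jit <- function(x, stream) {
    if (jitter <= 0) return(x)
    set.seed(derive_seed(seed, paste0("gait_", stream)))
    x * (1 + jitter * stats::rnorm(length(x)))
  }

  # pelvis path: double integration of the stance forces, with drift
  # corrections enforcing exact periodicity and average speed
  integrate_path <- function(acc, v_mean) {
    v <- pracma::cumtrapz(time, acc)[, 1]
    v <- v - (time / Tst) * (v[n_samples] - v[1])      # periodic rate
    v <- v - sum(trapz_weights(time) * v) / Tst + v_mean
    p <- pracma::cumtrapz(time, v)[, 1]
    p - (time / Tst) * (p[n_samples] - p[1] - v_mean * Tst)
  }
  pelvis_h <- jit(0.91, "h") * (L1 + L2 + ankle_h) - hip_dy
  # provisional pelvis path from an analytic single-peak template; the
  # final path below integrates the contact-model forces
  A_grf <- mass * GRAVITY / duty_factor
  tmpl_y <- function(phi_leg) {
    A_grf * sin(pi * pmin(phi_leg / duty_factor, 1))^2 *
      (phi_leg < duty_factor)
  }
  ty <- integrate_path((tmpl_y(phi %% 1) + tmpl_y((phi + 0.5) %% 1)) /
                         mass - GRAVITY, 0)
  Q[, "pelvis_ty"] <- pelvis_h + ty - sum(trapz_weights(time) * ty) / Tst
  Q[, "pelvis_tx"] <- speed * time
  Q[, "pelvis_tilt"] <- jit(-0.08, "tilt") + 0.02 * sin(4 * pi * phi)

  stride_len <- speed * Tst
  roll <- jit(0.12, "roll")           # forward ankle travel beyond the pivot
  lead <- 0.47 * (stride_len * duty_factor - roll)  # reach at touchdown

  mtp_x <- model$joints$loc_x[model$joints$name == "mtp_r"]

  leg_angles <- function(phi_leg, dip_scale = 1) {
    # ankle task-space path for a leg whose heel strike is at phi_leg = 0;
    # per-stride ankle advance = roll (stance) + stride_len - roll (swing)
    # ground foot pitch: flat at contact, plantarflexing through push-off
    pitch <- -0.35 * bump(phi_leg, 0.55 * duty_factor, 0.9 * duty_factor)
    # the ankle pivots about the metatarsophalangeal contact through
    # push-off (exact pivot geometry), with extra stance roll and the
    # swing recovery carrying the rest of the per-stride advance
    pivot_dx <- mtp_x * (1 - cos(pitch)) - foot_h * sin(pitch)
    # roll split to the lightly loaded edges of stance so sliding
    # friction stays small where the normal load peaks
    P <- roll * (0.5 * smooth_ramp(phi_leg, 0, 0.25 * duty_factor) +
                   0.5 * smooth_ramp(phi_leg, 0.8 * duty_factor,
                                     0.45 * duty_factor)) +
      (stride_len - roll) * swing_progress(phi_leg, duty_factor) +
      pivot_dx
    ax <- lead + P - stride_len * phi_leg + speed * time
    sphere_r <- ankle_h - foot_h
    # smooth sin^2 stance penetration (bounded acceleration at
    # touchdown); depth seeded from the Hertz law over ~3 loaded
    # spheres and rescaled below until the contact-model impulse
    # balances body weight
    k_hz <- 4 / 3 * 1e7 * sqrt(0.035)
    u_st <- pmin(phi_leg / duty_factor, 1)
    dip <- dip_scale *
      (mass * GRAVITY / duty_factor / (3 * k_hz))^(2 / 3) *
      sin(pi * u_st)^2
    ay <- sphere_r + mtp_x * sin(-pitch) + foot_h * cos(pitch) - dip +
      jit(0.09, "clr") * swing_window(phi_leg, duty_factor) +
      0.09 * bump(phi_leg, 0.85 * duty_factor, 0.55)
    tilt <- Q[, "pelvis_tilt"]
    hx <- Q[, "pelvis_tx"] - hip_dy * sin(tilt)
    hy <- Q[, "pelvis_ty"] + hip_dy * cos(tilt)
    dx <- ax - hx; dy <- ay - hy
    r <- sqrt(dx * dx + dy * dy)
    # smooth soft cap on leg extension: asymptotes below full extension
    # so the inverse kinematics stay C2 (a hard clamp puts near-impulsive
    # knee accelerations into the reference)
    rcap <- 0.985 * (L1 + L2); wcap <- 0.015
    r <- r - wcap * log1p(exp((r - rcap) / wcap))
    phid <- atan2(dx, -dy)
    gam <- acos(pmin(pmax((L1^2 + r^2 - L2^2) / (2 * L1 * r), -1), 1))
    beta <- acos(pmin(pmax((L1^2 + L2^2 - r^2) / (2 * L1 * L2), -1), 1))
    theta_t <- phid + gam
    knee <- -(pi - beta)
    hip <- theta_t - tilt
    theta_s <- theta_t + knee
    # foot orientation: tracks the ground pitch while the foot is loaded,
    # hangs from the shank with mild dorsiflexion through swing
    w_st <- 1 - swing_window(phi_leg, duty_factor)
    ankle <- w_st * (pitch - theta_s) +
      (1 - w_st) * jit(0.10, "ank")
    # toes stay flat on the ground through push-off
    mtp <- -pitch
    list(hip = hip, knee = knee, ankle = ankle, mtp = mtp)
  }

  fill_legs <- function(dip_scale) {
    right <- leg_angles(phi %% 1, dip_scale)
    left <- leg_angles((phi + 0.5) %% 1, dip_scale)
    Q[, "hip_flexion_r"] <<- right$hip
    Q[, "knee_angle_r"] <<- right$knee
    Q[, "ankle_angle_r"] <<- right$ankle
    Q[, "mtp_angle_r"] <<- right$mtp
    Q[, "hip_flexion_l"] <<- left$hip
    Q[, "knee_angle_l"] <<- left$knee
    Q[, "ankle_angle_l"] <<- left$ankle
    Q[, "mtp_angle_l"] <<- left$mtp
  }
  Q[, "lumbar_extension"] <- -0.12 + 0.03 * sin(4 * pi * (phi - 0.1))
  arm_amp <- jit(0.30, "arm")
  Q[, "arm_flex_r"] <- -arm_amp * cos(2 * pi * phi)      # anti-phase w/ leg
  Q[, "arm_flex_l"] <- arm_amp * cos(2 * pi * phi)
  Q[, "elbow_flex_r"] <- 1.3 + 0.15 * sin(2 * pi * phi)
  Q[, "elbow_flex_l"] <- 1.3 - 0.15 * sin(2 * pi * phi)

  # reference GRFs come from the contact model evaluated on the
  # reference kinematics, so the tracked forces and the model's own
  # contact law agree at the reference; the penetration depth is
  # rescaled until the vertical impulse balances body weight over the
  # stride, and the pelvis path is re-integrated from those forces
  spline_rates <- function() {
    apply(Q, 2, function(y) {
      y2 <- y
      sl <- 0
      if (abs(y2[n_samples] - y2[1]) > 1e-9) {          # secular (tx)
        sl <- (y2[n_samples] - y2[1]) / Tst
        y2 <- y2 - sl * time
      }
      y2[n_samples] <- y2[1]                 # exact periodic closure
      stats::splinefun(time, y2, method = "periodic")(time, deriv = 1) + sl
    })
  }
  # Coupled fixed point: (a) the penetration depth is rescaled until the
  # contact-model vertical impulse balances body weight, and (b) the
  # pelvis is placed so the whole-body COM follows the double integral
  # of the contact forces (Newton's second law; ballistic in flight).
  # The two interact weakly through the soft leg-extension cap, so they
  # are iterated together.
  wts <- trapz_weights(time)
  target <- mass * GRAVITY * Tst
  model_com <- function() {
    bk <- body_kinematics(model, Q)
    cx <- 0; cy <- 0
    for (k in seq_along(model$bodies)) {
      cx <- cx + model$bodies[[k]]$mass * bk[[k]]$c[, 1]
      cy <- cy + model$bodies[[k]]$mass * bk[[k]]$c[, 2]
    }
    cbind(cx, cy) / mass
  }
  dip_scale <- 1
  grf <- NULL
  for (it in 1:8) {
    fill_legs(dip_scale)
    grf <- foot_grf(model, Q, spline_rates())
    imp <- sum(wts * (grf$r[, 2] + grf$l[, 2]))
    ty_target <- integrate_path((grf$r[, 2] + grf$l[, 2]) / mass -
                                  GRAVITY, 0)
    tx_target <- integrate_path((grf$r[, 1] + grf$l[, 1]) / mass, speed)
    com <- model_com()
    err_y <- (ty_target - sum(wts * ty_target) / Tst) -
      (com[, 2] - sum(wts * com[, 2]) / Tst)
    err_x <- tx_target - com[, 1]
    err_x <- err_x - sum(wts * err_x) / Tst
    Q[, "pelvis_ty"] <- Q[, "pelvis_ty"] + err_y
    Q[, "pelvis_tx"] <- Q[, "pelvis_tx"] + err_x
    done <- abs(imp / target - 1) < 0.004 &&
      max(abs(err_y), abs(err_x)) < 1e-4
    dip_scale <- dip_scale * (target / imp)^(2 / 3)
    if (done) break
  }
  fill_legs(dip_scale)
  grf <- foot_grf(model, Q, spline_rates())

  ref <- reference_data(time, Q, grf$r, grf$l, speed, Tst, mass,
                        duty_factor)
  attr(ref, "phase") <- phi
  attr(ref, "dip_scale") <- dip_scale
  ref
}

#' Rescale a reference gait to a new stride duration
#'
#' Time-normalizes the reference and maps it onto a scaled stride
#' duration: joint angles keep their shape over the stride, the pelvis
#' forward translation is adjusted so the average speed is preserved
#' (stride length scales with duration), and GRF shapes are kept (their
#' impulse then scales with the duration, preserving the
#' impulse-momentum balance).
#'
#' @param ref a [reference_data()].
#' @param scale stride-duration multiplier (> 0), e.g. 0.9-1.05.
#' @return a rescaled `reference_data`.
#' @export
rescale_reference <- function(ref, scale) {
  if (scale <= 0) stopf("stride-duration scale must be positive")
  if (scale == 1) return(ref)
  phi <- ref$time / ref$stride_duration
  new_T <- ref$stride_duration * scale
  coords <- ref$coords
  coords[, "pelvis_tx"] <- coords[, "pelvis_tx"] +
    ref$speed * ref$stride_duration * (scale - 1) * phi
  reference_data(phi * new_T, coords, ref$grf_r, ref$grf_l, ref$speed,
                 new_T, ref$mass, ref$duty_factor)
}
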