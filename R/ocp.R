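#' Muscle-driven tracking optimization
#'
#' The tracking problem follows the reference kinematics and GRFs over
#' half a gait cycle (with left-right symmetry) while minimizing muscle
#' effort: the running cost integrates weighted squared kinematic
#' deviations, body-weight-normalized GRF deviations, squared muscle
#' activations and squared per-muscle metabolic rates.
#'
#' Transcription: coordinate trajectories are parameterized as the
#' reference plus periodic Fourier deviations whose structure builds the
#' half-cycle symmetry in exactly (left-leg deviations are the right-leg
#' deviations shifted by half a stride; pelvis/lumbar deviations have
#' half-stride period; forward-translation deviations are periodic, so
#' the average-speed constraint holds by construction). At each mesh
#' node, smoothed contact and exotendon forces are evaluated from the
#' candidate kinematics, inverse dynamics yields the required joint
#' torques, and a static muscle-redundancy problem resolves activations;
#' torque left at the unactuated pelvis coordinates (residual forces)
#' and any torque the muscles cannot produce (reserves) are penalized.
#' Because every objective term is a square, the transcribed problem is
#' a nonlinear least-squares problem and is solved with
#' Levenberg-Marquardt. Dynamics at actuated coordinates are satisfied
#' identically by construction (inverse dynamics); the reported dynamics
#' residual is the pelvis/reserve remainder.
#'
#' @name tracking_ocp
NULL

#' Tracking-problem configuration
#'
#' @param w_kin kinematic tracking weight (1e-6).
#' @param w_grf GRF tracking weight (14), applied to body-weight
#'   normalized errors.
#' @param w_act activation weight (8.0).
#' @param w_met metabolic weight (4e-5), applied to squared per-muscle
#'   metabolic rates in W.
#' @param mesh mesh intervals per half cycle (>= 10).
#' @param n_harm_leg,n_harm_pelvis Fourier harmonics of the leg and
#'   pelvis/lumbar deviation bases.
#' @param w_residual penalty weight on body-weight-normalized pelvis
#'   residual forces.
#' @param w_reserve penalty weight on normalized reserve torques.
#' @param w_impulse weight on the cycle-level momentum balance (vertical
#'   contact impulse = body weight x cycle time; zero net fore-aft
#'   impulse).
#' @param exo_smoothing exotendon tension softplus width inside the
#'   optimizer, m (the analysis path uses the exact piecewise law).
#' @param basal_wkg whole-body basal rate added to reported gross cost,
#'   W/kg.
#' @param maxiter,ftol,ptol,epsfcn Levenberg-Marquardt controls; the
#'   forward-difference step implied by `epsfcn` is kept large enough to
#'   average over the muscle-redundancy active-set kinks.
#' @param stride_scale stride-duration multiplier bookkeeping field.
#' @param seed seed for any stochastic initial-guess perturbation (the
#'   default guess is deterministic).
#' @return an `ocp_config` list; also carries the term counts
#'   (`n_coord`, `n_grf`, `n_musc`) once bound to a problem.
#' @export
ocp_config <- function(w_kin = 1e-6, w_grf = 14, w_act = 8, w_met = 4e-5,
                       mesh = 15, n_harm_leg = 3, n_harm_pelvis = 2,
                       w_residual = 200, w_reserve = 50,
                       w_impulse = 2000,
                       exo_smoothing = 1e-3, basal_wkg = 1.2,
                       maxiter = 60, ftol = 1e-10, ptol = 1e-8,
                       epsfcn = 1e-4, stride_scale = 1, seed = 0) {
  if (any(c(w_kin, w_grf, w_act, w_met) < 0)) {
    stopf("objective weights must be non-negative")
  }
  if (mesh < 10) stopf("mesh must have at least 10 intervals")
  structure(as.list(environment()), class = "ocp_config")
}

#' Closed-form decision-variable count
#'
#' Deviation-basis coefficients: five mirrored limb coordinates (hip,
#' knee, ankle, shoulder, elbow) x `(2 n_harm_leg + 1)` (shared between
#' sides by symmetry), plus `2 n_harm_pelvis` for the forward
#' translation (no constant term) and `(2 n_harm_pelvis + 1)` each for
#' pelvis height, pelvis tilt and lumbar extension.
#'
#' @param config an [ocp_config()].
#' @return integer.
#' @export
count_decision_variables <- function(config) {
  5L * (2L * config$n_harm_leg + 1L) +
    2L * config$n_harm_pelvis + 3L * (2L * config$n_harm_pelvis + 1L)
}

# Fourier deviation basis on stride phase phi (period `period` strides).
# Returns value/derivative/second-derivative matrices w.r.t. time.
fourier_basis <- function(phi, Tcycle, H, period = 1, constant = TRUE) {
  cols <- list(); d1 <- list(); d2 <- list()
  if (constant) {
    cols[[1]] <- rep(1, length(phi)); d1[[1]] <- rep(0, length(phi))
    d2[[1]] <- rep(0, length(phi))
  }
  for (h in seq_len(H)) {
    w <- 2 * pi * h / (period * Tcycle)
    arg <- w * phi * Tcycle
    cols <- c(cols, list(cos(arg), sin(arg)))
    d1 <- c(d1, list(-w * sin(arg), w * cos(arg)))
    d2 <- c(d2, list(-w^2 * cos(arg), -w^2 * sin(arg)))
  }
  list(B = do.call(cbind, cols), Bd = do.call(cbind, d1),
       Bdd = do.call(cbind, d2))
}

# periodic spline evaluation of reference coordinates (+ derivatives)
reference_at <- function(ref, t_eval) {
  Tc <- ref$stride_duration
  n <- length(ref$time)
  cn <- colnames(ref$coords)
  Q <- matrix(0, length(t_eval), ncol(ref$coords),
              dimnames = list(NULL, cn))
  Qd <- Q; Qdd <- Q
  tmod <- t_eval %% Tc
  for (j in seq_len(ncol(ref$coords))) {
    y <- ref$coords[, j]
    slope <- 0
    if (cn[j] == "pelvis_tx") { slope <- ref$speed; y <- y - slope * ref$time }
    y[n] <- y[1]                      # enforce exact periodicity
    sf <- stats::splinefun(ref$time, y, method = "periodic")
    Q[, j] <- sf(tmod) + slope * t_eval
    Qd[, j] <- sf(tmod, deriv = 1) + slope
    Qdd[, j] <- sf(tmod, deriv = 2)
  }
  interp_grf <- function(G) {
    cbind(stats::approx(ref$time, G[, 1], xout = tmod, rule = 2)$y,
          stats::approx(ref$time, G[, 2], xout = tmod, rule = 2)$y)
  }
  list(Q = Q, Qd = Qd, Qdd = Qdd,
       grf_r = interp_grf(ref$grf_r), grf_l = interp_grf(ref$grf_l))
}

#' Build a muscle-driven tracking problem
#'
#' @param model a `skeleton_model`.
#' @param reference a [reference_data()] (already rescaled to the stride
#'   duration being simulated).
#' @param exotendon an [exotendon_spec()] or `NULL` for natural running
#'   (a zero-stiffness spec is equivalent to no device).
#' @param config an [ocp_config()].
#' @param muscle_params optional muscle table (default
#'   [default_muscle_params()]).
#' @return an `ocp` object holding the mesh, deviation-basis structure,
#'   reference samples, symmetry map, term counts (`n_coord`, `n_grf`,
#'   `n_musc`), decision-variable names (`par_names`) and the residual
#'   function used by [solve_tracking()].
#' @export
build_tracking_problem <- function(model, reference, exotendon = NULL,
                                   config = ocp_config(),
                                   muscle_params = default_muscle_params()) {
  Tc <- reference$stride_duration
  n_t <- 2L * config$mesh + 1L          # nodes over the full cycle
  phi <- seq(0, 1, length.out = n_t)
  t_nodes <- phi * Tc
  wt <- trapz_weights(t_nodes)
  refn <- reference_at(reference, t_nodes)
  cn <- coord_names(model)
  paths <- muscle_paths(muscle_params, model)
  sym <- symmetry_map(model)

  H1 <- config$n_harm_leg; H2 <- config$n_harm_pelvis
  leg_basis_r <- fourier_basis(phi, Tc, H1, period = 1)
  leg_basis_l <- fourier_basis((phi + 0.5) %% 1, Tc, H1, period = 1)
  pel_basis <- fourier_basis(phi, Tc, H2, period = 0.5)
  tx_basis <- fourier_basis(phi, Tc, H2, period = 0.5, constant = FALSE)
  # per-coefficient path bounds keep deviations within a physiological
  # corridor around the reference (the transcription's path constraints)
  blocks <- list(
    list(coords = c("hip_flexion_r", "hip_flexion_l"),
         bases = list(leg_basis_r, leg_basis_l), n = 2 * H1 + 1,
         tag = "hip", bound = 0.35),
    list(coords = c("knee_angle_r", "knee_angle_l"),
         bases = list(leg_basis_r, leg_basis_l), n = 2 * H1 + 1,
         tag = "knee", bound = 0.35),
    list(coords = c("ankle_angle_r", "ankle_angle_l"),
         bases = list(leg_basis_r, leg_basis_l), n = 2 * H1 + 1,
         tag = "ankle", bound = 0.35),
    list(coords = c("arm_flex_r", "arm_flex_l"),
         bases = list(leg_basis_r, leg_basis_l), n = 2 * H1 + 1,
         tag = "arm", bound = 0.6),
    list(coords = c("elbow_flex_r", "elbow_flex_l"),
         bases = list(leg_basis_r, leg_basis_l), n = 2 * H1 + 1,
         tag = "elbow", bound = 0.6),
    list(coords = "pelvis_tx", bases = list(tx_basis), n = 2 * H2,
         tag = "pelvis_tx", bound = 0.06),
    list(coords = "pelvis_ty", bases = list(pel_basis), n = 2 * H2 + 1,
         tag = "pelvis_ty", bound = 0.06),
    list(coords = "pelvis_tilt", bases = list(pel_basis), n = 2 * H2 + 1,
         tag = "pelvis_tilt", bound = 0.25),
    list(coords = "lumbar_extension", bases = list(pel_basis),
         n = 2 * H2 + 1, tag = "lumbar", bound = 0.25))
  n_par <- as.integer(sum(vapply(blocks, `[[`, 0, "n")))
  stopifnot(n_par == count_decision_variables(config))
  par_names <- unlist(lapply(blocks, function(b) {
    paste0(b$tag, "_c", seq_len(b$n))
  }))
  par_bound <- unlist(lapply(blocks, function(b) rep(b$bound, b$n)))

  tracked <- which(!model$coords$locked)
  bw <- model$mass * GRAVITY
  Lref <- model$leg_length
  mtp_idx <- match(c("mtp_angle_r", "mtp_angle_l"), cn)
  pelvis_idx <- match(c("pelvis_tx", "pelvis_ty", "pelvis_tilt"), cn)
  pelvis_scale <- c(bw, bw, bw * Lref)
  sphere <- contact_sphere_spec()
  exo_active <- !is.null(exotendon) && exotendon$stiffness > 0

  deviations <- function(par) {
    dQ <- matrix(0, n_t, length(cn), dimnames = list(NULL, cn))
    dQd <- dQ; dQdd <- dQ
    off <- 0L
    for (b in blocks) {
      th <- par[off + seq_len(b$n)]
      for (k in seq_along(b$coords)) {
        j <- match(b$coords[k], cn)
        dQ[, j] <- dQ[, j] + drop(b$bases[[k]]$B %*% th)
        dQd[, j] <- dQd[, j] + drop(b$bases[[k]]$Bd %*% th)
        dQdd[, j] <- dQdd[, j] + drop(b$bases[[k]]$Bdd %*% th)
      }
      off <- off + b$n
    }
    list(dQ = dQ, dQd = dQd, dQdd = dQdd)
  }

  evaluate <- function(par) {
    d <- deviations(par)
    Q <- refn$Q + d$dQ; Qd <- refn$Qd + d$dQd; Qdd <- refn$Qdd + d$dQdd
    grf <- foot_grf(model, Q, Qd, sphere)
    pf <- grf$per_sphere
    tension <- rep(0, n_t); dist <- rep(NA_real_, n_t)
    if (exo_active) {
      ex <- exotendon_generalized_forces(model, Q, exotendon,
                                         smoothing = config$exo_smoothing)
      pf <- c(pf, ex$point_forces)
      tension <- ex$tension
      dist <- ex$distance
    } else if (!is.null(exotendon)) {
      dist <- anchor_distance(model, Q, exotendon)
    }
    passive <- passive_joint_torques(model, Q, Qd)
    tau_req <- inverse_dynamics(model, Q, Qd, Qdd, point_forces = pf,
                                coord_torques = passive)
    mtuk <- mtu_kinematics(paths, Q, Qd)
    red <- resolve_muscle_activations(tau_req, mtuk, muscle_params, paths,
                                      model, config$w_act, config$w_met)
    list(Q = Q, Qd = Qd, Qdd = Qdd, grf = grf, tau_req = tau_req,
         red = red, tension = tension, distance = dist, passive = passive)
  }

  residuals <- function(par) {
    ev <- evaluate(par)
    sw <- sqrt(wt)
    res_kin <- sqrt(config$w_kin) * sw * (ev$Q[, tracked] -
                                            refn$Q[, tracked])
    res_grf <- sqrt(config$w_grf) * sw *
      cbind(ev$grf$r - refn$grf_r, ev$grf$l - refn$grf_l) / bw
    res_act <- sqrt(config$w_act) * sw * ev$red$activations
    res_met <- sqrt(config$w_met) * sw * ev$red$edot
    res_pel <- sqrt(config$w_residual) * sw *
      sweep(ev$tau_req[, pelvis_idx, drop = FALSE], 2, pelvis_scale, `/`)
    res_resv <- sqrt(config$w_reserve) * sw *
      cbind(ev$red$reserve, ev$tau_req[, mtp_idx, drop = FALSE]) /
      (bw * Lref)
    # periodic momentum balance: over one cycle the contact impulse must
    # equal the gravitational impulse (vertical) and vanish (fore-aft);
    # these are the time-integrals of the pelvis residuals and are
    # enforced with their own strong weight
    fy <- ev$grf$r[, 2] + ev$grf$l[, 2]
    fx <- ev$grf$r[, 1] + ev$grf$l[, 1]
    Tcyc <- sum(wt)
    res_imp <- sqrt(config$w_impulse) *
      c(sum(wt * fy) / (bw * Tcyc) - 1, sum(wt * fx) / (bw * Tcyc))
    c(kin = as.numeric(res_kin), grf = as.numeric(res_grf),
      act = as.numeric(res_act), met = as.numeric(res_met),
      pelvis = as.numeric(res_pel), reserve = as.numeric(res_resv),
      impulse = as.numeric(res_imp))
  }

  structure(list(
    model = model, reference = reference, exotendon = exotendon,
    config = config, muscle_params = muscle_params, paths = paths,
    mesh = config$mesh, n_nodes = n_t, t_nodes = t_nodes, phi = phi,
    weights_t = wt, refn = refn, blocks = blocks, n_par = n_par,
    par_names = par_names, par_bound = par_bound, symmetry = sym,
    n_coord = length(tracked), n_grf = 4L, n_musc = nrow(muscle_params),
    deviations = deviations, evaluate = evaluate, residuals = residuals
  ), class = "ocp")
}

#' @export
print.ocp <- function(x, ...) {
  cat(sprintf(
    "<tracking ocp> %d mesh intervals/half cycle, %d nodes, %d decision vars, %s\n",
    x$mesh, x$n_nodes, x$n_par,
    if (is.null(x$exotendon)) "natural" else x$exotendon$name))
  invisible(x)
}

#' Evaluate the tracking objective on given trajectories
#'
#' Trapezoidal quadrature of the running cost
#' `sum w_kin dq^2 + sum w_grf dGRF^2 + sum w_act a^2 + sum w_met Edot^2`
#' on the trajectory's own time grid (for smooth periodic integrands on
#' a uniform grid this quadrature is spectrally accurate). GRF errors
#' are body-weight normalized.
#'
#' @param trajectories list with `time`, `coords` (matrix), `grf_r`,
#'   `grf_l`, `activations`, `edot`.
#' @param reference a [reference_data()] sampled on the same time grid
#'   (or a list with `coords`, `grf_r`, `grf_l` on that grid).
#' @param config an [ocp_config()].
#' @param mass body mass for the GRF normalization (taken from
#'   `reference$mass` if present).
#' @return list with `total` and the per-term breakdown `kin`, `grf`,
#'   `act`, `met` (the breakdown sums to the total).
#' @export
evaluate_objective <- function(trajectories, reference, config = ocp_config(),
                               mass = NULL) {
  tt <- trajectories$time
  if (length(tt) != nrow(reference$coords)) {
    stopf("trajectory and reference grids differ (%d vs %d samples)",
          length(tt), nrow(reference$coords))
  }
  mass <- mass %||% reference$mass
  bw <- mass * GRAVITY
  w <- trapz_weights(tt)
  term <- function(M) sum(w * rowSums(M * M))
  kin <- config$w_kin * term(trajectories$coords - reference$coords)
  grf <- config$w_grf * term(cbind(trajectories$grf_r - reference$grf_r,
                                   trajectories$grf_l - reference$grf_l) / bw)
  act <- config$w_act * term(trajectories$activations)
  met <- config$w_met * term(trajectories$edot)
  list(total = kin + grf + act + met, kin = kin, grf = grf, act = act,
       met = met)
}

#' Solve the tracking problem
#'
#' Levenberg-Marquardt on the deviation coefficients, starting from the
#' reference kinematics (all deviations zero). Deterministic for a given
#' configuration and seed.
#'
#' @param ocp an `ocp` from [build_tracking_problem()].
#' @param par0 optional initial coefficients (default zeros).
#' @return an `ocp_solution`: full-cycle `trajectories` (time, coords,
#'   speeds, activations = excitations, GRFs, per-muscle metabolic rates,
#'   exotendon tension and anchor distance), `half` (first half cycle),
#'   `objective` (Eq-style terms + penalty breakdown; terms sum to
#'   `total`), `cost_wkg` (muscle-only average metabolic cost),
#'   `cost_gross_wkg` (plus whole-body basal), `par`, `converged`,
#'   `info`, `residual_norms` and diagnostics (peak pelvis residual
#'   force/moment, peak reserve torque).
#' @export
solve_tracking <- function(ocp, par0 = NULL, max_restarts = 1) {
  cfg <- ocp$config
  par0 <- par0 %||% rep(0, ocp$n_par)
  run <- function(p) minpack.lm::nls.lm(
    par = p, fn = ocp$residuals,
    lower = -ocp$par_bound, upper = ocp$par_bound,
    control = minpack.lm::nls.lm.control(
      maxiter = cfg$maxiter, ftol = cfg$ftol, ptol = cfg$ptol,
      factor = 10, epsfcn = cfg$epsfcn %||% 1e-4,
      maxfev = 200 * (ocp$n_par + 1), nprint = 0))
  fit <- run(par0)
  # Levenberg-Marquardt tends to satisfy its step tolerance before the
  # damping has fully relaxed on this landscape; a bounded number of
  # restarts polishes the solution (stationarity under restarts is at
  # the 1e-3 relative level, reported in the methods vignette)
  for (r in seq_len(max_restarts)) {
    fit2 <- run(fit$par)
    rel <- (fit$deviance - fit2$deviance) / max(fit$deviance, 1e-300)
    if (fit2$deviance <= fit$deviance) fit <- fit2
    if (rel < 1e-4) break
  }
  build_solution(ocp, fit$par, fit)
}

build_solution <- function(ocp, par, fit = NULL) {
  ev <- ocp$evaluate(par)
  res <- ocp$residuals(par)
  seg <- sub("[0-9]+$", "", names(res))
  norms2 <- tapply(res^2, seg, sum)
  model <- ocp$model
  Tc <- ocp$reference$stride_duration
  traj <- list(time = ocp$t_nodes, coords = ev$Q, speeds = ev$Qd,
               activations = ev$red$activations,
               excitations = ev$red$activations,
               grf_r = ev$grf$r, grf_l = ev$grf$l, edot = ev$red$edot,
               tension = ev$tension, distance = ev$distance,
               stride_duration = Tc, speed = ocp$reference$speed)
  nh <- ocp$mesh + 1L
  half <- list(time = ocp$t_nodes[1:nh],
               coords = ev$Q[1:nh, , drop = FALSE],
               speeds = ev$Qd[1:nh, , drop = FALSE],
               activations = ev$red$activations[1:nh, , drop = FALSE],
               grf_r = ev$grf$r[1:nh, , drop = FALSE],
               grf_l = ev$grf$l[1:nh, , drop = FALSE],
               stride_duration = Tc, speed = ocp$reference$speed)
  obj <- list(kin = unname(norms2["kin"]), grf = unname(norms2["grf"]),
              act = unname(norms2["act"]), met = unname(norms2["met"]),
              penalty = unname(norms2["pelvis"] + norms2["reserve"] +
                                 norms2["impulse"]))
  obj$total <- sum(unlist(obj))
  wt <- ocp$weights_t
  e_int <- sum(wt * rowSums(ev$red$edot))
  cost <- e_int / (Tc * model$mass)
  info <- if (is.null(fit)) NA_integer_ else fit$info
  structure(list(
    trajectories = traj, half = half, objective = obj, par = par,
    cost_wkg = cost, cost_gross_wkg = cost + ocp$config$basal_wkg,
    converged = is.na(info) || info %in% 1:4,
    info = info, message = if (is.null(fit)) "" else fit$message,
    residual_norms = norms2,
    peak_pelvis_residual = max(abs(ev$tau_req[, match(
      c("pelvis_tx", "pelvis_ty", "pelvis_tilt"), coord_names(model))])),
    peak_reserve = max(abs(ev$red$reserve)),
    ocp = ocp), class = "ocp_solution")
}

#' @export
print.ocp_solution <- function(x, ...) {
  cat(sprintf(
    "<ocp_solution> J = %.4g (kin %.3g, grf %.3g, act %.3g, met %.3g, pen %.3g)\n",
    x$objective$total, x$objective$kin, x$objective$grf, x$objective$act,
    x$objective$met, x$objective$penalty))
  cat(sprintf("  cost %.3f W/kg (muscle), %.3f W/kg (+basal); converged: %s\n",
              x$cost_wkg, x$cost_gross_wkg, x$converged))
  invisible(x)
}

#' Mirror a half gait cycle into a full cycle
#'
#' Applies the left-right involution to the half-cycle states: the
#' second half's left-leg trajectories equal the first half's right-leg
#' trajectories (and vice versa), pelvis forward translation advances by
#' speed x half duration, and the feet swap GRFs. Applying the involution
#' twice is the identity, so mirroring the mirrored second half
#' reproduces the original.
#'
#' @param half list with `time` (over `[0, T/2]`), `coords`, optional
#'   `speeds`, `activations`, `grf_r`, `grf_l`, plus `stride_duration`
#'   and `speed`.
#' @param model the `skeleton_model` (for the coordinate involution).
#' @return the same structure over the full cycle `[0, T]`.
#' @export
mirror_half_cycle <- function(half, model) {
  p <- symmetry_map(model)
  cn <- coord_names(model)
  Tc <- half$stride_duration
  shift <- half$speed * Tc / 2
  mir_coords <- function(Q) {
    M <- Q[, p, drop = FALSE]
    colnames(M) <- cn
    M[, "pelvis_tx"] <- M[, "pelvis_tx"] + shift
    M
  }
  mir_names <- function(M) {
    nm <- colnames(M)
    swapped <- ifelse(grepl("_r$", nm), sub("_r$", "_l", nm),
                      ifelse(grepl("_l$", nm), sub("_l$", "_r", nm), nm))
    M2 <- M[, match(nm, swapped), drop = FALSE]
    colnames(M2) <- nm
    M2
  }
  n <- length(half$time)
  idx2 <- 2:n
  out <- list(time = c(half$time, half$time[idx2] + Tc / 2),
              coords = rbind(half$coords, mir_coords(half$coords)[idx2, ,
                                                                  drop = FALSE]),
              stride_duration = Tc, speed = half$speed)
  if (!is.null(half$speeds)) {
    M <- half$speeds[, p, drop = FALSE]; colnames(M) <- cn
    out$speeds <- rbind(half$speeds, M[idx2, , drop = FALSE])
  }
  if (!is.null(half$activations)) {
    out$activations <- rbind(half$activations,
                             mir_names(half$activations)[idx2, ,
                                                         drop = FALSE])
  }
  if (!is.null(half$grf_r)) {
    out$grf_r <- rbind(half$grf_r, half$grf_l[idx2, , drop = FALSE])
    out$grf_l <- rbind(half$grf_l, half$grf_r[idx2, , drop = FALSE])
  }
  out
}

#' Average whole-body metabolic cost of a solution
#'
#' Integral of the summed per-muscle metabolic rates over the cycle,
#' divided by cycle duration and body mass; optionally plus a whole-body
#' basal rate.
#'
#' @param solution an `ocp_solution` (or any list with `trajectories`
#'   holding `time` and `edot`).
#' @param mass body mass, kg.
#' @param basal_wkg whole-body basal rate to add, W/kg (default 0:
#'   muscle-only net cost).
#' @return average cost in W/kg.
#' @export
average_metabolic_cost <- function(solution, mass, basal_wkg = 0) {
  tr <- solution$trajectories %||% solution
  w <- trapz_weights(tr$time)
  Tc <- tr$time[length(tr$time)] - tr$time[1]
  sum(w * rowSums(tr$edot)) / (Tc * mass) + basal_wkg
}
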