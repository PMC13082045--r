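#' Hill-type muscle-tendon units
#'
#' Nine muscle groups per leg (iliopsoas, gluteus maximus, rectus femoris,
#' biarticular hamstrings, vasti, biceps femoris short head, gastrocnemius,
#' soleus, tibialis anterior) modeled as Hill-type muscle-tendon units
#' (MTUs). Maximum isometric forces are doubled relative to generic values
#' and the active force-length operating range is widened by 50%
#' (symmetrically about the optimal fiber length) to reflect the
#' force-generating capacity of trained runners. All curve constants live
#' in [muscle_curve_constants()].
#'
#' @name muscle
NULL

#' Curve and metabolic constants
#'
#' One config block holding every smooth-curve constant: active
#' force-length Gaussian width, force-velocity shape coefficients
#' (normalized so the isometric value is exactly 1), passive exponential
#' shape (strain at one normalized force `e0`, exponent `kpe`), tendon
#' exponential (`c1 * exp(kT (lt_norm - 1)) - c1`, zero force at slack),
#' activation smoothing sharpness, and Bhargava-style metabolic
#' coefficients (W/kg of muscle mass) with the specific tension and
#' density used to derive muscle masses from doubled isometric forces.
#'
#' @return named list of constants.
#' @export
muscle_curve_constants <- function() {
  list(
    fl_gamma = 0.45,           # Gaussian width of the active FL curve
    fv_d = c(-0.318, -8.149, -0.374, 0.886),  # log-stretch FV shape
    kpe = 4, e0 = 0.6,         # passive FL
    kT = 35, cT = 0.2,         # tendon force-length
    act_blend = 20,            # tanh sharpness of the activation switch
    phi_act = 40, phi_maint = 74,  # activation / maintenance heat, W/kg
    alpha_short = 0.25,        # shortening heat per unit fiber force
    specific_tension = 6e5,    # N/m^2
    density = 1059.7,          # kg/m^3
    met_smooth = 1e-6          # W, non-negativity clamp width
  )
}

#' Default muscle parameter table
#'
#' Generic lower-limb values with maximum isometric forces scaled by
#' `force_scale` (default 2: doubled). Muscle mass for the metabolic model
#' is derived as `Fmax / sigma * rho * lopt`. The gastrocnemius and soleus
#' default to compliant tendons; all others are rigid.
#'
#' @param force_scale multiplier on generic maximum isometric forces.
#' @param widen active force-length widening factor (>= 1).
#' @param sides character vector of side suffixes to generate.
#' @return data.frame, one row per MTU, with SI-unit columns
#'   `name, side, group, fmax_N, lopt_m, lts_m, alpha0_rad,
#'   vmax_lopt_per_s, tau_act_s, tau_deact_s, widen, mass_kg,
#'   rigid_tendon`.
#' @export
default_muscle_params <- function(force_scale = 2, widen = 1.5,
                                  sides = c("r", "l")) {
  cc <- muscle_curve_constants()
  base <- data.frame(
    group = c("iliopsoas", "glut_max", "rect_fem", "hamstrings", "vasti",
              "bifemsh", "gastroc", "soleus", "tib_ant"),
    f0 = c(2000, 3000, 1200, 2500, 5000, 800, 2500, 3500, 1200),
    lopt_m = c(0.11, 0.14, 0.08, 0.10, 0.09, 0.17, 0.06, 0.05, 0.10),
    lts_m = c(0.14, 0.12, 0.35, 0.33, 0.22, 0.10, 0.39, 0.25, 0.22),
    alpha0_rad = c(0.14, 0.00, 0.09, 0.00, 0.09, 0.40, 0.30, 0.44, 0.09),
    rigid_tendon = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  )
  out <- do.call(rbind, lapply(sides, function(s) {
    d <- base
    d$side <- s
    d$name <- paste0(d$group, "_", s)
    d
  }))
  out$fmax_N <- out$f0 * force_scale
  out$f0 <- NULL
  out$vmax_lopt_per_s <- ifelse(out$group %in% c("gastroc", "soleus"),
                                12, 10)
  out$tau_act_s <- 0.015
  out$tau_deact_s <- 0.060
  out$widen <- widen
  out$mass_kg <- out$fmax_N / cc$specific_tension * cc$density * out$lopt_m
  rownames(out) <- NULL
  out[, c("name", "side", "group", "fmax_N", "lopt_m", "lts_m",
          "alpha0_rad", "vmax_lopt_per_s", "tau_act_s", "tau_deact_s",
          "widen", "mass_kg", "rigid_tendon")]
}

#' Read / write a muscle parameter table as CSV
#' @param path CSV file path.
#' @param params data.frame as from [default_muscle_params()].
#' @return `read_muscle_params` returns the data.frame; the writer returns
#'   `path` invisibly. Columns are SI units as documented in
#'   [default_muscle_params()].
#' @export
write_muscle_params <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_muscle_params
#' @export
read_muscle_params <- function(path) {
  need <- c("name", "fmax_N", "lopt_m", "lts_m", "alpha0_rad",
            "vmax_lopt_per_s", "tau_act_s", "tau_deact_s", "widen",
            "mass_kg", "rigid_tendon")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("muscle CSV missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(d$fmax_N <= 0 | d$lopt_m <= 0 | d$lts_m <= 0 | d$widen < 1)) {
    stopf("invalid muscle parameters in %s", path)
  }
  d
}

#' Muscle dynamic state
#'
#' @param excitation,activation values in `[0, 1]`.
#' @param lm_norm fiber length / optimal fiber length (> 0).
#' @param vm_norm fiber velocity in optimal lengths per second, normalized
#'   by `vmax` (shortening negative).
#' @return a `muscle_state` list.
#' @export
muscle_state <- function(excitation = 0, activation = 0, lm_norm = 1,
                         vm_norm = 0) {
  if (any(excitation < 0 | excitation > 1) ||
      any(activation < 0 | activation > 1)) {
    stopf("excitation and activation must lie in [0, 1]")
  }
  if (any(lm_norm <= 0)) stopf("normalized fiber length must be positive")
  structure(list(excitation = excitation, activation = activation,
                 lm_norm = lm_norm, vm_norm = vm_norm),
            class = "muscle_state")
}

#' First-order activation dynamics
#'
#' Smooth first-order lag between neural excitation and activation with a
#' faster time constant during activation than deactivation; the two
#' regimes are blended with a tanh switch so the rate is C1 in `(e, a)`.
#' The rate always has the sign of `e - a`.
#'
#' @param e excitation in `[0, 1]`.
#' @param a activation in `[0, 1]`.
#' @param tau_act,tau_deact activation / deactivation time constants (s).
#' @return activation rate, 1/s.
#' @export
activation_rate <- function(e, a, tau_act = 0.015, tau_deact = 0.060) {
  if (any(e < 0 | e > 1 | a < 0 | a > 1)) {
    stopf("activation_rate: e and a must lie in [0, 1]")
  }
  cc <- muscle_curve_constants()
  f <- 0.5 * (1 + tanh(cc$act_blend * (e - a)))
  tau <- tau_deact + (tau_act - tau_deact) * f
  (e - a) / tau
}

#' Active force-length multiplier
#'
#' Gaussian bell centered on the optimal fiber length. The widening factor
#' rescales the length deviation about the optimum by `1/widen`, so
#' `active_force_length(1 + d, widen) == active_force_length(1 + d/widen, 1)`.
#'
#' @param lm_norm normalized fiber length (> 0).
#' @param widen widening factor (>= 1; 1.5 widens the operating range by
#'   50%).
#' @return multiplier in `(0, 1]`, exactly 1 at `lm_norm = 1`.
#' @export
active_force_length <- function(lm_norm, widen = 1.5) {
  cc <- muscle_curve_constants()
  d <- (lm_norm - 1) / widen
  exp(-d * d / cc$fl_gamma)
}

#' Force-velocity multiplier
#'
#' Monotone smooth curve: ~0 at maximal shortening (`vm_norm = -1`), 1 at
#' isometric, eccentric plateau near 1.5. `vm_norm` is fiber velocity
#' normalized by maximal shortening velocity (shortening negative).
#'
#' @param vm_norm normalized fiber velocity.
#' @return force multiplier (> 0).
#' @export
force_velocity <- function(vm_norm) {
  cc <- muscle_curve_constants()
  d <- cc$fv_d
  raw <- function(v) d[1] * log((d[2] * v + d[3]) +
                                  sqrt((d[2] * v + d[3])^2 + 1)) + d[4]
  raw(vm_norm) / raw(0)
}

#' Passive force-length multiplier
#'
#' Exponential passive fiber force, zero at (and slightly below) the
#' optimal length, reaching 1 at strain `e0`.
#'
#' @param lm_norm normalized fiber length.
#' @return passive force multiplier.
#' @export
passive_force_length <- function(lm_norm) {
  cc <- muscle_curve_constants()
  # exponent capped so off-manifold optimizer probes stay finite
  (exp(pmin(cc$kpe * (lm_norm - 1) / cc$e0, 40)) - 1) / (exp(cc$kpe) - 1)
}

#' Tendon force-length
#'
#' Exponential tendon: zero force at the slack length, stiffening with
#' strain.
#'
#' @param lt_norm tendon length / tendon slack length.
#' @return normalized tendon force (units of `fmax`).
#' @export
tendon_force <- function(lt_norm) {
  cc <- muscle_curve_constants()
  cc$cT * (exp(pmin(cc$kT * (lt_norm - 1), 40)) - 1)
}

# pennation from the constant-thickness assumption
pennation_cos <- function(lm_norm, lopt, alpha0) {
  w <- sin(alpha0)           # normalized fiber width
  h <- pmin(w / pmax(lm_norm, w + 1e-9), 1 - 1e-9)
  sqrt(1 - h * h)
}

#' Fiber-tendon equilibrium residual
#'
#' Force balance across the MTU: active+passive fiber force projected
#' along the tendon minus tendon force, in N. Zero iff the fiber and
#' tendon are in equilibrium at the given MTU length.
#'
#' @param params one row of a muscle parameter table.
#' @param state a [muscle_state()] (activation and normalized fiber
#'   velocity are used; the fiber length is taken from `lm_norm`).
#' @param mtu_length total muscle-tendon length, m.
#' @param mtu_velocity unused in the residual itself (the fiber velocity
#'   in `state` governs the force-velocity multiplier); kept for the
#'   operation's documented signature.
#' @return residual force in N.
#' @export
mtu_equilibrium_residual <- function(params, state, mtu_length,
                                     mtu_velocity = 0) {
  if (any(mtu_length <= 0)) stopf("MTU length must be positive")
  lm <- state$lm_norm * params$lopt_m
  cosa <- pennation_cos(state$lm_norm, params$lopt_m, params$alpha0_rad)
  lt <- mtu_length - lm * cosa
  f_fiber <- params$fmax_N *
    (state$activation * active_force_length(state$lm_norm, params$widen) *
       force_velocity(state$vm_norm) +
       passive_force_length(state$lm_norm))
  f_fiber * cosa - params$fmax_N * tendon_force(lt / params$lts_m)
}

#' Solve fiber-tendon equilibrium for the fiber length
#'
#' Root of [mtu_equilibrium_residual()] in the normalized fiber length at
#' fixed activation and fiber velocity, by safeguarded bisection.
#'
#' @param params one muscle parameter row.
#' @param a activation.
#' @param mtu_length MTU length, m.
#' @param vm_norm normalized fiber velocity.
#' @param tol force tolerance, N.
#' @return normalized fiber length at equilibrium.
#' @export
solve_fiber_equilibrium <- function(params, a, mtu_length, vm_norm = 0,
                                    tol = 1e-9) {
  f <- function(ln) mtu_equilibrium_residual(
    params, muscle_state(activation = a, lm_norm = ln, vm_norm = vm_norm),
    mtu_length)
  lo <- 0.2; hi <- 2.5
  # residual is decreasing in ln (longer fiber -> shorter, slacker tendon)
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  r$root
}

# rigid-tendon fiber kinematics from MTU length/velocity
rigid_tendon_fiber <- function(params, lmtu, vmtu) {
  w <- params$lopt_m * sin(params$alpha0_rad)
  seg <- pmax(lmtu - params$lts_m, 0.05 * params$lopt_m)
  lm <- sqrt(seg * seg + w * w)
  cosa <- seg / lm
  vm <- vmtu * cosa
  list(lm_norm = lm / params$lopt_m,
       vm_norm = vm / (params$vmax_lopt_per_s * params$lopt_m),
       cosa = cosa, vm = vm)
}

#' Muscle metabolic rate
#'
#' Smoothed Bhargava-style energy model: activation heat + maintenance
#' heat (scaled by the active force-length multiplier) + shortening heat +
#' mechanical work rate, with the sum clamped smoothly at zero, plus an
#' optional basal rate. Coefficients live in [muscle_curve_constants()].
#'
#' @param params one muscle parameter row (uses `mass_kg`, `widen`).
#' @param state a [muscle_state()].
#' @param fiber_force fiber force along the fiber, N.
#' @param fiber_velocity fiber velocity, m/s (shortening negative).
#' @param basal basal rate, W (default 0; whole-body basal handling is a
#'   cost-level choice).
#' @return list of class `metabolic_terms`: `activation_maintenance`,
#'   `shortening`, `work`, `basal`, `total` (W); `total` is the clamped
#'   sum of the terms and is never negative.
#' @export
metabolic_rate <- function(params, state, fiber_force, fiber_velocity,
                           basal = 0) {
  cc <- muscle_curve_constants()
  am <- params$mass_kg * state$activation *
    (cc$phi_act + cc$phi_maint * active_force_length(state$lm_norm,
                                                     params$widen))
  sh <- cc$alpha_short * fiber_force * smooth_pos(-fiber_velocity, 1e-4)
  wk <- -fiber_force * fiber_velocity
  total <- smooth_pos(am + sh + wk, cc$met_smooth) + basal
  structure(list(activation_maintenance = am, shortening = sh, work = wk,
                 basal = basal, total = total),
            class = "metabolic_terms")
}
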