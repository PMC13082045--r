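#' Smoothed Hunt-Crossley foot-ground contact
#'
#' Sphere-on-halfspace contact with a Hertz-type elastic normal force
#' (exponent 3/2), Hunt-Crossley dissipation, and a smoothed Coulomb +
#' viscous friction law. Penetration depth is smoothed with
#' [smooth_pos()] so the force is C1 across lift-off and vanishes (below
#' 1e-3 N) once the sphere clears the ground by more than a few smoothing
#' widths.
#'
#' @name contact
NULL

#' Contact sphere specification
#'
#' @param radius sphere radius, m.
#' @param stiffness elastic modulus parameter, Pa; enters the Hertz
#'   normal-force law as `k = 4/3 * stiffness * sqrt(radius)`.
#' @param dissipation Hunt-Crossley dissipation coefficient, s/m.
#' @param mu_static,mu_dynamic static / dynamic friction coefficients.
#' @param mu_viscous viscous friction coefficient (per m/s of slip).
#' @param v_transition friction transition velocity, m/s.
#' @param smoothing penetration smoothing half-width, m.
#' @return a `contact_sphere_spec` list.
#' @export
contact_sphere_spec <- function(radius = 0.035, stiffness = 1e7,
                                dissipation = 1.0, mu_static = 0.8,
                                mu_dynamic = 0.8, mu_viscous = 0.5,
                                v_transition = 0.2, smoothing = 1e-4) {
  if (radius <= 0) stopf("sphere radius must be positive")
  if (any(c(stiffness, dissipation, mu_static, mu_dynamic, mu_viscous,
            v_transition, smoothing) < 0)) {
    stopf("contact parameters must be non-negative")
  }
  structure(list(radius = radius, stiffness = stiffness,
                 dissipation = dissipation, mu_static = mu_static,
                 mu_dynamic = mu_dynamic, mu_viscous = mu_viscous,
                 v_transition = v_transition, smoothing = smoothing),
            class = "contact_sphere_spec")
}

#' Contact force on a sphere
#'
#' @param sphere a [contact_sphere_spec()].
#' @param position sphere-center position: `n_t x 2` matrix or length-2
#'   vector (x forward, y up), m.
#' @param velocity sphere-center velocity, same shape, m/s.
#' @param ground_height height of the ground plane, m (default 0).
#' @return `n_t x 2` matrix (or length-2 vector for vector input) of
#'   force on the sphere, N: column 1 tangential (x), column 2 normal (y).
#' @export
contact_force <- function(sphere, position, velocity,
                          ground_height = 0) {
  vec_in <- !is.matrix(position)
  if (vec_in) {
    position <- matrix(position, 1); velocity <- matrix(velocity, 1)
  }
  if (any(!is.finite(position)) || any(!is.finite(velocity))) {
    stopf("contact_force: non-finite inputs")
  }
  depth <- (ground_height + sphere$radius) - position[, 2]
  d <- smooth_pos(depth, sphere$smoothing)
  k <- 4 / 3 * sphere$stiffness * sqrt(sphere$radius)
  v_pen <- -velocity[, 2]                # penetration rate, + when sinking
  # Hunt-Crossley: f = k d^{3/2} (1 + 3/2 c v_pen), clamped smoothly >= 0
  fn <- smooth_pos(k * d^1.5 * (1 + 1.5 * sphere$dissipation * v_pen),
                   1e-6)
  vt <- velocity[, 1]
  vs <- sqrt(vt * vt + (0.05 * sphere$v_transition)^2)  # smooth |vt|
  mu <- sphere$mu_dynamic * tanh(2 * vs / sphere$v_transition) +
    sphere$mu_viscous * vs
  ft <- -(vt / vs) * fn * mu
  out <- cbind(ft, fn)
  colnames(out) <- c("fx", "fy")
  if (vec_in) drop(out) else out
}

#' Total foot-ground reaction force per foot
#'
#' Sums [contact_force()] over the four sphere centers of each foot at
#' poses along a trajectory.
#'
#' @param model a `skeleton_model` with the default foot points.
#' @param q,qdot trajectory matrices (`n_t x nq`).
#' @param sphere a [contact_sphere_spec()].
#' @return list with elements `r` and `l`, each an `n_t x 2` matrix of
#'   GRF (fore-aft, vertical) in N, plus `per_sphere` (named list of
#'   per-sphere forces).
#' @export
foot_grf <- function(model, q, qdot, sphere = contact_sphere_spec()) {
  sphere_names <- list(
    r = c("heel_r", "mtp_post_r", "mtp_ant_r", "forefoot_r"),
    l = c("heel_l", "mtp_post_l", "mtp_ant_l", "forefoot_l"))
  pk <- forward_kinematics(model, q, qdot, unlist(sphere_names))
  per <- lapply(pk, function(p) contact_force(sphere, p$pos, p$vel))
  tot <- lapply(sphere_names, function(nms) {
    Reduce(`+`, lapply(per[nms], function(f) {
      if (is.matrix(f)) f else matrix(f, 1)
    }))
  })
  list(r = tot$r, l = tot$l, per_sphere = per)
}
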