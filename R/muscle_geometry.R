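#' Muscle path geometry
#'
#' Muscle-tendon paths are represented by coordinate-dependent moment-arm
#' polynomials (fit to published anatomical values; the convention is
#' `torque_j = r_j(q_j) * tension`, so flexor/extensor action is encoded
#' in the sign of `r`). The MTU length follows from integrating
#' `dL = -r(q) dq` away from the zero pose, where each MTU is at its
#' reference length `lopt * cos(alpha0) + lts`.
#'
#' @name muscle_geometry
NULL

# per-group moment-arm polynomials, ascending powers (m, m/rad, ...)
muscle_moment_arm_polys <- function() {
  list(
    iliopsoas = list(hip_flexion = c(0.050)),
    glut_max = list(hip_flexion = c(-0.062)),
    rect_fem = list(hip_flexion = c(0.034), knee_angle = c(0.042, 0.008)),
    hamstrings = list(hip_flexion = c(-0.060), knee_angle = c(-0.028)),
    vasti = list(knee_angle = c(0.045, 0.007)),
    bifemsh = list(knee_angle = c(-0.028)),
    gastroc = list(knee_angle = c(-0.018), ankle_angle = c(-0.048, 0.006)),
    soleus = list(ankle_angle = c(-0.050, 0.006)),
    tib_ant = list(ankle_angle = c(0.040))
  )
}

polyval_asc <- function(coef, q) {
  out <- 0
  for (p in rev(seq_along(coef))) out <- out * q + coef[p]
  out
}

# integral of the ascending-power polynomial from 0 to q
polyint_asc <- function(coef, q) {
  out <- 0
  n <- length(coef)
  for (p in n:1) out <- out * q + coef[p] / p
  out * q
}

#' Build muscle path table for a model
#'
#' Joins the parameter table with the moment-arm polynomials, resolving
#' side-suffixed coordinate names and reference lengths.
#'
#' @param params muscle parameter table ([default_muscle_params()]).
#' @param model a `skeleton_model` (for coordinate name checking).
#' @param neutral_pose named joint angles (rad, side-less names) at which
#'   each MTU sits at its reference length `lopt cos(alpha0) + lts`;
#'   defaults to a mid-stride running posture so fibers operate around
#'   the optimum over the gait cycle.
#' @return list of per-muscle paths: `name`, `row` (index into `params`),
#'   `coords` (coordinate names), `cidx`, `polys`, `lref_m` (MTU length
#'   at the zero pose).
#' @export
muscle_paths <- function(params, model,
                         neutral_pose = c(hip_flexion = 0.25,
                                          knee_angle = -0.8,
                                          ankle_angle = 0.05)) {
  polys <- muscle_moment_arm_polys()
  cn <- coord_names(model)
  lapply(seq_len(nrow(params)), function(i) {
    g <- params$group[i]; s <- params$side[i]
    pg <- polys[[g]]
    if (is.null(pg)) stopf("no path geometry for muscle group '%s'", g)
    coords <- paste0(names(pg), "_", s)
    ci <- match(coords, cn)
    if (anyNA(ci)) stopf("muscle %s spans unknown coordinate", params$name[i])
    # reference length holds at the neutral pose; convert to the zero
    # pose via the moment-arm integrals
    lref0 <- params$lopt_m[i] * cos(params$alpha0_rad[i]) + params$lts_m[i]
    for (j in seq_along(pg)) {
      q_n <- neutral_pose[[names(pg)[j]]] %||% 0
      lref0 <- lref0 + polyint_asc(pg[[j]], q_n)
    }
    list(name = params$name[i], row = i, coords = coords, cidx = ci,
         polys = unname(pg), lref_m = lref0)
  })
}

#' MTU lengths, velocities and moment arms along a trajectory
#'
#' @param paths output of [muscle_paths()].
#' @param Q,Qd trajectory matrices (`n_t x nq`).
#' @return list of `length` (`n_t x n_musc`), `velocity` (`n_t x n_musc`)
#'   and `arms` (list per muscle of `n_t x n_coords-spanned` moment-arm
#'   matrices).
#' @export
mtu_kinematics <- function(paths, Q, Qd = NULL) {
  n_t <- nrow(Q)
  nm <- length(paths)
  L <- matrix(0, n_t, nm); V <- matrix(0, n_t, nm)
  arms <- vector("list", nm)
  for (i in seq_len(nm)) {
    p <- paths[[i]]
    li <- rep(p$lref_m, n_t); vi <- rep(0, n_t)
    A <- matrix(0, n_t, length(p$cidx))
    for (j in seq_along(p$cidx)) {
      qj <- Q[, p$cidx[j]]
      r <- polyval_asc(p$polys[[j]], qj)
      A[, j] <- r
      li <- li - polyint_asc(p$polys[[j]], qj)
      if (!is.null(Qd)) vi <- vi - r * Qd[, p$cidx[j]]
    }
    L[, i] <- li; V[, i] <- vi; arms[[i]] <- A
  }
  colnames(L) <- vapply(paths, `[[`, "", "name")
  colnames(V) <- colnames(L)
  list(length = L, velocity = V, arms = arms)
}

#' Passive joint torques (lumbar and MTP soft tissues)
#'
#' Rotational spring-dampers representing ligaments and other passive
#' structures at the lumbar and metatarsophalangeal joints.
#'
#' @param model a `skeleton_model`.
#' @param Q,Qd trajectory matrices.
#' @param k_mtp,c_mtp MTP stiffness (N m/rad) and damping (N m s/rad).
#' @param k_lumbar,c_lumbar lumbar stiffness and damping.
#' @return `n_t x nq` matrix of applied generalized torques.
#' @export
passive_joint_torques <- function(model, Q, Qd = NULL, k_mtp = 25,
                                  c_mtp = 0.4, k_lumbar = 40,
                                  c_lumbar = 1.0) {
  Q <- as_Q(model, Q)
  if (is.null(Qd)) Qd <- matrix(0, nrow(Q), ncol(Q)) else Qd <- as_Q(model, Qd)
  tau <- matrix(0, nrow(Q), ncol(Q),
                dimnames = list(NULL, coord_names(model)))
  for (cn in c("mtp_angle_r", "mtp_angle_l")) {
    if (cn %in% colnames(tau)) {
      tau[, cn] <- -k_mtp * Q[, cn] - c_mtp * Qd[, cn]
    }
  }
  if ("lumbar_extension" %in% colnames(tau)) {
    tau[, "lumbar_extension"] <- -k_lumbar * Q[, "lumbar_extension"] -
      c_lumbar * Qd[, "lumbar_extension"]
  }
  tau
}
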