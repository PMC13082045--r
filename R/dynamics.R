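#' Planar kinematics and implicit rigid-body dynamics
#'
#' The engine computes body kinematics recursively over the tree and
#' generalized forces by projecting Newton-Euler terms onto coordinate
#' Jacobians. All functions accept a single pose (vectors) or a whole
#' trajectory (matrices with one row per time sample); trajectory calls are
#' vectorized over time, which is what makes the tracking optimization
#' affordable.
#'
#' @name dynamics
NULL

as_Q <- function(model, q) {
  nq <- n_coords(model)
  if (is.null(q)) return(NULL)
  if (is.matrix(q)) {
    if (ncol(q) != nq) stopf("expected %d coordinate columns, got %d", nq, ncol(q))
    q
  } else {
    if (length(q) != nq) stopf("expected %d coordinates, got %d", nq, length(q))
    matrix(q, nrow = 1)
  }
}

# Recursive body kinematics. Returns, per body, time-vectors theta/omega/
# alpha and n_t x 2 matrices o/vo/ao (frame origin) and c/vc/ac (COM).
body_kinematics <- function(model, Q, Qd = NULL, Qdd = NULL) {
  Q <- as_Q(model, Q)
  n_t <- nrow(Q)
  z <- matrix(0, n_t, 1)
  Qd <- if (is.null(Qd)) matrix(0, n_t, ncol(Q)) else as_Q(model, Qd)
  Qdd <- if (is.null(Qdd)) matrix(0, n_t, ncol(Q)) else as_Q(model, Qdd)
  nb <- length(model$bodies)
  out <- vector("list", nb)
  names(out) <- names(model$bodies)
  for (i in seq_len(nb)) {
    b <- model$bodies[[i]]
    if (b$jtype == "free") {
      itx <- b$cidx[1]; ity <- b$cidx[2]; irot <- b$cidx[3]
      th <- Q[, irot]; om <- Qd[, irot]; al <- Qdd[, irot]
      o <- cbind(Q[, itx], Q[, ity])
      vo <- cbind(Qd[, itx], Qd[, ity])
      ao <- cbind(Qdd[, itx], Qdd[, ity])
    } else {
      ic <- b$cidx[1]
      if (b$parent == 0L) {
        th <- Q[, ic]; om <- Qd[, ic]; al <- Qdd[, ic]
        o <- matrix(rep(b$jloc, each = n_t), n_t, 2)
        vo <- matrix(0, n_t, 2); ao <- matrix(0, n_t, 2)
      } else {
        p <- out[[b$parent]]
        d <- rot2(p$theta, b$jloc[1], b$jloc[2])
        th <- p$theta + Q[, ic]; om <- p$omega + Qd[, ic]
        al <- p$alpha + Qdd[, ic]
        o <- cbind(p$o[, 1] + d$x, p$o[, 2] + d$y)
        vo <- cbind(p$vo[, 1] - p$omega * d$y, p$vo[, 2] + p$omega * d$x)
        ao <- cbind(p$ao[, 1] - p$alpha * d$y - p$omega^2 * d$x,
                    p$ao[, 2] + p$alpha * d$x - p$omega^2 * d$y)
      }
    }
    rc <- rot2(th, b$com[1], b$com[2])
    cm <- cbind(o[, 1] + rc$x, o[, 2] + rc$y)
    vc <- cbind(vo[, 1] - om * rc$y, vo[, 2] + om * rc$x)
    ac <- cbind(ao[, 1] - al * rc$y - om^2 * rc$x,
                ao[, 2] + al * rc$x - om^2 * rc$y)
    out[[i]] <- list(theta = th, omega = om, alpha = al, o = o, vo = vo,
                     ao = ao, c = cm, vc = vc, ac = ac)
  }
  out
}

# positions/velocities of named model points given body kinematics
point_kin_from_bodies <- function(model, bk, point_names = NULL) {
  pts <- model$points
  if (!is.null(point_names)) {
    miss <- setdiff(point_names, pts$name)
    if (length(miss)) stopf("unknown point(s): %s", paste(miss, collapse = ", "))
    pts <- pts[match(point_names, pts$name), , drop = FALSE]
  }
  body_idx <- match(pts$segment, names(model$bodies))
  out <- vector("list", nrow(pts))
  names(out) <- pts$name
  for (i in seq_len(nrow(pts))) {
    k <- bk[[body_idx[i]]]
    r <- rot2(k$theta, pts$x[i], pts$y[i])
    out[[i]] <- list(
      pos = cbind(k$o[, 1] + r$x, k$o[, 2] + r$y),
      vel = cbind(k$vo[, 1] - k$omega * r$y, k$vo[, 2] + k$omega * r$x),
      z = pts$z[i], body = body_idx[i])
  }
  out
}

#' Forward kinematics of named points
#'
#' Positions and velocities, in the ground frame, of every named point
#' (contact-sphere centers, exotendon anchors, shoe markers) fixed to a
#' segment, at a single pose or along a trajectory.
#'
#' @param model a `skeleton_model`.
#' @param q coordinate vector (length `n_coords(model)`) or trajectory
#'   matrix (rows = time samples).
#' @param qdot coordinate rates, same shape as `q` (default zero).
#' @param points optional character vector restricting which points to
#'   evaluate.
#' @return a list, one entry per point, each with `pos` and `vel`
#'   (`n_t x 2` matrices: x forward, y up) and the constant mediolateral
#'   offset `z`.
#' @export
forward_kinematics <- function(model, q, qdot = NULL, points = NULL) {
  bk <- body_kinematics(model, q, qdot)
  point_kin_from_bodies(model, bk, points)
}

# Per-body translational Jacobian columns are recovered on demand from the
# coordinate structure: tx -> (1,0); ty -> (0,1); revolute j with axis point
# o_b -> perp(p - o_b) for points on b's subtree.

coord_kind <- function(model) {
  # "tx", "ty", "rev", "oop" per coordinate, plus owning body for revolutes
  nq <- n_coords(model)
  kind <- rep("oop", nq)
  owner <- integer(nq)
  for (i in seq_along(model$bodies)) {
    b <- model$bodies[[i]]
    if (b$jtype == "free") {
      kind[b$cidx[1]] <- "tx"; kind[b$cidx[2]] <- "ty"; kind[b$cidx[3]] <- "rev"
      owner[b$cidx] <- i
    } else {
      kind[b$cidx[1]] <- "rev"; owner[b$cidx[1]] <- i
    }
  }
  list(kind = kind, owner = owner)
}

#' Mass matrix
#'
#' @param model a `skeleton_model`.
#' @param q coordinate vector.
#' @return symmetric positive-definite `nq x nq` matrix (locked
#'   out-of-plane coordinates contribute decoupled diagonal inertias).
#' @export
mass_matrix <- function(model, q) {
  nq <- n_coords(model)
  bk <- body_kinematics(model, q)
  ck <- coord_kind(model)
  M <- diag(model$oop_inertia, nq)
  nb <- length(model$bodies)
  # COM Jacobians, one column set per coordinate
  for (k in seq_len(nb)) {
    b <- model$bodies[[k]]
    Jc <- matrix(0, 2, nq); Jw <- numeric(nq)
    cx <- bk[[k]]$c[1, 1]; cy <- bk[[k]]$c[1, 2]
    for (j in seq_len(nq)) {
      if (ck$kind[j] == "tx") { Jc[1, j] <- 1 }
      else if (ck$kind[j] == "ty") { Jc[2, j] <- 1 }
      else if (ck$kind[j] == "rev" && model$ancestors[k, ck$owner[j]]) {
        ob <- bk[[ck$owner[j]]]$o[1, ]
        Jc[1, j] <- -(cy - ob[2]); Jc[2, j] <- cx - ob[1]
        Jw[j] <- 1
      }
    }
    M <- M + b$mass * crossprod(Jc) + b$inertia * tcrossprod(Jw)
  }
  M
}

#' Inverse dynamics along a trajectory
#'
#' Generalized forces required to realize `(q, qdot, qddot)` given the
#' applied external point forces and coordinate torques:
#' `tau_req = M(q) qddot + bias(q, qdot) - J^T F_ext - tau_applied`.
#' A converged simulation drives `tau_req` to zero at unactuated
#' coordinates.
#'
#' @param model a `skeleton_model`.
#' @param q,qdot,qddot trajectory matrices (`n_t x nq`) or single vectors.
#' @param point_forces optional named list; each element is a force history
#'   for the model point of that name, as an `n_t x 2` matrix (N, ground
#'   frame) or length-2 vector.
#' @param coord_torques optional `n_t x nq` matrix (or named vector) of
#'   directly applied generalized forces.
#' @return `n_t x nq` matrix of residual generalized forces (N or N m).
#' @export
inverse_dynamics <- function(model, q, qdot, qddot, point_forces = NULL,
                             coord_torques = NULL) {
  Q <- as_Q(model, q); Qd <- as_Q(model, qdot); Qdd <- as_Q(model, qddot)
  n_t <- nrow(Q); nq <- n_coords(model)
  bk <- body_kinematics(model, Q, Qd, Qdd)
  ck <- coord_kind(model)
  g <- GRAVITY
  nb <- length(model$bodies)
  # inertial + gravity wrench per body COM
  W <- lapply(seq_len(nb), function(k) {
    b <- model$bodies[[k]]
    cbind(b$mass * bk[[k]]$ac[, 1],
          b$mass * (bk[[k]]$ac[, 2] + g))
  })
  tau <- matrix(0, n_t, nq)
  colnames(tau) <- coord_names(model)
  for (j in seq_len(nq)) {
    if (ck$kind[j] == "tx") {
      s <- 0
      for (k in seq_len(nb)) s <- s + W[[k]][, 1]
      tau[, j] <- s
    } else if (ck$kind[j] == "ty") {
      s <- 0
      for (k in seq_len(nb)) s <- s + W[[k]][, 2]
      tau[, j] <- s
    } else if (ck$kind[j] == "rev") {
      bown <- ck$owner[j]
      ob <- bk[[bown]]$o
      s <- 0
      for (k in seq_len(nb)) {
        if (!model$ancestors[k, bown]) next
        rx <- bk[[k]]$c[, 1] - ob[, 1]; ry <- bk[[k]]$c[, 2] - ob[, 2]
        s <- s - W[[k]][, 1] * ry + W[[k]][, 2] * rx +
          model$bodies[[k]]$inertia * bk[[k]]$alpha
      }
      tau[, j] <- s
    } else { # decoupled out-of-plane rotation
      tau[, j] <- model$oop_inertia[j] * Qdd[, j]
    }
  }
  if (!is.null(point_forces) && length(point_forces)) {
    pk <- point_kin_from_bodies(model, bk, names(point_forces))
    for (nm in names(point_forces)) {
      F <- point_forces[[nm]]
      if (!is.matrix(F)) F <- matrix(F, n_t, 2, byrow = TRUE)
      kP <- pk[[nm]]$body; p <- pk[[nm]]$pos
      for (j in seq_len(nq)) {
        if (ck$kind[j] == "tx") tau[, j] <- tau[, j] - F[, 1]
        else if (ck$kind[j] == "ty") tau[, j] <- tau[, j] - F[, 2]
        else if (ck$kind[j] == "rev" && model$ancestors[kP, ck$owner[j]]) {
          ob <- bk[[ck$owner[j]]]$o
          tau[, j] <- tau[, j] -
            (-F[, 1] * (p[, 2] - ob[, 2]) + F[, 2] * (p[, 1] - ob[, 1]))
        }
      }
    }
  }
  if (!is.null(coord_torques)) {
    if (is.null(dim(coord_torques)) && !is.null(names(coord_torques))) {
      ct <- matrix(0, n_t, nq, dimnames = list(NULL, coord_names(model)))
      ct[, names(coord_torques)] <- matrix(coord_torques, n_t,
                                           length(coord_torques), byrow = TRUE)
      coord_torques <- ct
    }
    tau <- tau - coord_torques
  }
  tau
}

#' Gravity + velocity-product bias forces
#' @param model a `skeleton_model`.
#' @param q,qdot coordinate vector and rates.
#' @return length-`nq` vector such that the equations of motion read
#'   `M(q) qddot + bias(q, qdot) = tau_applied`.
#' @export
bias_forces <- function(model, q, qdot) {
  drop(inverse_dynamics(model, q, qdot, rep(0, n_coords(model))))
}

#' Implicit equations-of-motion residual
#'
#' `residual = M(q) qddot + bias(q, qdot) - tau_applied`, zero iff the
#' dynamics are satisfied; the form used as the defect in collocation.
#'
#' @param model a `skeleton_model`.
#' @param q,qdot,qddot coordinate vectors.
#' @param point_forces,coord_torques applied loads as in
#'   [inverse_dynamics()].
#' @return residual vector (N for translational, N m for rotational
#'   coordinates).
#' @export
dynamics_residual <- function(model, q, qdot, qddot, point_forces = NULL,
                              coord_torques = NULL) {
  drop(inverse_dynamics(model, q, qdot, qddot, point_forces, coord_torques))
}

#' Total mechanical energy of a pose
#' @param model a `skeleton_model`.
#' @param q,qdot coordinate vector and rates.
#' @return list with `kinetic`, `potential` (gravity, zero at y = 0) and
#'   `total` in J.
#' @export
mechanical_energy <- function(model, q, qdot) {
  bk <- body_kinematics(model, q, qdot)
  Q <- as_Q(model, q); Qd <- as_Q(model, qdot)
  ke <- 0; pe <- 0
  for (k in seq_along(model$bodies)) {
    b <- model$bodies[[k]]
    ke <- ke + 0.5 * b$mass * (bk[[k]]$vc[, 1]^2 + bk[[k]]$vc[, 2]^2) +
      0.5 * b$inertia * bk[[k]]$omega^2
    pe <- pe + b$mass * GRAVITY * bk[[k]]$c[, 2]
  }
  ke <- ke + drop(0.5 * (Qd^2) %*% model$oop_inertia)
  list(kinetic = drop(ke), potential = drop(pe), total = drop(ke + pe))
}

#' Forward dynamics at a single state
#'
#' Solves `M qddot = tau_applied - bias` over the unlocked coordinates;
#' locked coordinates keep zero acceleration.
#'
#' @param model a `skeleton_model`.
#' @param q,qdot state.
#' @param point_forces,coord_torques applied loads as in
#'   [inverse_dynamics()].
#' @return coordinate accelerations, length `nq`.
#' @export
forward_dynamics <- function(model, q, qdot, point_forces = NULL,
                             coord_torques = NULL) {
  nq <- n_coords(model)
  tau_req <- drop(inverse_dynamics(model, q, qdot, rep(0, nq),
                                   point_forces, coord_torques))
  M <- mass_matrix(model, q)
  free <- !model$coords$locked
  qdd <- rep(0, nq)
  qdd[free] <- solve(M[free, free, drop = FALSE], -tau_req[free])
  qdd
}

#' Integrate passive (unforced) dynamics
#'
#' Used for conservation checks: with no applied forces or contact the
#' motion conserves total mechanical energy.
#'
#' @param model a `skeleton_model`.
#' @param q0,qd0 initial state.
#' @param t_end duration in s.
#' @param n_steps output samples.
#' @param gravity_only if `TRUE` (default) no external forces at all.
#' @return data.frame with `time`, coordinates and rates.
#' @export
simulate_passive <- function(model, q0, qd0, t_end = 1, n_steps = 200,
                             gravity_only = TRUE) {
  nq <- n_coords(model)
  rhs <- function(t, y, parms) {
    q <- y[1:nq]; qd <- y[nq + (1:nq)]
    list(c(qd, forward_dynamics(model, q, qd)))
  }
  times <- seq(0, t_end, length.out = n_steps + 1)
  sol <- deSolve::ode(y = c(q0, qd0), times = times, func = rhs,
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-10)
  out <- as.data.frame(sol)
  names(out) <- c("time", coord_names(model),
                  paste0(coord_names(model), "_u"))
  out
}

#' Left-right coordinate involution
#'
#' The symmetry map used for half-gait-cycle simulation: left and right
#' limb coordinates swap; pelvis, lumbar and time-like coordinates map to
#' themselves. Applying the map twice is the identity.
#'
#' @param model a `skeleton_model` with `_r`/`_l` coordinate suffixes.
#' @return integer permutation `p` with `coord i <-> coord p[i]`.
#' @export
symmetry_map <- function(model) {
  nm <- coord_names(model)
  p <- seq_along(nm)
  for (i in seq_along(nm)) {
    if (grepl("_r$", nm[i])) p[i] <- match(sub("_r$", "_l", nm[i]), nm)
    else if (grepl("_l$", nm[i])) p[i] <- match(sub("_l$", "_r", nm[i]), nm)
  }
  if (anyNA(p) || any(p[p] != seq_along(nm))) {
    stopf("coordinate names do not define a left-right involution")
  }
  p
}
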