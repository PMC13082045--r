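#' Static muscle-redundancy resolution
#'
#' At each mesh node the required hip, knee and ankle torques of one leg
#' are distributed over that leg's nine muscles by minimizing a weighted
#' sum of squared activations (the weights fold the activation-squared
#' and metabolic-rate-squared objective terms into one diagonal quadratic
#' form), subject to the torque-matching equality and activation bounds.
#' Solved in closed form via the equality-constrained normal equations
#' with an active-set pass for the box bounds; torque that no admissible
#' activation can produce is returned as a reserve torque (penalized by
#' the outer problem).
#'
#' @name redundancy
NULL

# Solve min sum(D a^2) s.t. G a = b, 0 <= a <= 1, for one node.
# G: n_joint x n_musc torque gains; b: required active torque.
solve_activation_qp <- function(G, b, D, max_passes = 3) {
  nm <- ncol(G)
  lo <- rep(0, nm); hi <- rep(1, nm)
  fixed <- rep(NA_real_, nm)
  for (pass in seq_len(max_passes + 1)) {
    free <- is.na(fixed)
    bf <- b - if (any(!free)) G[, !free, drop = FALSE] %*% fixed[!free] else 0
    a <- fixed
    if (any(free)) {
      Gf <- G[, free, drop = FALSE]
      Dinv <- 1 / D[free]
      GDG <- Gf %*% (Dinv * t(Gf))
      # ridge keeps the 3x3 system well-posed even if a joint loses all
      # its actuators (e.g. force-velocity collapse)
      diag(GDG) <- diag(GDG) + 1e-8 * (1 + max(abs(GDG)))
      lam <- solve(GDG, bf)
      a[free] <- Dinv * drop(crossprod(Gf, lam))
    }
    viol_lo <- !is.na(a) & is.na(fixed) & a < 0
    viol_hi <- !is.na(a) & is.na(fixed) & a > 1
    if (!any(viol_lo | viol_hi) || pass > max_passes) break
    fixed[viol_lo] <- 0; fixed[viol_hi] <- 1
  }
  a <- pmin(pmax(a, 0), 1)
  list(a = a, reserve = drop(b - G %*% a))
}

#' Resolve muscle activations along a trajectory
#'
#' @param tau_req `n_t x nq` required generalized forces (from
#'   [inverse_dynamics()] with contact, exotendon and passive torques
#'   already applied).
#' @param mtuk output of [mtu_kinematics()] for all muscles.
#' @param params muscle parameter table.
#' @param paths [muscle_paths()] list.
#' @param model the skeleton (for coordinate indices).
#' @param w_act,w_met objective weights used to form the diagonal
#'   quadratic weights.
#' @return list: `activations` (`n_t x n_musc`), `fiber_force` (N, along
#'   the fiber), `fiber_velocity` (m/s), `lm_norm`, `reserve`
#'   (`n_t x 6` leftover torques at hip/knee/ankle of both legs, N m),
#'   `edot` (`n_t x n_musc` metabolic rates, W).
#' @export
resolve_muscle_activations <- function(tau_req, mtuk, params, paths, model,
                                       w_act = 8, w_met = 4e-5) {
  cc <- muscle_curve_constants()
  n_t <- nrow(tau_req)
  nm <- nrow(params)
  cn <- coord_names(model)
  # rigid-tendon fiber kinematics, gains and passive forces, vectorized
  FL <- matrix(0, n_t, nm); FV <- FL; FP <- FL; COSA <- FL
  LMn <- FL; VM <- FL
  plist <- lapply(seq_len(nm), function(i) as.list(params[i, ]))
  for (i in seq_len(nm)) {
    p <- plist[[i]]
    fk <- rigid_tendon_fiber(p, mtuk$length[, i], mtuk$velocity[, i])
    LMn[, i] <- fk$lm_norm; VM[, i] <- fk$vm; COSA[, i] <- fk$cosa
    FL[, i] <- active_force_length(fk$lm_norm, p$widen)
    FV[, i] <- force_velocity(fk$vm_norm)
    FP[, i] <- pmax(passive_force_length(fk$lm_norm), 0)
  }
  gain <- sweep(FL * FV * COSA, 2, params$fmax_N, `*`)   # dF_tendon/da
  fpass <- sweep(FP * COSA, 2, params$fmax_N, `*`)
  # diagonal weights: activation term + linearized metabolic term
  met_gain <- params$mass_kg * (cc$phi_act + cc$phi_maint)
  D <- pmax(w_act + w_met * met_gain^2, 1e-9)  # positive even if both
                                               # weights are zero

  legs <- list(r = c("hip_flexion_r", "knee_angle_r", "ankle_angle_r"),
               l = c("hip_flexion_l", "knee_angle_l", "ankle_angle_l"))
  A <- matrix(0, n_t, nm, dimnames = list(NULL, params$name))
  reserve <- matrix(0, n_t, 6,
                    dimnames = list(NULL, unlist(legs)))
  for (side in names(legs)) {
    jidx <- match(legs[[side]], cn)
    midx <- which(params$side == side)
    # per-muscle moment-arm columns restricted to this leg's coords
    Rarr <- array(0, c(n_t, 3, length(midx)))
    for (kk in seq_along(midx)) {
      p <- paths[[midx[kk]]]
      for (j in seq_along(p$cidx)) {
        jj <- match(p$cidx[j], jidx)
        if (!is.na(jj)) Rarr[, jj, kk] <- mtuk$arms[[midx[kk]]][, j]
      }
    }
    for (t in seq_len(n_t)) {
      G <- Rarr[t, , ] * rep(gain[t, midx], each = 3)
      b <- tau_req[t, jidx] - drop(Rarr[t, , ] %*% fpass[t, midx])
      sol <- solve_activation_qp(G, b, D[midx])
      A[t, midx] <- sol$a
      reserve[t, legs[[side]]] <- sol$reserve
    }
  }
  Ffib <- sweep(A * FL * FV + FP, 2, params$fmax_N, `*`)
  edot <- matrix(0, n_t, nm, dimnames = list(NULL, params$name))
  for (i in seq_len(nm)) {
    st <- list(activation = A[, i], lm_norm = LMn[, i],
               vm_norm = VM[, i] /
                 (params$vmax_lopt_per_s[i] * params$lopt_m[i]))
    edot[, i] <- metabolic_rate(plist[[i]], st, Ffib[, i], VM[, i])$total
  }
  list(activations = A, fiber_force = Ffib, fiber_velocity = VM,
       lm_norm = LMn, reserve = reserve, edot = edot)
}
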