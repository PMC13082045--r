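#' The exotendon spring
#'
#' The exotendon is a linear extension spring connecting anchor points on
#' the two calcanei, parameterized by stiffness `k` (N/m) and slack length
#' `l` (m, or % of leg length). Tension is `k * max(0, d - l)` where `d`
#' is the 3-D anchor separation (the planar model supplies a constant
#' mediolateral offset between the feet). A smoothed (softplus) variant is
#' used inside the optimizer; the analysis path uses the exact piecewise
#' form.
#'
#' @name exotendon
NULL

#' Exotendon design specification
#'
#' @param stiffness spring stiffness `k`, N/m (>= 0).
#' @param slack_m slack length in m (> 0); give either this or
#'   `slack_pct`.
#' @param slack_pct slack length as % of leg length, converted with
#'   `leg_length`.
#' @param leg_length leg length used for the % convention, m (default
#'   0.92).
#' @param anchors names of the two anchor points on the model.
#' @param name optional design label.
#' @return an `exotendon_spec` list with fields `stiffness`, `slack_m`,
#'   `slack_pct`, `leg_length`, `anchors`, `name`.
#' @export
exotendon_spec <- function(stiffness, slack_m = NULL, slack_pct = NULL,
                           leg_length = 0.92,
                           anchors = c("exo_anchor_r", "exo_anchor_l"),
                           name = NULL) {
  if (!is.finite(stiffness) || stiffness < 0) {
    stopf("exotendon stiffness must be >= 0")
  }
  if (is.null(slack_m) && is.null(slack_pct)) {
    stopf("give slack_m or slack_pct")
  }
  if (is.null(slack_m)) slack_m <- slack_pct / 100 * leg_length
  if (is.null(slack_pct)) slack_pct <- 100 * slack_m / leg_length
  if (!is.finite(slack_m) || slack_m <= 0) {
    stopf("exotendon slack length must be positive")
  }
  structure(list(stiffness = stiffness, slack_m = slack_m,
                 slack_pct = slack_pct, leg_length = leg_length,
                 anchors = anchors,
                 name = name %||% sprintf("k%g_l%g", stiffness, slack_pct)),
            class = "exotendon_spec")
}

#' @export
print.exotendon_spec <- function(x, ...) {
  cat(sprintf("<exotendon> %s: k = %g N/m, slack = %.3f m (%.3g%% leg)\n",
              x$name, x$stiffness, x$slack_m, x$slack_pct))
  invisible(x)
}

#' Named exotendon presets
#'
#' The four designs carried forward to experimental evaluation:
#' medium-original (k = 120 N/m, l = 25% leg length — the previously
#' published design), long-stiff (240, 37.5%), short-stiff (240, 12.5%),
#' long-compliant (30, 37.5%).
#'
#' @param name one of `"medium-original"`, `"long-stiff"`,
#'   `"short-stiff"`, `"long-compliant"`.
#' @param leg_length leg length for the % convention, m.
#' @return an [exotendon_spec()].
#' @export
exotendon_preset <- function(name = c("medium-original", "long-stiff",
                                      "short-stiff", "long-compliant"),
                             leg_length = 0.92) {
  name <- match.arg(name)
  p <- switch(name,
    "medium-original" = c(120, 25),
    "long-stiff" = c(240, 37.5),
    "short-stiff" = c(240, 12.5),
    "long-compliant" = c(30, 37.5))
  exotendon_spec(p[1], slack_pct = p[2], leg_length = leg_length,
                 name = name)
}

#' Read / write an exotendon design as JSON
#'
#' Schema: `{"stiffness_N_per_m": k, "slack_pct_leg_length": l}` or
#' `{"stiffness_N_per_m": k, "slack_m": l}`, optional `"name"` and
#' `"leg_length_m"`.
#'
#' @param spec an [exotendon_spec()].
#' @param path JSON file path.
#' @return reader returns an `exotendon_spec`; writer returns `path`
#'   invisibly.
#' @export
write_exotendon_json <- function(spec, path) {
  jsonlite::write_json(list(stiffness_N_per_m = spec$stiffness,
                            slack_pct_leg_length = spec$slack_pct,
                            leg_length_m = spec$leg_length,
                            name = spec$name),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_exotendon_json
#' @export
read_exotendon_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(d$stiffness_N_per_m)) stopf("missing stiffness_N_per_m")
  exotendon_spec(d$stiffness_N_per_m, slack_m = d$slack_m,
                 slack_pct = d$slack_pct_leg_length,
                 leg_length = d$leg_length_m %||% 0.92,
                 name = d$name)
}

#' Exotendon tension from anchor separation
#'
#' Exact piecewise law `k * max(0, d - l)`; with `smoothing > 0` a
#' softplus variant `k * s * log1p(exp((d - l)/s))` whose error from the
#' exact law is bounded by `k * s * log(2)`.
#'
#' @param distance anchor separation, m (>= 0); vectorized.
#' @param spec an [exotendon_spec()].
#' @param smoothing softplus width `s` in m (0 = exact).
#' @return tension in N (>= 0).
#' @export
exotendon_tension <- function(distance, spec, smoothing = 0) {
  if (any(distance < 0)) stopf("anchor distance must be >= 0")
  x <- distance - spec$slack_m
  if (smoothing > 0) {
    # numerically safe softplus
    spec$stiffness * smoothing * (pmax(x / smoothing, 0) +
                                    log1p(exp(-abs(x / smoothing))))
  } else {
    spec$stiffness * pmax(x, 0)
  }
}

# anchor separation (3-D: planar positions + constant z offsets) along a
# trajectory, plus the planar unit vector from left to right anchor
anchor_geometry <- function(model, q, qdot = NULL, spec = NULL) {
  anchors <- spec$anchors %||% c("exo_anchor_r", "exo_anchor_l")
  pk <- forward_kinematics(model, q, qdot, anchors)
  pr <- pk[[anchors[1]]]; pl <- pk[[anchors[2]]]
  dx <- pr$pos[, 1] - pl$pos[, 1]
  dy <- pr$pos[, 2] - pl$pos[, 2]
  dz <- pr$z - pl$z
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  list(distance = d, dx = dx, dy = dy, dz = dz, kin = pk,
       anchors = anchors)
}

#' Anchor separation over a trajectory
#'
#' @param model a `skeleton_model`.
#' @param q coordinate vector or trajectory matrix.
#' @param spec optional [exotendon_spec()] naming the anchors.
#' @return numeric vector of 3-D anchor distances, m.
#' @export
anchor_distance <- function(model, q, spec = NULL) {
  anchor_geometry(model, q, spec = spec)$distance
}

#' Generalized forces applied by the exotendon
#'
#' Equal and opposite forces along the line between the two anchors with
#' magnitude [exotendon_tension()] at the current separation; the planar
#' components are applied to the model (the mediolateral component has no
#' planar coordinate to act on). The resulting force pair has zero net
#' force and zero net moment; its generalized-force projection equals the
#' negative gradient of the spring potential.
#'
#' @param model a `skeleton_model`.
#' @param q coordinate vector or trajectory matrix.
#' @param spec an [exotendon_spec()].
#' @param smoothing tension smoothing width passed to
#'   [exotendon_tension()].
#' @return list with `point_forces` (named list of `n_t x 2` force
#'   matrices keyed by anchor name, for [inverse_dynamics()]), `tension`
#'   (N) and `distance` (m).
#' @export
exotendon_generalized_forces <- function(model, q, spec, smoothing = 0) {
  ag <- anchor_geometry(model, q, spec = spec)
  Tn <- exotendon_tension(ag$distance, spec, smoothing)
  d_safe <- pmax(ag$distance, 1e-9)   # degenerate coincident anchors
  # force on the right anchor points toward the left anchor
  f_r <- cbind(-Tn * ag$dx / d_safe, -Tn * ag$dy / d_safe)
  f_l <- -f_r
  pf <- stats::setNames(list(f_r, f_l), ag$anchors)
  list(point_forces = pf, tension = Tn, distance = ag$distance)
}
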