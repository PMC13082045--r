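#' Exotendon design-space sweep
#'
#' Drives the stiffness x slack-length grid (5 x 5 by default) across
#' candidate stride durations, selects the energetically optimal stride
#' per design, and reports percent changes in average energetic cost
#' relative to simulated natural running, peak tensions and tension
#' profiles.
#'
#' @name design_sweep
NULL

#' Design grid specification
#'
#' @param stiffness stiffness values, N/m.
#' @param slack_pct slack lengths, % of leg length.
#' @param leg_length leg length for the % convention, m.
#' @param stride_scales stride-duration multipliers relative to the
#'   natural stride (sorted ascending).
#' @return a `design_grid` list.
#' @export
design_grid <- function(stiffness = c(30, 60, 120, 180, 240),
                        slack_pct = c(6.25, 12.5, 25, 37.5, 50),
                        leg_length = 0.92,
                        stride_scales = c(0.90, 0.95, 1.00, 1.05)) {
  if (any(stiffness < 0) || any(slack_pct <= 0)) {
    stopf("invalid grid values")
  }
  structure(list(stiffness = stiffness, slack_pct = slack_pct,
                 leg_length = leg_length,
                 stride_scales = sort(stride_scales)),
            class = "design_grid")
}

#' Enumerate the design grid
#'
#' Cartesian product in deterministic stiffness-major order, with slack
#' lengths converted to meters.
#'
#' @param grid a [design_grid()].
#' @return list of [exotendon_spec()]s of length
#'   `length(stiffness) * length(slack_pct)`.
#' @export
enumerate_designs <- function(grid) {
  out <- list()
  for (k in grid$stiffness) {
    for (l in grid$slack_pct) {
      out[[length(out) + 1]] <- exotendon_spec(
        k, slack_pct = l, leg_length = grid$leg_length)
    }
  }
  out
}

#' Percent change relative to a baseline cost
#'
#' @param cost condition cost (W/kg).
#' @param baseline natural-running cost (W/kg, > 0).
#' @return `100 * (cost - baseline) / baseline`; negative = savings.
#' @export
percent_change <- function(cost, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stopf("baseline cost must be positive")
  }
  100 * (cost - baseline) / baseline
}

#' Exotendon tension profile of a solved simulation
#'
#' Tension at each mesh point from the anchor separation via the exact
#' piecewise spring law, aligned to start at heel strike (first upward
#' crossing of 5% body weight by the right vertical GRF) and resampled
#' to 101 points over 0-100% of the gait cycle.
#'
#' @param solution an `ocp_solution`.
#' @param spec the design's [exotendon_spec()] (defaults to the one the
#'   problem was built with).
#' @param n_points profile resolution.
#' @return list with `phase` (0-1), `tension` (N), `peak` (N),
#'   `heel_strike_index`.
#' @export
extract_tension_profile <- function(solution, spec = NULL,
                                    n_points = 101) {
  ocp <- solution$ocp
  spec <- spec %||% ocp$exotendon
  tr <- solution$trajectories
  n <- length(tr$time)
  if (is.null(spec) || spec$stiffness <= 0) {
    return(list(phase = seq(0, 1, length.out = n_points),
                tension = rep(0, n_points), peak = 0,
                heel_strike_index = 1L))
  }
  d <- anchor_distance(ocp$model, tr$coords, spec)
  tension <- exotendon_tension(d, spec)           # exact law
  thr <- 0.05 * ocp$model$mass * GRAVITY
  fy <- tr$grf_r[, 2]
  ups <- which(fy[-1] >= thr & fy[-n] < thr)
  hs <- if (length(ups)) ups[1] + 1L else 1L
  # rotate the periodic profile (first and last node coincide)
  per <- tension[-n]
  rot <- c(per[hs:length(per)], per[seq_len(hs - 1)])
  rot <- c(rot, rot[1])
  u_in <- seq(0, 1, length.out = n)
  u_out <- seq(0, 1, length.out = n_points)
  prof <- stats::approx(u_in, rot, xout = u_out)$y
  list(phase = u_out, tension = prof, peak = max(prof),
       heel_strike_index = hs)
}

#' Run the design sweep
#'
#' For every design in the grid, solves the tracking problem at each
#' stride-duration multiplier and keeps the converged solution with the
#' lowest average energetic cost; the natural baseline is treated the
#' same way. Per-design failures are recorded, never fatal; a
#' non-converging natural baseline is a configuration error.
#'
#' @param model a `skeleton_model`.
#' @param reference the natural-stride [reference_data()].
#' @param grid a [design_grid()].
#' @param config an [ocp_config()].
#' @param designs optional subset (list of [exotendon_spec()]); default
#'   [enumerate_designs()] of the grid.
#' @param natural_scales stride multipliers tried for the natural
#'   baseline (default: the grid's).
#' @param muscle_params optional muscle table.
#' @param store_solutions keep each best `ocp_solution` in the result.
#' @param verbose print one line per design.
#' @return a `sweep_result`: `table` (one row per design: stiffness,
#'   slack %, best stride scale, costs, percent changes net and gross,
#'   peak tension, convergence flag), `baseline` (natural costs),
#'   `profiles` (per-design 101-point tension profiles), `grid`, and
#'   optionally `solutions`.
#' @export
run_sweep <- function(model, reference, grid = design_grid(),
                      config = ocp_config(), designs = NULL,
                      natural_scales = NULL,
                      muscle_params = default_muscle_params(),
                      store_solutions = FALSE, verbose = FALSE) {
  designs <- designs %||% enumerate_designs(grid)
  natural_scales <- natural_scales %||% grid$stride_scales

  solve_best <- function(spec, scales) {
    best <- NULL
    for (s in scales) {
      refs <- rescale_reference(reference, s)
      cfg <- config; cfg$stride_scale <- s
      ocp <- build_tracking_problem(model, refs, spec, cfg, muscle_params)
      sol <- solve_tracking(ocp)
      if (!sol$converged) next
      if (is.null(best) || sol$cost_wkg < best$sol$cost_wkg) {
        best <- list(sol = sol, scale = s)
      }
    }
    best
  }

  nat <- solve_best(NULL, natural_scales)
  if (is.null(nat)) stopf("natural baseline failed to converge")
  base_net <- nat$sol$cost_wkg
  base_gross <- nat$sol$cost_gross_wkg

  rows <- list(); profiles <- list(); sols <- list()
  for (i in seq_along(designs)) {
    spec <- designs[[i]]
    best <- solve_best(spec, grid$stride_scales)
    if (is.null(best)) {
      rows[[i]] <- data.frame(
        design = spec$name, stiffness = spec$stiffness,
        slack_pct = spec$slack_pct, best_scale = NA_real_,
        cost_wkg = NA_real_, cost_gross_wkg = NA_real_,
        pct_change = NA_real_, pct_change_gross = NA_real_,
        peak_tension = NA_real_, converged = FALSE)
      profiles[[spec$name]] <- rep(NA_real_, 101)
      next
    }
    prof <- extract_tension_profile(best$sol, spec)
    rows[[i]] <- data.frame(
      design = spec$name, stiffness = spec$stiffness,
      slack_pct = spec$slack_pct, best_scale = best$scale,
      cost_wkg = best$sol$cost_wkg,
      cost_gross_wkg = best$sol$cost_gross_wkg,
      pct_change = percent_change(best$sol$cost_wkg, base_net),
      pct_change_gross = percent_change(best$sol$cost_gross_wkg,
                                        base_gross),
      peak_tension = prof$peak, converged = TRUE)
    profiles[[spec$name]] <- prof$tension
    if (store_solutions) sols[[spec$name]] <- best$sol
    if (verbose) {
      cat(sprintf("design %-14s k=%3g l=%5.2f%%: cost %.3f W/kg (%+.2f%%), peak %.1f N\n",
                  spec$name, spec$stiffness, spec$slack_pct,
                  best$sol$cost_wkg, rows[[i]]$pct_change, prof$peak))
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table,
                 baseline = list(cost_wkg = base_net,
                                 cost_gross_wkg = base_gross,
                                 best_scale = nat$scale,
                                 solution = if (store_solutions) nat$sol),
                 profiles = profiles, grid = grid,
                 solutions = if (store_solutions) sols),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  n_ok <- sum(x$table$converged)
  cat(sprintf(
    "<sweep_result> %d designs (%d converged); natural %.3f W/kg\n",
    nrow(x$table), n_ok, x$baseline$cost_wkg))
  if (n_ok) {
    best <- x$table[which.min(x$table$pct_change), ]
    cat(sprintf("  best: k=%g N/m, slack %.3g%% (%+.2f%%)\n",
                best$stiffness, best$slack_pct, best$pct_change))
  }
  invisible(x)
}

#' Rank designs by predicted percent change
#'
#' Ascending percent change (most negative = largest predicted savings),
#' with ties broken by grid order. Reports the four named experimental
#' presets with their grid values and flags the predicted-optimal
#' design.
#'
#' @param sweep a `sweep_result`.
#' @return list: `ranked` (the sweep table, ordered, with `rank`),
#'   `optimal` (top row), `presets` (rows for the four named designs
#'   with their predicted changes).
#' @export
rank_designs <- function(sweep) {
  tab <- sweep$table
  ord <- order(tab$pct_change, seq_len(nrow(tab)), na.last = TRUE)
  ranked <- tab[ord, ]
  ranked$rank <- seq_len(nrow(ranked))
  presets <- lapply(c("medium-original", "long-stiff", "short-stiff",
                      "long-compliant"), function(nm) {
    sp <- exotendon_preset(nm, leg_length = sweep$grid$leg_length)
    hit <- tab[tab$stiffness == sp$stiffness &
                 abs(tab$slack_pct - sp$slack_pct) < 1e-9, , drop = FALSE]
    if (nrow(hit)) hit$design <- nm
    hit
  })
  presets <- do.call(rbind, presets)
  list(ranked = ranked, optimal = ranked[1, ], presets = presets)
}

#' Write the sweep table as a Table-1-style CSV
#'
#' Rows = stiffness (N/m), columns = slack length (% leg length), cells
#' = percent change in average energetic cost vs natural; non-converged
#' cells are written as `"failed"`.
#'
#' @param sweep a `sweep_result`.
#' @param path output CSV path.
#' @param gross use the gross (basal-included) percent changes.
#' @return `path` invisibly.
#' @export
write_sweep_csv <- function(sweep, path, gross = FALSE) {
  g <- sweep$grid
  col <- if (gross) "pct_change_gross" else "pct_change"
  M <- matrix("failed", length(g$stiffness), length(g$slack_pct),
              dimnames = list(paste0("k_", g$stiffness),
                              paste0("slack_", g$slack_pct)))
  for (i in seq_len(nrow(sweep$table))) {
    r <- sweep$table[i, ]
    ri <- match(r$stiffness, g$stiffness)
    ci <- which(abs(g$slack_pct - r$slack_pct) < 1e-9)
    if (!is.na(ri) && length(ci) && isTRUE(r$converged)) {
      M[ri, ci] <- sprintf("%.2f", r[[col]])
    }
  }
  df <- data.frame(stiffness_N_per_m = g$stiffness, M,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
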