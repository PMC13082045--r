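#' Marker-derived exotendon tension
#'
#' In-lab exotendon tension is estimated from the two shoe markers: the
#' Euclidean distance between their 3-D positions gives the spring
#' length, stretch is that distance minus the known slack length, and
#' tension is stiffness times stretch (zero when slack). Trials are
#' segmented into gait cycles at ipsilateral foot strikes detected as
#' vertical-position minima of a shoe marker; per-cycle profiles are
#' time-normalized to 101 points, averaged across cycles within each
#' runner and then across runners.
#'
#' @name markers
NULL

#' Segment a marker trial into gait cycles
#'
#' Foot-strike events are local minima of the first marker's vertical
#' position, found with a prominence threshold and a minimum-period guard
#' (both config parameters).
#'
#' @param trial a [marker_trial()].
#' @param min_prominence minimum peak prominence, m.
#' @param min_period minimum cycle duration, s.
#' @param min_cycles minimum acceptable number of cycles.
#' @return integer vector of cycle-boundary sample indices (each the
#'   start of a cycle; cycle i spans `[b[i], b[i+1])`).
#' @export
segment_gait_cycles <- function(trial, min_prominence = 0.01,
                                min_period = 0.3, min_cycles = 5) {
  h <- trial$p1[, 2]
  y <- -h                      # minima of height = maxima of -height
  pk <- pracma::findpeaks(y, minpeakdistance =
                            max(2L, round(min_period * trial$rate)),
                          zero = "0")
  if (!is.null(pk)) {
    # prominence guard: the minimum must dip below the series median
    pk <- pk[pk[, 1] >= -stats::median(h) + min_prominence, , drop = FALSE]
  }
  if (is.null(pk) || nrow(pk) < min_cycles + 1) {
    stopf("fewer than %d gait cycles detected", min_cycles)
  }
  sort(pk[, 2])
}

# fill marker gaps (NA runs) up to max_gap samples by linear interpolation;
# returns the matrix plus a logical vector flagging still-missing samples
fill_marker_gaps <- function(p, max_gap = 5) {
  bad <- rowSums(is.na(p)) > 0
  if (!any(bad)) return(list(p = p, missing = bad))
  r <- rle(bad)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in which(r$values & r$lengths <= max_gap)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1 || i1 == nrow(p)) next     # edge gaps stay missing
    for (col in 1:3) {
      p[i0:i1, col] <- stats::approx(c(i0 - 1, i1 + 1),
                                     p[c(i0 - 1, i1 + 1), col],
                                     xout = i0:i1)$y
    }
  }
  list(p = p, missing = rowSums(is.na(p)) > 0)
}

#' Tension profiles from a marker trial
#'
#' @param trial a [marker_trial()].
#' @param spec the worn [exotendon_spec()] (defaults to `trial$spec`).
#' @param n_points profile resolution over the normalized gait cycle
#'   (0-100% inclusive).
#' @param max_gap maximum marker gap (samples) bridged by linear
#'   interpolation; cycles containing longer gaps are dropped.
#' @param ... passed to [segment_gait_cycles()].
#' @return list: `profiles` (`n_cycles x n_points` matrix, N), `mean`
#'   (runner-mean profile), `peak` (N, peak of the mean profile),
#'   `tension` (per-sample tension series), `distance` (per-sample
#'   marker separation, m), `dropped_cycles` (count).
#' @export
tension_from_markers <- function(trial, spec = NULL, n_points = 101,
                                 max_gap = 5, ...) {
  spec <- spec %||% trial$spec
  if (is.null(spec)) stopf("no exotendon spec for this trial")
  g1 <- fill_marker_gaps(trial$p1, max_gap)
  g2 <- fill_marker_gaps(trial$p2, max_gap)
  dvec <- sqrt(rowSums((g1$p - g2$p)^2))
  missing <- g1$missing | g2$missing
  tension <- exotendon_tension(ifelse(missing, 0, dvec), spec)
  # segment on the gap-filled series; unfillable samples are pushed high
  # so they can never register as foot-strike minima
  seg_trial <- trial
  seg_trial$p1 <- g1$p
  if (any(g1$missing)) {
    seg_trial$p1[g1$missing, 2] <- max(g1$p[, 2], na.rm = TRUE) + 1
  }
  bounds <- segment_gait_cycles(seg_trial, ...)
  u <- seq(0, 1, length.out = n_points)
  profs <- list(); dropped <- 0L
  for (i in seq_len(length(bounds) - 1)) {
    idx <- bounds[i]:bounds[i + 1]
    if (any(missing[idx])) { dropped <- dropped + 1L; next }
    s <- (idx - idx[1]) / (idx[length(idx)] - idx[1])
    profs[[length(profs) + 1]] <- stats::approx(s, tension[idx],
                                                xout = u)$y
  }
  if (!length(profs)) stopf("no complete gait cycles after gap handling")
  P <- do.call(rbind, profs)
  m <- colMeans(P)
  list(profiles = P, mean = m, peak = max(m), tension = tension,
       distance = dvec, dropped_cycles = dropped, phase = u)
}

#' Group-average tension profiles across runners
#'
#' Cycle-averaged profiles are first averaged within each runner, then
#' across runners for each condition.
#'
#' @param runner_results list (one per runner) of [tension_from_markers()]
#'   outputs.
#' @return list with `mean` profile, `sd` profile and `peak` of the group
#'   mean.
#' @export
group_tension_profile <- function(runner_results) {
  M <- do.call(rbind, lapply(runner_results, `[[`, "mean"))
  m <- colMeans(M)
  list(mean = m, sd = apply(M, 2, stats::sd), peak = max(m))
}
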