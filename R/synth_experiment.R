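#' Synthetic experimental recordings
#'
#' Generators for marker trials and breath-by-breath calorimetry with
#' known ground truth, emulating the in-lab measurement campaign: one
#' retroreflective marker per shoe at 200 Hz, 6-minute treadmill trials
#' with breath-by-breath gas exchange, a 5-minute standing baseline, and
#' paired 5-km track sessions. Every generator is a pure function of its
#' parameters and seed, and returns its ground truth alongside the data;
#' the analysis pipeline never reads the ground truth.
#'
#' @name synthetic_experiment
NULL

#' Marker trial container
#'
#' @param time sample times, s.
#' @param p1,p2 `n x 3` marker position matrices (x forward, y up, z
#'   mediolateral), m.
#' @param rate sampling rate, Hz.
#' @param spec the [exotendon_spec()] worn (or `NULL`).
#' @param runner runner identifier.
#' @return a `marker_trial` object.
#' @export
marker_trial <- function(time, p1, p2, rate, spec = NULL, runner = NA) {
  if (nrow(p1) != length(time) || nrow(p2) != length(time)) {
    stopf("marker series must have equal length")
  }
  structure(list(time = time, p1 = p1, p2 = p2, rate = rate, spec = spec,
                 runner = runner), class = "marker_trial")
}

#' Generate a synthetic two-marker shoe trial
#'
#' Constructs two foot-marker trajectories whose 3-D separation encodes a
#' prescribed smooth periodic tension profile under the given exotendon:
#' `distance(t) = slack + s(t)/k`, where `s` is a signed virtual
#' extension whose positive part is the ground-truth tension. Marker
#' vertical position has one clean minimum per cycle at the cycle start
#' (heel strike), which is what the gait-cycle segmentation keys on.
#' Isotropic Gaussian noise is added after construction.
#'
#' @param spec an [exotendon_spec()] with `stiffness > 0`.
#' @param stride_duration gait-cycle duration, s.
#' @param n_cycles number of gait cycles (>= 5 for the analysis
#'   pipeline).
#' @param peak_tension peak of the ground-truth tension profile, N; use 0
#'   for a never-taut trial.
#' @param rate sampling rate, Hz (default 200).
#' @param noise_sd isotropic marker noise SD, m.
#' @param speed forward speed of the marker midpoint, m/s.
#' @param seed integer seed.
#' @param runner runner identifier.
#' @return a `marker_trial` with attributes `"truth"` (function mapping
#'   stride phase in `[0, 1]` to tension, N) and `"truth_profile"` (the
#'   tension sampled at 101 phase points).
#' @export
generate_marker_trial <- function(spec, stride_duration = 0.7,
                                  n_cycles = 8, peak_tension = 100,
                                  rate = 200, noise_sd = 0,
                                  speed = 4, seed = 0, runner = 1) {
  if (spec$stiffness <= 0) stopf("marker generator needs k > 0")
  n <- round(n_cycles * stride_duration * rate) + 1
  time <- (seq_len(n) - 1) / rate
  # the recording starts mid-swing so foot-strike minima are interior
  # (a strike at the very first sample would be undetectable)
  phi <- (time / stride_duration + 0.75) %% 1
  # taut bump early in the cycle, a genuinely slack dip later; the two
  # windows do not overlap, so the recovered tension is exactly the
  # prescribed bump
  truth_fun <- function(ph) peak_tension * bump(ph, 0.05, 0.45)
  d <- spec$slack_m + truth_fun(phi) / spec$stiffness -
    0.3 * spec$slack_m * bump(phi, 0.55, 0.4)
  if (any(d <= 0)) stopf("tension profile incompatible with slack length")
  # marker midpoint path and a slowly swinging separation direction
  mid <- cbind(speed * time + 0.05 * sin(2 * pi * phi),
               0.10 + 0.04 * (1 - cos(2 * pi * phi)),
               0.01 * sin(2 * pi * phi))
  ux <- 0.25 * sin(2 * pi * phi)
  uy <- 0.05 * cos(2 * pi * phi)
  uz <- rep(1, n)
  un <- sqrt(ux^2 + uy^2 + uz^2)
  u <- cbind(ux, uy, uz) / un
  p1 <- mid + u * (d / 2)
  p2 <- mid - u * (d / 2)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "markers"))
    p1 <- p1 + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    p2 <- p2 + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
  }
  out <- marker_trial(time, p1, p2, rate, spec, runner)
  attr(out, "truth") <- truth_fun
  attr(out, "truth_profile") <- truth_fun(seq(0, 1, length.out = 101))
  attr(out, "stride_duration") <- stride_duration
  out
}

#' Calorimetry study specification
#'
#' @param n_subjects number of runners (>= 3).
#' @param conditions condition labels; first must be the natural
#'   (unassisted) condition.
#' @param effects_pct named percent change in net running power per
#'   condition relative to natural (negative = savings). Defaults follow
#'   the measured in-lab deltas.
#' @param baseline_mean,baseline_sd distribution of per-subject natural
#'   net running power, W/kg.
#' @param standing_gross standing gross power, W/kg.
#' @param mass_mean,mass_sd body-mass distribution, kg.
#' @param breath_rate breaths per second.
#' @param noise_sd log-normal multiplicative noise SD on VO2 per breath.
#' @param rer_mean,rer_sd respiratory-exchange-ratio process mean and
#'   between-breath SD.
#' @param rer_exceed_rate probability a running trial is generated with
#'   mean RER > 1.0 (to exercise the exclusion rule).
#' @param trial_minutes,standing_minutes record lengths.
#' @param ramp_tau time constant of the on-transient, s.
#' @param seed integer seed.
#' @return a `calorimetry_spec` list.
#' @export
calorimetry_spec <- function(n_subjects = 11,
                             conditions = c("natural", "long-compliant",
                                            "medium-original",
                                            "short-stiff", "long-stiff"),
                             effects_pct = c("natural" = 0,
                                             "long-compliant" = -1.9,
                                             "medium-original" = -5.7,
                                             "short-stiff" = -3.8,
                                             "long-stiff" = -1.9),
                             baseline_mean = 10, baseline_sd = 1,
                             standing_gross = 1.6,
                             mass_mean = 68, mass_sd = 7,
                             breath_rate = 0.75, noise_sd = 0.04,
                             rer_mean = 0.88, rer_sd = 0.02,
                             rer_exceed_rate = 0,
                             trial_minutes = 6, standing_minutes = 5,
                             ramp_tau = 30, seed = 0) {
  if (n_subjects < 3) stopf("need at least 3 subjects")
  if (baseline_sd < 0 || noise_sd < 0 || rer_sd < 0) {
    stopf("standard deviations must be >= 0")
  }
  if (!all(conditions %in% names(effects_pct))) {
    stopf("every condition needs an entry in effects_pct")
  }
  structure(as.list(environment()), class = "calorimetry_spec")
}

#' Breath-by-breath record container
#'
#' @param time breath timestamps, s (strictly increasing).
#' @param vo2,vco2 per-breath gas flows, L/min (non-negative).
#' @param trial trial label.
#' @param mass body mass, kg.
#' @param subject subject id.
#' @param condition condition label.
#' @return a `breath_record` object.
#' @export
breath_record <- function(time, vo2, vco2, trial = "", mass = NA,
                          subject = NA, condition = NA) {
  if (any(diff(time) <= 0)) stopf("breath timestamps must increase")
  if (any(vo2 < 0) || any(vco2 < 0)) stopf("gas flows must be >= 0")
  structure(list(time = time, vo2 = vo2, vco2 = vco2, trial = trial,
                 mass = mass, subject = subject, condition = condition),
            class = "breath_record")
}

# Brockway gas-exchange-to-power equation, W from L/min
brockway_power <- function(vo2_L_min, vco2_L_min) {
  (16.58e3 * vo2_L_min + 4.51e3 * vco2_L_min) / 60
}

# invert Brockway at a given RER: vo2 (L/min) producing power P (W)
brockway_vo2 <- function(P, rer) {
  P * 60 / (16.58e3 + 4.51e3 * rer)
}

#' Generate a breath-by-breath calorimetry dataset
#'
#' Per subject: one standing record plus one running record per
#' condition. Running gross power ramps exponentially from standing to
#' the steady state (the identical transient across conditions leaves
#' final-minute percent changes exact in the noiseless limit). Breath
#' noise is log-normal multiplicative on VO2 with VCO2 tied to a
#' per-breath RER process, so the measured RER is noise-consistent.
#'
#' @param spec a [calorimetry_spec()].
#' @return list with `records` (list of [breath_record()]s, including one
#'   with condition `"standing"` per subject) and `truth` (subject
#'   baselines W/kg, injected percent effects, masses, and which trials
#'   were generated as RER-exceeding).
#' @export
generate_calorimetry_dataset <- function(spec) {
  set.seed(derive_seed(spec$seed, "calorimetry"))
  ns <- spec$n_subjects
  mass <- pmax(stats::rnorm(ns, spec$mass_mean, spec$mass_sd), 40)
  base_net <- stats::rnorm(ns, spec$baseline_mean, spec$baseline_sd)
  base_net <- pmax(base_net, 0.2 * spec$baseline_mean)
  records <- list()
  exceed <- character(0)
  make_record <- function(subject, condition, net_wkg, minutes, label) {
    dur <- minutes * 60
    n_b <- floor(dur * spec$breath_rate)
    tb <- (seq_len(n_b)) / spec$breath_rate
    gross_ss <- (spec$standing_gross + net_wkg) * mass[subject]
    gross_stand <- spec$standing_gross * mass[subject]
    P <- if (net_wkg > 0) {
      gross_stand + (gross_ss - gross_stand) * (1 - exp(-tb / spec$ramp_tau))
    } else rep(gross_stand, n_b)
    rer_target <- if (label %in% exceed) 1.04 else spec$rer_mean
    rer <- rer_target + spec$rer_sd * stats::rnorm(n_b)
    vo2 <- brockway_vo2(P, rer)
    if (spec$noise_sd > 0) {
      vo2 <- vo2 * exp(stats::rnorm(n_b, -spec$noise_sd^2 / 2,
                                    spec$noise_sd))
    }
    vco2 <- rer * vo2
    breath_record(tb, vo2, pmax(vco2, 0), trial = label,
                  mass = mass[subject], subject = subject,
                  condition = condition)
  }
  for (s in seq_len(ns)) {
    for (cond in spec$conditions) {
      if (spec$rer_exceed_rate > 0 &&
          stats::runif(1) < spec$rer_exceed_rate) {
        exceed <- c(exceed, sprintf("s%d_%s", s, cond))
      }
    }
  }
  for (s in seq_len(ns)) {
    records[[sprintf("s%d_standing", s)]] <-
      make_record(s, "standing", 0, spec$standing_minutes,
                  sprintf("s%d_standing", s))
    for (cond in spec$conditions) {
      eff <- spec$effects_pct[[cond]]
      net <- base_net[s] * (1 + eff / 100)
      lab <- sprintf("s%d_%s", s, cond)
      records[[lab]] <- make_record(s, cond, net, spec$trial_minutes, lab)
    }
  }
  list(records = records,
       truth = list(baseline_net_wkg = base_net,
                    effects_pct = spec$effects_pct, mass = mass,
                    rer_exceeding = exceed))
}

#' Generate paired 5-km track sessions
#'
#' One natural and one exotendon session per runner with configurable
#' mean paired effects (exotendon minus natural) and between-runner SDs.
#' Defaults follow the reported time-trial contrasts: run time -13.5 s
#' (SD 24.6), heart rate -3.9 bpm (SD 3.8), cadence +15.9 spm (SD 9.6).
#'
#' @param n_runners number of runners.
#' @param effects named means of the paired differences
#'   (`time_s`, `hr_bpm`, `cadence_spm`).
#' @param sds named SDs of the paired differences.
#' @param natural_means named means of the natural-session metrics.
#' @param seed integer seed.
#' @return data.frame with columns `runner`, `condition`, `time_s`,
#'   `hr_bpm`, `cadence_spm`; attribute `"truth"` holds the injected
#'   effects.
#' @export
generate_track_sessions <- function(n_runners = 10,
                                    effects = c(time_s = -13.5,
                                                hr_bpm = -3.9,
                                                cadence_spm = 15.9),
                                    sds = c(time_s = 24.6, hr_bpm = 3.8,
                                            cadence_spm = 9.6),
                                    natural_means = c(time_s = 1120,
                                                      hr_bpm = 175,
                                                      cadence_spm = 172),
                                    seed = 0) {
  set.seed(derive_seed(seed, "track"))
  metrics <- names(effects)
  nat <- sapply(metrics, function(m) {
    natural_means[[m]] + 0.05 * abs(natural_means[[m]]) *
      stats::rnorm(n_runners)
  })
  dif <- sapply(metrics, function(m) {
    effects[[m]] + sds[[m]] * stats::rnorm(n_runners)
  })
  out <- rbind(
    data.frame(runner = seq_len(n_runners), condition = "natural", nat),
    data.frame(runner = seq_len(n_runners), condition = "exotendon",
               nat + dif))
  rownames(out) <- NULL
  attr(out, "truth") <- list(effects = effects, sds = sds)
  out
}
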