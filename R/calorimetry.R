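#' Indirect calorimetry processing
#'
#' Breath-by-breath gas exchange is converted to metabolic power with the
#' Brockway equation (16.58 kJ/L O2 + 4.51 kJ/L CO2), time-weight
#' averaged over the final minute of each trial, normalized by body mass,
#' and net cost obtained by subtracting the standing baseline processed
#' the same way. Trials whose mean respiratory exchange ratio (RER =
#' VCO2/VO2) over the averaging window exceeds 1.0 are flagged excluded
#' (anaerobic contribution invalidates the steady-state estimate).
#'
#' @name calorimetry
NULL

# time-weighted mean of per-breath values over the final `window` seconds
final_window_mean <- function(time, value, window = 60) {
  t_end <- time[length(time)]
  keep <- time >= t_end - window
  if (sum(keep) < 2 || (time[length(time)] - time[keep][1]) < 0.8 * window) {
    stopf("averaging window shorter than %g s of data", window)
  }
  tt <- time[keep]; vv <- value[keep]
  w <- trapz_weights(tt)
  sum(w * vv) / sum(w)
}

#' Read / write breath-by-breath tables as CSV
#'
#' Columns `time_s`, `vo2_L_min`, `vco2_L_min` (plus optional metadata
#' columns `trial`, `mass_kg`, `subject`, `condition`).
#'
#' @param record a [breath_record()].
#' @param path CSV file path.
#' @return the reader returns a [breath_record()]; the writer returns
#'   `path` invisibly.
#' @export
write_breath_csv <- function(record, path) {
  utils::write.csv(data.frame(
    time_s = record$time, vo2_L_min = record$vo2,
    vco2_L_min = record$vco2, trial = record$trial,
    mass_kg = record$mass, subject = record$subject,
    condition = record$condition), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_breath_csv
#' @export
read_breath_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "vo2_L_min", "vco2_L_min")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("breath CSV missing columns: %s",
                          paste(miss, collapse = ", "))
  breath_record(d$time_s, d$vo2_L_min, d$vco2_L_min,
                trial = d$trial[1] %||% "", mass = d$mass_kg[1] %||% NA,
                subject = d$subject[1] %||% NA,
                condition = d$condition[1] %||% NA)
}

#' Net metabolic power of a running trial
#'
#' @param trial a [breath_record()] of the running trial (>= `min_trial_s`
#'   seconds of data).
#' @param standing a [breath_record()] of the standing baseline
#'   (>= `min_standing_s` seconds).
#' @param window averaging window, s (final minute by default; the RER is
#'   averaged over the same window).
#' @param min_trial_s,min_standing_s minimum record durations, s.
#' @return a `trial_metabolics` list: `gross_wkg`, `standing_wkg`,
#'   `net_wkg` (gross minus standing), `rer` (mean over the window),
#'   `excluded` (`TRUE` iff `rer > 1.0`), `mass`, `condition`, `subject`.
#' @export
net_metabolic_power <- function(trial, standing, window = 60,
                                min_trial_s = 360, min_standing_s = 300) {
  if (trial$time[length(trial$time)] < min_trial_s) {
    stopf("running trial shorter than %g s", min_trial_s)
  }
  if (standing$time[length(standing$time)] < min_standing_s) {
    stopf("standing record shorter than %g s", min_standing_s)
  }
  if (is.na(trial$mass) || trial$mass <= 0) stopf("trial needs a body mass")
  p_tr <- final_window_mean(trial$time,
                            brockway_power(trial$vo2, trial$vco2), window)
  p_st <- final_window_mean(standing$time,
                            brockway_power(standing$vo2, standing$vco2),
                            window)
  rer <- final_window_mean(trial$time, trial$vco2 / pmax(trial$vo2, 1e-12),
                           window)
  gross <- p_tr / trial$mass
  standing_wkg <- p_st / trial$mass
  structure(list(gross_wkg = gross, standing_wkg = standing_wkg,
                 net_wkg = gross - standing_wkg, rer = rer,
                 excluded = rer > 1.0, mass = trial$mass,
                 condition = trial$condition, subject = trial$subject),
            class = "trial_metabolics")
}

#' Percent change in net cost per condition
#'
#' Relative to the same runner's natural trial:
#' `100 * (net_cond - net_natural) / net_natural`. Excluded conditions
#' propagate as missing values (never zeros).
#'
#' @param trials named list of `trial_metabolics`, one per exotendon
#'   condition.
#' @param natural the runner's natural-condition `trial_metabolics`.
#' @return named numeric vector of percent changes (NA where excluded).
#' @export
percent_change_by_condition <- function(trials, natural) {
  if (isTRUE(natural$excluded)) {
    stopf("natural trial excluded (RER > 1.0); no reference for subject")
  }
  if (natural$net_wkg <= 0) stopf("natural net power must be positive")
  vapply(trials, function(tr) {
    if (isTRUE(tr$excluded)) return(NA_real_)
    100 * (tr$net_wkg - natural$net_wkg) / natural$net_wkg
  }, numeric(1))
}

#' Process a whole calorimetry dataset
#'
#' Runs [net_metabolic_power()] for every subject x condition and
#' assembles the per-subject percent-change table.
#'
#' @param records list of [breath_record()]s as produced by
#'   [generate_calorimetry_dataset()] (one `"standing"` record per
#'   subject).
#' @param window averaging window, s.
#' @return data.frame with `subject`, `condition`, `net_wkg`, `rer`,
#'   `excluded`, `pct_change` (NA for the natural rows and excluded
#'   trials).
#' @export
process_calorimetry <- function(records, window = 60) {
  conds <- vapply(records, function(r) as.character(r$condition), "")
  subs <- vapply(records, function(r) as.integer(r$subject), 1L)
  out <- list()
  for (s in unique(subs)) {
    standing <- records[[which(subs == s & conds == "standing")[1]]]
    idx <- which(subs == s & conds != "standing")
    tm <- lapply(idx, function(i) net_metabolic_power(records[[i]],
                                                      standing, window))
    names(tm) <- conds[idx]
    natural <- tm[["natural"]]
    pct <- if (isTRUE(natural$excluded)) {
      # no within-subject reference: whole subject drops from comparisons
      stats::setNames(rep(NA_real_, sum(names(tm) != "natural")),
                      names(tm)[names(tm) != "natural"])
    } else {
      percent_change_by_condition(tm[names(tm) != "natural"], natural)
    }
    out[[length(out) + 1]] <- data.frame(
      subject = s, condition = names(tm),
      net_wkg = vapply(tm, `[[`, 0, "net_wkg"),
      rer = vapply(tm, `[[`, 0, "rer"),
      excluded = vapply(tm, `[[`, TRUE, "excluded"),
      pct_change = c(NA_real_, pct)[match(names(tm),
                                          c("natural", names(pct)))])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
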