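make_const_record <- function(vo2, vco2, minutes, mass = 70,
                              condition = NA, subject = 1L,
                              rate = 0.75) {
  n <- floor(minutes * 60 * rate)
  breath_record(seq_len(n) / rate, rep(vo2, n), rep(vco2, n),
                mass = mass, subject = subject, condition = condition)
}

test_that("constant gas exchange reproduces the Brockway value by hand", {
  # 3 L/min O2, RER 0.9: P = (16.58e3*3 + 4.51e3*2.7)/60 W
  tr <- make_const_record(3, 2.7, 6)
  st <- make_const_record(0.3, 0.25, 5)
  out <- net_metabolic_power(tr, st)
  hand_tr <- (16.58e3 * 3 + 4.51e3 * 2.7) / 60
  hand_st <- (16.58e3 * 0.3 + 4.51e3 * 0.25) / 60
  expect_equal(out$gross_wkg, hand_tr / 70, tolerance = 1e-12)
  expect_equal(out$net_wkg, (hand_tr - hand_st) / 70, tolerance = 1e-12)
  expect_equal(out$rer, 0.9, tolerance = 1e-12)
  expect_false(out$excluded)
})

test_that("breath tables round-trip through CSV", {
  r <- make_const_record(3, 2.7, 6, condition = "natural", subject = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_breath_csv(r, path)
  back <- read_breath_csv(path)
  expect_equal(back$time, r$time)
  expect_equal(back$vo2, r$vo2)
  expect_equal(back$mass, r$mass)
  expect_equal(as.character(back$condition), "natural")
  # missing required column rejected
  d <- utils::read.csv(path); d$vo2_L_min <- NULL
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_breath_csv(path), "missing columns")
})

test_that("trial identical to standing gives zero net power", {
  tr <- make_const_record(0.35, 0.3, 6)
  st <- make_const_record(0.35, 0.3, 5)
  expect_equal(net_metabolic_power(tr, st)$net_wkg, 0, tolerance = 1e-12)
})

test_that("mean RER above 1.0 flags exclusion; short records error", {
  tr <- make_const_record(3, 3.06, 6)      # RER 1.02
  st <- make_const_record(0.3, 0.25, 5)
  out <- net_metabolic_power(tr, st)
  expect_true(out$excluded)
  expect_gt(out$rer, 1.0)

  expect_error(net_metabolic_power(make_const_record(3, 2.7, 3), st),
               "shorter")
  expect_error(net_metabolic_power(tr, make_const_record(0.3, 0.25, 2)),
               "shorter")
})

test_that("averaging is invariant to integral-preserving resampling", {
  # halve the breath rate (double spacing), same underlying signal
  t1 <- seq(1, 360, by = 1)
  t2 <- seq(1, 360, by = 0.5)
  f <- function(t) 3 + 0.2 * sin(2 * pi * t / 47)
  tr1 <- breath_record(t1, f(t1), 0.9 * f(t1), mass = 70)
  tr2 <- breath_record(t2, f(t2), 0.9 * f(t2), mass = 70)
  st <- make_const_record(0.3, 0.25, 5)
  p1 <- net_metabolic_power(tr1, st)$gross_wkg
  p2 <- net_metabolic_power(tr2, st)$gross_wkg
  expect_lt(abs(p1 - p2) / p2, 0.005)
})

test_that("percent changes propagate exclusions and reject bad baselines", {
  mk <- function(net, excluded = FALSE) {
    structure(list(net_wkg = net, excluded = excluded),
              class = "trial_metabolics")
  }
  nat <- mk(10)
  out <- percent_change_by_condition(
    list(a = mk(9.43), b = mk(10), c = mk(11, excluded = TRUE)), nat)
  expect_equal(unname(out["a"]), -5.7, tolerance = 1e-12)
  expect_equal(unname(out["b"]), 0)
  expect_true(is.na(out["c"]))
  expect_error(percent_change_by_condition(list(mk(9)), mk(10, TRUE)),
               "excluded")
})

test_that("noiseless injected effects pass through the pipeline exactly", {
  spec <- calorimetry_spec(n_subjects = 3, noise_sd = 0, rer_sd = 0,
                           baseline_sd = 0, mass_sd = 0, seed = 1)
  ds <- generate_calorimetry_dataset(spec)
  tab <- process_calorimetry(ds$records)
  for (cond in names(spec$effects_pct)[-1]) {
    got <- tab$pct_change[tab$condition == cond]
    expect_equal(got, rep(spec$effects_pct[[cond]], 3), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("RER-exceedance generation drives exclusions at the set rate", {
  counts <- vapply(1:30, function(s) {
    spec <- calorimetry_spec(n_subjects = 4, rer_exceed_rate = 0.1,
                             seed = s)
    ds <- generate_calorimetry_dataset(spec)
    tab <- process_calorimetry(ds$records)
    sum(tab$excluded)
  }, numeric(1))
  n_trials <- 30 * 4 * 5
  p_hat <- sum(counts) / n_trials
  se <- sqrt(0.1 * 0.9 / n_trials)
  expect_lt(abs(p_hat - 0.1), 3 * se)
})
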