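test_that("muscle parameter table is valid and CSV round-trips", {
  mp <- default_muscle_params()
  expect_equal(nrow(mp), 18L)            # nine groups per leg
  expect_setequal(unique(mp$group),
                  c("iliopsoas", "glut_max", "rect_fem", "hamstrings",
                    "vasti", "bifemsh", "gastroc", "soleus", "tib_ant"))
  expect_true(all(mp$fmax_N > 0 & mp$lopt_m > 0 & mp$lts_m > 0 &
                    mp$mass_kg > 0 & mp$widen >= 1))
  # doubling: force_scale enters linearly
  mp1 <- default_muscle_params(force_scale = 1)
  expect_equal(mp$fmax_N, 2 * mp1$fmax_N)
  path <- withr::local_tempfile(fileext = ".csv")
  write_muscle_params(mp, path)
  expect_equal(read_muscle_params(path)$fmax_N, mp$fmax_N)

  # the bundled versioned table matches the in-code defaults
  bundled <- read_muscle_params(
    system.file("extdata", "muscle_params.csv", package = "exotendon"))
  expect_equal(bundled$fmax_N, mp$fmax_N)
  expect_equal(bundled$mass_kg, mp$mass_kg, tolerance = 1e-9)
  expect_identical(bundled$name, mp$name)
})

test_that("activation dynamics is a signed smooth first-order lag", {
  expect_equal(activation_rate(0.4, 0.4), 0)
  expect_gt(activation_rate(1, 0), 1)     # ~1/tau_act scale, positive
  expect_lt(activation_rate(0, 1), 0)
  expect_error(activation_rate(1.2, 0), "\\[0, 1\\]")
  set.seed(2)
  e <- stats::runif(100); a <- stats::runif(100)
  expect_true(all(sign(activation_rate(e, a)) == sign(e - a)))
})

test_that("activation step response reaches 63% in about one time constant", {
  tau <- 0.015
  a <- 0; dt <- 1e-5; t <- 0
  while (a < 1 - exp(-1)) {
    a <- a + dt * activation_rate(1, a, tau_act = tau)
    t <- t + dt
  }
  expect_equal(t, tau, tolerance = 0.05)
})

test_that("active force-length widening rescales deviations about optimum", {
  expect_equal(active_force_length(1, 1), 1)
  expect_equal(active_force_length(1, 1.5), 1)
  for (d in c(-0.3, -0.1, 0.15, 0.4)) {
    expect_equal(active_force_length(1 + d, 1.5),
                 active_force_length(1 + d / 1.5, 1), tolerance = 1e-12)
  }
  # widened curve is strictly larger away from the optimum
  expect_gt(active_force_length(1.3, 1.5), active_force_length(1.3, 1))
})

test_that("force-velocity, passive and tendon curves have Hill-type limits", {
  expect_equal(force_velocity(0), 1, tolerance = 1e-12)
  expect_lt(force_velocity(-1), 0.05)     # near-zero at max shortening
  expect_gt(force_velocity(0.8), 1.2)     # eccentric plateau
  # monotone increasing
  v <- seq(-1, 1, length.out = 201)
  expect_true(all(diff(force_velocity(v)) > 0))
  expect_equal(tendon_force(1), 0)
  expect_lt(abs(passive_force_length(1)), 1e-12)
  expect_equal(passive_force_length(1.6), 1, tolerance = 1e-12)
})

test_that("all multiplier curves are C1 (finite-difference gradient check)", {
  h <- 1e-6
  for (f in list(function(x) active_force_length(x, 1.5),
                 force_velocity, passive_force_length, tendon_force)) {
    x <- seq(0.6, 1.4, length.out = 41)
    g1 <- (f(x + h) - f(x - h)) / (2 * h)
    g2 <- (f(x + 2 * h) - f(x - 2 * h)) / (4 * h)
    expect_lt(max(abs(g1 - g2) / (1 + abs(g1))), 1e-5)
  }
})

test_that("fiber-tendon equilibrium: rigid limit, slack tendon, dual solvers", {
  mp <- default_muscle_params()
  sol <- mp[mp$name == "soleus_r", ]
  # slack tendon, no activation, fiber at optimum: residual ~ 0
  st0 <- muscle_state(activation = 0, lm_norm = 1, vm_norm = 0)
  lmtu_slack <- sol$lopt_m * cos(sol$alpha0_rad) + sol$lts_m
  expect_lt(abs(mtu_equilibrium_residual(sol, st0, lmtu_slack)),
            1e-6 * sol$fmax_N)

  # bisection root vs damped-integration oracle
  a <- 0.6
  lmtu <- lmtu_slack * 1.01
  ln_root <- solve_fiber_equilibrium(sol, a, lmtu)
  # oracle: damped integration toward equilibrium (the residual
  # increases with fiber length, so relax against it)
  ln <- 1
  for (i in 1:2000) {
    r <- mtu_equilibrium_residual(
      sol, muscle_state(activation = a, lm_norm = ln), lmtu)
    ln <- ln - 0.05 * r / sol$fmax_N
  }
  r_bis <- mtu_equilibrium_residual(
    sol, muscle_state(activation = a, lm_norm = ln_root), lmtu)
  r_int <- mtu_equilibrium_residual(
    sol, muscle_state(activation = a, lm_norm = ln), lmtu)
  expect_lt(abs(r_bis), 1e-6)
  expect_lt(abs(r_bis - r_int), 1e-6)
  expect_equal(ln_root, ln, tolerance = 1e-6)
})

test_that("isometric fiber force scales linearly with fmax", {
  mp <- default_muscle_params()
  v <- mp[mp$name == "vasti_r", ]
  v2 <- v; v2$fmax_N <- 2 * v$fmax_N
  st <- muscle_state(activation = 0.7, lm_norm = 1.1, vm_norm = 0)
  lmtu <- v$lopt_m * cos(v$alpha0_rad) * 1.1 + v$lts_m
  expect_equal(mtu_equilibrium_residual(v2, st, lmtu),
               2 * mtu_equilibrium_residual(v, st, lmtu),
               tolerance = 1e-10)
})

test_that("metabolic rate: resting, clamping, isometric hand value", {
  mp <- default_muscle_params()
  v <- as.list(mp[mp$name == "vasti_r", ])
  rest <- metabolic_rate(v, muscle_state(0, 0, 1, 0), 0, 0, basal = 3.5)
  expect_equal(rest$total, 3.5, tolerance = 1e-5)

  set.seed(3)
  for (k in 1:200) {
    st <- list(activation = stats::runif(1), lm_norm = stats::runif(1, 0.5, 1.6),
               vm_norm = stats::runif(1, -1, 1))
    f <- stats::runif(1, 0, v$fmax_N)
    vel <- stats::runif(1, -0.5, 0.5)
    expect_gte(metabolic_rate(v, st, f, vel)$total, 0)
  }

  # isometric at full activation: hand evaluation of the documented terms
  cc <- muscle_curve_constants()
  st1 <- muscle_state(1, 1, 1.05, 0)
  got <- metabolic_rate(v, st1, 1000, 0)
  hand <- v$mass_kg * 1 *
    (cc$phi_act + cc$phi_maint * active_force_length(1.05, v$widen))
  expect_equal(got$activation_maintenance, hand, tolerance = 1e-12)
  expect_equal(got$total, hand, tolerance = 1e-3)
})

test_that("metabolic totals are invariant to left-right relabeling", {
  mp <- default_muscle_params()
  st <- list(activation = 0.5, lm_norm = 1.1, vm_norm = -0.2)
  r <- metabolic_rate(as.list(mp[mp$name == "gastroc_r", ]), st, 800, -0.1)
  l <- metabolic_rate(as.list(mp[mp$name == "gastroc_l", ]), st, 800, -0.1)
  expect_equal(r$total, l$total)
})
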