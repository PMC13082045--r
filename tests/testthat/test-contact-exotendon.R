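test_that("contact force vanishes clear of the ground and grows with depth", {
  sp <- contact_sphere_spec()
  f <- contact_force(sp, c(0, sp$radius + 0.1), c(0, 0))
  expect_lt(sqrt(sum(f^2)), 1e-3)

  depths <- seq(0, 0.02, length.out = 30)
  fy <- contact_force(sp, cbind(0, sp$radius - depths),
                      matrix(0, 30, 2))[, 2]
  expect_true(all(diff(fy) > 0))

  expect_error(contact_force(sp, c(0, NA), c(0, 0)), "finite")
  expect_error(contact_sphere_spec(radius = -0.01), "positive")
})

test_that("sliding friction approaches the Coulomb + viscous limit", {
  sp <- contact_sphere_spec()
  # choose a depth giving a known normal load, then slide at 1 m/s
  depth <- 0.005
  f0 <- contact_force(sp, c(0, sp$radius - depth), c(0, 0))
  N <- f0[2]
  f1 <- contact_force(sp, c(0, sp$radius - depth), c(1, 0))
  expected <- -(sp$mu_dynamic + sp$mu_viscous * 1) * unname(N)
  expect_equal(unname(f1[1]), expected, tolerance = 2e-3)
  # opposing the slip direction
  f2 <- contact_force(sp, c(0, sp$radius - depth), c(-1, 0))
  expect_equal(unname(f2[1]), -unname(f1[1]), tolerance = 1e-9)
})

test_that("exotendon spec handles both slack conventions and presets", {
  s1 <- exotendon_spec(120, slack_pct = 25, leg_length = 0.92)
  expect_equal(s1$slack_m, 0.23)
  s2 <- exotendon_spec(120, slack_m = 0.23, leg_length = 0.92)
  expect_equal(s2$slack_pct, 25)
  expect_error(exotendon_spec(-5, slack_pct = 25), ">= 0")
  expect_error(exotendon_spec(120, slack_m = 0), "positive")

  p <- exotendon_preset("medium-original")
  expect_equal(c(p$stiffness, p$slack_pct), c(120, 25))
  p2 <- exotendon_preset("long-stiff")
  expect_equal(c(p2$stiffness, p2$slack_pct), c(240, 37.5))

  path <- withr::local_tempfile(fileext = ".json")
  write_exotendon_json(p, path)
  back <- read_exotendon_json(path)
  expect_equal(back$stiffness, p$stiffness)
  expect_equal(back$slack_m, p$slack_m)
})

test_that("tension law: scalar oracle, slack regime, linearity, smoothing", {
  spec <- exotendon_spec(120, slack_m = 0.23)
  expect_equal(exotendon_tension(1.15, spec), 120 * (1.15 - 0.23))
  expect_equal(exotendon_tension(1.15, spec), 110.4)
  expect_equal(exotendon_tension(0.2, spec), 0)
  expect_equal(exotendon_tension(0.23, spec), 0)
  spec2 <- exotendon_spec(240, slack_m = 0.23)
  d <- seq(0.3, 1.2, length.out = 50)
  expect_equal(exotendon_tension(d, spec2), 2 * exotendon_tension(d, spec))
  expect_error(exotendon_tension(-0.1, spec), ">= 0")

  # smoothed variant converges to the exact law: max error < width * k
  for (w in c(1e-2, 1e-3, 1e-4)) {
    err <- max(abs(exotendon_tension(d, spec, smoothing = w) -
                     exotendon_tension(d, spec)))
    err0 <- abs(exotendon_tension(spec$slack_m, spec, smoothing = w))
    expect_lt(max(err, err0), w * spec$stiffness)
  }
})

test_that("exotendon force pair: Newton's third law and potential gradient", {
  m <- default_model()
  spec <- exotendon_preset("medium-original")
  set.seed(21)
  q <- stats::rnorm(20, 0, 0.3); q[c(4, 5, 15, 16)] <- 0
  gf <- exotendon_generalized_forces(m, q, spec)
  F <- do.call(rbind, gf$point_forces)
  expect_equal(colSums(F), c(0, 0), tolerance = 1e-10)   # net force zero
  # net moment about the origin of the pair is zero (forces collinear)
  pk <- forward_kinematics(m, q, points = spec$anchors)
  mom <- 0
  for (nm in spec$anchors) {
    p <- pk[[nm]]$pos[1, ]; f <- gf$point_forces[[nm]][1, ]
    mom <- mom + p[1] * f[2] - p[2] * f[1]
  }
  expect_lt(abs(mom), 1e-8)

  # generalized force equals -d(potential)/dq by finite differences
  U <- function(qq) {
    d <- anchor_distance(m, qq, spec)
    0.5 * spec$stiffness * max(0, d - spec$slack_m)^2
  }
  tau <- drop(inverse_dynamics(m, q, rep(0, 20), rep(0, 20))) -
    drop(inverse_dynamics(m, q, rep(0, 20), rep(0, 20),
                          point_forces = gf$point_forces))
  for (j in c(1, 2, 3, 6, 7, 8, 10, 11)) {
    h <- 1e-7; qp <- q; qm <- q
    qp[j] <- qp[j] + h; qm[j] <- qm[j] - h
    expect_equal(tau[j], -(U(qp) - U(qm)) / (2 * h), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }

  # coincident anchors: degenerate direction handled smoothly
  gf0 <- exotendon_generalized_forces(
    m, rep(0, 20), exotendon_spec(120, slack_m = 0.5))
  expect_true(all(is.finite(unlist(gf0$point_forces))))
})

test_that("peak tension is monotone in stiffness and slack on fixed gait", {
  m <- default_model()
  ref <- reference_gait_31()
  grid <- design_grid()
  peaks <- matrix(NA_real_, length(grid$stiffness),
                  length(grid$slack_pct))
  d <- anchor_distance(m, ref$coords)
  for (i in seq_along(grid$stiffness)) {
    for (j in seq_along(grid$slack_pct)) {
      sp <- exotendon_spec(grid$stiffness[i],
                           slack_pct = grid$slack_pct[j],
                           leg_length = grid$leg_length)
      peaks[i, j] <- max(exotendon_tension(d, sp))
    }
  }
  expect_true(all(apply(peaks, 2, diff) >= 0))   # non-decreasing in k
  expect_true(all(apply(peaks, 1, diff) <= 0))   # non-increasing in l
})
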