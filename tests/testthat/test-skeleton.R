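test_that("default model has the documented coordinate and contact layout", {
  m <- default_model()
  expect_equal(n_coords(m), 20L)
  expect_equal(sum(grepl("^(heel|mtp_post|mtp_ant|forefoot)_", m$points$name)),
               8L)  # four contact spheres per foot
  expect_setequal(m$points$name[grepl("^exo_anchor", m$points$name)],
                  c("exo_anchor_r", "exo_anchor_l"))
  expect_equal(m$mass, sum(m$segments$mass), tolerance = 1e-12)
  expect_equal(m$mass, 73, tolerance = 1e-9)
  expect_gt(m$leg_length, 0)
  expect_true(all(m$segments$length > 0))
  # left/right limbs mirror-identical
  for (seg in c("thigh", "shank", "calcn", "toes", "upperarm", "forearm")) {
    r <- m$segments[m$segments$name == paste0(seg, "_r"), ]
    l <- m$segments[m$segments$name == paste0(seg, "_l"), ]
    expect_equal(r$mass, l$mass)
    expect_equal(r$length, l$length)
    expect_equal(r$inertia, l$inertia)
  }
})

test_that("coordinate count equals the sum of joint DOFs", {
  m <- default_model()
  dof <- sum(ifelse(m$joints$type == "free", 5L, 1L)) + 2L  # + lumbar oop
  expect_equal(n_coords(m), dof)
})

test_that("scaling is linear in height, mass and mass x length^2", {
  m <- default_model()
  expect_error(scale_spec(-1, 70), "positive")
  expect_error(scale_spec(1.7, 0), "positive")

  ident <- scale_model(m, scale_spec(m$height, m$mass))
  expect_equal(ident$segments, m$segments, tolerance = 1e-12)

  tall <- scale_model(m, scale_spec(2 * m$height, m$mass))
  expect_equal(tall$segments$length, 2 * m$segments$length)
  expect_equal(tall$leg_length, 2 * m$leg_length)
  expect_equal(tall$segments$inertia, 4 * m$segments$inertia)

  runner <- scale_model(m, scale_spec(1.78, 73))
  expect_equal(runner$mass, 73, tolerance = 1e-9)
  expect_equal(sum(runner$segments$mass), 73, tolerance = 1e-9)
})

test_that("model YAML round-trips", {
  m <- default_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(m, path)
  m2 <- read_model_yaml(path)
  expect_equal(coord_names(m2), coord_names(m))
  expect_equal(m2$mass, m$mass, tolerance = 1e-9)
  expect_equal(m2$points$x, m$points$x, tolerance = 1e-9)
  q <- stats::rnorm(20, 0, 0.2)
  # serialized at 12 significant digits
  expect_equal(mass_matrix(m2, q), mass_matrix(m, q), tolerance = 1e-8)
})

test_that("forward kinematics: zero pose, rigid translation, velocities", {
  m <- default_model()
  q0 <- rep(0, 20)
  fk <- forward_kinematics(m, q0, points = "exo_anchor_r")
  # at the zero pose the anchor position composes the frame offsets
  hip_y <- m$joints$loc_y[m$joints$name == "hip_r"]
  ankle_y <- m$joints$loc_y[m$joints$name == "ankle_r"]
  thigh_l <- -m$joints$loc_y[m$joints$name == "knee_r"]
  pt <- m$points[m$points$name == "exo_anchor_r", ]
  expect_equal(fk$exo_anchor_r$pos[1, 2],
               hip_y - thigh_l + ankle_y + pt$y, tolerance = 1e-12)
  expect_equal(fk$exo_anchor_r$pos[1, 1], pt$x, tolerance = 1e-12)

  # rigid pelvis translation moves every point by the same offset
  q1 <- q0; q1[1] <- 0.7; q1[2] <- -0.2
  fk0 <- forward_kinematics(m, q0)
  fk1 <- forward_kinematics(m, q1)
  for (nm in names(fk0)) {
    expect_equal(fk1[[nm]]$pos - fk0[[nm]]$pos,
                 matrix(c(0.7, -0.2), 1), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  expect_error(forward_kinematics(m, rep(0, 19)), "coordinates")
})

test_that("point velocities are time-derivatives of positions", {
  m <- default_model()
  tt <- seq(0, 0.3, length.out = 121)
  # smooth trajectory through a handful of coordinates
  Q <- matrix(0, length(tt), 20, dimnames = list(NULL, coord_names(m)))
  Qd <- Q
  for (j in c(1, 2, 3, 6, 7, 8)) {
    Q[, j] <- 0.3 * sin(2 * pi * tt + j)
    Qd[, j] <- 0.3 * 2 * pi * cos(2 * pi * tt + j)
  }
  fk <- forward_kinematics(m, Q, Qd, points = c("heel_r", "exo_anchor_l"))
  h <- tt[2] - tt[1]
  for (nm in names(fk)) {
    num <- (fk[[nm]]$pos[-1, ] - fk[[nm]]$pos[-length(tt), ]) / h
    mid <- (fk[[nm]]$vel[-1, ] + fk[[nm]]$vel[-length(tt), ]) / 2
    expect_lt(max(abs(num - mid)), 1e-3)   # O(h^2) central agreement
  }
  # tighter check by Richardson on a single instant
  f <- function(h) forward_kinematics(m, Q[1, ] + h * Qd[1, ])$heel_r$pos
  d <- (f(1e-6) - f(-1e-6)) / 2e-6
  expect_equal(drop(d),
               drop(forward_kinematics(m, Q[1, ], Qd[1, ])$heel_r$vel),
               tolerance = 1e-6)
})
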