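test_that("grid enumeration: 25 variants, ordering, slack conversion", {
  g <- design_grid()
  designs <- enumerate_designs(g)
  expect_length(designs, 25L)
  # stiffness-major ordering
  expect_equal(vapply(designs, `[[`, 0, "stiffness")[1:6],
               c(30, 30, 30, 30, 30, 60))
  # slack converted to meters with L = 0.92
  hit <- Filter(function(d) d$stiffness == 120 && d$slack_pct == 25,
                designs)[[1]]
  expect_equal(hit$slack_m, 0.23)
  expect_length(enumerate_designs(design_grid(stiffness = 120,
                                              slack_pct = 25)), 1L)
})

test_that("percent change arithmetic and guards", {
  expect_equal(percent_change(9, 10), -10)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(11.2, 10), 12, tolerance = 1e-12)
  expect_error(percent_change(9, 0), "positive")
  expect_error(percent_change(9, -1), "positive")
})

test_that("tension profile extraction matches the pointwise law", {
  sol <- natural_solution()
  # zero-stiffness: identically zero profile
  p0 <- extract_tension_profile(sol, exotendon_spec(0, slack_m = 0.23))
  expect_true(all(p0$tension == 0))

  spec <- exotendon_preset("medium-original")
  prof <- extract_tension_profile(sol, spec)
  expect_length(prof$tension, 101L)
  expect_true(all(prof$tension >= 0))
  # peak equals the max over mesh of k * max(0, d - l) recomputed
  # independently from the solution kinematics
  d <- anchor_distance(sol$ocp$model, sol$trajectories$coords, spec)
  oracle <- max(spec$stiffness * pmax(0, d - spec$slack_m))
  expect_equal(max(prof$tension), oracle, tolerance = 1e-6)
  # profile starts at heel strike: vertical GRF crosses 5% body weight
  hs <- prof$heel_strike_index
  thr <- 0.05 * sol$ocp$model$mass * 9.80665
  expect_gte(sol$trajectories$grf_r[hs, 2], thr)
})

test_that("sweep on a sub-grid completes with per-cell bookkeeping", {
  sol <- natural_solution()
  ocp <- sol$ocp
  g <- design_grid(stiffness = c(60, 240), slack_pct = c(12.5, 37.5),
                   stride_scales = 1)
  sw <- run_sweep(ocp$model, ocp$reference, g, ocp$config,
                  natural_scales = 1)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw$table), 4L)
  expect_equal(sum(is.finite(sw$table$pct_change)),
               sum(sw$table$converged))
  expect_gt(sw$baseline$cost_wkg, 0)
  expect_equal(sw$table$pct_change,
               percent_change(sw$table$cost_wkg, sw$baseline$cost_wkg))

  # stiff-short peak tension exceeds compliant-long on the same grid
  pk <- sw$table$peak_tension
  names(pk) <- sw$table$design
  expect_gte(pk[["k240_l12.5"]], pk[["k60_l37.5"]])

  # CSV writer mirrors the table layout
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, path)
  tab <- utils::read.csv(path, check.names = FALSE)
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(tab[[1]], c(60, 240))

  # ranking: ascending percent change, stable ties, preset lookup
  rk <- rank_designs(sw)
  expect_equal(rk$ranked$pct_change, sort(sw$table$pct_change))
  expect_equal(rk$optimal$pct_change, min(sw$table$pct_change))

  full <- design_grid()
  rk_tab <- sw$table[rep(1, 3), ]
  rk_tab$pct_change <- 1
  tie <- rank_designs(structure(list(table = rk_tab, grid = full),
                                class = "sweep_result"))
  expect_equal(tie$ranked$rank, 1:3)
  expect_identical(tie$ranked$design, rk_tab$design)  # stable on ties
})

test_that("named presets map to their grid cells", {
  g <- design_grid()
  designs <- enumerate_designs(g)
  for (nm in c("medium-original", "long-stiff", "short-stiff",
               "long-compliant")) {
    sp <- exotendon_preset(nm)
    hit <- Filter(function(d) d$stiffness == sp$stiffness &&
                    abs(d$slack_pct - sp$slack_pct) < 1e-9, designs)
    expect_length(hit, 1L)
    expect_equal(hit[[1]]$slack_m, sp$slack_m)
  }
})
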