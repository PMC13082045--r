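# Shared fixtures, built in code. Heavier objects are memoized per test
# run so independent test files do not rebuild them.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

default_model <- function() fixture("model", build_default_model)

reference_gait_31 <- function() {
  fixture("ref31", function() {
    generate_reference_gait(default_model(), speed = 4,
                            stride_duration = 0.7, n_samples = 31)
  })
}

# a small planar double pendulum fixed to ground, for conservation checks
pendulum_model <- function() {
  fixture("pendulum", function() {
    segs <- data.frame(name = c("link1", "link2"), mass = c(2, 1.5),
                       inertia = c(0.02, 0.01), com_x = 0,
                       com_y = c(-0.25, -0.2), length = c(0.5, 0.4))
    jts <- data.frame(name = c("j1", "j2"),
                      parent = c("ground", "link1"),
                      child = c("link1", "link2"),
                      loc_x = 0, loc_y = c(0, -0.5), type = "rev",
                      coord = c("q1", "q2"))
    planar_model(segs, jts)
  })
}

# coarse tracking solution reused by the OCP and sweep tests
natural_solution <- function() {
  fixture("nat_sol", function() {
    cfg <- ocp_config(mesh = 10, n_harm_pelvis = 3, maxiter = 60)
    ocp <- build_tracking_problem(default_model(), reference_gait_31(),
                                  NULL, cfg)
    solve_tracking(ocp)
  })
}
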