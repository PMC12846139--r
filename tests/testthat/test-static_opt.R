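# toy single-DOF model with two identical synergist muscles
two_synergist_model <- function(fmax = c(100, 100),
                                depth = c("deep", "deep")) {
  m <- pendulum_model()
  tab <- m$muscles[1:2, ]
  tab$name <- c("syn_a", "syn_b")
  tab$partner <- c("syn_b", "syn_a")
  tab$depth <- depth
  tab$fmax <- fmax
  tab$side <- c("right", "left")
  # both lines vertical, offset 0.02 m anterior of the joint: the moment
  # arm about the flexion (y) axis is exactly +0.02 m
  tab[, c("ox", "oy", "oz")] <- matrix(c(0.02, 0, -0.2, 0.02, 0, -0.2),
                                       2, 3, byrow = TRUE)
  tab$seg <- "head"
  tab[, c("ix", "iy", "iz")] <- matrix(c(0.02, 0, 0.05, 0.02, 0, 0.05),
                                       2, 3, byrow = TRUE)
  m$muscles <- tab
  m$muscles$rest_length <- muscle_lengths(m, rep(0, m$n_dof))
  m
}

test_that("metabolic cost has the stated normalization and homogeneity", {
  m <- two_synergist_model()
  cfg <- so_config()
  expect_equal(metabolic_cost(c(0, 0), model = m, config = cfg), c(0, 0))
  expect_equal(metabolic_cost(m$muscles$fmax, model = m, config = cfg),
               c(1, 1))
  f <- c(30, 70)
  expect_equal(metabolic_cost(2 * f, model = m, config = cfg),
               2 * metabolic_cost(f, model = m, config = cfg))
  expect_error(so_config(metabolic_form = "bogus"), "metabolic_form")
})

test_that("two equal synergists split the demand per the KKT closed form", {
  m <- two_synergist_model()
  R <- moment_arm_matrix(m, c(0, 0, 0))
  expect_equal(unname(R[1, ]), c(0.02, 0.02), tolerance = 1e-12)
  cfg <- so_config(lambda1 = 0, lambda2 = 0, symmetry_mode = "off",
                   w_deep = 1, w_sup = 1)
  tau <- c(1, 0, 0)
  sol <- solve_frame(m, tau, R = R, dt = 0.01, config = cfg,
                     first_frame = TRUE)
  expect_equal(sol$status, "converged")
  # closed form: f = tau / (2 r), split equally
  expect_equal(unname(sol$f), c(25, 25), tolerance = 1e-8)

  # dense grid search over the feasible line as an independent check
  f1 <- seq(0, 50, by = 0.001)
  f2 <- (1 - 0.02 * f1) / 0.02
  ok <- f2 >= 0 & f2 <= 100
  obj <- (f1 / 100)^2 + (f2 / 100)^2
  best <- f1[ok][which.min(obj[ok])]
  expect_equal(best, 25, tolerance = 1e-3)
})

test_that("zero demand with no metabolic drive gives zero force", {
  m <- two_synergist_model()
  cfg <- so_config(lambda1 = 0, symmetry_mode = "off")
  sol <- solve_frame(m, c(0, 0, 0), R = moment_arm_matrix(m, c(0, 0, 0)),
                     dt = 0.01, config = cfg, first_frame = TRUE)
  expect_equal(unname(sol$f), c(0, 0), tolerance = 1e-10)
})

test_that("hard bilateral symmetry equalizes partner forces", {
  m <- neck_model(muscle_set = "reduced16")
  q <- c(0.3, 0, 0, 0.3, 0, 0)  # sagittally symmetric pose
  tau <- inverse_dynamics(m, q)
  cfg <- so_config(symmetry_mode = "hard")
  sol <- solve_frame(m, tau, R = moment_arm_matrix(m, q), dt = 0.01,
                     config = cfg, first_frame = TRUE)
  expect_equal(sol$status, "converged")
  i_r <- which(m$muscles$side == "right")
  i_l <- match(m$muscles$partner[i_r], m$muscles$name)
  expect_lt(max(abs(sol$f[i_r] - sol$f[i_l])), 1e-6)
})

test_that("the deep-muscle weighting shifts load onto the deep muscle", {
  m <- two_synergist_model(depth = c("deep", "superficial"))
  cfg <- so_config(lambda1 = 0, lambda2 = 0, symmetry_mode = "off")
  for (tau1 in c(0.5, 1, 2)) {
    sol <- solve_frame(m, c(tau1, 0, 0),
                       R = moment_arm_matrix(m, c(0, 0, 0)),
                       dt = 0.01, config = cfg, first_frame = TRUE)
    expect_gt(sol$f[["syn_a"]], sol$f[["syn_b"]])
    # KKT ratio for weights w and identical geometry: f_a/f_b = w_b/w_a
    expect_equal(sol$f[["syn_a"]] / sol$f[["syn_b"]], 1.2 / 0.8,
                 tolerance = 1e-6)
  }
})

test_that("uniform-weight mode matches an independent classical SO", {
  m <- neck_model(muscle_set = "reduced16")
  cfg <- so_config(lambda1 = 0, lambda2 = 0, symmetry_mode = "off",
                   w_deep = 1, w_sup = 1)
  tr <- derive_kinematics(generate_motion(
    motion_spec("combined", cycle_period = 8, fs = 10)))
  for (t in seq(3, nrow(tr$q), by = 9)) {
    q <- tr$q[t, ]
    tau <- inverse_dynamics(m, q, tr$qd[t, ], tr$qdd[t, ])
    R <- moment_arm_matrix(m, q)
    sol <- solve_frame(m, tau, R = R, dt = 0.1, config = cfg,
                       first_frame = TRUE)
    expect_equal(sol$status, "converged")
    f_oracle <- classical_so_oracle(R, m$muscles$fmax, as.numeric(tau))
    expect_lt(max(abs(unname(sol$f) - f_oracle)), 1e-6)
  }
})

test_that("an unreachable demand is flagged, never silently accepted", {
  m <- two_synergist_model()
  R <- moment_arm_matrix(m, c(0, 0, 0))
  # max moment = 2 * 100 * 0.02 = 4 N m; ask for 10
  sol <- solve_frame(m, c(10, 0, 0), R = R, dt = 0.01,
                     config = so_config(symmetry_mode = "off"),
                     first_frame = TRUE)
  expect_equal(sol$status, "infeasible")
  expect_gt(sol$residual, so_config()$equality_tolerance)
})

test_that("a constant posture yields constant forces after the first frame", {
  m <- neck_model(muscle_set = "reduced16")
  n <- 30
  traj <- motion_trajectory(seq(0, by = 0.01, length.out = n),
                            matrix(rep(c(0.2, 0, 0, 0.2, 0, 0), each = n),
                                   n, 6),
                            dof_names = m$dof_names)
  fs <- solve_trajectory(m, traj)
  expect_true(all(fs$status == "converged"))
  dif <- diff(fs$forces[2:n, ])
  expect_lt(max(abs(dif)), 1e-6)
})

test_that("a larger rate weight never increases the per-frame rate penalty", {
  m <- neck_model(muscle_set = "reduced16")
  tr <- derive_kinematics(generate_motion(
    motion_spec("flexion_extension", cycle_period = 4, fs = 10)))
  base_run <- solve_trajectory(m, tr, so_config(lambda2 = 0.001))
  for (t in c(5, 15, 30)) {
    f_prev <- base_run$forces[t - 1, ]
    tau <- inverse_dynamics(m, tr$q[t, ], tr$qd[t, ], tr$qdd[t, ])
    R <- moment_arm_matrix(m, tr$q[t, ])
    rate_of <- function(lambda2) {
      sol <- solve_frame(m, tau, R = R, f_prev = f_prev, dt = 0.1,
                         config = so_config(lambda2 = lambda2))
      sum(((sol$f - f_prev) / m$muscles$fmax)^2)
    }
    # scalarization monotonicity at a fixed force history
    expect_lte(rate_of(0.01), rate_of(0.001) + 1e-12)
  }
})

test_that("moment closure and bounds hold along a solved trajectory", {
  m <- neck_model(muscle_set = "reduced16")
  tr <- derive_kinematics(generate_motion(
    motion_spec("combined", cycle_period = 8, fs = 10)))
  fs <- solve_trajectory(m, tr)
  expect_true(all(fs$status == "converged"))
  expect_true(all(fs$forces >= 0))
  expect_true(all(sweep(fs$forces, 2, m$muscles$fmax, "-") <= 1e-9))
  for (t in c(1, 25, 60)) {
    tau <- inverse_dynamics(m, tr$q[t, ], tr$qd[t, ], tr$qdd[t, ])
    R <- moment_arm_matrix(m, tr$q[t, ])
    expect_lt(sqrt(sum((R %*% fs$forces[t, ] - tau)^2)), 1e-6)
  }
})

test_that("the solver path is fully deterministic", {
  m <- neck_model(muscle_set = "reduced16")
  tr <- generate_motion(motion_spec("lateral_bending", cycle_period = 4,
                                    fs = 10))
  f1 <- solve_trajectory(m, tr)
  f2 <- solve_trajectory(m, tr)
  expect_identical(f1$forces, f2$forces)
})

test_that("force series round-trip through wide CSV", {
  m <- neck_model(muscle_set = "reduced16")
  tr <- generate_motion(motion_spec("flexion_extension", cycle_period = 2,
                                    fs = 10))
  fs <- solve_trajectory(m, tr)
  path <- withr::local_tempfile(fileext = ".csv")
  write_force_series(fs, path)
  fs2 <- read_force_series(path)
  expect_equal(fs2$forces, fs$forces, tolerance = 1e-9)
  expect_equal(fs2$muscle_names, fs$muscle_names)
})
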