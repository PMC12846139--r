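test_that("the default model has the full bilateral muscle complement", {
  m <- neck_model()
  expect_equal(nrow(m$muscles), 72)
  expect_equal(sum(m$muscles$side == "right"), 36)
  # partner relation is a symmetric bijection
  idx <- match(m$muscles$partner, m$muscles$name)
  expect_false(any(is.na(idx)))
  expect_equal(m$muscles$name[idx][idx], m$muscles$name[idx][idx])
  expect_equal(m$muscles$partner[idx], m$muscles$name)
  expect_true(all(m$muscles$fmax > 0))
  expect_true(all(m$muscles$depth %in% c("deep", "superficial")))
})

test_that("neutral-pose markers sit on and mirror the mid-sagittal plane", {
  m <- neck_model()
  fm <- forward_markers(m, rep(0, 6))
  expect_equal(fm["TP", "y"], 0)
  expect_equal(fm["LH", "y"], -fm["RH", "y"])
  expect_equal(fm["LH", c("x", "z")], fm["RH", c("x", "z")])
  expect_gt(fm["TP", "z"], fm["LH", "z"])
})

test_that("a marker on the rotation axis is unmoved by pure axial rotation", {
  m <- neck_model()
  fm0 <- forward_markers(m, rep(0, 6))
  fm1 <- forward_markers(m, c(0, 0, 0.5, 0, 0, 0.7))
  expect_equal(fm1["TP", ], fm0["TP", ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fm1["LH", ], fm0["LH", ])))
})

test_that("forward kinematics matches rotation-matrix composition", {
  m1 <- pendulum_model()
  th <- pi / 2
  fm <- forward_markers(m1, c(th, 0, 0))
  for (mk in c("TP", "LH", "RH")) {
    expect_equal(fm[mk, ], as.numeric(Ry(th) %*% m1$markers[mk, ]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # composed rotations on the single articulation
  q <- c(0.3, -0.2, 0.4)
  fm2 <- forward_markers(m1, q)
  Rtot <- Ry(0.3) %*% Rx(-0.2) %*% Rz(0.4)
  for (mk in c("TP", "LH", "RH")) {
    expect_equal(fm2[mk, ], as.numeric(Rtot %*% m1$markers[mk, ]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("moment arms equal the negative tendon excursion at random poses", {
  m <- neck_model()
  set.seed(20)
  h <- 1e-6
  for (k in 1:20) {
    q <- runif(6, -0.5, 0.5)
    R <- moment_arm_matrix(m, q)
    for (j in 1:6) {
      qp <- q; qm <- q
      qp[j] <- q[j] + h; qm[j] <- q[j] - h
      fd <- -(muscle_lengths(m, qp) - muscle_lengths(m, qm)) / (2 * h)
      expect_lt(max(abs(R[j, ] - fd)), 1e-4)
    }
  }
})

test_that("a muscle line through the joint center has zero moment arm", {
  m1 <- pendulum_model()
  m1$muscles <- m1$muscles[1, , drop = FALSE]
  # straight vertical line through the origin (the joint center)
  m1$muscles[1, c("ox", "oy", "oz")] <- c(0, 0, -0.1)
  m1$muscles[1, c("ix", "iy", "iz")] <- c(0, 0, 0.05)
  m1$muscles$seg <- "head"
  R <- moment_arm_matrix(m1, c(0, 0, 0))
  expect_equal(max(abs(R)), 0, tolerance = 1e-12)
})

test_that("mirrored pairs have equal flexion and opposite bending arms", {
  m <- neck_model()
  R0 <- moment_arm_matrix(m, rep(0, 6))
  i_r <- which(m$muscles$side == "right")
  i_l <- match(m$muscles$partner[i_r], m$muscles$name)
  for (j in grep("^flex", m$dof_names)) {
    expect_equal(R0[j, i_r], R0[j, i_l], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  for (j in grep("^bend", m$dof_names)) {
    expect_equal(R0[j, i_r], -R0[j, i_l], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("mirror symmetry: reflected poses reflect markers and swap sides", {
  m <- neck_model()
  q <- c(0.3, 0.2, -0.4, 0.1, -0.15, 0.25)
  q_ref <- q * c(1, -1, -1, 1, -1, -1)  # reflect bending and rotation
  fm <- forward_markers(m, q)
  fm_ref <- forward_markers(m, q_ref)
  expect_equal(fm_ref["TP", ], fm["TP", ] * c(1, -1, 1), tolerance = 1e-12)
  expect_equal(fm_ref["LH", ], fm["RH", ] * c(1, -1, 1), tolerance = 1e-12)
  expect_equal(fm_ref["RH", ], fm["LH", ] * c(1, -1, 1), tolerance = 1e-12)
  len <- muscle_lengths(m, q)
  len_ref <- muscle_lengths(m, q_ref)
  expect_equal(unname(len_ref[m$muscles$partner]), unname(len),
               tolerance = 1e-10)
})

test_that("gravity moment vanishes when the head COM lies on the joint axis", {
  m1 <- pendulum_model()
  expect_equal(unname(inverse_dynamics(m1, c(0, 0, 0))), rep(0, 3),
               tolerance = 1e-12)
})

test_that("static flexion matches the inverted-pendulum formula", {
  m1 <- pendulum_model(head_mass = 6.377, com_dist = 0.1073)
  tau <- inverse_dynamics(m1, c(30 * pi / 180, 0, 0))
  # gravity pulls into flexion; muscles must supply the extensor moment
  expect_equal(unname(tau[1]), -6.377 * 9.81 * 0.1073 * sin(pi / 6),
               tolerance = 1e-10)
  expect_equal(round(abs(unname(tau[1])), 3), 3.356)
})

test_that("with gravity disabled a single DOF reduces to tau = I qdd", {
  m1 <- pendulum_model(head_mass = 2, com_dist = 0.15)
  m1$gravity <- 0
  qdd <- 3.7
  tau <- inverse_dynamics(m1, c(0, 0, 0), qdd = c(qdd, 0, 0))
  I_analytic <- 2 * 0.15^2 + 2 / 5 * 2 * 0.09^2  # point mass + sphere
  expect_equal(unname(tau[1]), I_analytic * qdd, tolerance = 1e-10)
})

test_that("numerical differentiation recovers analytic derivatives", {
  n <- 301
  times <- seq(0, 3, length.out = n)
  const <- motion_trajectory(times, matrix(0.2, n, 2))
  dc <- derive_kinematics(const)
  expect_equal(max(abs(dc$qd)), 0)
  expect_equal(max(abs(dc$qdd)), 0)

  sin_traj <- motion_trajectory(times, matrix(sin(2 * pi * times), ncol = 1))
  ds <- derive_kinematics(sin_traj)
  expect_lt(max(abs(ds$qd - 2 * pi * cos(2 * pi * times))), 0.01)

  ramp <- motion_trajectory(times, matrix(0.5 * times, ncol = 1))
  dr <- derive_kinematics(ramp)
  expect_equal(as.numeric(dr$qd), rep(0.5, n), tolerance = 1e-9)
  expect_equal(max(abs(dr$qdd[2:(n - 1), ])), 0, tolerance = 1e-9)

  expect_error(derive_kinematics(motion_trajectory(times[1:2],
                                                   matrix(0, 2, 1))),
               "3 frames")
})

test_that("total energy is conserved in a passive free swing", {
  m1 <- pendulum_model(head_mass = 3, com_dist = 0.12)
  M <- mass_matrix <- neckforce:::mass_matrix(m1, c(0, 0, 0))[1, 1]
  deriv <- function(y) {
    # theta, omega; free swing about the flexion DOF only
    tau_bias <- inverse_dynamics(m1, c(y[1], 0, 0), c(y[2], 0, 0))[1]
    Mq <- neckforce:::mass_matrix(m1, c(y[1], 0, 0))[1, 1]
    # M qdd + bias(q, qd) = 0  with bias = ID(q, qd, 0)
    c(y[2], -tau_bias / Mq)
  }
  times <- seq(0, 1.2, by = 0.002)
  y <- rk4(deriv, c(1.0, 0), times)
  d <- 0.12
  energy <- apply(y, 1, function(s) {
    Mq <- neckforce:::mass_matrix(m1, c(s[1], 0, 0))[1, 1]
    0.5 * Mq * s[2]^2 + 3 * 9.81 * d * cos(s[1])
  })
  expect_lt(max(abs(energy - energy[1])) / abs(energy[1]), 1e-5)
})

test_that("model serialization round-trips through YAML", {
  m <- neck_model(anthro_profile(5.5, 42, 12), muscle_set = "reduced16",
                  passive_stiffness = 0.3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_neck_model(m, path)
  m2 <- read_neck_model(path)
  expect_equal(m2$muscles, m$muscles, tolerance = 1e-12)
  expect_equal(m2$bodies, m$bodies, tolerance = 1e-12)
  expect_equal(m2$passive_stiffness, m$passive_stiffness)
})
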