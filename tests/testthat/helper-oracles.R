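# Independent oracles and shared fixtures for the test suite.

.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

# Independently coded classical static optimization:
# min sum (f_i/fmax_i)^2  s.t.  R f = tau, 0 <= f <= fmax.
# Lagrangian dual ascent (the box-constrained inner minimum is separable
# and closed-form), followed by an exact KKT solve on the identified
# active set.  Shares no code path with the package solver.
classical_so_oracle <- function(R, fmax, tau) {
  qdiag <- 2 / fmax^2
  f_of <- function(lam) {
    pmin(pmax(as.numeric(crossprod(R, lam)) / qdiag, 0), fmax)
  }
  neg_dual <- function(lam) {
    f <- f_of(lam)
    -(0.5 * sum(qdiag * f^2) + sum(lam * (tau - R %*% f)))
  }
  grad <- function(lam) -as.numeric(tau - R %*% f_of(lam))
  o <- stats::optim(rep(0, length(tau)), neg_dual, grad, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  f0 <- f_of(o$par)
  # exact finish: active-set iteration on the KKT system, seeded by the
  # dual solution's bound pattern
  nm <- length(fmax)
  at_lo <- f0 <= 1e-7
  at_up <- f0 >= fmax - 1e-7
  f <- f0
  for (k in 1:100) {
    free <- !(at_lo | at_up)
    Rf <- R[, free, drop = FALSE]
    rhs <- tau - R[, at_up, drop = FALSE] %*% fmax[at_up]
    M <- Rf %*% (t(Rf) / qdiag[free])
    # M is rank-deficient when fewer muscles are free than constraints;
    # the pseudo-inverse gives the exact solution whenever one exists
    lam <- tryCatch(MASS::ginv(M) %*% rhs, error = function(e) NULL)
    if (is.null(lam)) break
    Rtlam <- as.numeric(crossprod(R, lam))
    f <- ifelse(at_up, fmax, ifelse(at_lo, 0, Rtlam / qdiag))
    changed <- FALSE
    # primal feasibility of the free set
    bad_lo <- free & f < -1e-10
    bad_up <- free & f > fmax + 1e-10
    # dual feasibility of the clamped sets
    rel_lo <- at_lo & Rtlam / qdiag > 1e-10
    rel_up <- at_up & Rtlam / qdiag < fmax - 1e-10
    if (any(bad_lo)) { at_lo[bad_lo] <- TRUE; changed <- TRUE }
    if (any(bad_up)) { at_up[bad_up] <- TRUE; changed <- TRUE }
    if (!changed && any(rel_lo)) {
      at_lo[which(rel_lo)[1]] <- FALSE; changed <- TRUE
    }
    if (!changed && any(rel_up)) {
      at_up[which(rel_up)[1]] <- FALSE; changed <- TRUE
    }
    if (!changed) break
  }
  pmin(pmax(f, 0), fmax)
}

# classic fixed-step RK4 for the energy-conservation check
rk4 <- function(deriv, y0, times) {
  y <- matrix(NA_real_, length(times), length(y0))
  y[1, ] <- y0
  for (i in seq_len(length(times) - 1)) {
    h <- times[i + 1] - times[i]
    k1 <- deriv(y[i, ])
    k2 <- deriv(y[i, ] + h / 2 * k1)
    k3 <- deriv(y[i, ] + h / 2 * k2)
    k4 <- deriv(y[i, ] + h * k3)
    y[i + 1, ] <- y[i, ] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# elementary rotation matrices (independent of the package's kinematics)
Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)

# single-articulation frictionless pendulum model (analytic test bed)
pendulum_model <- function(head_mass = 6.377, com_dist = 0.1073) {
  neck_model(anthro_profile(head_mass, 39.920, com_dist * 100),
             articulations = 1, head_com = c(0, 0, 0),
             neck_mass_frac = 0, passive_stiffness = 0,
             passive_damping = 0)
}

# a fast shared simulation dataset: 6 profiles, reduced model, 10 Hz suite
small_dataset <- function() {
  cached("small_dataset", {
    pop <- sample_population(ansur_population(), 6, seed = 101)
    base <- neck_model(muscle_set = "reduced16")
    suite <- standard_motion_suite(fs = 10)
    build_dataset(pop, suite, base)
  })
}

# a wider anthropometric spread for the held-out-profile generalization
# check (interpolation across anthropometry needs enough training models)
gen_dataset <- function() {
  cached("gen_dataset", {
    pop <- sample_population(ansur_population(), 16, seed = 202)
    base <- neck_model(muscle_set = "reduced16")
    suite <- standard_motion_suite(fs = 10)
    build_dataset(pop, suite, base)
  })
}
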