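# Inverse dynamics of the chain: recursive Newton-Euler in world frame.

#' External load on a model segment
#'
#' A wrench (force and couple, world frame) applied at the center of mass
#' of a named body.
#'
#' @param force 3-vector (N).
#' @param moment 3-vector (N m).
#' @param segment `"upper"` (head + upper neck, default) or `"lower"`.
#' @return An object of class `external_load`.
#' @export
external_load <- function(force = c(0, 0, 0), moment = c(0, 0, 0),
                          segment = "upper") {
  stopifnot(length(force) == 3, length(moment) == 3,
            all(is.finite(force)), all(is.finite(moment)),
            segment %in% c("upper", "lower"))
  structure(list(force = as.numeric(force), moment = as.numeric(moment),
                 segment = segment), class = "external_load")
}

#' Net joint moments from motion (inverse dynamics)
#'
#' Computes the generalized moments the muscles must supply,
#' `tau = M(q) qdd + C(q, qd) qd + G(q) - tau_passive - J^T F_ext`,
#' via a recursive Newton-Euler pass over the chain.  Passive joint
#' moments are the model's linear stiffness/damping,
#' `tau_passive = -(k q + c qd)`.  With zero velocity, acceleration,
#' passive and external terms the result is the pure gravitational demand
#' `G(q)` (positive = moment toward positive DOF direction required).
#'
#' @param model a [neck_model()].
#' @param q,qd,qdd joint angles, velocities, accelerations (rad, rad/s,
#'   rad/s^2); `qd`/`qdd` default to zero.
#' @param ext optional [external_load()].
#' @return Named numeric vector of joint moments (N m), one per DOF.
#' @export
inverse_dynamics <- function(model, q, qd = NULL, qdd = NULL, ext = NULL) {
  n <- model$n_dof
  if (is.null(qd)) qd <- rep(0, n)
  if (is.null(qdd)) qdd <- rep(0, n)
  if (length(q) != n || length(qd) != n || length(qdd) != n)
    stop("q, qd, qdd must have length ", n)

  fr <- chain_frames(model, q)
  g <- c(0, 0, -model$gravity)

  # forward pass: world angular vel/acc and frame-origin linear acceleration
  omega <- matrix(0, 3, n); alpha <- matrix(0, 3, n); acc <- matrix(0, 3, n)
  w <- c(0, 0, 0); al <- c(0, 0, 0); ac <- -g  # gravity trick: base "accelerates" at -g
  Rprev <- diag(3)
  for (j in seq_len(n)) {
    d <- Rprev %*% model$offsets[[j]]
    ac <- ac + cross3(al, d) + cross3(w, cross3(w, d))
    aj <- fr$a[, j]
    al <- al + aj * qdd[j] + cross3(w, aj * qd[j])
    w <- w + aj * qd[j]
    omega[, j] <- w; alpha[, j] <- al; acc[, j] <- ac
    Rprev <- fr$R[[j]]
  }

  bodies <- Filter(Negate(is.null), model$bodies)
  # per-body inertial force/moment about its COM, in world frame
  wrench <- lapply(bodies, function(b) {
    j <- b$joint
    Rj <- fr$R[[j]]
    cw <- as.numeric(fr$p[, j] + Rj %*% b$com)
    rc <- cw - fr$p[, j]
    a_c <- acc[, j] + cross3(alpha[, j], rc) +
      cross3(omega[, j], cross3(omega[, j], rc))
    Iw <- Rj %*% b$I %*% t(Rj)
    list(joint = j, com = cw,
         F = b$m * a_c,
         N = as.numeric(Iw %*% alpha[, j]) +
           cross3(omega[, j], as.numeric(Iw %*% omega[, j])))
  })

  tau <- numeric(n)
  for (j in seq_len(n)) {
    nt <- c(0, 0, 0)
    for (wb in wrench) {
      if (wb$joint >= j)
        nt <- nt + wb$N + cross3(wb$com - fr$p[, j], wb$F)
    }
    tau[j] <- sum(fr$a[, j] * nt)
  }

  # passive moments resist displacement and velocity
  tau <- tau + model$passive_stiffness * q + model$passive_damping * qd

  if (!is.null(ext)) {
    stopifnot(inherits(ext, "external_load"))
    b <- model$bodies[[ext$segment]]
    if (is.null(b)) stop("model has no '", ext$segment, "' segment")
    jb <- b$joint
    cw <- as.numeric(fr$p[, jb] + fr$R[[jb]] %*% b$com)
    for (j in seq_len(jb)) {
      tau[j] <- tau[j] - sum(fr$a[, j] *
        (ext$moment + cross3(cw - fr$p[, j], ext$force)))
    }
  }
  stats::setNames(tau, model$dof_names)
}

# Joint-space mass matrix by the unit-acceleration method (no gravity,
# no velocity, passive terms removed).  Used by the forward-dynamics
# validation tests.
mass_matrix <- function(model, q) {
  n <- model$n_dof
  saved_k <- model$passive_stiffness; saved_c <- model$passive_damping
  model$passive_stiffness <- rep(0, n); model$passive_damping <- rep(0, n)
  g <- model$gravity; model$gravity <- 0
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- 1
    M[, j] <- inverse_dynamics(model, q, rep(0, n), e)
  }
  model$gravity <- g
  model$passive_stiffness <- saved_k; model$passive_damping <- saved_c
  (M + t(M)) / 2
}
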