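# Enhanced static optimization: per-frame muscle redundancy resolution.

#' Configuration of the enhanced static optimization
#'
#' The per-frame objective is
#' `sum_i w_i (f_i/f_i^max)^2 + lambda1 sum_i Phi_i + lambda2 sum_i fdot_i^2`
#' subject to `R f = tau`, `0 <= f_i <= f_i^max` and, optionally, bilateral
#' symmetry `f_j ~ kappa f_k` between left/right partners.  Deep
#' stabilizing muscles receive a lower activation weight (`w_deep = 0.8`)
#' than large superficial movers (`w_sup = 1.2`), so the optimizer does
#' not underuse them; the metabolic term approximates the tendency to
#' minimize energy expenditure, and the force-rate term smooths the
#' solution across frames.  The force rate `fdot_i` is normalized by
#' `f_i^max` (like the activation term) and discretized backward against
#' the previous frame with a time-integral-consistent weight, so the rate
#' penalty remains a small temporal-smoothness regularizer at any
#' sampling rate.
#'
#' @param w_deep,w_sup activation weights for deep / superficial muscles.
#' @param lambda1 metabolic-cost weight.
#' @param lambda2 force-rate weight (on the normalized force rate).
#' @param kappa bilateral symmetry ratio (1.0 = exact symmetry).
#' @param kappa_tolerance fractional band around `kappa` in soft mode.
#' @param symmetry_mode `"off"`, `"soft"` (quadratic penalty, applied by
#'   [solve_trajectory()] only to sagittally symmetric motions) or
#'   `"hard"` (equality constraints).
#' @param metabolic_form `"normalized_force"` (default, `Phi_i = f_i/f_i^max`,
#'   linear so each frame stays a strictly convex QP).
#' @param equality_tolerance accepted residual of the moment-closure
#'   constraint (N m).
#' @param max_iterations solver iteration cap.
#' @return An object of class `so_config`.
#' @export
so_config <- function(w_deep = 0.8, w_sup = 1.2,
                      lambda1 = 0.01, lambda2 = 0.001,
                      kappa = 1.0, kappa_tolerance = 0.05,
                      symmetry_mode = c("soft", "off", "hard"),
                      metabolic_form = "normalized_force",
                      equality_tolerance = 1e-6,
                      max_iterations = 500L) {
  symmetry_mode <- match.arg(symmetry_mode)
  stopifnot(w_deep > 0, w_sup > 0, lambda1 >= 0, lambda2 >= 0, kappa > 0,
            kappa_tolerance >= 0, equality_tolerance > 0)
  if (!metabolic_form %in% c("normalized_force", "squared_force"))
    stop("unknown metabolic_form: ", metabolic_form)
  structure(list(w_deep = w_deep, w_sup = w_sup, lambda1 = lambda1,
                 lambda2 = lambda2, kappa = kappa,
                 kappa_tolerance = kappa_tolerance,
                 symmetry_mode = symmetry_mode,
                 metabolic_form = metabolic_form,
                 equality_tolerance = equality_tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "so_config")
}

muscle_weights <- function(model, config) {
  ifelse(model$muscles$depth == "deep", config$w_deep, config$w_sup)
}

#' Per-muscle metabolic cost
#'
#' Default form is the normalized-force proxy `Phi_i = f_i / f_i^max`
#' (linear, keeps each frame's problem convex); `"squared_force"` uses
#' `(f_i/f_i^max)^2`.
#'
#' @param f,f_prev force vectors (N); `f_prev` enters only through
#'   rate-dependent forms (none of the packaged forms use it, it is part
#'   of the stable signature).
#' @param dt frame interval (s).
#' @param model a [neck_model()].
#' @param config an [so_config()].
#' @return Per-muscle cost values.
#' @export
metabolic_cost <- function(f, f_prev = NULL, dt = 0.01, model, config) {
  if (length(f) != nrow(model$muscles)) stop("force vector length mismatch")
  fn <- f / model$muscles$fmax
  switch(config$metabolic_form,
         normalized_force = fn,
         squared_force = fn^2)
}

# left/right partner index pairs (right index, left index)
partner_pairs <- function(model) {
  i_r <- which(model$muscles$side == "right")
  i_l <- match(model$muscles$partner[i_r], model$muscles$name)
  cbind(i_r, i_l)
}

#' Solve one frame of the enhanced static optimization
#'
#' @param model a [neck_model()].
#' @param tau net joint moments (N m) from [inverse_dynamics()].
#' @param R optional precomputed moment-arm matrix for the frame.
#' @param f_prev previous frame's solution (zeros at the first frame; the
#'   force-rate term is inactive when `first_frame = TRUE`).
#' @param dt frame interval (s).
#' @param config an [so_config()].
#' @param first_frame logical; first frame has no force history.
#' @param symmetry_active logical; whether the bilateral term applies to
#'   this frame (set by [solve_trajectory()] from the motion's symmetry).
#' @return List with `f` (named forces, N), `residual` (`||Rf - tau||`,
#'   N m), `status` (`"converged"` or `"infeasible"`), `objective`.
#' @export
solve_frame <- function(model, tau, R = NULL, f_prev = NULL, dt = 0.01,
                        config = so_config(), first_frame = FALSE,
                        symmetry_active = TRUE) {
  nm <- nrow(model$muscles)
  fmax <- model$muscles$fmax
  if (is.null(f_prev)) f_prev <- rep(0, nm)
  if (is.null(R)) stop("moment-arm matrix R is required")
  w <- muscle_weights(model, config)

  # The frame problem is posed in normalized activations a = f / fmax.
  # The force rate is normalized as well (adot = (a - a_prev)/dt) and its
  # per-frame penalty uses the time-integral-consistent weight
  # lambda2 * dt * adot^2 = lambda2 (a - a_prev)^2 / dt, so the rate term
  # stays a smoothing perturbation of the activation objective at any
  # sampling rate instead of dominating it:
  #   min sum w a^2 + lambda1 sum Phi(a) + lambda2/dt sum (a - a_prev)^2
  #   s.t. (R diag(fmax)) a = tau, 0 <= a <= 1  [+ bilateral term]
  a_prev <- f_prev / fmax
  lam2 <- if (first_frame) 0 else config$lambda2
  Hdiag <- 2 * w + 2 * lam2 / dt
  H <- diag(Hdiag, nm)
  d <- -2 * lam2 * a_prev / dt
  if (config$lambda1 > 0) {
    if (config$metabolic_form == "normalized_force") {
      d <- d + config$lambda1
    } else {
      H <- H + diag(2 * config$lambda1, nm)
    }
  }

  Aeq <- R %*% diag(fmax, nm); beq <- as.numeric(tau)
  use_sym <- symmetry_active && config$symmetry_mode != "off"
  if (use_sym) {
    pp <- partner_pairs(model)
    if (config$symmetry_mode == "hard") {
      S <- matrix(0, nrow(pp), nm)
      S[cbind(seq_len(nrow(pp)), pp[, 1])] <- 1
      S[cbind(seq_len(nrow(pp)), pp[, 2])] <- -config$kappa
      Aeq <- rbind(Aeq, S); beq <- c(beq, rep(0, nrow(pp)))
    } else {
      # soft: quadratic penalty on (a_j - kappa a_k), scaled so a deviation
      # of kappa_tolerance costs about one activation-term unit
      mu <- 1 / (config$kappa_tolerance^2 + 1e-12)
      for (r in seq_len(nrow(pp))) {
        j <- pp[r, 1]; k <- pp[r, 2]
        H[j, j] <- H[j, j] + 2 * mu
        H[k, k] <- H[k, k] + 2 * mu * config$kappa^2
        H[j, k] <- H[j, k] - 2 * mu * config$kappa
        H[k, j] <- H[k, j] - 2 * mu * config$kappa
      }
    }
  }

  # diagonal preconditioning: z = s a with s = sqrt(diag(H)) makes the
  # quadratic near-identity, which the active-set solver handles robustly
  s <- sqrt(diag(H))
  Dz <- t(H / s) / s
  Dz <- (Dz + t(Dz)) / 2
  dz <- d / s
  Az <- t(t(Aeq) / s)
  sol <- tryCatch(
    pracma::quadprog(Dz, dz, Aeq = Az, beq = beq,
                     lb = rep(0, nm), ub = s),
    error = function(e) NULL)
  if (is.null(sol) || sol$eflag != 1 || any(!is.finite(sol$xmin))) {
    # exact closure unattainable (the lumped chain is direction-degenerate
    # at some poses): solve the penalized closure min rho ||A a - tau||^2 +
    # objective over the bounds alone, and accept only if the recorded
    # residual meets the configured tolerance -- never silently
    rho <- 1e8 * max(Hdiag) / max(colSums(Aeq^2))
    Hp <- H + 2 * rho * crossprod(Aeq)
    dp <- d - 2 * rho * as.numeric(crossprod(Aeq, beq))
    sp_ <- sqrt(diag(Hp))
    Dp <- t(Hp / sp_) / sp_
    Dp <- (Dp + t(Dp)) / 2
    sol <- tryCatch(
      pracma::quadprog(Dp, dp / sp_, lb = rep(0, nm), ub = sp_),
      error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol$xmin))) {
      return(list(f = stats::setNames(rep(NA_real_, nm), model$muscles$name),
                  residual = NA_real_, status = "infeasible",
                  objective = NA_real_))
    }
    s <- sp_
  }
  f <- pmin(pmax(fmax * sol$xmin / s, 0), fmax)
  resid <- sqrt(sum((R %*% f - as.numeric(tau))^2))
  status <- if (resid <= config$equality_tolerance) "converged" else "infeasible"
  a <- f / fmax
  list(f = stats::setNames(f, model$muscles$name),
       residual = resid, status = status,
       objective = 0.5 * sum(a * (H %*% a)) + sum(d * a))
}

# a motion is sagittally symmetric when it never bends or rotates
sagittally_symmetric <- function(traj, tol = 1e-9) {
  idx <- grep("^(bend|rot)_", colnames(traj$q))
  length(idx) == 0 || max(abs(traj$q[, idx])) <= tol
}

#' Resolve muscle forces along a whole trajectory
#'
#' Runs [inverse_dynamics()] and [solve_frame()] frame by frame, feeding
#' each frame's optimum to the next frame's force-rate term (a
#' receding-horizon discretization of the rate penalty).  The bilateral
#' symmetry term is applied only when the commanded motion is sagittally
#' symmetric, unless `symmetry_mode = "off"`.
#'
#' @param model a [neck_model()].
#' @param motion a [motion_trajectory()]; derivatives are added with
#'   [derive_kinematics()] if missing.
#' @param config an [so_config()].
#' @param ext optional [external_load()] applied at every frame.
#' @return An object of class `force_series`: `times`, `forces`
#'   (frames x muscles, N), `residuals`, `status` per frame.
#' @export
solve_trajectory <- function(model, motion, config = so_config(), ext = NULL) {
  stopifnot(inherits(motion, "motion_trajectory"))
  if (is.null(motion$qd)) motion <- derive_kinematics(motion)
  nt <- nrow(motion$q)
  nm <- nrow(model$muscles)
  dt <- 1 / motion$fs
  sym <- sagittally_symmetric(motion)
  forces <- matrix(NA_real_, nt, nm,
                   dimnames = list(NULL, model$muscles$name))
  residuals <- rep(NA_real_, nt)
  status <- character(nt)
  f_prev <- rep(0, nm)
  for (t in seq_len(nt)) {
    q <- motion$q[t, ]
    tau <- inverse_dynamics(model, q, motion$qd[t, ], motion$qdd[t, ], ext)
    R <- moment_arm_matrix(model, q)
    sol <- solve_frame(model, tau, R = R, f_prev = f_prev, dt = dt,
                       config = config, first_frame = (t == 1L),
                       symmetry_active = sym)
    forces[t, ] <- sol$f
    residuals[t] <- sol$residual
    status[t] <- sol$status
    if (sol$status == "converged") f_prev <- sol$f
  }
  structure(list(times = motion$times, forces = forces,
                 residuals = residuals, status = status,
                 muscle_names = model$muscles$name),
            class = "force_series")
}

#' @export
print.force_series <- function(x, ...) {
  ok <- mean(x$status == "converged")
  cat("Force series:", nrow(x$forces), "frames x", ncol(x$forces),
      sprintf("muscles | %.1f%% frames converged | max residual %.2e N m\n",
              100 * ok, max(x$residuals, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.force_series <- function(object, ...) {
  print(object)
  pk <- apply(object$forces, 2, max, na.rm = TRUE)
  cat("peak force (N): min", round(min(pk), 2), "median",
      round(stats::median(pk), 2), "max", round(max(pk), 2), "\n")
  invisible(object)
}

#' Write / read a force series as wide CSV
#'
#' Columns: `time`, one per muscle name, plus `residual` and `status`.
#'
#' @param fs a `force_series`.
#' @param path file path.
#' @return `read_force_series` returns the `force_series`.
#' @export
write_force_series <- function(fs, path) {
  df <- data.frame(time = fs$times, fs$forces, check.names = FALSE)
  df$residual <- fs$residuals
  df$status <- fs$status
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_series
#' @export
read_force_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mcols <- setdiff(names(df), c("time", "residual", "status"))
  structure(list(times = df$time,
                 forces = as.matrix(df[, mcols, drop = FALSE]),
                 residuals = df$residual, status = df$status,
                 muscle_names = mcols),
            class = "force_series")
}
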