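# Frame kinematics of the serial chain.

rot_axis <- function(axis, theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  if (axis[1] == 1) matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
  else if (axis[2] == 1) matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
  else matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# World-frame pose of every joint frame: R[[j]], origin p[,j], axis a[,j].
chain_frames <- function(model, q) {
  n <- model$n_dof
  if (length(q) != n) stop("q must have length ", n)
  R <- vector("list", n)
  p <- matrix(0, 3, n)
  a <- matrix(0, 3, n)
  Rprev <- diag(3); pprev <- c(0, 0, 0)
  for (j in seq_len(n)) {
    pj <- pprev + Rprev %*% model$offsets[[j]]
    aj <- Rprev %*% model$axes[[j]]
    Rj <- Rprev %*% rot_axis(model$axes[[j]], q[j])
    R[[j]] <- Rj; p[, j] <- pj; a[, j] <- aj
    Rprev <- Rj; pprev <- pj
  }
  list(R = R, p = p, a = a)
}

# joint indices whose motion moves a point on the given body
body_joint <- function(model, seg) {
  if (model$articulations == 1L) return(model$n_dof)
  if (seg == "neck_lower") 3L else 6L
}

# world positions of the muscle insertions (3 x n_muscles)
insertion_points <- function(model, fr) {
  m <- model$muscles
  out <- matrix(0, 3, nrow(m))
  for (i in seq_len(nrow(m))) {
    j <- body_joint(model, m$seg[i])
    out[, i] <- fr$p[, j] + fr$R[[j]] %*% c(m$ix[i], m$iy[i], m$iz[i])
  }
  out
}

#' Forward kinematics of the three head markers
#'
#' Positions of the TP/LH/RH markers in the torso frame (meters) at a
#' given pose.
#'
#' @param model a [neck_model()].
#' @param q joint-angle vector (rad), length `model$n_dof`.
#' @return A 3x3 numeric matrix, rows TP/LH/RH, columns x/y/z.
#' @export
forward_markers <- function(model, q) {
  fr <- chain_frames(model, q)
  j <- model$n_dof
  out <- t(apply(model$markers, 1, function(off)
    as.numeric(fr$p[, j] + fr$R[[j]] %*% off)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Straight-line muscle lengths at a pose
#'
#' @inheritParams forward_markers
#' @return Named numeric vector of origin-insertion distances (m).
#' @export
muscle_lengths <- function(model, q) {
  fr <- chain_frames(model, q)
  ins <- insertion_points(model, fr)
  m <- model$muscles
  d <- ins - t(as.matrix(m[, c("ox", "oy", "oz")]))
  stats::setNames(sqrt(colSums(d^2)), m$name)
}

#' Muscle moment-arm matrix
#'
#' Entry `(j, i)` is muscle i's moment arm about DOF j at pose `q`,
#' computed analytically from the chain geometry as
#' `-u . (a_j x (p_ins - p_j))` with `u` the unit line of action; this
#' equals the negative tendon excursion `-dl_i/dq_j`, so a positive entry
#' means the muscle generates a positive joint moment.
#'
#' @inheritParams forward_markers
#' @return A `n_dof x n_muscles` matrix (m), dimnames DOF x muscle.
#' @export
moment_arm_matrix <- function(model, q) {
  fr <- chain_frames(model, q)
  ins <- insertion_points(model, fr)
  m <- model$muscles
  n <- model$n_dof
  R <- matrix(0, n, nrow(m),
              dimnames = list(model$dof_names, m$name))
  for (i in seq_len(nrow(m))) {
    o <- c(m$ox[i], m$oy[i], m$oz[i])
    pin <- ins[, i]
    u <- (pin - o) / sqrt(sum((pin - o)^2))
    jmax <- body_joint(model, m$seg[i])
    for (j in seq_len(jmax)) {
      R[j, i] <- -sum(u * cross3(fr$a[, j], pin - fr$p[, j]))
    }
  }
  R
}

#' Uniformly sampled joint-angle trajectory
#'
#' @param times numeric vector of sample times (s), uniformly spaced.
#' @param q frames x DOF matrix of joint angles (rad).
#' @param qd,qdd optional matching velocity/acceleration matrices.
#' @param dof_names optional column names for `q`.
#' @return An object of class `motion_trajectory`.
#' @export
motion_trajectory <- function(times, q, qd = NULL, qdd = NULL,
                              dof_names = NULL) {
  q <- as.matrix(q)
  if (length(times) != nrow(q)) stop("times and q disagree in length")
  if (length(times) >= 2) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-8 * max(dt[1], 1e-12))
      stop("times must be uniformly spaced")
  }
  if (!is.null(dof_names)) colnames(q) <- dof_names
  structure(list(times = times, q = q, qd = qd, qdd = qdd,
                 fs = if (length(times) >= 2) 1 / (times[2] - times[1]) else NA_real_),
            class = "motion_trajectory")
}

#' @export
print.motion_trajectory <- function(x, ...) {
  cat("Motion trajectory:", nrow(x$q), "frames x", ncol(x$q), "DOFs at",
      round(x$fs, 3), "Hz",
      if (is.null(x$qd)) "(angles only)\n" else "(with derivatives)\n")
  invisible(x)
}

#' Numerical differentiation of a joint trajectory
#'
#' Adds velocities and accelerations by central differences on interior
#' frames and one-sided differences at the ends.
#'
#' @param traj a [motion_trajectory()] with at least 3 frames.
#' @return The trajectory with `qd` and `qdd` filled in.
#' @export
derive_kinematics <- function(traj) {
  stopifnot(inherits(traj, "motion_trajectory"))
  q <- traj$q
  n <- nrow(q)
  if (n < 3) stop("need at least 3 frames to differentiate")
  dt <- traj$times[2] - traj$times[1]
  d1 <- function(x) {
    v <- c(x[2] - x[1],
           (x[3:n] - x[1:(n - 2)]) / 2,
           x[n] - x[n - 1]) / dt
    v
  }
  qd <- apply(q, 2, d1)
  qdd <- apply(qd, 2, d1)
  motion_trajectory(traj$times, q, qd, qdd)
}

#' Marker trajectories from a joint-angle trajectory
#'
#' Runs [forward_markers()] on every frame: the re-implementation of the
#' point-kinematics step that turns simulated joint motion into the
#' torso-frame head-marker time series used as surrogate features.
#'
#' @param model a [neck_model()].
#' @param traj a [motion_trajectory()].
#' @return An object of class `marker_trajectory`: `times` plus a
#'   `frames x 9` matrix `positions` with columns
#'   `TP_x .. RH_z` (m, torso frame).
#' @export
marker_trajectory <- function(model, traj) {
  stopifnot(inherits(traj, "motion_trajectory"))
  pos <- t(apply(traj$q, 1, function(qi) as.numeric(t(forward_markers(model, qi)))))
  colnames(pos) <- as.vector(t(outer(c("TP", "LH", "RH"), c("x", "y", "z"),
                                     paste, sep = "_")))
  structure(list(times = traj$times, positions = pos, fs = traj$fs),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat("Marker trajectory:", nrow(x$positions), "frames, 3 markers at",
      round(x$fs, 3), "Hz\n")
  invisible(x)
}
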