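# Standardized and restricted neck-motion synthesis.
#
# Motions emulate slow standardized range-of-motion tasks: each cycle is a
# sequence of raised-cosine quarter-strokes (neutral -> +A -> neutral ->
# -A -> neutral) with zero velocity at every stroke boundary.  The default
# cycle period of 8 s matches the slow, controlled pace of clinical
# cervical ROM testing.  Commanded head angles are split equally between
# the two articulations.

HEAD_DOFS <- c("flexion", "lateral", "rotation")

#' Specification of a synthesized neck motion
#'
#' @param motion_type one of `"flexion_extension"`, `"lateral_bending"`,
#'   `"axial_rotation"`, `"combined"`, `"spontaneous"`.
#' @param amplitudes named numeric vector of peak head angles (rad) for
#'   `flexion`, `lateral`, `rotation`; defaults are the physiological
#'   range used throughout the package (50, 40, 70 degrees).
#' @param cycles number of full cycles.
#' @param cycle_period seconds per cycle (default 8 s, slow clinical pace).
#' @param fs sampling rate (Hz), default 100.
#' @param restriction optional list `list(sector = ..., factor = ...)`
#'   produced by [restrict_motion()].
#' @param seed RNG seed for `"spontaneous"` motions.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(motion_type = c("flexion_extension", "lateral_bending",
                                        "axial_rotation", "combined",
                                        "spontaneous"),
                        amplitudes = c(flexion = 50 * pi / 180,
                                       lateral = 40 * pi / 180,
                                       rotation = 70 * pi / 180),
                        cycles = 1L, cycle_period = 8, fs = 100,
                        restriction = NULL, seed = 1L) {
  motion_type <- match.arg(motion_type)
  amp <- c(flexion = 0, lateral = 0, rotation = 0)
  amp[names(amplitudes)] <- amplitudes
  if (any(amp < 0) || any(amp > pi)) stop("amplitudes must be in [0, pi]")
  if (fs <= 0 || cycle_period <= 0 || cycles < 1) stop("invalid timing spec")
  if (!is.null(restriction)) {
    if (!all(restriction$sector %in% sector_names()))
      stop("unknown sector(s): ",
           paste(setdiff(restriction$sector, sector_names()), collapse = ", "))
    if (length(restriction$sector) == 0) stop("empty restriction sector")
    if (restriction$factor <= 0 || restriction$factor > 1)
      stop("restriction factor must be in (0, 1]")
  }
  structure(list(motion_type = motion_type, amplitudes = amp,
                 cycles = as.integer(cycles), cycle_period = cycle_period,
                 fs = fs, restriction = restriction, seed = seed),
            class = "motion_spec")
}

sector_names <- function() {
  as.vector(outer(c("flexion", "lateral", "rotation"), c("pos", "neg"),
                  paste, sep = "_"))
}

#' Attenuate a motion in chosen direction sectors
#'
#' Marks signed half-ranges of head DOFs (for example `"flexion_pos"` =
#' anterior flexion, `"lateral_neg"` = leftward bending) for attenuation
#' by `factor`; excursions into other directions are untouched.  Used to
#' emulate a patient with a restricted range of motion.
#'
#' @param spec a [motion_spec()].
#' @param sector character vector of sector names, each
#'   `"<dof>_pos"`/`"<dof>_neg"` with dof in flexion/lateral/rotation.
#' @param factor attenuation in (0, 1]; 1 leaves the motion unchanged.
#' @return The modified `motion_spec`.
#' @export
restrict_motion <- function(spec, sector, factor) {
  stopifnot(inherits(spec, "motion_spec"))
  if (length(sector) == 0) stop("empty restriction sector")
  spec$restriction <- list(sector = sector, factor = factor)
  # re-validate
  motion_spec(spec$motion_type, spec$amplitudes, spec$cycles,
              spec$cycle_period, spec$fs, spec$restriction, spec$seed)
}

# one raised-cosine cycle 0 -> +1 -> 0 -> -1 -> 0 on phase s in [0, 1)
rc_cycle <- function(s) {
  u <- (s %% 1) * 4
  k <- pmin(floor(u), 3)
  v <- u - k
  w <- (1 - cos(pi * v)) / 2
  ifelse(k == 0, w, ifelse(k == 1, 1 - w, ifelse(k == 2, -w, -1 + w)))
}

#' Generate a joint-angle trajectory from a motion specification
#'
#' Single-plane motions drive one head DOF through raised-cosine cycles
#' reaching exactly the specified amplitude; `"combined"` runs
#' half-amplitude flexion and rotation cycles phase-shifted by a quarter
#' cycle; `"spontaneous"` is a seeded sum of band-limited sinusoids kept
#' inside the amplitude bounds and windowed to start/end at neutral.
#' Commanded head angles are split equally between the lower and upper
#' articulations.  Restrictions attenuate signed excursions after
#' synthesis (zero crossings keep the trajectory continuous).
#'
#' @param spec a [motion_spec()].
#' @param articulations number of articulations of the target model.
#' @return A [motion_trajectory()].
#' @export
generate_motion <- function(spec, articulations = 2) {
  stopifnot(inherits(spec, "motion_spec"))
  duration <- spec$cycles * spec$cycle_period
  n <- round(duration * spec$fs)
  times <- seq(0, by = 1 / spec$fs, length.out = n)
  s <- times / spec$cycle_period
  amp <- spec$amplitudes

  head_q <- matrix(0, n, 3, dimnames = list(NULL, HEAD_DOFS))
  if (spec$motion_type == "flexion_extension") {
    head_q[, "flexion"] <- amp["flexion"] * rc_cycle(s)
  } else if (spec$motion_type == "lateral_bending") {
    head_q[, "lateral"] <- amp["lateral"] * rc_cycle(s)
  } else if (spec$motion_type == "axial_rotation") {
    head_q[, "rotation"] <- amp["rotation"] * rc_cycle(s)
  } else if (spec$motion_type == "combined") {
    head_q[, "flexion"] <- amp["flexion"] / 2 * rc_cycle(s)
    head_q[, "rotation"] <- amp["rotation"] / 2 * rc_cycle(s + 0.25)
  } else {
    head_q <- with_seed(spec$seed, {
      env <- (1 - cos(pi * pmin(times / (0.1 * duration), 1,
                                (duration - times) / (0.1 * duration)))) / 2
      sapply(seq_len(3), function(d) {
        k <- 4
        fr <- stats::runif(k, 0.05, 0.4)
        ph <- stats::runif(k, 0, 2 * pi)
        am <- stats::runif(k, 0.3, 1)
        x <- rowSums(sapply(seq_len(k), function(i)
          am[i] * sin(2 * pi * fr[i] * times + ph[i])))
        x <- x / max(abs(x), 1e-12) * 0.9 * amp[d]
        x * env
      })
    })
    colnames(head_q) <- HEAD_DOFS
  }

  if (!is.null(spec$restriction)) {
    fac <- spec$restriction$factor
    for (sec in spec$restriction$sector) {
      parts <- strsplit(sec, "_")[[1]]
      dof <- parts[1]; sgn <- parts[2]
      col <- head_q[, dof]
      if (sgn == "pos") col[col > 0] <- col[col > 0] * fac
      else col[col < 0] <- col[col < 0] * fac
      head_q[, dof] <- col
    }
  }

  if (articulations == 2) {
    q <- cbind(head_q, head_q) / 2
    colnames(q) <- as.vector(outer(c("flex", "bend", "rot"),
                                   c("lower", "upper"), paste, sep = "_"))
  } else {
    q <- head_q
    colnames(q) <- c("flex_lower", "bend_lower", "rot_lower")
  }
  motion_trajectory(times, q)
}

#' Standardized motion suite
#'
#' The four standardized tasks (flexion-extension, lateral bending, axial
#' rotation, combined), each one cycle, concatenated generation-side as a
#' list.  Pass a `restriction` to produce the "patient" variant of every
#' task.
#'
#' @param amplitudes,cycle_period,fs,restriction see [motion_spec()].
#' @return Named list of [motion_spec()] objects.
#' @export
standard_motion_suite <- function(amplitudes = c(flexion = 50 * pi / 180,
                                                 lateral = 40 * pi / 180,
                                                 rotation = 70 * pi / 180),
                                  cycle_period = 8, fs = 100,
                                  restriction = NULL) {
  types <- c("flexion_extension", "lateral_bending", "axial_rotation",
             "combined")
  stats::setNames(lapply(types, function(tt)
    motion_spec(tt, amplitudes = amplitudes, cycle_period = cycle_period,
                fs = fs, restriction = restriction)), types)
}

#' Write / read a motion trajectory as CSV
#'
#' Columns: `time` plus one named column per DOF (rad).
#'
#' @param traj a [motion_trajectory()].
#' @param path file path.
#' @return `read_motion` returns the `motion_trajectory`.
#' @export
write_motion <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$q, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  motion_trajectory(df$time, as.matrix(df[, -1, drop = FALSE]))
}
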