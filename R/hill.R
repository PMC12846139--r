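# Hill-type activation inversion: a(t) = F(t) / (Fmax * fl(l) * fv(v)).

#' Hill-type muscle parameters
#'
#' @param f_max maximal isometric force (N).
#' @param l_opt optimal fiber length (m).
#' @param v_max maximal shortening velocity (optimal lengths / s).
#' @param fl_width width of the Gaussian force-length curve
#'   (dimensionless, on normalized length).
#' @param fv_shape curvature of the concentric force-velocity hyperbola.
#' @param fv_ecc_max eccentric force plateau (multiplier > 1).
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(f_max, l_opt = 0.1, v_max = 10,
                        fl_width = 0.45, fv_shape = 0.25,
                        fv_ecc_max = 1.4) {
  vals <- c(f_max, l_opt, v_max, fl_width, fv_shape, fv_ecc_max)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Hill parameters must be positive and finite")
  structure(list(f_max = f_max, l_opt = l_opt, v_max = v_max,
                 fl_width = fl_width, fv_shape = fv_shape,
                 fv_ecc_max = fv_ecc_max), class = "hill_params")
}

#' Force-length and force-velocity multipliers
#'
#' Default curves: Gaussian force-length
#' `exp(-((l_norm - 1) / width)^2)` (1 at the optimum) and a Hill
#' hyperbola for concentric force-velocity with a smooth eccentric
#' plateau (1 at isometric, `fv_ecc_max` asymptotically for lengthening).
#' `v_norm` is positive for shortening, in optimal lengths per second
#' divided by `v_max`.
#'
#' @param l_norm normalized fiber length (> 0).
#' @param hill a [hill_params()].
#' @return Multiplier in `(0, fv_ecc_max]`.
#' @export
force_length <- function(l_norm, hill = hill_params(100)) {
  if (any(l_norm <= 0)) stop("normalized length must be positive")
  exp(-((l_norm - 1) / hill$fl_width)^2)
}

#' @rdname force_length
#' @param v_norm normalized contraction velocity (positive = shortening).
#' @export
force_velocity <- function(v_norm, hill = hill_params(100)) {
  a <- hill$fv_shape
  conc <- (1 - pmin(v_norm, 1)) / (1 + pmin(v_norm, 1) / a)
  ecc <- hill$fv_ecc_max -
    (hill$fv_ecc_max - 1) * (1 - pmax(-v_norm, 0) / a /
                               (1 + pmax(-v_norm, 0) / a))
  out <- ifelse(v_norm >= 0, conc, ecc)
  pmax(out, 0)
}

#' Invert predicted force to activation (Hill-type)
#'
#' `a = F / (F_max * f_l * f_v)`, clipped to `[0, 1]`.  Clipping events
#' are counted and reported as an attribute rather than silently
#' saturated, since predicted force can outrun the multipliers.
#'
#' @param F predicted muscle force (N, >= 0); vectorized.
#' @param hill a [hill_params()].
#' @param l_norm,v_norm normalized length and velocity (recycled).
#' @return Numeric vector of activations in `[0, 1]` with attribute
#'   `clipped` giving the number of clipped samples.
#' @export
activation_from_force <- function(F, hill, l_norm = 1, v_norm = 0) {
  if (any(F < 0)) stop("force must be non-negative")
  fl <- force_length(l_norm, hill)
  fv <- force_velocity(v_norm, hill)
  denom <- hill$f_max * fl * fv
  if (any(denom == 0)) stop("force-length/velocity multiplier is zero")
  a_raw <- F / denom
  clipped <- sum(a_raw > 1 | a_raw < 0)
  a <- pmin(pmax(a_raw, 0), 1)
  attr(a, "clipped") <- clipped
  a
}

#' Normalized length and velocity of a straight-line muscle
#'
#' For the simplified straight-line muscle set, normalized length is the
#' instantaneous origin-insertion distance divided by the neutral-pose
#' rest length, and normalized velocity is its numerical rate divided by
#' `v_max * rest_length` (shortening positive).
#'
#' @param model a [neck_model()].
#' @param motion a [motion_trajectory()].
#' @param muscle muscle name.
#' @param v_max maximal shortening velocity (rest lengths / s).
#' @return List with vectors `l_norm`, `v_norm` over frames.
#' @export
muscle_norm_kinematics <- function(model, motion, muscle, v_max = 10) {
  i <- match(muscle, model$muscles$name)
  if (is.na(i)) stop("unknown muscle: ", muscle)
  len <- apply(motion$q, 1, function(qi) muscle_lengths(model, qi)[i])
  rest <- model$muscles$rest_length[i]
  dt <- 1 / motion$fs
  n <- length(len)
  dl <- c(len[2] - len[1], (len[3:n] - len[1:(n - 2)]) / 2,
          len[n] - len[n - 1]) / dt
  list(l_norm = len / rest, v_norm = (-dl / rest) / v_max)
}
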