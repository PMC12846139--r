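#' Parametric head-neck rigid-body model
#'
#' Builds the simplified cervical linkage used throughout the package: the
#' cervical column is lumped into two articulations (skull-C4 and C4-T1),
#' each with three rotational degrees of freedom in the order
#' flexion-extension (about y, positive = anterior flexion), lateral
#' bending (about x, positive = rightward) and axial rotation (about z,
#' positive = leftward), giving six DOFs total.  Muscles are straight
#' lines from torso-fixed origins to insertions on the moving bodies,
#' organized as 36 bilateral pairs (72 muscles) with a deep/superficial
#' class per muscle.  The torso frame has x anterior, y left, z superior
#' (the A/L/S convention), origin at the chain base (T1).
#'
#' Personalization uses exactly three parameters: neck length scales the
#' chain, shoulder width scales the lateral torso attachment sites, and
#' head mass sets the head segment's mass (inertia scaled by the mass
#' ratio).  Neck-segment soft-tissue masses are a fixed fraction of head
#' mass so the total gravitational demand scales proportionally with head
#' mass.
#'
#' @param profile optional [anthro_profile()]; default is the packaged
#'   population mean (head mass 6.377 kg, shoulder width 39.92 cm, neck
#'   length 10.73 cm).
#' @param muscle_set `"full72"` (default) or `"reduced16"` (a bilateral
#'   8-pair subset spanning flexors, extensors, lateral benders and
#'   rotators, for fast simulation).
#' @param articulations 2 (default) or 1; the single-articulation
#'   reduction is useful for analytic checks.
#' @param head_com head center-of-mass offset (m) from the chain top in
#'   the skull frame; the default places it on the joint axis at neutral.
#' @param neck_mass_frac per-segment neck mass as a fraction of head mass.
#' @param passive_stiffness,passive_damping per-DOF linear passive
#'   rotational stiffness (N m/rad) and damping (N m s/rad); set to zero
#'   for analytic tests.
#' @param gravity gravitational acceleration magnitude (m/s^2).
#' @return An object of class `neck_model`.
#' @export
neck_model <- function(profile = NULL,
                       muscle_set = c("full72", "reduced16"),
                       articulations = 2,
                       head_com = c(0, 0, 0.08),
                       neck_mass_frac = 0.08,
                       passive_stiffness = 0.5,
                       passive_damping = 0.01,
                       gravity = 9.81) {
  muscle_set <- match.arg(muscle_set)
  if (is.null(profile))
    profile <- anthro_profile(6.377, 39.920, 10.730)
  stopifnot(inherits(profile, "anthro_profile"))
  articulations <- as.integer(articulations)
  stopifnot(articulations %in% c(1L, 2L))

  L <- profile$neck_length / 100   # cm -> m (the only unit conversion site)
  W <- profile$shoulder_width / 100
  mh <- profile$head_mass
  n_art <- articulations
  L1 <- if (n_art == 2L) L / 2 else L
  L2 <- if (n_art == 2L) L / 2 else 0

  n_dof <- 3L * n_art
  dof_names <- as.vector(outer(c("flex", "bend", "rot"),
                               c("lower", "upper")[seq_len(n_art)],
                               function(a, b) paste(a, b, sep = "_")))
  axes <- list(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))[rep(seq_len(3L), n_art)]
  # translation from the previous joint frame to this joint, in parent frame
  offsets <- rep(list(c(0, 0, 0)), n_dof)
  if (n_art == 2L) offsets[[4L]] <- c(0, 0, L1)

  # inertia of a solid cylinder about its COM, axis along z
  cyl_inertia <- function(m, r, h)
    diag(c(m * (3 * r^2 + h^2) / 12, m * (3 * r^2 + h^2) / 12, m * r^2 / 2))
  m_seg <- neck_mass_frac * mh
  r_neck <- 0.05
  head_r <- 0.09
  I_head <- diag(rep(2 / 5 * mh * head_r^2, 3))  # sphere, scaled with mass

  if (n_art == 2L) {
    # lower body: lower neck cylinder after joint 3
    low <- list(joint = 3L, m = m_seg, com = c(0, 0, L1 / 2),
                I = cyl_inertia(m_seg, r_neck, L1))
    # upper body: upper neck cylinder + head, composed about a joint-frame COM
    up_parts <- list(
      list(m = m_seg, com = c(0, 0, L2 / 2), I = cyl_inertia(m_seg, r_neck, L2)),
      list(m = mh, com = c(0, 0, L2) + head_com, I = I_head))
  } else {
    low <- NULL
    up_parts <- list(
      list(m = m_seg, com = c(0, 0, L1 / 2), I = cyl_inertia(m_seg, r_neck, L1)),
      list(m = mh, com = c(0, 0, L1) + head_com, I = I_head))
  }
  m_up <- sum(vapply(up_parts, `[[`, numeric(1), "m"))
  com_up <- Reduce(`+`, lapply(up_parts, function(p) p$m * p$com)) / m_up
  I_up <- Reduce(`+`, lapply(up_parts, function(p) {
    d <- p$com - com_up
    p$I + p$m * (sum(d * d) * diag(3) - outer(d, d))
  }))
  up <- list(joint = n_dof, m = m_up, com = com_up, I = I_up)

  top_z <- if (n_art == 2L) L2 else L1  # chain top in the upper-body frame
  markers <- rbind(TP = c(0, 0, top_z + 0.12),
                   LH = c(0, 0.09, top_z + 0.04),
                   RH = c(0, -0.09, top_z + 0.04))
  colnames(markers) <- c("x", "y", "z")

  muscles <- build_muscle_table(W, L1, if (n_art == 2L) L2 else L1, muscle_set)
  if (n_art == 1L) {
    # single-articulation reduction: every insertion rides the single body
    muscles$seg[muscles$seg == "neck_lower"] <- "neck_upper"
  }

  model <- structure(list(
    profile = profile,
    muscle_set = muscle_set,
    articulations = n_art,
    n_dof = n_dof,
    dof_names = dof_names,
    axes = axes,
    offsets = offsets,
    L1 = L1, L2 = L2,
    bodies = list(lower = low, upper = up),
    head_com = head_com,
    neck_mass_frac = neck_mass_frac,
    markers = markers,
    muscles = muscles,
    passive_stiffness = rep(passive_stiffness, n_dof),
    passive_damping = rep(passive_damping, n_dof),
    gravity = gravity
  ), class = "neck_model")
  model$muscles$rest_length <- muscle_lengths(model, rep(0, n_dof))
  model
}

#' Scale a model to an anthropometric profile
#'
#' Rebuilds the parametric linkage for a new profile while keeping every
#' structural option (muscle set, articulation count, passive parameters)
#' of the base model: the chain length scales with neck length, lateral
#' torso attachment sites with shoulder width, and the head mass/inertia
#' with head mass.  Muscle rest lengths are recomputed from the scaled
#' geometry.
#'
#' @param base a [neck_model()].
#' @param profile an [anthro_profile()].
#' @return A `neck_model` for the new profile.
#' @export
scale_model <- function(base, profile) {
  stopifnot(inherits(base, "neck_model"), inherits(profile, "anthro_profile"))
  neck_model(profile = profile,
             muscle_set = base$muscle_set,
             articulations = base$articulations,
             head_com = base$head_com,
             neck_mass_frac = base$neck_mass_frac,
             passive_stiffness = base$passive_stiffness[1],
             passive_damping = base$passive_damping[1],
             gravity = base$gravity)
}

#' @export
print.neck_model <- function(x, ...) {
  cat("Head-neck model:", x$articulations, "articulation(s),",
      x$n_dof, "DOFs,", nrow(x$muscles), "muscles\n")
  cat(sprintf("  head mass %.3f kg | shoulder width %.2f cm | neck length %.2f cm\n",
              x$profile$head_mass, x$profile$shoulder_width,
              x$profile$neck_length))
  invisible(x)
}

#' @export
summary.neck_model <- function(object, ...) {
  print(object)
  cat("  muscle classes:",
      sum(object$muscles$depth == "deep"), "deep /",
      sum(object$muscles$depth == "superficial"), "superficial\n")
  cat("  passive stiffness", object$passive_stiffness[1], "N m/rad, damping",
      object$passive_damping[1], "N m s/rad\n")
  invisible(object)
}

#' Serialize a model to / from a YAML document
#'
#' Stores the constructor arguments (the model is fully parametric), so a
#' round trip rebuilds an identical model.
#'
#' @param model a `neck_model`.
#' @param path file path.
#' @return `read_neck_model` returns the rebuilt `neck_model`.
#' @export
write_neck_model <- function(model, path) {
  doc <- list(
    profile = unclass(model$profile),
    muscle_set = model$muscle_set,
    articulations = model$articulations,
    head_com = model$head_com,
    neck_mass_frac = model$neck_mass_frac,
    passive_stiffness = model$passive_stiffness[1],
    passive_damping = model$passive_damping[1],
    gravity = model$gravity)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_neck_model
#' @export
read_neck_model <- function(path) {
  doc <- yaml::read_yaml(path)
  neck_model(
    profile = anthro_profile(doc$profile$head_mass,
                             doc$profile$shoulder_width,
                             doc$profile$neck_length),
    muscle_set = doc$muscle_set,
    articulations = doc$articulations,
    head_com = unlist(doc$head_com),
    neck_mass_frac = doc$neck_mass_frac,
    passive_stiffness = doc$passive_stiffness,
    passive_damping = doc$passive_damping,
    gravity = doc$gravity)
}
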