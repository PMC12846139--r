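# Default straight-line muscle attachment geometry.
#
# Coordinates are in the torso-fixed frame: x anterior, y left, z superior,
# origin at the chain base (T1).  The table describes the RIGHT-side muscle
# of each bilateral pair (y <= 0); the left partner is the mirror image
# across the mid-sagittal plane (y = 0) and carries the "_L" name suffix.
#
# Parameterization used for anthropometric scaling:
#   oyf  - origin lateral position as a fraction of the shoulder half-width,
#          so torso attachment sites move with biacromial breadth;
#   seg  - body carrying the insertion: "head" (skull-fixed local coords,
#          relative to the chain top), "neck_upper" / "neck_lower"
#          (iz read as a fraction of the segment length, so insertions ride
#          with neck length).
# Muscles whose true origin lies on a cervical vertebra are approximated by
# a torso-frame origin at the corresponding neutral-pose height: a
# documented simplification of the straight-line muscle set.

muscle_geometry_table <- function() {
  # name, depth, fmax(N), ox, oyf, oz, seg, ix, iy, iz
  rows <- list(
    list("digastric_post",      "superficial",  40, 0.040, 0.10, -0.020, "head",        0.000, -0.045,  0.020),
    list("digastric_ant",       "superficial",  60, 0.050, 0.08, -0.020, "head",        0.060, -0.010, -0.010),
    list("Geniohyoid",          "superficial",  60, 0.050, 0.05, -0.030, "head",        0.065, -0.005, -0.015),
    list("Mylohyoid_Post",      "superficial",  45, 0.045, 0.12, -0.025, "head",        0.050, -0.020, -0.005),
    list("Mylohyoid_Ant",       "superficial",  45, 0.050, 0.06, -0.030, "head",        0.060, -0.008, -0.010),
    list("Stylohyoid_Lat",      "superficial",  25, 0.040, 0.15, -0.030, "head",        0.010, -0.040,  0.000),
    list("Stylohyoid_Med",      "superficial",  25, 0.045, 0.08, -0.030, "head",        0.012, -0.030,  0.000),
    list("Sterno_hyoid",        "superficial",  90, 0.050, 0.06, -0.050, "head",        0.055, -0.010, -0.020),
    list("SternoThyroid",       "superficial",  90, 0.050, 0.08, -0.060, "head",        0.050, -0.012, -0.030),
    list("Omo_hyoid",           "superficial",  40, -0.020, 0.85, -0.060, "head",       0.050, -0.010, -0.020),
    list("stern_mast",          "superficial", 220, 0.050, 0.10, -0.030, "head",        0.000, -0.045,  0.020),
    list("cleid_mast",          "superficial", 160, 0.035, 0.45, -0.020, "head",        0.000, -0.045,  0.015),
    list("cleid_occ",           "superficial", 140, 0.030, 0.50, -0.020, "head",       -0.040, -0.035,  0.020),
    list("scalenus_ant",        "deep",        150, 0.030, 0.35, -0.050, "neck_lower",  0.015, -0.025,  0.90),
    list("scalenus_med",        "deep",        140, 0.000, 0.40, -0.050, "neck_upper",  0.005, -0.030,  0.50),
    list("scalenus_post",       "deep",        110, -0.020, 0.42, -0.060, "neck_lower", -0.005, -0.030,  0.85),
    list("long_cap_sklc4",      "deep",        180, 0.030, 0.10, -0.010, "head",        0.030, -0.008, -0.005),
    list("long_col_c1thx",      "deep",        120, 0.030, 0.06, -0.040, "neck_upper",  0.020, -0.006,  0.90),
    list("long_col_c1c5",       "deep",        100, 0.028, 0.05, -0.015, "neck_upper",  0.020, -0.005,  0.85),
    list("long_col_c5thx",      "deep",        100, 0.030, 0.06, -0.050, "neck_lower",  0.022, -0.006,  0.80),
    list("trap_cl",             "superficial", 250, 0.020, 0.60, -0.030, "head",       -0.045, -0.030,  0.025),
    list("trap_acr",            "superficial", 220, 0.000, 1.00, -0.020, "head",       -0.045, -0.028,  0.022),
    list("splen_cap_sklc6",     "superficial", 190, -0.050, 0.03, -0.010, "head",      -0.040, -0.030,  0.020),
    list("splen_cap_sklthx",    "superficial", 170, -0.055, 0.02, -0.060, "head",      -0.040, -0.032,  0.020),
    list("splen_cerv_c3thx",    "superficial", 120, -0.055, 0.02, -0.080, "neck_upper", -0.020, -0.025,  0.30),
    list("semi_cap_sklc5",      "deep",        200, -0.040, 0.15, -0.020, "head",      -0.050, -0.012,  0.022),
    list("semi_cap_sklthx",     "deep",        180, -0.050, 0.12, -0.070, "head",      -0.050, -0.014,  0.020),
    list("semi_cerv_c3thx",     "deep",        130, -0.050, 0.12, -0.080, "neck_upper", -0.020, -0.010,  0.35),
    list("levator_scap",        "superficial", 150, -0.050, 0.70, -0.070, "neck_upper", -0.005, -0.030,  0.80),
    list("longissi_cap_sklc6",  "deep",        120, -0.045, 0.18, -0.030, "head",      -0.010, -0.040,  0.015),
    list("longissi_cerv_c4thx", "deep",        110, -0.050, 0.15, -0.080, "neck_lower", -0.010, -0.028,  0.90),
    list("iliocost_cerv_c5rib", "deep",        100, -0.040, 0.40, -0.090, "neck_lower", -0.008, -0.030,  0.80),
    list("rectcap_post_maj",    "deep",         60, -0.045, 0.04,  0.020, "head",      -0.050, -0.008,  0.020),
    list("rectcap_post_min",    "deep",         50, -0.040, 0.03,  0.030, "head",      -0.048, -0.006,  0.022),
    list("obl_cap_sup",         "deep",         55, -0.030, 0.10,  0.030, "head",      -0.040, -0.025,  0.020),
    list("obl_cap_inf",         "deep",         70, -0.045, 0.03,  0.020, "neck_upper",  0.000, -0.035,  0.95)
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], depth = r[[2]], fmax = r[[3]],
               ox = r[[4]], oyf = r[[5]], oz = r[[6]], seg = r[[7]],
               ix = r[[8]], iy = r[[9]], iz = r[[10]],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# Base names retained in the fast 16-muscle bilateral subset: flexors,
# extensors, lateral benders and rotators all represented so the six net
# joint moments stay feasible.
reduced_muscle_names <- function() {
  c("stern_mast", "Sterno_hyoid", "Omo_hyoid", "long_cap_sklc4",
    "trap_cl", "longissi_cerv_c4thx", "semi_cap_sklc5", "obl_cap_inf")
}

# Materialize the bilateral muscle table for given chain dimensions.
# W, L1, L2 in meters.  Local insertion coordinates are expressed in the
# carrying body's frame; for the "head"/"neck_upper" entries this is the
# upper-body frame whose origin sits at the mid (C4) articulation.
build_muscle_table <- function(W, L1, L2, muscle_set = "full72") {
  tab <- muscle_geometry_table()
  if (identical(muscle_set, "reduced16"))
    tab <- tab[tab$name %in% reduced_muscle_names(), , drop = FALSE]
  mk <- function(side) {
    s <- if (side == "right") -1 else 1
    suffix <- if (side == "right") "" else "_L"
    data.frame(
      name = paste0(tab$name, suffix),
      side = side,
      depth = tab$depth,
      fmax = tab$fmax,
      partner = paste0(tab$name, if (side == "right") "_L" else ""),
      ox = tab$ox,
      oy = s * tab$oyf * W / 2,
      oz = tab$oz,
      seg = tab$seg,
      ix = tab$ix,
      iy = s * abs(tab$iy),
      iz = ifelse(tab$seg == "head", tab$iz + L2,
           ifelse(tab$seg == "neck_upper", tab$iz * L2, tab$iz * L1)),
      stringsAsFactors = FALSE)
  }
  out <- rbind(mk("right"), mk("left"))
  rownames(out) <- NULL
  out
}
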