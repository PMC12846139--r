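# Motion envelopes: 3-D hulls of marker point clouds, voxel-grid IoU,
# best-match search, force-ratio deficit maps and the paired comparison.

# Incremental 3-D convex hull.  Returns vertex coordinates, outward-
# oriented triangular faces (index triplets), outward unit normals and
# plane offsets.  O(n * faces); inputs are downsampled upstream.
convex_hull_3d <- function(points, tol = 1e-10) {
  P <- unique(as.matrix(points))
  if (ncol(P) != 3) stop("points must be n x 3")
  n <- nrow(P)
  if (n < 4) stop("need at least 4 distinct points")

  # initial non-degenerate tetrahedron
  i1 <- 1L
  d <- rowSums(sweep(P, 2, P[i1, ])^2); i2 <- which.max(d)
  if (d[i2] < tol) stop("degenerate point set (all coincident)")
  u <- P[i2, ] - P[i1, ]
  v <- sweep(P, 2, P[i1, ])
  cr <- cbind(v[, 2] * u[3] - v[, 3] * u[2],
              v[, 3] * u[1] - v[, 1] * u[3],
              v[, 1] * u[2] - v[, 2] * u[1])
  a2 <- rowSums(cr^2); i3 <- which.max(a2)
  if (a2[i3] < tol) stop("degenerate point set (collinear)")
  nrm <- cross3(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  h <- abs(as.numeric(v %*% nrm)) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] < 1e-9) stop("degenerate point set (coplanar)")

  interior <- colMeans(P[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- P[f[1], ]; nn <- cross3(P[f[2], ] - a, P[f[3], ] - a)
    if (sum(nn * (a - interior)) < 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))

  face_planes <- function(faces) {
    N <- t(apply(faces, 1, function(f) {
      a <- P[f[1], ]
      nn <- cross3(P[f[2], ] - a, P[f[3], ] - a)
      nn / sqrt(sum(nn^2))
    }))
    off <- rowSums(N * P[faces[, 1], , drop = FALSE])
    list(N = N, off = off)
  }

  pl <- face_planes(faces)
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  eps <- 1e-9 * max(1, max(abs(P)))
  for (ip in rest) {
    p <- P[ip, ]
    vis <- as.numeric(pl$N %*% p) - pl$off > eps
    if (!any(vis)) next
    vf <- faces[vis, , drop = FALSE]
    # horizon = edges of visible faces appearing exactly once
    ed <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    horizon <- ed[key %in% names(which(table(key) == 1)), , drop = FALSE]
    newf <- cbind(horizon, ip)
    newf <- t(apply(newf, 1, orient))
    faces <- rbind(faces[!vis, , drop = FALSE], newf)
    pl <- face_planes(faces)
  }
  verts_used <- sort(unique(as.vector(faces)))
  list(points = P, faces = faces, normals = pl$N, offsets = pl$off,
       vertices = P[verts_used, , drop = FALSE], interior = interior)
}

hull_volume <- function(hull) {
  c0 <- hull$interior
  vols <- apply(hull$faces, 1, function(f) {
    a <- hull$points[f[1], ] - c0
    b <- hull$points[f[2], ] - c0
    cc <- hull$points[f[3], ] - c0
    sum(a * cross3(b, cc)) / 6
  })
  sum(vols)
}

# logical inside test for an n x 3 matrix of query points
hull_contains <- function(hull, X, slack = 1e-9) {
  X <- as.matrix(X)
  inside <- rep(TRUE, nrow(X))
  for (k in seq_len(nrow(hull$normals))) {
    inside <- inside &
      (X %*% hull$normals[k, ] <= hull$offsets[k] + slack)
    if (!any(inside)) break
  }
  as.vector(inside)
}

#' Build a 3-D motion envelope from marker points
#'
#' The default (`alpha = Inf`) envelope is the convex hull of the point
#' cloud, a faithful choice for the near-convex clouds head markers trace
#' during smooth motion.  A finite `alpha` intersects the hull with the
#' union of radius-`alpha` balls around the samples, evaluated on a voxel
#' grid (a conservative concave refinement; its volume never exceeds the
#' hull's).
#'
#' @param points n x 3 matrix of marker positions (m); at least 4
#'   non-coplanar points.
#' @param alpha shape parameter (m); `Inf` = convex hull.
#' @param marker marker id (metadata).
#' @param max_points clouds larger than this are thinned deterministically
#'   (every k-th point) before hull construction.
#' @param resolution voxel grid resolution for finite-alpha volume.
#' @return An object of class `envelope` with the surface, `alpha` and
#'   `volume` (m^3).
#' @export
build_envelope <- function(points, alpha = Inf, marker = "",
                           max_points = 2000L, resolution = 64L) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points")
  if (nrow(points) > max_points) {
    keep <- unique(round(seq(1, nrow(points), length.out = max_points)))
    points <- points[keep, , drop = FALSE]
  }
  hull <- convex_hull_3d(points)
  vol <- hull_volume(hull)
  if (is.finite(alpha)) {
    box <- apply(hull$points, 2, range)
    gr <- voxel_grid(box, resolution)
    inside <- envelope_contains_raw(hull, points, alpha, gr$centers)
    # the alpha region is a subset of the hull by construction; cap the
    # voxel estimate so discretization noise cannot exceed the hull volume
    vol <- min(sum(inside) * gr$cell_volume, vol)
  }
  structure(list(marker = marker, points = points, hull = hull,
                 alpha = alpha, volume = vol), class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("Envelope [%s]: %d points, %d hull faces, alpha = %s, volume %.3e m^3\n",
              x$marker, nrow(x$points), nrow(x$hull$faces),
              format(x$alpha), x$volume))
  invisible(x)
}

voxel_grid <- function(box, resolution) {
  resolution <- as.integer(resolution)
  ax <- lapply(1:3, function(k) {
    lo <- box[1, k]; hi <- box[2, k]
    if (hi - lo <= 0) { lo <- lo - 1e-9; hi <- hi + 1e-9 }
    seq(lo + (hi - lo) / (2 * resolution), hi - (hi - lo) / (2 * resolution),
        length.out = resolution)
  })
  centers <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  cell <- prod(vapply(1:3, function(k)
    (box[2, k] - box[1, k]) / resolution, 0))
  list(centers = centers, cell_volume = max(cell, .Machine$double.xmin))
}

envelope_contains_raw <- function(hull, pts, alpha, X) {
  inside <- hull_contains(hull, X)
  if (is.finite(alpha) && any(inside)) {
    idx <- which(inside)
    # chunked nearest-sample distance test
    near <- logical(length(idx))
    chunk <- 20000L
    for (s in seq(1, length(idx), by = chunk)) {
      ii <- idx[s:min(s + chunk - 1, length(idx))]
      D <- outer(rowSums(X[ii, , drop = FALSE]^2), rowSums(pts^2), "+") -
        2 * X[ii, , drop = FALSE] %*% t(pts)
      near[s:min(s + chunk - 1, length(idx))] <-
        sqrt(pmax(apply(D, 1, min), 0)) <= alpha
    }
    inside[idx] <- near
  }
  inside
}

envelope_contains <- function(env, X) {
  envelope_contains_raw(env$hull, env$points, env$alpha, X)
}

#' Volumetric intersection-over-union of two envelopes
#'
#' `V_intersection / V_union` estimated on a common axis-aligned voxel
#' grid over the joint bounding box: deterministic for a fixed
#' resolution, symmetric in its arguments.
#'
#' @param A,B [build_envelope()] objects.
#' @param resolution voxels per axis (default 64).
#' @return IoU in `[0, 1]`.
#' @export
envelope_iou <- function(A, B, resolution = 64L) {
  stopifnot(inherits(A, "envelope"), inherits(B, "envelope"))
  boxA <- apply(A$hull$points, 2, range)
  boxB <- apply(B$hull$points, 2, range)
  box <- rbind(pmin(boxA[1, ], boxB[1, ]), pmax(boxA[2, ], boxB[2, ]))
  gr <- voxel_grid(box, resolution)
  ina <- envelope_contains(A, gr$centers)
  inb <- envelope_contains(B, gr$centers)
  uni <- sum(ina | inb)
  if (uni == 0) stop("empty union on the voxel grid")
  sum(ina & inb) / uni
}

#' Marker envelopes of a model's ideal motion
#'
#' Runs the motion suite through forward kinematics and builds one
#' envelope per head marker.
#'
#' @param model a [neck_model()].
#' @param motions list of [motion_spec()]s or [motion_trajectory()]s.
#' @param alpha envelope shape parameter.
#' @return Named list of three [build_envelope()] objects (TP, LH, RH).
#' @export
marker_envelopes <- function(model, motions, alpha = Inf) {
  if (inherits(motions, "motion_spec") ||
      inherits(motions, "motion_trajectory")) motions <- list(motions)
  pos <- do.call(rbind, lapply(motions, function(mo) {
    traj <- if (inherits(mo, "motion_spec"))
      generate_motion(mo, articulations = model$articulations) else mo
    marker_trajectory(model, traj)$positions
  }))
  out <- lapply(c(TP = "TP", LH = "LH", RH = "RH"), function(mk)
    build_envelope(pos[, paste(mk, c("x", "y", "z"), sep = "_")],
                   alpha = alpha, marker = mk))
  out
}

#' Best-matching model in an envelope database
#'
#' Per candidate model the score is `IoU_TP + IoU_LH + IoU_RH` (each
#' marker weighted equally); the candidate with the highest total is the
#' best match, ties broken by the lowest model id.
#'
#' @param subject_envelopes named list with `TP`, `LH`, `RH` envelopes of
#'   the subject's observed motion.
#' @param database list (one element per candidate model) of named
#'   per-marker envelope lists.
#' @param resolution voxel resolution for [envelope_iou()].
#' @return List of class `envelope_match`: `best_id`, `best_ious` (named
#'   per-marker), `total_score`, `scores` (per-model data frame).
#' @export
best_match <- function(subject_envelopes, database, resolution = 64L) {
  mk <- c("TP", "LH", "RH")
  if (!all(mk %in% names(subject_envelopes)))
    stop("subject envelopes must include TP, LH and RH")
  if (length(database) == 0) stop("empty envelope database")
  scores <- do.call(rbind, lapply(seq_along(database), function(i) {
    db <- database[[i]]
    if (!all(mk %in% names(db)))
      stop("database model ", i, " is missing a marker envelope")
    ious <- vapply(mk, function(m)
      envelope_iou(subject_envelopes[[m]], db[[m]], resolution), 0)
    data.frame(model = i, TP = ious["TP"], LH = ious["LH"],
               RH = ious["RH"], total = sum(ious), row.names = NULL)
  }))
  best <- scores$model[order(-scores$total, scores$model)][1]
  structure(list(best_id = best,
                 best_ious = unlist(scores[scores$model == best, mk]),
                 total_score = scores$total[scores$model == best],
                 scores = scores),
            class = "envelope_match")
}

#' @export
print.envelope_match <- function(x, ...) {
  cat(sprintf("Best-match model %d | IoU TP %.4f LH %.4f RH %.4f | total %.4f\n",
              x$best_id, x$best_ious["TP"], x$best_ious["LH"],
              x$best_ious["RH"], x$total_score))
  invisible(x)
}

#' Peak-force ratio map (actual vs ideal motion)
#'
#' Ratio of per-muscle peak force predicted from the subject's actual
#' motion to the peak predicted from the ideal (reference) motion.
#' Ideal peaks below `floor` are reported `NA` (undefined) rather than
#' divided.
#'
#' @param actual,ideal force tables (frames x muscles) over the same
#'   muscle set.
#' @param floor smallest meaningful ideal peak (N).
#' @return Named vector of ratios (`NA` = undefined).
#' @export
force_ratio_map <- function(actual, ideal, floor = 1e-3) {
  actual <- as.matrix(actual); ideal <- as.matrix(ideal)
  if (!identical(colnames(actual), colnames(ideal)))
    stop("muscle sets differ between actual and ideal tables")
  pa <- apply(actual, 2, max)
  pi_ <- apply(ideal, 2, max)
  out <- ifelse(pi_ < floor, NA_real_, pa / pi_)
  stats::setNames(out, colnames(actual))
}

#' Paired t-test on per-marker IoU triplets
#'
#' Standard paired t on the differences (df = n - 1) via
#' [stats::t.test()].  Identical inputs give `t = 0, p = 1`; any other
#' zero-variance difference vector is an error.
#'
#' @param x,y equal-length numeric vectors (n >= 2), e.g. the per-marker
#'   IoUs of two subjects.
#' @return List `t`, `df`, `p_value`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("need equal lengths >= 2")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p_value = 1))
    stop("zero-variance differences; paired t undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Assessment report for a subject against an envelope database
#'
#' Combines the best-match search with the peak-force-ratio deficit map:
#' ratios below `theta_low` flag possible impairment (underactivation),
#' ratios above `theta_high` flag possible compensation.
#'
#' @param match an [best_match()] result.
#' @param force_ratios a [force_ratio_map()] result (optional).
#' @param theta_low,theta_high flag thresholds on the peak-force ratio.
#' @return An object of class `assessment_report`.
#' @export
assessment_report <- function(match, force_ratios = NULL,
                              theta_low = 0.85, theta_high = 1.15) {
  stopifnot(inherits(match, "envelope_match"))
  ratios <- NULL
  if (!is.null(force_ratios)) {
    ratios <- data.frame(
      muscle = names(force_ratios),
      ratio = as.numeric(force_ratios),
      impaired = !is.na(force_ratios) & force_ratios < theta_low,
      compensating = !is.na(force_ratios) & force_ratios > theta_high,
      row.names = NULL)
  }
  structure(list(best_id = match$best_id,
                 marker_iou = match$best_ious,
                 average_iou = mean(match$best_ious),
                 total_score = match$total_score,
                 ratios = ratios,
                 theta_low = theta_low, theta_high = theta_high),
            class = "assessment_report")
}

#' Per-subject IoU summary table
#'
#' The averaging path of the assessment report: per subject the TP/RH/LH
#' IoUs and their mean, plus the paired t comparison of the first subject
#' against the last (the patient-vs-healthy layout).
#'
#' @param ious named list: one numeric vector of per-marker IoUs (names
#'   TP/RH/LH) per subject.
#' @return Data frame with columns `subject`, `TP`, `RH`, `LH`,
#'   `average_iou`, and attributes `t`, `df`, `p_value` when two or more
#'   subjects are given.
#' @export
iou_summary <- function(ious) {
  out <- do.call(rbind, lapply(names(ious), function(s) {
    v <- ious[[s]]
    data.frame(subject = s, TP = v[["TP"]], RH = v[["RH"]], LH = v[["LH"]],
               average_iou = mean(c(v[["TP"]], v[["RH"]], v[["LH"]])),
               row.names = NULL)
  }))
  if (length(ious) >= 2) {
    ord <- c("TP", "RH", "LH")
    tt <- paired_ttest(ious[[1]][ord], ious[[length(ious)]][ord])
    attr(out, "t") <- tt$t
    attr(out, "df") <- tt$df
    attr(out, "p_value") <- tt$p_value
  }
  out
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("Assessment report\n")
  cat(sprintf("  best-match model: %d | total IoU score %.4f (of 3)\n",
              x$best_id, x$total_score))
  cat(sprintf("  marker IoU: TP %.4f | LH %.4f | RH %.4f | average %.4f\n",
              x$marker_iou["TP"], x$marker_iou["LH"], x$marker_iou["RH"],
              x$average_iou))
  if (!is.null(x$ratios)) {
    cat(sprintf("  muscles flagged impaired (ratio < %.2f): %d | compensating (> %.2f): %d\n",
                x$theta_low, sum(x$ratios$impaired),
                x$theta_high, sum(x$ratios$compensating)))
  }
  invisible(x)
}

#' Export an assessment report as CSV
#'
#' @param report an [assessment_report()].
#' @param path file path.
#' @export
write_assessment <- function(report, path) {
  hdr <- data.frame(
    muscle = c(".best_model", ".iou_TP", ".iou_LH", ".iou_RH",
               ".iou_average", ".total_score"),
    ratio = c(report$best_id, report$marker_iou["TP"],
              report$marker_iou["LH"], report$marker_iou["RH"],
              report$average_iou, report$total_score),
    impaired = NA, compensating = NA)
  body <- report$ratios
  utils::write.csv(rbind(hdr, body), path, row.names = FALSE)
  invisible(path)
}

#' Export an envelope surface as a Wavefront OBJ mesh
#'
#' @param env a [build_envelope()] object (hull surface).
#' @param path file path (`.obj`).
#' @export
write_envelope_obj <- function(env, path) {
  stopifnot(inherits(env, "envelope"))
  P <- env$hull$points
  used <- sort(unique(as.vector(env$hull$faces)))
  remap <- match(seq_len(nrow(P)), used)
  con <- file(path, "w")
  writeLines(sprintf("v %.9g %.9g %.9g",
                     P[used, 1], P[used, 2], P[used, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     remap[env$hull$faces[, 1]],
                     remap[env$hull$faces[, 2]],
                     remap[env$hull$faces[, 3]]), con)
  close(con)
  invisible(path)
}
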