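cube_pts <- function(origin = c(0, 0, 0), side = 1) {
  sweep(as.matrix(expand.grid(0:1, 0:1, 0:1)) * side, 2, origin, "+")
}

test_that("convex-hull envelopes recover analytic volumes", {
  e <- build_envelope(cube_pts())
  expect_equal(e$volume, 1, tolerance = 1e-12)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(build_envelope(tet)$volume, 1 / 6, tolerance = 1e-12)
  # interior points do not change the hull
  pts <- rbind(cube_pts(), matrix(runif(30, 0.2, 0.8), ncol = 3))
  expect_equal(build_envelope(pts)$volume, 1, tolerance = 1e-12)
})

test_that("degenerate point sets raise explicit errors", {
  expect_error(build_envelope(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               "at least 4")
  coplanar <- cbind(matrix(runif(20), ncol = 2), 0.5)
  expect_error(build_envelope(coplanar), "coplanar")
  collinear <- cbind(seq(0, 1, length.out = 8), 0, 0)
  expect_error(build_envelope(collinear), "degenerate|collinear")
})

test_that("IoU matches analytic box geometry", {
  A <- build_envelope(cube_pts())
  expect_equal(envelope_iou(A, A, resolution = 32), 1)
  B <- build_envelope(cube_pts(origin = c(0.5, 0, 0)))
  expect_lt(abs(envelope_iou(A, B, resolution = 100) - 1 / 3), 0.01)
  expect_equal(envelope_iou(A, B, resolution = 100),
               envelope_iou(B, A, resolution = 100))
  D <- build_envelope(cube_pts(origin = c(5, 5, 5)))
  expect_equal(envelope_iou(A, D, resolution = 32), 0)
})

test_that("shrinking one envelope inside the other strictly lowers IoU", {
  A <- build_envelope(cube_pts(side = 1))
  prev <- 1
  for (s in c(0.9, 0.7, 0.5)) {
    B <- build_envelope(sweep(cube_pts(side = s), 2, (1 - s) / 2, "+"))
    iou <- envelope_iou(A, B, resolution = 64)
    expect_lt(iou, prev)
    expect_lt(abs(iou - s^3), 0.03)  # nested boxes: V_B / V_A
    prev <- iou
  }
})

test_that("a finite alpha never exceeds the hull volume", {
  set.seed(9)
  pts <- matrix(runif(600), ncol = 3)
  hull <- build_envelope(pts)
  shaped <- build_envelope(pts, alpha = 0.2)
  expect_lte(shaped$volume, hull$volume + 1e-9)
  expect_gt(shaped$volume, 0)
})

test_that("best match maximizes the summed per-marker IoU with stable ties", {
  subject <- lapply(c(TP = 0, LH = 0, RH = 0), function(o)
    build_envelope(cube_pts()))
  # model 1: perfect copy; model 2: shifted boxes
  db <- list(
    lapply(c(TP = 0, LH = 0, RH = 0), function(o) build_envelope(cube_pts())),
    lapply(c(TP = 0, LH = 0, RH = 0), function(o)
      build_envelope(cube_pts(origin = c(0.5, 0, 0)))))
  m <- best_match(subject, db, resolution = 48)
  expect_equal(m$best_id, 1)
  expect_equal(m$total_score, 3, tolerance = 1e-9)
  expect_equal(unname(m$best_ious), c(1, 1, 1), tolerance = 1e-9)

  # constructed scores from nested boxes of known analytic IoU:
  # model A IoUs (1, 1, 0.5^3) = 2.125 beats model B (0.9^3 x 3) = 2.187?
  dbA <- list(TP = build_envelope(cube_pts()),
              LH = build_envelope(cube_pts()),
              RH = build_envelope(sweep(cube_pts(side = 0.5), 2, 0.25, "+")))
  dbB <- lapply(c(TP = 0, LH = 0, RH = 0), function(o)
    build_envelope(sweep(cube_pts(side = 0.9), 2, 0.05, "+")))
  m2 <- best_match(subject, list(dbA, dbB), resolution = 64)
  scoreA <- 2 + 0.5^3
  scoreB <- 3 * 0.9^3
  expect_equal(m2$scores$total, c(scoreA, scoreB), tolerance = 0.05)
  expect_equal(m2$best_id, which.max(c(scoreA, scoreB)))

  # single-model database always returns that model
  m3 <- best_match(subject, list(dbB), resolution = 32)
  expect_equal(m3$best_id, 1)
  # exact ties break to the lowest id
  m4 <- best_match(subject, list(dbB, dbB), resolution = 32)
  expect_equal(m4$best_id, 1)
  expect_error(best_match(subject, list(), 32), "empty")
  expect_error(best_match(subject[1:2], db, 32), "TP, LH and RH")
})

test_that("force-ratio maps are unit-consistent with guarded peaks", {
  f <- matrix(runif(40, 1, 10), 10, 4,
              dimnames = list(NULL, paste0("m", 1:4)))
  expect_equal(unname(force_ratio_map(f, f)), rep(1, 4))
  expect_equal(unname(force_ratio_map(0.5 * f, f)), rep(0.5, 4))
  g <- f; g[, 2] <- 0
  r <- force_ratio_map(f, g)
  expect_true(is.na(r["m2"]))
  expect_equal(unname(r[c(1, 3, 4)]), rep(1, 3))
  h <- f; colnames(h)[1] <- "other"
  expect_error(force_ratio_map(f, h), "muscle sets")
})

test_that("the paired t-test matches the published-table computation", {
  # identical triplets: t = 0, p = 1 by convention
  tt0 <- paired_ttest(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p_value, 1)

  patient <- c(TP = 0.7325, RH = 0.7812, LH = 0.8024)
  healthy <- c(TP = 0.9328, RH = 0.9221, LH = 0.9275)
  tt <- paired_ttest(patient, healthy)
  # independent oracle: the direct paired-t formula on the differences
  d <- patient - healthy
  t_ref <- mean(d) / (stats::sd(d) / sqrt(3))
  expect_equal(tt$t, t_ref, tolerance = 1e-12)
  expect_equal(tt$t, -6.79, tolerance = 0.01)
  expect_equal(tt$df, 2)
  expect_equal(tt$p_value, 2 * stats::pt(t_ref, 2), tolerance = 1e-12)

  expect_error(paired_ttest(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
  expect_error(paired_ttest(1, 2), "lengths")
})

test_that("the IoU summary reproduces per-subject averages from its cells", {
  s <- iou_summary(list(
    patient = c(TP = 0.7325, RH = 0.7812, LH = 0.8024),
    healthy = c(TP = 0.9328, RH = 0.9221, LH = 0.9275)))
  expect_equal(s$average_iou,
               c(mean(c(0.7325, 0.7812, 0.8024)),
                 mean(c(0.9328, 0.9221, 0.9275))))
  expect_equal(attr(s, "df"), 2)
  expect_lt(attr(s, "p_value"), 0.05)
})

test_that("restricted motion shrinks the envelope and its IoU", {
  model <- neck_model(muscle_set = "reduced16")
  sp <- motion_spec("combined", cycle_period = 8, fs = 25)
  full_env <- marker_envelopes(model, sp)
  restr_env <- marker_envelopes(model,
                                restrict_motion(sp, "flexion_pos", 0.5))
  for (mk in c("TP", "LH", "RH")) {
    expect_lt(restr_env[[mk]]$volume, full_env[[mk]]$volume)
    expect_lt(envelope_iou(restr_env[[mk]], full_env[[mk]], 48), 1)
  }
})

test_that("assessment reports flag impairment and compensation", {
  subject <- lapply(c(TP = 0, LH = 0, RH = 0), function(o)
    build_envelope(cube_pts()))
  db <- list(lapply(c(TP = 0, LH = 0, RH = 0), function(o)
    build_envelope(cube_pts())))
  m <- best_match(subject, db, resolution = 32)
  ratios <- c(weak = 0.5, normal = 1.0, strong = 1.5)
  rep_ <- assessment_report(m, ratios)
  expect_equal(rep_$ratios$impaired, c(TRUE, FALSE, FALSE))
  expect_equal(rep_$ratios$compensating, c(FALSE, FALSE, TRUE))
  expect_equal(rep_$average_iou, 1, tolerance = 1e-9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_assessment(rep_, path)
  expect_true(file.exists(path))
  back <- utils::read.csv(path)
  expect_true(all(c("muscle", "ratio") %in% names(back)))
})

test_that("envelope surfaces export as valid OBJ meshes", {
  e <- build_envelope(cube_pts())
  path <- withr::local_tempfile(fileext = ".obj")
  write_envelope_obj(e, path)
  lines <- readLines(path)
  nv <- sum(startsWith(lines, "v "))
  nf <- sum(startsWith(lines, "f "))
  expect_equal(nv, 8)
  expect_gte(nf, 12)  # triangulated cube
  # Euler characteristic of a closed surface: V - E + F = 2, E = 3F/2
  expect_equal(nv - 3 * nf / 2 + nf, 2)
})
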