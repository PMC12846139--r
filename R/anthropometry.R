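#' Population statistics of the three personalization parameters
#'
#' Container for the mean vector and covariance matrix of the three
#' anthropometric parameters that personalize the head-neck model:
#' head mass (kg), shoulder (biacromial) width (cm) and neck length (cm),
#' in that fixed order.  The packaged default, [ansur_population()], carries
#' the published ANSUR-II-derived values, so no external download is ever
#' needed.
#'
#' @param mean numeric length-3 vector `(head_mass_kg, shoulder_width_cm,
#'   neck_length_cm)`; all components must be strictly positive.
#' @param covariance numeric 3x3 symmetric positive-semidefinite matrix in
#'   the same unit order.
#' @return An object of class `population_stats`.
#' @export
population_stats <- function(mean, covariance) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  if (length(mean) != 3L || any(!is.finite(mean)) || any(mean <= 0))
    stop("`mean` must be 3 strictly positive finite values")
  if (!all(dim(covariance) == c(3L, 3L)) || any(!is.finite(covariance)))
    stop("`covariance` must be a finite 3x3 matrix")
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("`covariance` must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("`covariance` must be positive semidefinite")
  structure(
    list(mean = stats::setNames(mean, c("head_mass", "shoulder_width", "neck_length")),
         covariance = covariance),
    class = "population_stats")
}

#' ANSUR-II-derived cervical anthropometry statistics
#'
#' The packaged population distribution of head mass (kg), biacromial
#' shoulder width (cm) and neck length (cm): mean
#' `(6.377, 39.920, 10.730)` with covariance rows
#' `(1.568, 2.678, -0.001)`, `(2.678, 9.143, 0.378)`,
#' `(-0.001, 0.378, 1.546)`.  The near-zero head-mass/neck-length
#' covariance is used verbatim.
#'
#' @return A [population_stats()] object.
#' @export
ansur_population <- function() {
  population_stats(
    mean = c(6.377, 39.920, 10.730),
    covariance = matrix(c(
      1.568, 2.678, -0.001,
      2.678, 9.143,  0.378,
     -0.001, 0.378,  1.546), nrow = 3, byrow = TRUE))
}

#' @export
print.population_stats <- function(x, ...) {
  cat("Population statistics (head mass kg, shoulder width cm, neck length cm)\n")
  cat("mean:", format(x$mean, digits = 5), "\n")
  cat("covariance:\n")
  print(x$covariance, digits = 5)
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample anthropometric profiles from a population distribution
#'
#' Draws multivariate-normal samples of the three personalization
#' parameters.  Draws with any nonpositive component, or any component more
#' than 5 standard deviations from its mean, are rejected and redrawn:
#' under the packaged statistics this is vanishingly rare but it guarantees
#' anatomical plausibility of every returned profile.
#'
#' @param stats a [population_stats()] object.
#' @param n number of profiles (>= 1).
#' @param seed integer seed; the same `(stats, n, seed)` always returns the
#'   identical sample.
#' @return A data frame of class `anthro_population` with columns
#'   `id`, `head_mass_kg`, `shoulder_width_cm`, `neck_length_cm`, `seed`.
#' @export
sample_population <- function(stats, n, seed = 1L) {
  stopifnot(inherits(stats, "population_stats"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  sds <- sqrt(pmax(diag(stats$covariance), 0))
  lo <- pmax(stats$mean - 5 * sds, .Machine$double.eps)
  hi <- stats$mean + 5 * sds
  draws <- with_seed(seed, {
    x <- MASS::mvrnorm(n, mu = stats$mean, Sigma = stats$covariance)
    x <- matrix(x, ncol = 3)
    bad <- which(apply(x, 1, function(r) any(r <= 0 | r < lo | r > hi)))
    guard <- 0L
    while (length(bad) > 0L && guard < 1000L) {
      redo <- matrix(MASS::mvrnorm(length(bad), mu = stats$mean,
                                   Sigma = stats$covariance), ncol = 3)
      x[bad, ] <- redo
      bad <- which(apply(x, 1, function(r) any(r <= 0 | r < lo | r > hi)))
      guard <- guard + 1L
    }
    if (length(bad) > 0L) stop("rejection sampling failed to converge")
    x
  })
  out <- data.frame(
    id = seq_len(n),
    head_mass_kg = draws[, 1],
    shoulder_width_cm = draws[, 2],
    neck_length_cm = draws[, 3],
    seed = seed)
  class(out) <- c("anthro_population", "data.frame")
  out
}

#' Single anthropometric profile
#'
#' @param head_mass head mass in kg (> 0).
#' @param shoulder_width biacromial breadth in cm (> 0).
#' @param neck_length C7-to-occiput neck length in cm (> 0).
#' @return A named list of class `anthro_profile`.
#' @export
anthro_profile <- function(head_mass, shoulder_width, neck_length) {
  vals <- c(head_mass = head_mass, shoulder_width = shoulder_width,
            neck_length = neck_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all profile parameters must be strictly positive and finite")
  structure(as.list(vals), class = "anthro_profile")
}

# i-th row of an anthro_population as an anthro_profile
profile_from_row <- function(pop, i) {
  anthro_profile(pop$head_mass_kg[i], pop$shoulder_width_cm[i],
                 pop$neck_length_cm[i])
}

#' Head mass from body weight
#'
#' Estimates head mass as 8% of total body weight.
#'
#' @param body_weight body weight in kg (> 0).
#' @return Head mass in kg.
#' @export
head_mass_from_body_weight <- function(body_weight) {
  if (any(!is.finite(body_weight)) || any(body_weight <= 0))
    stop("`body_weight` must be strictly positive")
  0.08 * body_weight
}

#' Write / read a sampled population as CSV
#'
#' Columns: `id, head_mass_kg, shoulder_width_cm, neck_length_cm, seed`.
#'
#' @param pop an `anthro_population` data frame.
#' @param path file path.
#' @return `read_population` returns the `anthro_population` data frame.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  out <- utils::read.csv(path)
  need <- c("id", "head_mass_kg", "shoulder_width_cm", "neck_length_cm", "seed")
  if (!all(need %in% names(out)))
    stop("population CSV must have columns: ", paste(need, collapse = ", "))
  class(out) <- c("anthro_population", "data.frame")
  out
}
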