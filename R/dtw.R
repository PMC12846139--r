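# Dynamic time warping over multivariate joint-angle series.
# Euclidean local cost, symmetric step pattern (diagonal, horizontal,
# vertical), no window.

local_cost <- function(a, b) {
  # a: n x d, b: m x d -> n x m Euclidean distance matrix
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' DTW distance and alignment path between two trajectories
#'
#' @param a,b [motion_trajectory()] objects (or plain matrices) with the
#'   same number of DOF columns.
#' @return `dtw_distance` returns the accumulated alignment cost;
#'   `dtw_path` returns a two-column matrix of aligned (row of a, row of
#'   b) index pairs from (1,1) to (n,m).
#' @export
dtw_distance <- function(a, b) {
  dtw_align(a, b)$distance
}

#' @rdname dtw_distance
#' @export
dtw_path <- function(a, b) {
  dtw_align(a, b)$path
}

as_q_matrix <- function(x) {
  if (inherits(x, "motion_trajectory")) x$q else as.matrix(x)
}

dtw_align <- function(a, b) {
  a <- as_q_matrix(a); b <- as_q_matrix(b)
  if (ncol(a) != ncol(b)) stop("mismatched DOF counts")
  C <- local_cost(a, b)
  n <- nrow(C); m <- ncol(C)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    row_prev <- D[i, ]
    row_cur <- D[i + 1, ]
    for (j in seq_len(m)) {
      row_cur[j + 1] <- C[i, j] +
        min(row_prev[j], row_prev[j + 1], row_cur[j])
    }
    D[i + 1, ] <- row_cur
  }
  # backtrack
  path <- matrix(0L, n + m, 2)
  i <- n; j <- m; k <- 1L
  path[k, ] <- c(i, j)
  while (i > 1 || j > 1) {
    if (i == 1) j <- j - 1
    else if (j == 1) i <- i - 1
    else {
      steps <- c(D[i, j], D[i, j + 1], D[i + 1, j])  # diag, up, left
      pick <- which.min(steps)
      if (pick == 1) { i <- i - 1; j <- j - 1 }
      else if (pick == 2) i <- i - 1
      else j <- j - 1
    }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  list(distance = D[n + 1, m + 1], path = path[k:1, , drop = FALSE])
}

#' DTW-aligned average of several trajectories
#'
#' Picks the medoid (smallest total pairwise DTW distance, ties to the
#' first), warps every trajectory onto the medoid's timebase along its
#' DTW path (frames of a trajectory matched to the same medoid frame are
#' averaged), and returns the point-wise mean.  This is the alignment/
#' averaging step that turns repeated task executions into one unified
#' kinematic input.
#'
#' @param trajectories list of >= 2 [motion_trajectory()] objects with
#'   identical DOF counts.
#' @return A [motion_trajectory()] on the medoid's timebase.
#' @export
dtw_average <- function(trajectories) {
  if (length(trajectories) < 2) stop("need at least 2 trajectories")
  qs <- lapply(trajectories, as_q_matrix)
  d <- ncol(qs[[1]])
  if (any(vapply(qs, ncol, 0L) != d)) stop("mismatched DOF counts")
  k <- length(qs)
  Dm <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    Dm[i, j] <- Dm[j, i] <- dtw_distance(qs[[i]], qs[[j]])
  }
  med <- which.min(rowSums(Dm))
  ref <- qs[[med]]
  n <- nrow(ref)
  acc <- matrix(0, n, d); cnt <- 0
  for (i in seq_len(k)) {
    if (i == med) {
      warped <- ref
    } else {
      path <- dtw_align(ref, qs[[i]])$path
      warped <- matrix(0, n, d)
      for (r in seq_len(n)) {
        rows <- path[path[, 1] == r, 2]
        warped[r, ] <- colMeans(qs[[i]][rows, , drop = FALSE])
      }
    }
    acc <- acc + warped; cnt <- cnt + 1
  }
  out <- acc / cnt
  colnames(out) <- colnames(ref)
  tmpl <- trajectories[[med]]
  times <- if (inherits(tmpl, "motion_trajectory")) tmpl$times
           else seq_len(n) - 1
  motion_trajectory(times, out)
}
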