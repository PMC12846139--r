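# Per-muscle feedforward surrogates: 12 -> 64 -> 32 -> 1 with ReLU hidden
# layers, trained with Adam, minibatches and early stopping on a
# validation split.  Features are the nine torso-frame marker coordinates
# plus the three anthropometric parameters, in a fixed documented order.

#' Fixed feature order of the surrogate input
#'
#' Nine marker coordinates (`TP_x..RH_z`, meters, torso frame) followed by
#' `neck_length` (cm), `shoulder_width` (cm), `head_mass` (kg).
#'
#' @return Character vector of the 12 feature names.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(c("TP", "LH", "RH"), c("x", "y", "z"),
                      paste, sep = "_"))),
    "neck_length", "shoulder_width", "head_mass")
}

#' Build the supervised dataset from simulated profiles
#'
#' For every anthropometric profile: scales the base model, runs the
#' motion specs through inverse dynamics and the enhanced static
#' optimization, records the forward-kinematics marker positions per
#' frame, and stacks `profiles x frames` rows of 12 features next to the
#' per-muscle force labels.  Frames whose solver did not converge are
#' flagged and excluded from training by default.
#'
#' @param profiles an `anthro_population` data frame
#'   ([sample_population()]) or list of [anthro_profile()]s.
#' @param motions a single [motion_spec()]/[motion_trajectory()] or a list
#'   of them (e.g. [standard_motion_suite()]).
#' @param base_model the base [neck_model()] to scale per profile.
#' @param config an [so_config()].
#' @return A list of class `muscle_dataset`: `features` (rows x 12),
#'   `labels` (rows x muscles, N), `profile_id`, `converged` (logical per
#'   row), `muscle_names`.
#' @export
build_dataset <- function(profiles, motions, base_model,
                          config = so_config()) {
  if (inherits(profiles, "anthro_population")) {
    idx <- seq_len(nrow(profiles))
    plist <- lapply(idx, function(i) profile_from_row(profiles, i))
  } else if (inherits(profiles, "anthro_profile")) {
    plist <- list(profiles)
  } else plist <- profiles
  if (length(plist) == 0) stop("no profiles given")
  if (inherits(motions, "motion_spec") ||
      inherits(motions, "motion_trajectory")) motions <- list(motions)

  feat_list <- list(); lab_list <- list(); pid <- list(); conv <- list()
  for (p in seq_along(plist)) {
    prof <- plist[[p]]
    model <- scale_model(base_model, prof)
    for (mo in motions) {
      traj <- if (inherits(mo, "motion_spec"))
        generate_motion(mo, articulations = model$articulations) else mo
      traj <- derive_kinematics(traj)
      mk <- marker_trajectory(model, traj)
      fs <- solve_trajectory(model, traj, config)
      nf <- nrow(mk$positions)
      feat <- cbind(mk$positions,
                    neck_length = rep(prof$neck_length, nf),
                    shoulder_width = rep(prof$shoulder_width, nf),
                    head_mass = rep(prof$head_mass, nf))
      feat_list[[length(feat_list) + 1L]] <- feat
      lab_list[[length(lab_list) + 1L]] <- fs$forces
      pid[[length(pid) + 1L]] <- rep(p, nf)
      conv[[length(conv) + 1L]] <- fs$status == "converged"
    }
  }
  features <- do.call(rbind, feat_list)
  colnames(features) <- feature_names()
  structure(list(features = features,
                 labels = do.call(rbind, lab_list),
                 profile_id = unlist(pid),
                 converged = unlist(conv),
                 muscle_names = base_model$muscles$name),
            class = "muscle_dataset")
}

#' @export
print.muscle_dataset <- function(x, ...) {
  cat("Muscle dataset:", nrow(x$features), "rows x", ncol(x$features),
      "features,", ncol(x$labels), "muscles |",
      sum(!x$converged), "non-converged rows\n")
  invisible(x)
}

#' Z-score normalizer
#'
#' `zscore_fit` estimates per-column mean and (population) standard
#' deviation on the training rows only; `zscore_apply` standardizes,
#' `zscore_invert` undoes it.  Columns with zero spread get sigma
#' replaced by 1 (with a warning), so constant features pass through as
#' zeros instead of dividing by zero.
#'
#' @param x numeric matrix.
#' @param rows training row indices used for fitting (default all).
#' @return `zscore_fit` returns an object of class `normalizer` with
#'   fields `mu`, `sigma`.
#' @export
zscore_fit <- function(x, rows = seq_len(nrow(x))) {
  x <- as.matrix(x)
  if (length(rows) == 0) stop("empty training rows")
  xt <- x[rows, , drop = FALSE]
  mu <- colMeans(xt)
  sigma <- sqrt(colMeans(sweep(xt, 2, mu)^2))  # population sd
  if (any(sigma == 0)) {
    warning("zero-variance column(s); sigma set to 1")
    sigma[sigma == 0] <- 1
  }
  structure(list(mu = mu, sigma = sigma), class = "normalizer")
}

#' @rdname zscore_fit
#' @param nz a `normalizer`.
#' @export
zscore_apply <- function(nz, x) {
  sweep(sweep(as.matrix(x), 2, nz$mu), 2, nz$sigma, "/")
}

#' @rdname zscore_fit
#' @export
zscore_invert <- function(nz, x) {
  sweep(sweep(as.matrix(x), 2, nz$sigma, "*"), 2, nz$mu, "+")
}

#' Two-stage train/validation/test split
#'
#' First holds out 20% of rows as the independent test set, then splits
#' the remainder 80/20 into training and validation, giving 64/16/20
#' overall.  With `by_profile = TRUE` the split is over whole profiles
#' (all frames of a model stay together), for testing generalization to
#' unseen anthropometry.
#'
#' @param n_rows number of rows (or a `muscle_dataset`).
#' @param seed integer seed; identical seeds give identical splits.
#' @param by_profile split on profiles instead of rows (needs a dataset).
#' @return List of class `split_indices` with `train`, `val`, `test`.
#' @export
split_dataset <- function(n_rows, seed = 1L, by_profile = FALSE) {
  ds <- NULL
  if (inherits(n_rows, "muscle_dataset")) {
    ds <- n_rows; n_rows <- nrow(ds$features)
  }
  if (n_rows < 5) stop("need at least 5 rows to split")
  units <- if (by_profile) {
    if (is.null(ds)) stop("by_profile split needs a muscle_dataset")
    unique(ds$profile_id)
  } else seq_len(n_rows)
  perm <- with_seed(seed, sample(units))
  n <- length(perm)
  n_test <- round(0.2 * n)
  n_val <- round(0.2 * (n - n_test))
  test_u <- perm[seq_len(n_test)]
  val_u <- perm[n_test + seq_len(n_val)]
  train_u <- perm[-seq_len(n_test + n_val)]
  to_rows <- function(u) {
    if (by_profile) which(ds$profile_id %in% u) else u
  }
  structure(list(train = sort(to_rows(train_u)), val = sort(to_rows(val_u)),
                 test = sort(to_rows(test_u)), seed = seed,
                 by_profile = by_profile),
            class = "split_indices")
}

## ---- minimal feedforward net -------------------------------------------

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      # He initialization for ReLU layers
      sd <- sqrt(2 / sizes[l])
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sd),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    list(W = W, b = b, sizes = sizes)
  })
}

mlp_forward <- function(net, X) {
  A <- list(X)
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- if (l < nl) pmax(Z, 0) else Z
  }
  A
}

mlp_predict <- function(net, X) {
  mlp_forward(net, X)[[length(net$W) + 1]][, 1]
}

# gradient of mean squared error over the batch
mlp_grad <- function(net, A, y) {
  nl <- length(net$W)
  n <- nrow(A[[1]])
  delta <- (A[[nl + 1]] - matrix(y, ncol = 1)) * (2 / n)
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in nl:1) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (A[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' Train the surrogate network of one muscle
#'
#' Trains a 12-64-32-1 ReLU network on standardized features and a
#' standardized force label with Adam, minibatches and early stopping on
#' the validation loss (the weights at the best validation epoch are
#' kept).  Fully deterministic for a fixed seed.
#'
#' @param features numeric matrix of raw features (rows x 12).
#' @param labels numeric vector of raw forces (N) for one muscle.
#' @param split a [split_dataset()] result.
#' @param muscle muscle name (metadata).
#' @param hyper list of hyperparameters: `lr` (1e-3), `batch` (256),
#'   `epochs` (200), `patience` (20), `hidden` (c(64, 32)),
#'   `standardize_anthro` (TRUE: z-score all 12 features; FALSE: only the
#'   9 marker coordinates).
#' @param seed integer seed for initialization and batch shuffling.
#' @return An object of class `surrogate_net` with the weights, the
#'   feature/label normalizers and training metadata.
#' @export
train_muscle_net <- function(features, labels, split, muscle = "",
                             hyper = list(), seed = 1L) {
  hp <- utils::modifyList(list(lr = 1e-3, batch = 256L, epochs = 200L,
                               patience = 20L, hidden = c(64L, 32L),
                               standardize_anthro = TRUE), hyper)
  if (any(!is.finite(labels))) stop("non-finite labels")
  features <- as.matrix(features)
  nz_x <- zscore_fit(features, split$train)
  if (!hp$standardize_anthro) {
    anth <- intersect(colnames(features),
                      c("neck_length", "shoulder_width", "head_mass"))
    nz_x$mu[anth] <- 0; nz_x$sigma[anth] <- 1
  }
  X <- zscore_apply(nz_x, features)
  nz_y <- zscore_fit(matrix(labels, ncol = 1), split$train)
  y <- as.numeric(zscore_apply(nz_y, matrix(labels, ncol = 1)))

  sizes <- c(ncol(X), hp$hidden, 1L)
  net <- mlp_init(sizes, seed)
  nl <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xva <- X[split$val, , drop = FALSE]; yva <- y[split$val]
  ntr <- nrow(Xtr)
  best <- list(loss = Inf, W = net$W, b = net$b, epoch = 0L)
  wait <- 0L; epochs_run <- 0L

  orders <- with_seed(seed + 1L,
    lapply(seq_len(hp$epochs), function(e) sample.int(ntr)))

  for (e in seq_len(hp$epochs)) {
    ord <- orders[[e]]
    for (s in seq(1L, ntr, by = hp$batch)) {
      idx <- ord[s:min(s + hp$batch - 1L, ntr)]
      A <- mlp_forward(net, Xtr[idx, , drop = FALSE])
      g <- mlp_grad(net, A, ytr[idx])
      step <- step + 1L
      corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
      for (l in seq_len(nl)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$W[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$W[[l]]^2
        net$W[[l]] <- net$W[[l]] -
          hp$lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$b[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$b[[l]]^2
        net$b[[l]] <- net$b[[l]] -
          hp$lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    epochs_run <- e
    val_loss <- if (length(yva)) mean((mlp_predict(net, Xva) - yva)^2)
                else mean((mlp_predict(net, Xtr) - ytr)^2)
    if (val_loss < best$loss - 1e-7) {
      best <- list(loss = val_loss, W = net$W, b = net$b, epoch = e)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
  }
  net$W <- best$W; net$b <- best$b
  structure(list(muscle = muscle, net = net,
                 norm_x = nz_x, norm_y = nz_y,
                 hyper = hp, seed = seed,
                 epochs_run = epochs_run, best_epoch = best$epoch,
                 val_loss = best$loss),
            class = "surrogate_net")
}

#' @export
print.surrogate_net <- function(x, ...) {
  cat("Surrogate net [", x$muscle, "]: ",
      paste(x$net$sizes, collapse = "-"),
      sprintf(" | best epoch %d/%d | val loss %.3g\n",
              x$best_epoch, x$epochs_run, x$val_loss), sep = "")
  invisible(x)
}

#' Predict muscle force with a trained surrogate
#'
#' Standardizes the features, runs the network, de-standardizes and clips
#' negative raw outputs to 0 N (muscle forces are tensile).
#'
#' @param object a `surrogate_net`.
#' @param features raw feature matrix in [feature_names()] order.
#' @param ... unused.
#' @return Numeric vector of predicted forces (N).
#' @export
predict.surrogate_net <- function(object, features, ...) {
  X <- zscore_apply(object$norm_x, as.matrix(features))
  raw <- mlp_predict(object$net, X)
  pred <- as.numeric(zscore_invert(object$norm_y, matrix(raw, ncol = 1)))
  pmax(pred, 0)
}

#' Train one surrogate per muscle
#'
#' Per-muscle seeds are `seed + muscle_index`, so the ensemble is
#' reproducible and each muscle's training is independent.  Rows whose
#' solver frame did not converge are dropped before splitting.
#'
#' @param dataset a [build_dataset()] result.
#' @param split optional precomputed [split_dataset()]; by default a row
#'   split with the given seed.
#' @param hyper see [train_muscle_net()].
#' @param seed global seed.
#' @param muscles optional subset of muscle names.
#' @param verbose print progress.
#' @return An object of class `surrogate_ensemble`.
#' @export
train_ensemble <- function(dataset, split = NULL, hyper = list(), seed = 1L,
                           muscles = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "muscle_dataset"))
  keep <- which(dataset$converged)
  if (is.null(split)) split <- split_dataset(nrow(dataset$features),
                                             seed = seed)
  # split indices always refer to full-dataset rows; non-converged frames
  # are excluded from every subset
  eff <- split
  eff$train <- intersect(split$train, keep)
  eff$val <- intersect(split$val, keep)
  eff$test <- intersect(split$test, keep)
  if (is.null(muscles)) muscles <- colnames(dataset$labels)
  nets <- vector("list", length(muscles))
  names(nets) <- muscles
  for (i in seq_along(muscles)) {
    mu <- muscles[i]
    nets[[i]] <- train_muscle_net(dataset$features, dataset$labels[, mu],
                                  eff, muscle = mu,
                                  hyper = hyper, seed = seed + i)
    if (verbose) cat("trained", mu, "(", i, "/", length(muscles), ")\n")
  }
  structure(list(nets = nets, split = eff, seed = seed,
                 muscle_names = muscles),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("Surrogate ensemble:", length(x$nets), "muscle networks",
      "(12-64-32-1), global seed", x$seed, "\n")
  invisible(x)
}

#' Predict the force table for all muscles
#'
#' @param object a `surrogate_ensemble`.
#' @param features raw feature matrix in [feature_names()] order.
#' @param muscles optional subset of muscle names.
#' @param ... unused.
#' @return Matrix rows x muscles of predicted forces (N).
#' @export
predict.surrogate_ensemble <- function(object, features, muscles = NULL, ...) {
  if (is.null(muscles)) muscles <- names(object$nets)
  missing <- setdiff(muscles, names(object$nets))
  if (length(missing))
    stop("no trained net for muscle(s): ", paste(missing, collapse = ", "))
  out <- vapply(muscles, function(mu)
    predict(object$nets[[mu]], features), numeric(nrow(as.matrix(features))))
  matrix(out, ncol = length(muscles),
         dimnames = list(NULL, muscles))
}

#' @rdname predict.surrogate_ensemble
#' @export
predict_forces <- function(object, features, muscles = NULL) {
  predict.surrogate_ensemble(object, features, muscles)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` of predictions against a reference.
#'
#' @param pred,ref equal-length numeric vectors; `ref` must not be
#'   constant.
#' @return Scalar R-squared (<= 1).
#' @export
r2 <- function(pred, ref) {
  if (length(pred) != length(ref) || length(ref) < 2)
    stop("pred and ref must have equal length >= 2")
  sst <- sum((ref - mean(ref))^2)
  if (sst == 0) stop("reference is constant; R^2 undefined")
  1 - sum((pred - ref)^2) / sst
}

#' Range-normalized root-mean-square error
#'
#' RMSE divided by the reference range, comparable across muscles.
#'
#' @inheritParams r2
#' @return Scalar NRMSE (>= 0).
#' @export
nrmse <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch")
  rng <- max(ref) - min(ref)
  if (rng == 0) stop("reference has zero range; NRMSE undefined")
  sqrt(mean((pred - ref)^2)) / rng
}

#' Evaluate an ensemble on the held-out test split
#'
#' @param ensemble a [train_ensemble()] result.
#' @param dataset the dataset it was trained on.
#' @return Data frame with columns `muscle`, `NRMSE`, `R2` (the
#'   per-muscle evaluation-report layout).
#' @export
evaluate_ensemble <- function(ensemble, dataset) {
  feats <- dataset$features
  labs <- dataset$labels
  idx <- intersect(ensemble$split$test, which(dataset$converged))
  pred <- predict(ensemble, feats[idx, , drop = FALSE])
  out <- data.frame(
    muscle = ensemble$muscle_names,
    NRMSE = vapply(ensemble$muscle_names, function(mu)
      nrmse(pred[, mu], labs[idx, mu]), 0),
    R2 = vapply(ensemble$muscle_names, function(mu)
      r2(pred[, mu], labs[idx, mu]), 0),
    row.names = NULL)
  out
}

#' Serialize a trained ensemble to a JSON archive
#'
#' Stores architecture, weights, normalizers and seeds as a single plain
#' JSON document; `read_ensemble` rebuilds an identical ensemble.
#'
#' @param ensemble a `surrogate_ensemble`.
#' @param path file path.
#' @return `read_ensemble` returns the `surrogate_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  doc <- list(
    seed = ensemble$seed,
    muscle_names = ensemble$muscle_names,
    split = ensemble$split[c("train", "val", "test", "seed")],
    nets = lapply(ensemble$nets, function(sn) list(
      muscle = sn$muscle, sizes = sn$net$sizes,
      W = lapply(sn$net$W, function(w) as.vector(w)),
      b = sn$net$b,
      mu_x = sn$norm_x$mu, sigma_x = sn$norm_x$sigma,
      mu_y = sn$norm_y$mu, sigma_y = sn$norm_y$sigma,
      seed = sn$seed, epochs_run = sn$epochs_run,
      best_epoch = sn$best_epoch)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nets <- lapply(doc$nets, function(sn) {
    sizes <- as.integer(sn$sizes)
    W <- lapply(seq_len(length(sizes) - 1), function(l)
      matrix(sn$W[[l]], sizes[l], sizes[l + 1]))
    structure(list(
      muscle = sn$muscle,
      net = list(W = W, b = lapply(sn$b, as.numeric), sizes = sizes),
      norm_x = structure(list(mu = unlist(sn$mu_x),
                              sigma = unlist(sn$sigma_x)),
                         class = "normalizer"),
      norm_y = structure(list(mu = unlist(sn$mu_y),
                              sigma = unlist(sn$sigma_y)),
                         class = "normalizer"),
      seed = sn$seed, epochs_run = sn$epochs_run,
      best_epoch = sn$best_epoch), class = "surrogate_net")
  })
  structure(list(nets = nets,
                 split = doc$split,
                 seed = doc$seed,
                 muscle_names = doc$muscle_names),
            class = "surrogate_ensemble")
}
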