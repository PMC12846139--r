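# End-to-end workflow: sample -> simulate -> train -> evaluate -> assess.

log_stage <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                 paste(..., collapse = " "))
  cat(msg, "\n", sep = "", file = log, append = TRUE)
}

file_checksum <- function(path) {
  as.character(sum(utf8ToInt(paste(readLines(path, warn = FALSE),
                                   collapse = "\n")) *
                     seq_along(utf8ToInt(paste(readLines(path, warn = FALSE),
                                               collapse = "\n")))) %% 2^31)
}

#' Run the full personalized-assessment pipeline
#'
#' Executes the stages of the framework end to end with one seed:
#' samples anthropometric profiles, simulates the standardized motion
#' suite through inverse dynamics and enhanced static optimization,
#' builds the 12-feature dataset, trains the per-muscle surrogates,
#' evaluates them on the held-out split, and assesses a restricted
#' "patient" subject against the simulated envelope database.  Artifacts
#' (population CSV, metrics CSV, trained-ensemble JSON, assessment CSV,
#' stage log) are written under `config$outdir`.
#'
#' @param config a [read_run_config()] list (or a YAML path).
#' @return Invisibly, a list with the in-memory artifacts: `population`,
#'   `dataset`, `ensemble`, `metrics`, `assessment`.
#' @export
run_pipeline <- function(config = read_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$outdir, "pipeline.log")
  cat("", file = log)
  seed <- as.integer(config$seed)
  log_stage(log, "start", "seed =", seed)

  # 1. population
  pop <- sample_population(ansur_population(), config$n_profiles, seed = seed)
  pop_path <- file.path(config$outdir, "population.csv")
  write_population(pop, pop_path)
  log_stage(log, "sample-population", "n =", nrow(pop),
            "checksum =", file_checksum(pop_path))

  # 2. simulate + dataset
  base <- neck_model(muscle_set = config$muscle_set)
  amps <- unlist(config$motion$amplitudes)
  suite <- standard_motion_suite(amplitudes = amps,
                                 cycle_period = config$motion$cycle_period,
                                 fs = config$motion$fs)
  so_cfg <- do.call(so_config, config$so)
  dataset <- build_dataset(pop, suite, base, so_cfg)
  log_stage(log, "build-dataset", "rows =", nrow(dataset$features),
            "non-converged =", sum(!dataset$converged))

  # 3. train + evaluate
  ens <- train_ensemble(dataset, hyper = config$train, seed = seed)
  ens_path <- file.path(config$outdir, "ensemble.json")
  write_ensemble(ens, ens_path)
  metrics <- evaluate_ensemble(ens, dataset)
  met_path <- file.path(config$outdir, "metrics.csv")
  utils::write.csv(metrics, met_path, row.names = FALSE)
  log_stage(log, "train-evaluate", "min R2 =", round(min(metrics$R2), 4),
            "max NRMSE =", round(max(metrics$NRMSE), 4),
            "checksum =", file_checksum(met_path))

  # 4. assess a restricted subject against the simulated envelope library
  res <- config$subject$restriction
  subj_suite <- standard_motion_suite(amplitudes = amps,
                                      cycle_period = config$motion$cycle_period,
                                      fs = config$motion$fs,
                                      restriction = res)
  subj_model <- scale_model(base, profile_from_row(pop, 1L))
  subj_env <- marker_envelopes(subj_model, subj_suite,
                               alpha = config$envelope$alpha)
  db <- lapply(seq_len(nrow(pop)), function(i)
    marker_envelopes(scale_model(base, profile_from_row(pop, i)), suite,
                     alpha = config$envelope$alpha))
  match <- best_match(subj_env, db, resolution = config$envelope$resolution)

  ideal_model <- scale_model(base, profile_from_row(pop, match$best_id))
  feats_of <- function(model, specs, prof) {
    pos <- do.call(rbind, lapply(specs, function(sp)
      marker_trajectory(model,
                        generate_motion(sp, model$articulations))$positions))
    cbind(pos, neck_length = prof$neck_length,
          shoulder_width = prof$shoulder_width, head_mass = prof$head_mass)
  }
  prof1 <- profile_from_row(pop, 1L)
  actual <- predict(ens, feats_of(subj_model, subj_suite, prof1))
  ideal <- predict(ens, feats_of(ideal_model, suite,
                                 profile_from_row(pop, match$best_id)))
  ratios <- force_ratio_map(actual, ideal)
  report <- assessment_report(match, ratios)
  rep_path <- file.path(config$outdir, "assessment.csv")
  write_assessment(report, rep_path)
  log_stage(log, "assess", "best model =", match$best_id,
            "total IoU =", round(match$total_score, 4),
            "checksum =", file_checksum(rep_path))
  log_stage(log, "done")

  invisible(list(population = pop, dataset = dataset, ensemble = ens,
                 metrics = metrics, assessment = report))
}
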