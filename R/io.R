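# Marker-file ingestion (TRC and CSV dialects) and run configuration.

#' Read head-marker trajectories
#'
#' Supports the TRC motion-capture format (tab-separated, millimeter
#' units per the format convention, rate from the `DataRate` header) and
#' a plain CSV dialect (`time` plus `TP_x..RH_z` columns, meters).
#' Marker names are mapped onto TP/LH/RH through the alias table; a
#' missing marker is an explicit error naming the column.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"trc"` or `"csv"`.
#' @param aliases named character vector mapping file marker names to
#'   canonical ids, e.g. `c(HeadTop = "TP")`.
#' @return A `marker_trajectory` (positions in meters, torso frame).
#' @export
read_markers <- function(path, format = c("auto", "trc", "csv"),
                         aliases = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.trc$", path, ignore.case = TRUE)) "trc" else "csv"
  if (format == "trc") read_markers_trc(path, aliases)
  else read_markers_csv(path, aliases)
}

canonical_marker <- function(nm, aliases) {
  if (!is.null(aliases) && nm %in% names(aliases)) unname(aliases[nm]) else nm
}

read_markers_trc <- function(path, aliases = NULL) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("malformed TRC header: file too short")
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  if (!"DataRate" %in% keys) stop("malformed TRC header: no DataRate")
  fs <- as.numeric(vals[match("DataRate", keys)])
  units <- if ("Units" %in% keys) vals[match("Units", keys)] else "mm"
  scale <- switch(units, mm = 1e-3, m = 1, cm = 1e-2,
                  stop("unknown TRC units: ", units))
  hdr <- strsplit(lines[4], "\t")[[1]]
  marker_names <- hdr[-(1:2)]
  marker_names <- marker_names[marker_names != ""]
  marker_names <- vapply(marker_names, canonical_marker, "",
                         aliases = aliases)
  need <- c("TP", "LH", "RH")
  miss <- setdiff(need, marker_names)
  if (length(miss))
    stop("missing marker column(s) in TRC file: ",
         paste(miss, collapse = ", "))
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  dat <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  times <- dat[, 2]
  if (length(times) > 2) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-6)
      stop("non-uniform timestamps in TRC file")
  }
  pos <- matrix(0, nrow(dat), 9)
  for (k in seq_along(marker_names)) {
    cols <- 2 + (k - 1) * 3 + 1:3
    mk <- marker_names[k]
    if (mk %in% need) {
      j <- (match(mk, need) - 1) * 3 + 1:3
      pos[, j] <- dat[, cols] * scale
    }
  }
  colnames(pos) <- as.vector(t(outer(need, c("x", "y", "z"),
                                     paste, sep = "_")))
  structure(list(times = times, positions = pos, fs = fs),
            class = "marker_trajectory")
}

read_markers_csv <- function(path, aliases = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  base <- sub("_(x|y|z)$", "", nm)
  mapped <- vapply(base, canonical_marker, "", aliases = aliases)
  names(df) <- ifelse(grepl("_(x|y|z)$", nm),
                      paste0(mapped, sub("^.*(_[xyz])$", "\\1", nm)), nm)
  need <- as.vector(t(outer(c("TP", "LH", "RH"), c("x", "y", "z"),
                            paste, sep = "_")))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing marker column(s) in CSV file: ",
         paste(miss, collapse = ", "))
  times <- df$time
  if (is.null(times)) stop("marker CSV needs a 'time' column")
  if (length(times) > 2) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-6) stop("non-uniform timestamps")
  }
  pos <- as.matrix(df[, need])
  structure(list(times = times, positions = pos,
                 fs = 1 / (times[2] - times[1])),
            class = "marker_trajectory")
}

#' Write marker trajectories
#'
#' `write_markers_trc` emits a standard TRC file (millimeters);
#' `write_markers_csv` the plain meter-unit CSV dialect.
#'
#' @param mk a `marker_trajectory`.
#' @param path file path.
#' @export
write_markers_trc <- function(mk, path) {
  fs <- mk$fs
  n <- nrow(mk$positions)
  con <- file(path, "w")
  writeLines(c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(fs, fs, n, 3, "mm", fs, 1, n, sep = "\t"),
    paste("Frame#", "Time", "TP", "", "", "LH", "", "", "RH", "", "",
          sep = "\t"),
    paste("", "", "X1", "Y1", "Z1", "X2", "Y2", "Z2", "X3", "Y3", "Z3",
          sep = "\t")), con)
  mmpos <- mk$positions * 1000
  for (i in seq_len(n)) {
    writeLines(paste(c(i, format(mk$times[i], digits = 10),
                       format(mmpos[i, ], digits = 10)), collapse = "\t"),
               con)
  }
  close(con)
  invisible(path)
}

#' @rdname write_markers_trc
#' @export
write_markers_csv <- function(mk, path) {
  df <- data.frame(time = mk$times, mk$positions, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' A single YAML document holding the global seed and the per-stage
#' parameter blocks (population, motions, solver, training, envelope,
#' output), merged over the packaged defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list merged on top (highest priority).
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L,
    n_profiles = 8L,
    muscle_set = "reduced16",
    motion = list(cycle_period = 8, fs = 100,
                  amplitudes = list(flexion = 50 * pi / 180,
                                    lateral = 40 * pi / 180,
                                    rotation = 70 * pi / 180)),
    so = list(),
    train = list(epochs = 60L, patience = 10L),
    envelope = list(resolution = 48L, alpha = "Inf"),
    subject = list(restriction = list(
      sector = c("flexion_pos", "lateral_neg"), factor = 0.6)),
    outdir = "neckforce_run")
  cfg <- defaults
  if (!is.null(path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  cfg <- utils::modifyList(cfg, overrides)
  cfg$envelope$alpha <- if (identical(cfg$envelope$alpha, "Inf")) Inf
                        else as.numeric(cfg$envelope$alpha)
  class(cfg) <- c("run_config", "list")
  cfg
}
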