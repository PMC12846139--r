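# Surface-EMG envelope processing for pattern-level validation.

#' Surface EMG recording
#'
#' @param samples raw signal (mV).
#' @param fs sampling rate (Hz), default 1000.
#' @param channel muscle/channel name.
#' @param mvc maximal-voluntary-contraction reference amplitude (same
#'   units as the envelope; > 0).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs = 1000, channel = "emg", mvc = 1) {
  if (mvc <= 0) stop("MVC must be positive")
  if (fs <= 2 * 450) stop("sampling rate must exceed twice the band edge")
  structure(list(samples = as.numeric(samples), fs = fs,
                 channel = channel, mvc = mvc), class = "emg_recording")
}

#' Linear-envelope processing of a surface EMG channel
#'
#' The standard chain: Butterworth band-pass 20-450 Hz, full-wave
#' rectification, Butterworth low-pass at 10 Hz, MVC normalization, and
#' resampling onto the 100 Hz marker timebase.  Filtering is zero-phase
#' (forward-backward), chosen so the envelope is not phase-lagged when
#' correlated against predicted activations; this doubles the effective
#' filter order.
#'
#' @param rec an [emg_recording()].
#' @param target_fs output rate (Hz), default 100.
#' @return List of class `emg_envelope`: `times`, `envelope` (0-1 scale),
#'   `fs`.
#' @export
process_semg <- function(rec, target_fs = 100) {
  stopifnot(inherits(rec, "emg_recording"))
  x <- rec$samples
  ny <- rec$fs / 2
  if (length(x) < 6 * rec$fs / 20)
    stop("signal too short for filter warm-up")
  bp <- signal::butter(2, c(20, 450) / ny, type = "pass")
  xf <- signal::filtfilt(bp, x)
  xr <- abs(xf)
  lp <- signal::butter(2, 10 / ny, type = "low")
  env <- signal::filtfilt(lp, xr)
  env <- pmax(env, 0) / rec$mvc
  t_in <- (seq_along(x) - 1) / rec$fs
  t_out <- seq(0, t_in[length(t_in)], by = 1 / target_fs)
  out <- stats::approx(t_in, env, xout = t_out)$y
  structure(list(times = t_out, envelope = out, fs = target_fs,
                 channel = rec$channel), class = "emg_envelope")
}

#' Pearson correlation between two pattern series
#'
#' Thin wrapper over the product-moment correlation with explicit guards,
#' used to compare predicted activations against sEMG envelopes.
#'
#' @param a,b equal-length numeric vectors (>= 3 samples, non-constant).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop("need equal lengths >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input; correlation undefined")
  stats::cor(a, b)
}

#' Read / write sEMG channels as CSV
#'
#' Layout: a two-line header (`# fs=<Hz>` and `# mvc=<name>=<value>,...`)
#' followed by `time` plus one column per channel.
#'
#' @param path file path.
#' @param recs named list of [emg_recording()]s (equal lengths, equal fs).
#' @return `read_semg` returns a named list of `emg_recording`s.
#' @export
write_semg <- function(recs, path) {
  fs <- recs[[1]]$fs
  n <- length(recs[[1]]$samples)
  mvc <- paste(vapply(recs, function(r)
    paste0(r$channel, "=", r$mvc), ""), collapse = ",")
  con <- file(path, "w")
  writeLines(c(paste0("# fs=", fs), paste0("# mvc=", mvc)), con)
  df <- data.frame(time = (seq_len(n) - 1) / fs,
                   lapply(recs, `[[`, "samples"), check.names = FALSE)
  names(df) <- c("time", vapply(recs, `[[`, "", "channel"))
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_semg
#' @export
read_semg <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(sub("# fs=", "", hdr[1]))
  mvc_parts <- strsplit(sub("# mvc=", "", hdr[2]), ",")[[1]]
  mvc <- stats::setNames(
    as.numeric(sub(".*=", "", mvc_parts)),
    sub("=.*", "", mvc_parts))
  df <- utils::read.csv(path, skip = 2, check.names = FALSE)
  chans <- setdiff(names(df), "time")
  stats::setNames(lapply(chans, function(ch)
    emg_recording(df[[ch]], fs = fs, channel = ch,
                  mvc = unname(mvc[ch]))), chans)
}
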