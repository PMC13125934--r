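#' RR-interval series container
#'
#' @param peak_times R-peak times in ms, strictly increasing.
#' @param corrected_mask logical, one per interval; `TRUE` where the
#'   interval was replaced during artifact correction.
#' @return An object of class `rri_series` with fields `peak_times` (ms),
#'   `rr_intervals` (ms, successive differences) and `corrected_mask`.
#' @export
rri_series <- function(peak_times,
                       corrected_mask = rep(FALSE, length(peak_times) - 1)) {
  assert_that(length(peak_times) >= 2, "need at least two R-peaks",
              class = "mmempathy_data_error")
  assert_that(all(diff(peak_times) > 0),
              "peak_times must be strictly increasing",
              class = "mmempathy_data_error")
  assert_that(length(corrected_mask) == length(peak_times) - 1,
              "corrected_mask must have one entry per interval")
  structure(
    list(peak_times = as.numeric(peak_times),
         rr_intervals = diff(as.numeric(peak_times)),
         corrected_mask = corrected_mask),
    class = "rri_series")
}

## rebuild an rri_series with explicitly supplied (corrected) intervals;
## peak times are kept, so intervals need not match diffs exactly
rri_series_corrected <- function(peak_times, rr_intervals, corrected_mask) {
  x <- rri_series(peak_times, corrected_mask)
  x$rr_intervals <- rr_intervals
  x
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> %d intervals, mean RR %.1f ms, %d corrected\n",
              length(x$rr_intervals), mean(x$rr_intervals),
              sum(x$corrected_mask)))
  invisible(x)
}

#' Simulate an RR-interval series with controllable autonomic structure
#'
#' The instantaneous RR interval is
#' `RR(t) = mean_rr + lf_amp sin(2 pi 0.10 t) + hf_amp sin(2 pi 0.25 t) +`
#' Gaussian jitter, evaluated at successive beat times (each beat time is
#' the previous one plus the current RR). The two sinusoids place spectral
#' power squarely inside the standard low-frequency (0.04-0.15 Hz) and
#' high-frequency (0.15-0.40 Hz) HRV bands with the closed-form power
#' ratio `lf_amp^2 / hf_amp^2`, giving the frequency-domain estimator an
#' analytic ground truth. In post-stimulation lDLPFC cells the modulation
#' depths and jitter are multiplied by `hrv_effect_ldlpfc`.
#'
#' @param cfg a [sim_config()].
#' @param duration_s recording duration, s (>= 60 to resolve the LF band).
#' @param cell list with elements `group` (`"ldlpfc"`, `"rtpj"`, `"sham"`)
#'   and `time` (`"pre"`, `"post"`); decides whether the post-stimulation
#'   boost applies.
#' @param stream label mixed into the child seed so that different design
#'   cells draw independent series.
#' @return A list with `rri` (an [rri_series()]) and `truth` (the realised
#'   modulation depths and jitter SD).
#' @export
simulate_rri <- function(cfg, duration_s = 120,
                         cell = list(group = "sham", time = "pre"),
                         stream = paste("rri", cell$group, cell$time,
                                        sep = "_")) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_that(duration_s >= 60, "duration_s must be >= 60 s",
              class = "mmempathy_config_error")
  boost <- if (identical(cell$group, "ldlpfc") &&
                 identical(cell$time, "post")) cfg$hrv_effect_ldlpfc else 1
  lf <- cfg$lf_amp * boost
  hf <- cfg$hf_amp * boost
  jitter <- cfg$rr_noise_sd * boost

  with_seed(child_seed(cfg$seed, stream), {
    t_ms <- 0
    times <- numeric(ceiling(duration_s * 1000 / max(cfg$mean_rr - lf - hf,
                                                     250)) + 2)
    times[1] <- 0
    n <- 1L
    while (t_ms <= duration_s * 1000) {
      t_s <- t_ms / 1000
      rr <- cfg$mean_rr + lf * sin(2 * pi * 0.10 * t_s) +
        hf * sin(2 * pi * 0.25 * t_s) +
        (if (jitter > 0) rnorm(1, sd = jitter) else 0)
      if (rr <= 250) {
        stop_mm("generated RR interval <= 250 ms (non-physiological); ",
                "reduce modulation depths or jitter",
                class = "mmempathy_generation_error")
      }
      t_ms <- t_ms + rr
      n <- n + 1L
      times[n] <- t_ms
    }
    list(
      rri = rri_series(times[seq_len(n)]),
      truth = list(lf_amp = lf, hf_amp = hf, jitter_sd = jitter,
                   mean_rr = cfg$mean_rr)
    )
  })
}

#' ECG trace container
#'
#' @param samples amplitude in mV.
#' @param fs sampling rate, Hz (>= 100 to resolve the QRS complex).
#' @return An object of class `ecg_trace` with `samples`, `fs`, `duration`.
#' @export
ecg_trace <- function(samples, fs) {
  assert_that(fs >= 100, "ecg_trace requires fs >= 100 Hz",
              class = "mmempathy_config_error")
  assert_that(all(is.finite(samples)), "ECG samples must be finite",
              class = "mmempathy_data_error")
  structure(
    list(samples = as.numeric(samples), fs = fs,
         duration = length(samples) / fs),
    class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %.1f s @ %g Hz (%d samples)\n",
              x$duration, x$fs, length(x$samples)))
  invisible(x)
}

## fixed P-QRS-T template as a sum of Gaussians; time in s relative to the
## R-wave apex, amplitude in mV (R amplitude 1 mV)
ecg_beat_template <- function(dt) {
  g <- function(a, mu, sigma) a * exp(-(dt - mu)^2 / (2 * sigma^2))
  g(0.12, -0.20, 0.030) +    # P
    g(-0.12, -0.028, 0.010) + # Q
    g(1.00, 0.00, 0.012) +    # R
    g(-0.18, 0.030, 0.011) +  # S
    g(0.35, 0.28, 0.060)      # T
}

#' Synthesise a continuous ECG trace from an RR series
#'
#' Places a fixed P-QRS-T template (sum of Gaussians, R amplitude 1 mV) at
#' each beat time, then adds white measurement noise and a slow
#' baseline-wander sinusoid. A 0.5-s lead-in keeps the first complex
#' fully inside the trace; the returned ground truth carries the template
#' peak times on the trace's clock, so downstream peak detection can be
#' scored exactly.
#'
#' @param rri an [rri_series()] (beat times in ms).
#' @param cfg a [sim_config()]; uses `ecg_fs`, `ecg_noise_sd` (fraction of
#'   the R amplitude), `ecg_wander_amp` (mV) and `ecg_wander_hz`.
#' @param stream seed-stream label.
#' @return A list with `trace` (an [ecg_trace()]) and `truth` (ground-truth
#'   R-peak times in ms).
#' @export
simulate_ecg_waveform <- function(rri, cfg, stream = "ecg_waveform") {
  stopifnot(inherits(rri, "rri_series"), inherits(cfg, "sim_config"))
  fs <- cfg$ecg_fs
  assert_that(fs >= 100, "ecg_fs must be >= 100 Hz to resolve the QRS",
              class = "mmempathy_config_error")
  beat_s <- rri$peak_times / 1000 + 0.5
  dur <- max(beat_s) + 0.5
  n <- as.integer(ceiling(dur * fs))
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  half_w <- 0.45                       # template support, s
  for (b in beat_s) {
    i0 <- max(1L, as.integer(floor((b - half_w) * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling((b + half_w) * fs)) + 1L)
    idx <- i0:i1
    x[idx] <- x[idx] + ecg_beat_template(t[idx] - b)
  }
  with_seed(child_seed(cfg$seed, stream), {
    if (cfg$ecg_noise_sd > 0) x <- x + rnorm(n, sd = cfg$ecg_noise_sd)
  })
  if (cfg$ecg_wander_amp > 0) {
    x <- x + cfg$ecg_wander_amp * sin(2 * pi * cfg$ecg_wander_hz * t)
  }
  list(trace = ecg_trace(x, fs),
       truth = list(r_peak_times = beat_s * 1000))
}

#' Write / read a trace or RR series as two-column CSV
#'
#' Traces are written as `(time_s, value)`; RR series as
#' `(peak_time_ms, rr_ms, corrected)`.
#'
#' @param trace an [ecg_trace()].
#' @param rri an [rri_series()].
#' @param path file path.
#' @param fs sampling rate when reading a trace.
#' @return The written path (invisibly) or the reconstructed object.
#' @export
write_ecg <- function(trace, path) {
  stopifnot(inherits(trace, "ecg_trace"))
  t <- (seq_along(trace$samples) - 1) / trace$fs
  write.csv(data.frame(time_s = t, value = trace$samples), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg
#' @export
read_ecg <- function(path, fs = NULL) {
  d <- read.csv(path)
  if (is.null(fs)) fs <- 1 / median(diff(d$time_s))
  ecg_trace(d$value, fs = fs)
}

#' @rdname write_ecg
#' @export
write_rri <- function(rri, path) {
  stopifnot(inherits(rri, "rri_series"))
  write.csv(data.frame(
    peak_time_ms = rri$peak_times[-1],
    rr_ms = rri$rr_intervals,
    corrected = rri$corrected_mask
  ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg
#' @export
read_rri <- function(path) {
  d <- read.csv(path)
  peaks <- c(d$peak_time_ms[1] - d$rr_ms[1], d$peak_time_ms)
  rri_series_corrected(peaks, d$rr_ms, as.logical(d$corrected))
}
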