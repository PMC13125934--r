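#' Extreme-point R-peak detection with an adaptive threshold
#'
#' Identifies R-peaks as local maxima exceeding an adaptive amplitude
#' threshold: `threshold_fraction` times a near-maximal quantile
#' (`amplitude_quantile`, default 0.999) of the trace in a 2-s window
#' centered on each candidate, measured above the local median so slow
#' baseline wander cancels. A refractory period is enforced by keeping
#' the larger of two candidates closer together than `refractory_ms`;
#' peak times are the samples of the local maxima.
#'
#' @param trace an [ecg_trace()], duration >= 5 s.
#' @param refractory_ms refractory period, ms.
#' @param threshold_fraction fraction of the rolling amplitude quantile a
#'   candidate must exceed.
#' @param amplitude_quantile quantile of the 2-s window defining the
#'   local amplitude reference.
#' @return An [rri_series()] of detected peaks.
#' @export
detect_r_peaks <- function(trace, refractory_ms = 250,
                           threshold_fraction = 0.5,
                           amplitude_quantile = 0.999) {
  stopifnot(inherits(trace, "ecg_trace"))
  assert_that(trace$duration >= 5, "trace must span >= 5 s",
              class = "mmempathy_data_error")
  x <- trace$samples
  n <- length(x)
  fs <- trace$fs
  ## candidate local maxima well above the global floor (cheap pre-filter;
  ## the per-candidate adaptive threshold below is strictly stricter)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  glob_med <- median(x)
  glob_ref <- quantile(x, amplitude_quantile, names = FALSE)
  cand <- cand[x[cand] > glob_med + 0.25 * (glob_ref - glob_med)]
  if (length(cand) == 0) {
    stop_mm("no R-peak candidates found", class = "mmempathy_signal_error")
  }
  ## adaptive threshold per candidate from its 2-s neighbourhood
  half_win <- as.integer(fs)                 # 1 s each side
  win_stat <- vapply(cand, function(i) {
    lo <- max(1L, i - half_win)
    hi <- min(n, i + half_win)
    w <- x[lo:hi]
    c(quantile(w, amplitude_quantile, names = FALSE), median(w))
  }, numeric(2))
  keep <- x[cand] - win_stat[2, ] >=
    threshold_fraction * (win_stat[1, ] - win_stat[2, ])
  cand <- cand[keep]
  if (length(cand) < 2) {
    stop_mm("fewer than two peaks above threshold",
            class = "mmempathy_signal_error")
  }
  ## refractory rule: sweep in time, keep the larger of conflicting peaks
  refr <- refractory_ms / 1000 * fs
  kept <- cand[1]
  for (i in cand[-1]) {
    last <- kept[length(kept)]
    if (i - last < refr) {
      if (x[i] > x[last]) kept[length(kept)] <- i
    } else {
      kept <- c(kept, i)
    }
  }
  if (length(kept) < 2) {
    stop_mm("fewer than two peaks after refractory pruning",
            class = "mmempathy_signal_error")
  }
  rri_series((kept - 1) / fs * 1000)
}

#' Automatic RR-interval correction by a rolling-median rule
#'
#' Replaces physiologically implausible intervals - those deviating from
#' the 11-beat rolling median by more than `tolerance_fraction` - with a
#' cubic-spline interpolation through the surrounding plausible intervals,
#' and flags them in `corrected_mask`. If more than 20% of intervals
#' require correction, the series is rejected as unusable.
#'
#' @param rri an [rri_series()] with >= 5 intervals.
#' @param tolerance_fraction allowed relative deviation from the rolling
#'   median (default 0.3).
#' @return The corrected [rri_series()]; `rr_intervals` holds the
#'   corrected values, `peak_times` the original detections.
#' @export
correct_rri <- function(rri, tolerance_fraction = 0.3) {
  stopifnot(inherits(rri, "rri_series"))
  rr <- rri$rr_intervals
  assert_that(length(rr) >= 5, "need >= 5 intervals",
              class = "mmempathy_data_error")
  k <- min(11L, length(rr) - (1 - length(rr) %% 2))  # odd, <= n
  med <- runmed(rr, k = k, endrule = "median")
  bad <- abs(rr - med) > tolerance_fraction * med
  if (mean(bad) > 0.2) {
    stop_mm(sprintf(
      "%.0f%% of intervals flagged (> 20%%): series rejected",
      100 * mean(bad)), class = "mmempathy_quality_error")
  }
  if (any(bad)) {
    good <- which(!bad)
    rr[bad] <- spline(good, rr[good], xout = which(bad),
                      method = "natural")$y
  }
  rri_series_corrected(rri$peak_times, rr, bad)
}
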