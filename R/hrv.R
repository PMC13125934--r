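#' Time-domain HRV indices
#'
#' Computes HR (mean heart rate, beats/min), SDNN (population SD of RR
#' intervals, ms), RMSSD (root mean square of successive RR differences,
#' ms) and pNN50 (percentage of successive differences exceeding 50 ms).
#' Dispersion uses the population (divide-by-n) convention throughout the
#' package, which makes the Poincare identity `SD1 = RMSSD / sqrt(2)`
#' exact.
#'
#' @param rri an [rri_series()] with >= 2 intervals.
#' @return A named list: `hr`, `sdnn`, `rmssd`, `pnn50`.
#' @export
hrv_time_domain <- function(rri) {
  stopifnot(inherits(rri, "rri_series"))
  rr <- rri$rr_intervals
  assert_that(length(rr) >= 2, "need >= 2 intervals",
              class = "mmempathy_data_error")
  d <- diff(rr)
  list(
    hr = 60000 / mean(rr),
    sdnn = sd_pop(rr),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50)
  )
}

## Welch power spectral density: Hann-windowed overlapping segments,
## per-segment periodograms normalised to power per Hz, averaged.
welch_psd <- function(x, fs, segment_s = 120, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, as.integer(round(segment_s * fs)))
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  u <- sum(w^2)
  acc <- numeric(floor(nseg / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (u * fs)
    half <- seq_len(floor(nseg / 2) + 1)
    p <- p[half]
    ## one-sided: double all bins except DC (and Nyquist for even nseg)
    dbl <- rep(2, length(half)); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[length(half)] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(floor(nseg / 2) + 1) - 1) * fs / nseg,
       psd = acc / length(starts))
}

#' Frequency-domain HRV indices
#'
#' Resamples the RR tachogram (RR interval versus beat time) onto an even
#' grid by cubic-spline interpolation (default 4 Hz), removes mean and
#' linear trend, estimates the power spectral density with Welch-averaged
#' Hann-windowed FFT periodograms (120-s segments, 50% overlap; shorter
#' series fall back to a single full-length segment), and integrates band
#' powers over the low-frequency (0.04-0.15 Hz) and high-frequency
#' (0.15-0.40 Hz) bands.
#'
#' @param rri an [rri_series()] spanning >= 60 s (to resolve 0.04 Hz).
#' @param resample_hz even resampling rate for the tachogram, Hz.
#' @param segment_s Welch segment length, s.
#' @return A named list: `lf_power`, `hf_power` (ms^2) and `lf_hf`
#'   (`NA` when HF power is zero, never infinity).
#' @export
hrv_frequency_domain <- function(rri, resample_hz = 4, segment_s = 120) {
  stopifnot(inherits(rri, "rri_series"))
  t_beat <- rri$peak_times[-1] / 1000          # s, interval end times
  span <- t_beat[length(t_beat)] - t_beat[1]
  assert_that(span >= 60,
              "series must span >= 60 s to resolve the LF band",
              class = "mmempathy_data_error")
  grid <- seq(t_beat[1], t_beat[length(t_beat)], by = 1 / resample_hz)
  rr_even <- spline(t_beat, rri$rr_intervals, xout = grid,
                    method = "natural")$y
  ## detrend: remove mean and linear trend
  fit <- lm.fit(cbind(1, grid), rr_even)
  rr_even <- rr_even - cbind(1, grid) %*% fit$coefficients
  ps <- welch_psd(as.numeric(rr_even), fs = resample_hz,
                  segment_s = segment_s)
  band_power <- function(lo, hi) {
    idx <- ps$freq >= lo & ps$freq < hi
    df <- ps$freq[2] - ps$freq[1]
    sum(ps$psd[idx]) * df
  }
  lf <- band_power(0.04, 0.15)
  hf <- band_power(0.15, 0.40)
  ## HF power at numerical zero: the ratio is undefined, not infinite
  list(lf_power = lf, hf_power = hf,
       lf_hf = if (hf > 1e-12) lf / hf else NA_real_)
}

#' Sample entropy of a series
#'
#' `SampEn(m, r) = -log(A / B)` where `B` counts template pairs matching
#' within tolerance `r` (Chebyshev distance) for `m` consecutive points
#' and `A` those still matching for `m + 1`; self-matches are excluded.
#'
#' @param x numeric series.
#' @param m template length.
#' @param r tolerance (absolute units).
#' @return SampEn, or `NA` (with attribute `reason`) when no template
#'   pair matches at length `m`.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd_pop(x)) {
  n <- length(x)
  assert_that(n >= m + 2, "series too short for sample entropy",
              class = "mmempathy_data_error")
  ## both template lengths use the same n - m templates (standard SampEn)
  count_matches <- function(len) {
    nt <- n - m
    templ <- t(vapply(seq_len(nt), function(i) x[i:(i + len - 1)],
                      numeric(len)))
    cnt <- 0
    for (i in seq_len(nt - 1)) {
      d <- abs(templ[(i + 1):nt, , drop = FALSE] -
                 matrix(templ[i, ], nt - i, len, byrow = TRUE))
      cnt <- cnt + sum(apply(d, 1, max) <= r)
    }
    cnt
  }
  b <- count_matches(m)
  a <- count_matches(m + 1)
  if (b == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no template matches at length m"
    return(out)
  }
  if (a == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no template matches at length m + 1"
    return(out)
  }
  -log(a / b)
}

#' Nonlinear HRV indices
#'
#' Sample entropy (`m = 2`, `r = r_fraction` times the population SD of
#' the intervals) and the Poincare plot axes: `SD1` (dispersion
#' perpendicular to the identity line) and `SD2` (dispersion along it),
#' computed as `SD1 = sqrt(mean(d^2) / 2)` with `d` the successive RR
#' differences (their mean is taken as zero, the convention that makes
#' `SD1 = RMSSD / sqrt(2)` an exact identity) and
#' `SD2 = sqrt(2 Var(rr) - mean(d^2) / 2)` with population variance.
#' A negative `SD2^2` arising from numerical error is clamped to zero
#' with a warning.
#'
#' @param rri an [rri_series()]; >= 2 intervals for Poincare, >= 50
#'   recommended for a stable sample entropy.
#' @param m sample-entropy template length.
#' @param r_fraction sample-entropy tolerance as a fraction of the SD.
#' @return A named list: `sampen`, `sd1`, `sd2`, `sd1_sd2`.
#' @export
hrv_nonlinear <- function(rri, m = 2, r_fraction = 0.2) {
  stopifnot(inherits(rri, "rri_series"))
  rr <- rri$rr_intervals
  assert_that(length(rr) >= 2, "need >= 2 intervals",
              class = "mmempathy_data_error")
  d <- diff(rr)
  msd <- mean(d^2)
  sd1 <- sqrt(msd / 2)
  sd2sq <- 2 * var_pop(rr) - msd / 2
  if (sd2sq < 0) {
    warning("negative SD2^2 from numerical error; clamped to 0")
    sd2sq <- 0
  }
  sd2 <- sqrt(sd2sq)
  sampen <- if (length(rr) >= m + 2) {
    r_tol <- r_fraction * sd_pop(rr)
    se <- sample_entropy(rr, m = m, r = r_tol)
    ## constant series: every template matches (A = B) => entropy 0
    se
  } else {
    NA_real_
  }
  list(sampen = sampen, sd1 = sd1, sd2 = sd2,
       sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

#' Full HRV profile for one RR series
#'
#' Composes the time-, frequency- and nonlinear-domain indices into one
#' record. Indices whose preconditions fail (e.g. a series too short for
#' the frequency bands) are reported as `NA` with the failure reason in
#' attribute `missing`, never silently zero-filled.
#'
#' @param rri an [rri_series()].
#' @param resample_hz tachogram resampling rate for the spectral indices.
#' @param segment_s Welch segment length, s.
#' @param m,r_fraction sample-entropy settings.
#' @return A one-row `data.frame` with columns `hr`, `sdnn`, `rmssd`,
#'   `pnn50`, `lf_power`, `hf_power`, `lf_hf`, `sampen`, `sd1`, `sd2`,
#'   `sd1_sd2`.
#' @export
hrv_profile <- function(rri, resample_hz = 4, segment_s = 120, m = 2,
                        r_fraction = 0.2) {
  td <- hrv_time_domain(rri)
  missing <- character(0)
  fd <- tryCatch(
    hrv_frequency_domain(rri, resample_hz = resample_hz,
                         segment_s = segment_s),
    error = function(e) {
      missing <<- c(missing, paste0("frequency: ", conditionMessage(e)))
      list(lf_power = NA_real_, hf_power = NA_real_, lf_hf = NA_real_)
    })
  nl <- tryCatch(
    hrv_nonlinear(rri, m = m, r_fraction = r_fraction),
    error = function(e) {
      missing <<- c(missing, paste0("nonlinear: ", conditionMessage(e)))
      list(sampen = NA_real_, sd1 = NA_real_, sd2 = NA_real_,
           sd1_sd2 = NA_real_)
    })
  out <- data.frame(
    hr = td$hr, sdnn = td$sdnn, rmssd = td$rmssd, pnn50 = td$pnn50,
    lf_power = fd$lf_power, hf_power = fd$hf_power, lf_hf = fd$lf_hf,
    sampen = as.numeric(nl$sampen), sd1 = nl$sd1, sd2 = nl$sd2,
    sd1_sd2 = nl$sd1_sd2
  )
  if (length(missing)) attr(out, "missing") <- missing
  out
}
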