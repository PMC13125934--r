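## --- Empirical mode decomposition -------------------------------------
## Sifting with cubic-spline envelopes through the local maxima/minima
## (endpoints appended to both knot sets, the usual simple boundary
## treatment), the Cauchy-type SD stopping criterion, and a sift cap.

local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  ## collapse exact plateaus so a flat top counts once
  s <- sign(d)
  nz <- which(s != 0)
  maxima <- integer(0); minima <- integer(0)
  if (length(nz) >= 2) {
    for (j in seq_len(length(nz) - 1)) {
      i1 <- nz[j]; i2 <- nz[j + 1]
      if (s[i1] > 0 && s[i2] < 0) maxima <- c(maxima, i2)
      if (s[i1] < 0 && s[i2] > 0) minima <- c(minima, i2)
    }
  }
  list(max = maxima, min = minima)
}

## envelopes use mirror-extended extrema at both ends, which suppresses
## the boundary swings that drive mode mixing
envelope_mean <- function(x) {
  n <- length(x)
  ex <- local_extrema(x)
  if (length(ex$max) < 2 || length(ex$min) < 2) return(NULL)
  mirror <- function(idx) {
    k <- as.numeric(idx)
    c(2 - k[min(2, length(k))], k, 2 * n - k[max(1, length(k) - 1)])
  }
  kmax <- mirror(ex$max)
  kmin <- mirror(ex$min)
  vmax <- x[ex$max][c(min(2, length(ex$max)), seq_along(ex$max),
                      max(1, length(ex$max) - 1))]
  vmin <- x[ex$min][c(min(2, length(ex$min)), seq_along(ex$min),
                      max(1, length(ex$min) - 1))]
  upper <- spline(kmax, vmax, xout = seq_len(n), method = "natural")$y
  lower <- spline(kmin, vmin, xout = seq_len(n), method = "natural")$y
  (upper + lower) / 2
}

sift_imf <- function(x, sd_stop = 0.2, max_sift = 10) {
  h <- x
  for (i in seq_len(max_sift)) {
    m <- envelope_mean(h)
    if (is.null(m)) return(if (i == 1) NULL else h)
    h_new <- h - m
    sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (sd_crit < sd_stop) break
  }
  h
}

#' Empirical mode decomposition (single realisation)
#'
#' Extracts intrinsic mode functions (IMFs) by iterative sifting: cubic
#' spline envelopes through the local maxima and minima, subtraction of
#' the mean envelope, stopping a mode when the normalised squared change
#' between sifts falls below `sd_stop` (or after `max_sift` sifts), and
#' stopping the decomposition when the residue has too few extrema to
#' sift (e.g. is monotone).
#'
#' @param x numeric signal.
#' @param max_imfs maximum number of IMFs to extract.
#' @param sd_stop sift stopping threshold (Cauchy-type SD criterion).
#' @param max_sift maximum sifts per mode.
#' @return A list with `imfs` (list of numeric vectors, possibly empty)
#'   and `residue`.
#' @export
emd <- function(x, max_imfs = 12, sd_stop = 0.2, max_sift = 10) {
  assert_that(all(is.finite(x)), "input must be finite",
              class = "mmempathy_validation_error")
  imfs <- list()
  r <- x
  while (length(imfs) < max_imfs) {
    imf <- sift_imf(r, sd_stop = sd_stop, max_sift = max_sift)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1]] <- imf
    r <- r - imf
  }
  list(imfs = imfs, residue = r)
}

#' Ensemble empirical mode decomposition (EEMD)
#'
#' Runs [emd()] on `ensemble_size` noise-perturbed copies of the signal
#' (white noise with SD `noise_sd_fraction` times the signal SD added to
#' each copy) and averages the IMFs rank-wise across the ensemble, which
#' stabilises mode mixing for non-stationary physiological signals.
#' Members yielding fewer modes contribute zeros at the missing ranks.
#' The averaged residue completes the reconstruction; for
#' `noise_sd_fraction = 0` the reconstruction `sum(imfs) + residue` is
#' exact, and for positive noise its error shrinks as the ensemble grows
#' (the added noise averages out at rate `1/sqrt(ensemble_size)`).
#'
#' @param x numeric signal, length >= 64.
#' @param ensemble_size number of noise-perturbed members (>= 1).
#' @param noise_sd_fraction added-noise SD as a fraction of `sd(x)`.
#' @param max_imfs,sd_stop,max_sift passed to [emd()].
#' @param seed seed for the ensemble noise.
#' @return An object of class `imf_decomposition`: `imfs` (list),
#'   `residue`, `ensemble_size`, `noise_sd_fraction`.
#' @export
eemd <- function(x, ensemble_size = 100, noise_sd_fraction = 0.2,
                 max_imfs = 12, sd_stop = 0.2, max_sift = 10, seed = 1) {
  assert_that(all(is.finite(x)), "input must be finite",
              class = "mmempathy_validation_error")
  assert_that(length(x) >= 64, "signal must have >= 64 samples",
              class = "mmempathy_validation_error")
  assert_that(ensemble_size >= 1 && noise_sd_fraction >= 0,
              "ensemble_size >= 1 and noise_sd_fraction >= 0 required",
              class = "mmempathy_validation_error")
  sdx <- sd(x)
  runs <- with_seed(seed, {
    lapply(seq_len(ensemble_size), function(i) {
      xi <- if (noise_sd_fraction > 0 && sdx > 0) {
        x + rnorm(length(x), sd = noise_sd_fraction * sdx)
      } else {
        x
      }
      emd(xi, max_imfs = max_imfs, sd_stop = sd_stop, max_sift = max_sift)
    })
  })
  n_modes <- max(vapply(runs, function(r) length(r$imfs), 0L))
  imfs <- lapply(seq_len(n_modes), function(k) {
    acc <- numeric(length(x))
    for (r in runs) {
      if (length(r$imfs) >= k) acc <- acc + r$imfs[[k]]
    }
    acc / ensemble_size
  })
  residue <- Reduce(`+`, lapply(runs, `[[`, "residue")) / ensemble_size
  structure(
    list(imfs = imfs, residue = residue, ensemble_size = ensemble_size,
         noise_sd_fraction = noise_sd_fraction),
    class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMFs, ensemble %d, noise %.2f\n",
              length(x$imfs), x$ensemble_size, x$noise_sd_fraction))
  invisible(x)
}

#' Power-spectral centroid of a signal
#'
#' Mean frequency weighted by periodogram power; used to classify IMFs as
#' high-frequency noise or slow baseline wander.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @return Centroid frequency in Hz (`NA` for an all-zero signal).
#' @export
spectral_centroid <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  half <- seq_len(floor(n / 2))
  f <- (half - 1) * fs / n
  pw <- p[half]
  if (sum(pw) == 0) return(NA_real_)
  sum(f * pw) / sum(pw)
}

#' Reconstruct a denoised ECG from its EEMD modes
#'
#' Rebuilds the trace omitting (a) leading high-frequency IMFs whose
#' spectral centroid exceeds `hf_cutoff` (measurement noise) and (b) the
#' residue together with trailing IMFs whose centroid falls below
#' `lf_cutoff` (baseline wander). If the selection would remove every
#' component, the original trace is returned with a warning.
#'
#' @param trace an [ecg_trace()].
#' @param decomposition an [eemd()] decomposition of that trace.
#' @param hf_cutoff noise cutoff, Hz.
#' @param lf_cutoff wander cutoff, Hz.
#' @return A denoised [ecg_trace()].
#' @export
denoise_ecg <- function(trace, decomposition, hf_cutoff = 45,
                        lf_cutoff = 0.5) {
  stopifnot(inherits(trace, "ecg_trace"),
            inherits(decomposition, "imf_decomposition"))
  imfs <- decomposition$imfs
  assert_that(length(imfs) == 0 ||
                length(imfs[[1]]) == length(trace$samples),
              "decomposition length does not match trace",
              class = "mmempathy_validation_error")
  cent <- vapply(imfs, spectral_centroid, 0, fs = trace$fs)
  keep <- rep(TRUE, length(imfs))
  ## leading noise modes: contiguous high-centroid run from the top
  for (k in seq_along(imfs)) {
    if (!is.na(cent[k]) && cent[k] > hf_cutoff) keep[k] <- FALSE else break
  }
  ## trailing wander modes: contiguous low-centroid run from the bottom
  for (k in rev(seq_along(imfs))) {
    if (is.na(cent[k]) || cent[k] < lf_cutoff) keep[k] <- FALSE else break
  }
  if (!any(keep)) {
    warning("IMF selection removed every component; returning original trace")
    return(trace)
  }
  x <- Reduce(`+`, imfs[keep])
  ecg_trace(x, fs = trace$fs)
}
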