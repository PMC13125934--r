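test_that("a monotone signal yields no IMFs, only the residue", {
  ramp <- seq(0, 1, length.out = 128)
  d <- emd(ramp)
  expect_length(d$imfs, 0)
  expect_equal(d$residue, ramp)
})

test_that("plain EMD separates a two-tone signal into its components", {
  t <- seq(0, 4, length.out = 1024)
  fast <- sin(2 * pi * 20 * t)
  slow <- sin(2 * pi * 2 * t)
  d <- eemd(fast + slow, ensemble_size = 1, noise_sd_fraction = 0)
  expect_gte(length(d$imfs), 2)
  expect_gt(cor(d$imfs[[1]], fast), 0.95)
  expect_gt(cor(d$imfs[[2]], slow), 0.95)

  ## IMF property: extrema and zero-crossing counts differ by at most one
  ## (allowing boundary slack of one extra crossing pair)
  imf <- d$imfs[[1]]
  n_zc <- sum(diff(sign(imf)) != 0)
  ex <- sum(diff(sign(diff(imf))) != 0)
  expect_lte(abs(ex - n_zc), 2)
})

test_that("reconstruction is exact without noise and improves with ensemble", {
  set.seed(5)
  t <- seq(0, 2, length.out = 512)
  x <- sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 15 * t) + 0.2 * t
  rel_err <- function(d) {
    rec <- Reduce(`+`, c(d$imfs, list(d$residue)))
    sqrt(sum((x - rec)^2) / sum(x^2))
  }
  expect_lt(rel_err(eemd(x, ensemble_size = 1, noise_sd_fraction = 0)),
            1e-10)
  e10 <- rel_err(eemd(x, ensemble_size = 10, noise_sd_fraction = 0.2,
                      seed = 9))
  e100 <- rel_err(eemd(x, ensemble_size = 100, noise_sd_fraction = 0.2,
                       seed = 9))
  expect_lt(e100, e10)
})

test_that("EEMD denoising removes baseline wander and spares the ECG", {
  cfg <- sim_config("study2", ecg_noise_sd = 0, ecg_wander_amp = 0,
                    seed = 7)
  s <- simulate_rri(cfg, duration_s = 60)
  clean <- simulate_ecg_waveform(s$rri, cfg)$trace
  seg <- ecg_trace(clean$samples[1:16384], clean$fs)

  ## clean trace: nothing to remove
  dec <- eemd(seg$samples, ensemble_size = 1, noise_sd_fraction = 0)
  den <- denoise_ecg(seg, dec)
  expect_gt(cor(den$samples, seg$samples), 0.99)

  ## added 0.3 Hz wander is strongly attenuated
  tt <- (seq_along(seg$samples) - 1) / seg$fs
  wander <- 0.3 * sin(2 * pi * 0.3 * tt)
  noisy <- ecg_trace(seg$samples + wander, seg$fs)
  dec2 <- eemd(noisy$samples, ensemble_size = 1, noise_sd_fraction = 0)
  den2 <- denoise_ecg(noisy, dec2)
  amp_03 <- function(v) {
    Mod(sum((v - mean(v)) * exp(-2i * pi * 0.3 * tt))) * 2 / length(v)
  }
  expect_lt(amp_03(den2$samples), 0.2 * amp_03(noisy$samples))

  ## broadband noise: denoising never hurts R-peak recovery
  set.seed(31)
  long <- ecg_trace(clean$samples + rnorm(length(clean$samples), sd = 0.08),
                    clean$fs)
  dec3 <- eemd(long$samples, ensemble_size = 1, noise_sd_fraction = 0,
               max_imfs = 6)
  den3 <- denoise_ecg(long, dec3)
  truth <- simulate_ecg_waveform(s$rri, cfg)$truth$r_peak_times
  raw_sens <- score_peaks(detect_r_peaks(long)$peak_times, truth)["sensitivity"]
  den_sens <- score_peaks(detect_r_peaks(den3)$peak_times,
                          truth)["sensitivity"]
  expect_gte(den_sens, raw_sens - 1e-9)
})

test_that("EEMD is deterministic under a fixed seed and validates input", {
  x <- sin(seq(0, 10, length.out = 256))
  d1 <- eemd(x, ensemble_size = 5, noise_sd_fraction = 0.1, seed = 3)
  d2 <- eemd(x, ensemble_size = 5, noise_sd_fraction = 0.1, seed = 3)
  expect_identical(d1$imfs, d2$imfs)
  expect_error(eemd(c(x, NA)), class = "mmempathy_validation_error")
  expect_error(eemd(x[1:32]), class = "mmempathy_validation_error")
})
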