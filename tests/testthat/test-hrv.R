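rri_from_rr <- function(rr) rri_series(cumsum(c(0, rr)))

test_that("time-domain indices match hand computation", {
  rri <- rri_from_rr(c(800, 810, 790, 805))
  td <- hrv_time_domain(rri)
  expect_equal(td$rmssd, sqrt((10^2 + 20^2 + 15^2) / 3), tolerance = 1e-10)
  expect_equal(td$hr, 60000 / mean(c(800, 810, 790, 805)))

  const <- hrv_time_domain(rri_from_rr(rep(800, 10)))
  expect_equal(const$hr, 75)
  expect_equal(const$sdnn, 0)
  expect_equal(const$rmssd, 0)
  expect_equal(const$pnn50, 0)

  expect_equal(hrv_time_domain(rri_from_rr(c(700, 800)))$pnn50, 100)
})

test_that("Poincare indices satisfy the exact RMSSD identity", {
  ## alternating series, by hand: d = +/-100, mean(d^2) = 10000,
  ## sd1 = sqrt(5000); rmssd = 100
  alt <- rri_from_rr(rep(c(800, 900), 10))
  nl <- hrv_nonlinear(alt)
  td <- hrv_time_domain(alt)
  expect_equal(nl$sd1, sqrt(5000), tolerance = 1e-10)
  expect_equal(nl$sd1, td$rmssd / sqrt(2), tolerance = 1e-12)

  set.seed(8)
  for (i in 1:10) {
    rr <- 800 + cumsum(rnorm(60, sd = 10))
    nl <- hrv_nonlinear(rri_from_rr(rr))
    td <- hrv_time_domain(rri_from_rr(rr))
    expect_equal(nl$sd1, td$rmssd / sqrt(2), tolerance = 1e-12)
    expect_gte(nl$sd2, 0)
  }
})

test_that("sample entropy ranks noise above a regular oscillation", {
  set.seed(9)
  n <- 150
  sine <- 800 + 50 * sin(2 * pi * seq_len(n) / 20)
  noise <- 800 + rnorm(n, sd = sd_pop_ref(sine))
  se_sine <- sample_entropy(sine, r = 0.2 * sd_pop_ref(sine))
  se_noise <- sample_entropy(noise, r = 0.2 * sd_pop_ref(noise))
  expect_gt(se_noise, se_sine)

  ## constant series: all templates match, entropy 0
  nl <- hrv_nonlinear(rri_from_rr(rep(800, 60)))
  expect_equal(nl$sampen, 0)
  expect_equal(nl$sd1, 0)
  expect_equal(nl$sd2, 0)
})

test_that("band powers reflect the generator's modulation structure", {
  cfg_lf <- sim_config("study2", lf_amp = 30, hf_amp = 0, rr_noise_sd = 0,
                       seed = 2)
  fd_lf <- hrv_frequency_domain(simulate_rri(cfg_lf, 300)$rri)
  expect_gt(fd_lf$lf_power / max(fd_lf$hf_power, 1e-9), 10)

  cfg_hf <- sim_config("study2", lf_amp = 0, hf_amp = 30, rr_noise_sd = 0,
                       seed = 2)
  fd_hf <- hrv_frequency_domain(simulate_rri(cfg_hf, 300)$rri)
  expect_gt(fd_hf$hf_power / max(fd_hf$lf_power, 1e-9), 10)

  fd_const <- hrv_frequency_domain(
    rri_series(seq(0, 120000, by = 800)))
  expect_lt(fd_const$lf_power, 1e-6)
  expect_lt(fd_const$hf_power, 1e-6)
  expect_true(is.na(fd_const$lf_hf))
})

test_that("the LF/HF ratio recovers the analytic value within 20%", {
  cfg <- sim_config("study2", lf_amp = 30, hf_amp = 25, rr_noise_sd = 5,
                    seed = 21)
  fd <- hrv_frequency_domain(simulate_rri(cfg, 300)$rri)
  analytic <- (30 / 25)^2
  expect_lt(abs(fd$lf_hf - analytic) / analytic, 0.2)
})

test_that("profiles are complete, reproducible and flag short series", {
  cfg <- tiny_study2(seed = 5)
  rri <- simulate_rri(cfg, 120)$rri
  p1 <- hrv_profile(rri)
  p2 <- hrv_profile(rri)
  expect_identical(p1, p2)
  expect_true(all(is.finite(unlist(p1))))
  expect_equal(p1$sd1, p1$rmssd / sqrt(2), tolerance = 1e-12)

  short <- rri_series(seq(0, 20000, by = 800))
  ps <- hrv_profile(short)
  expect_true(is.na(ps$lf_power))
  expect_match(paste(attr(ps, "missing"), collapse = " "), "frequency")
  expect_false(is.na(ps$sdnn))
})

test_that("the lDLPFC post-stimulation boost raises SDNN, RMSSD and SD1", {
  gaps <- t(vapply(1:20, function(s) {
    cfg <- tiny_study2(seed = s, hrv_effect_ldlpfc = 1.5)
    pre <- hrv_time_domain(simulate_rri(cfg, 90,
      cell = list(group = "ldlpfc", time = "pre"),
      stream = paste0("a", s))$rri)
    post <- hrv_time_domain(simulate_rri(cfg, 90,
      cell = list(group = "ldlpfc", time = "post"),
      stream = paste0("b", s))$rri)
    c(post$sdnn - pre$sdnn, post$rmssd - pre$rmssd)
  }, numeric(2)))
  expect_gt(mean(gaps[, 1]), 0)
  expect_gt(mean(gaps[, 2]), 0)
  expect_gt(mean(gaps[, 1] > 0), 0.8)
})
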