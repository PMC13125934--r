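make_epochs <- function(data, fs = 100, t_start = -1,
                        labels = NULL) {
  if (is.null(labels)) {
    labels <- data.frame(stimulus = rep("a", dim(data)[1]))
  }
  epoch_set(data, fs = fs, t_start = t_start,
            channel_names = sprintf("ch%d", seq_len(dim(data)[2])),
            trial_labels = labels)
}

test_that("band-pass filtering preserves the passband and rejects DC", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  in_band <- eeg_bandpass(sin(2 * pi * 5 * t), fs)
  expect_equal(max(abs(in_band[mid])), 1, tolerance = 0.01)
  out_band <- eeg_bandpass(sin(2 * pi * 45 * t), fs)
  expect_lt(max(abs(out_band[mid])), 0.1)        # >= 90% attenuation
  dc <- eeg_bandpass(rep(3, length(t)), fs)
  expect_lt(max(abs(dc)), 1e-8)
  expect_error(eeg_bandpass(t, fs, low = 0.1, high = 200),
               class = "mmempathy_validation_error")
})

test_that("epoching slices the recording exactly and flags bad onsets", {
  fs <- 100
  x <- seq(0, 20, by = 1 / fs)        # ramp: value equals time
  ep <- eeg_epoch(x, fs, onsets = 10, window = c(-1, 3))
  expect_equal(drop(ep$data[1, 1, ]), seq(9, 13, by = 1 / fs))

  ep2 <- eeg_epoch(x, fs, onsets = c(5, 5), window = c(-1, 3))
  expect_equal(ep2$data[1, , ], ep2$data[2, , ])

  expect_message(
    ep3 <- eeg_epoch(x, fs, onsets = c(10, 19.5), window = c(-1, 3)),
    "excluded")
  expect_equal(dim(ep3$data)[1], 1)
  expect_equal(attr(ep3, "n_excluded"), 1)
})

test_that("baseline correction is exact arithmetic and idempotent", {
  fs <- 100
  n <- 4 * fs
  t <- -1 + (seq_len(n) - 1) / fs
  const <- make_epochs(array(7, c(1, 2, n)), fs = fs)
  expect_true(all(abs(baseline_correct(const)$data) < 1e-12))

  sig <- ifelse(t < 0, 2, 5)
  ep <- make_epochs(array(rep(sig, each = 2), c(1, 2, n)), fs = fs)
  bc <- baseline_correct(ep)
  expect_equal(unique(round(bc$data[1, 1, t >= 0], 10)), 3)
  expect_equal(baseline_correct(bc)$data, bc$data)
})

test_that("artifact rejection masks exactly the epochs above threshold", {
  set.seed(1)
  n <- 200
  data <- array(rnorm(10 * 3 * n), c(10, 3, n))
  data[4, 2, 100] <- 500
  ep <- make_epochs(data, fs = 100)
  expect_message(clean <- reject_artifacts(ep, threshold = 100), "1 epoch")
  expect_equal(which(clean$reject_mask), 4)
  expect_message(none <- reject_artifacts(ep, threshold = 1e6), "0 epoch")
  expect_false(any(none$reject_mask))
  ## oracle: direct peak-to-peak scan
  ptp <- apply(data, c(1, 2), function(v) max(v) - min(v))
  expect_equal(clean$reject_mask, apply(ptp > 100, 1, any))
})

test_that("common-average re-referencing zeroes the channel mean", {
  n <- 50
  a <- rnorm(n)
  d2 <- array(0, c(1, 2, n))
  d2[1, 1, ] <- a
  d2[1, 2, ] <- -a
  two <- make_epochs(d2)
  expect_equal(rereference_average(two)$data, two$data)

  same <- make_epochs(array(rep(rnorm(n), each = 3), c(1, 3, n)))
  expect_true(all(abs(rereference_average(same)$data) < 1e-12))

  set.seed(2)
  ep <- make_epochs(array(rnorm(2 * 4 * n), c(2, 4, n)))
  rr <- rereference_average(ep)
  expect_lt(max(abs(colMeans(aperm(rr$data, c(2, 1, 3))))), 1e-12)
  expect_equal(rereference_average(rr)$data, rr$data)
  one <- make_epochs(array(rnorm(n), c(1, 1, n)))
  expect_error(rereference_average(one),
               class = "mmempathy_validation_error")

  ## linearity: re-reference and baseline correction commute
  ep2 <- make_epochs(array(rnorm(2 * 4 * 400), c(2, 4, 400)), fs = 100)
  ab <- baseline_correct(rereference_average(ep2))
  ba <- rereference_average(baseline_correct(ep2))
  expect_equal(ab$data, ba$data, tolerance = 1e-12)
})

test_that("condition averaging respects the rejection mask", {
  n <- 30
  x <- matrix(rnorm(2 * n), 2)
  data <- array(0, c(3, 2, n))
  data[1, , ] <- x
  data[2, , ] <- -x
  data[3, , ] <- 5
  labels <- data.frame(stimulus = c("a", "a", "a"))
  ep <- make_epochs(data, labels = labels)
  av <- condition_average(ep, by = "stimulus")
  ## mean of x, -x and 5 = 5/3
  expect_equal(av$waveforms[["a"]], (x - x + 5) / 3)
  ## mask the third epoch: mean of x and -x = 0
  ep$reject_mask <- c(FALSE, FALSE, TRUE)
  av2 <- condition_average(ep, by = "stimulus")
  expect_true(all(abs(av2$waveforms[["a"]]) < 1e-12))
  expect_equal(av2$cells$n_epochs, 2)
  ## empty condition flagged, not invented
  ep$reject_mask <- rep(TRUE, 3)
  av3 <- condition_average(ep, by = "stimulus")
  expect_equal(av3$missing_cells, "a")
})

test_that("LPP extraction is exact window algebra", {
  fs <- 100
  n <- 4 * fs
  t <- -1 + (seq_len(n) - 1) / fs
  labels <- data.frame(stimulus = "a")
  mk_av <- function(sig) {
    condition_average(
      epoch_set(array(rep(sig, each = 2), c(1, 2, n)), fs = fs,
                t_start = -1, channel_names = c("CP1", "CP2"),
                trial_labels = labels),
      by = "stimulus")
  }
  flat <- extract_lpp(mk_av(rep(4, n)))
  expect_equal(flat$early_lpp, 4)
  expect_equal(flat$late_lpp, 4)

  boxcar <- extract_lpp(mk_av(ifelse(t >= 0.5 & t < 1.0, 6, 0)))
  expect_equal(boxcar$early_lpp, 6)
  expect_equal(boxcar$late_lpp, 0)

  expect_error(extract_lpp(mk_av(rep(1, n)), channels = c("CP1", "Pz")),
               regexp = "Pz", class = "mmempathy_validation_error")
})

test_that("delta-LPP is an antisymmetric elementwise difference", {
  pain <- data.frame(participant = "p1", early_lpp = 5, late_lpp = 7)
  nonpain <- data.frame(participant = "p1", early_lpp = 2, late_lpp = 7)
  d <- delta_lpp(pain, nonpain)
  expect_equal(d$early_lpp_delta, 3)
  expect_equal(d$late_lpp_delta, 0)
  d_rev <- delta_lpp(nonpain, pain)
  expect_equal(d_rev$early_lpp_delta, -3)
  bad <- data.frame(participant = "p2", early_lpp = 2, late_lpp = 7)
  expect_error(delta_lpp(pain, bad), class = "mmempathy_validation_error")
})
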