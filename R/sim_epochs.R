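#' EpochSet container
#'
#' Holds EEG epochs as an `epochs x channels x samples` array (microvolts)
#' together with the sampling rate, the time of the first sample relative
#' to stimulus onset, channel names, per-epoch condition labels, and a
#' per-epoch rejection mask.
#'
#' @param data numeric array, `epochs x channels x samples`.
#' @param fs sampling rate, Hz.
#' @param t_start time of the first sample relative to onset, s.
#' @param channel_names character vector, one per channel, unique.
#' @param trial_labels `data.frame` with one row per epoch (condition
#'   labels; free-form columns).
#' @param reject_mask logical vector, one per epoch; `TRUE` = rejected.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t_start, channel_names, trial_labels,
                      reject_mask = rep(FALSE, dim(data)[1])) {
  stopifnot(length(dim(data)) == 3)
  assert_that(length(channel_names) == dim(data)[2] &&
                !anyDuplicated(channel_names),
              "channel_names must be unique, one per channel")
  assert_that(nrow(trial_labels) == dim(data)[1],
              "trial_labels must have one row per epoch")
  assert_that(length(reject_mask) == dim(data)[1],
              "reject_mask length must equal epoch count")
  structure(
    list(data = data, fs = fs, t_start = t_start,
         channel_names = channel_names, trial_labels = trial_labels,
         reject_mask = reject_mask),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz",
              d[1], d[2], d[3], x$fs),
      sprintf("(t = %.3f..%.3f s; %d rejected)\n",
              x$t_start, x$t_start + (d[3] - 1) / x$fs, sum(x$reject_mask)))
  invisible(x)
}

epoch_times <- function(epochs) {
  epochs$t_start + (seq_len(dim(epochs$data)[3]) - 1) / epochs$fs
}

## The simulated LPP is a half-cosine-ramped plateau: zero before 0.4 s,
## cosine rise over [0.4, 0.7], unit plateau to 2.7 s, cosine fall over
## [2.7, 3.0]. Closed form, so window-average overlap factors can be
## verified by direct quadrature.
#' Unit-amplitude simulated LPP time course
#'
#' @param t time in seconds relative to stimulus onset (vectorised).
#' @param ramp ramp duration, s.
#' @param t_on,t_off onset and offset of the (ramped) plateau, s.
#' @return Values in `[0, 1]`.
#' @export
lpp_hump <- function(t, ramp = 0.3, t_on = 0.4, t_off = 3.0) {
  up <- 0.5 * (1 - cos(pi * (t - t_on) / ramp))
  down <- 0.5 * (1 - cos(pi * (t_off - t) / ramp))
  out <- rep(1, length(t))
  out[t < t_on + ramp] <- up[t < t_on + ramp]
  out[t > t_off - ramp] <- down[t > t_off - ramp]
  out[t < t_on | t > t_off] <- 0
  out
}

## reduced centroparietal montage; the LPP topography peaks at CP1/CP2
lpp_montage <- function() {
  data.frame(
    channel = c("Fz", "Cz", "CP1", "CPz", "CP2", "Pz", "P3", "P4"),
    weight = c(0.3, 0.6, 1.0, 0.8, 1.0, 0.6, 0.4, 0.4),
    stringsAsFactors = FALSE
  )
}

## 1/f-amplitude-shaped Gaussian noise, one column per trace;
## returns an n x m matrix, each column rescaled to unit population SD
one_over_f_noise <- function(n, m) {
  white <- matrix(rnorm(n * m), nrow = n)
  spec <- mvfft(white)
  k <- seq_len(n) - 1
  fbin <- pmin(k, n - k)           # symmetric frequency index
  scale <- ifelse(fbin == 0, 0, 1 / sqrt(fbin))
  shaped <- Re(mvfft(spec * scale, inverse = TRUE)) / n
  sds <- sqrt(colMeans(shaped^2) - colMeans(shaped)^2)
  sds[sds == 0] <- 1
  sweep(shaped, 2, sds, "/")
}

#' Simulate centroparietal ERP epochs for the pain-empathy design
#'
#' Each epoch spans -1000..3000 ms around picture onset on the reduced
#' 8-channel montage (see [lpp_montage()]) and is the sum of 1/f-shaped
#' background noise (SD `eeg_noise_sd` microvolts per channel) and a
#' positive LPP-like hump ([lpp_hump()]) whose amplitude is
#' `lpp_amp_pain` or `lpp_amp_nonpain` microvolts depending on the
#' stimulus, plus `lpp_effect_rtpj` on painful trials in real-rTPJ cells.
#' The hump is spatially weighted to peak at CP1/CP2. The prestimulus
#' noise mean is removed per epoch and channel, so the prestimulus mean is
#' approximately zero by construction.
#'
#' @param cfg a [sim_config()] with `design = "study1"`.
#' @return A list with `epochs` (an [epoch_set()]) and `truth`, a
#'   `data.frame` with the generating amplitude of every epoch.
#' @export
simulate_epochs_study1 <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_that(cfg$design == "study1",
              "simulate_epochs_study1 requires design = 'study1'",
              class = "mmempathy_config_error")
  assert_that(cfg$eeg_fs >= 100, "eeg_fs must be >= 100 Hz",
              class = "mmempathy_config_error")
  fs <- cfg$eeg_fs
  n_samp <- as.integer(round(4 * fs))      # half-open [-1, 3) sampling
  t <- -1 + (seq_len(n_samp) - 1) / fs
  montage <- lpp_montage()
  n_ch <- nrow(montage)

  labels <- expand.grid(
    trial = seq_len(cfg$n_trials_per_cell),
    stimulus = c("painful", "nonpainful"),
    task = c("somatic", "affective"),
    tdcs = c("real", "sham"),
    participant_idx = seq_len(cfg$n_participants_per_group),
    target = c("ldlpfc", "rtpj"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  labels$participant <- sprintf("%s_%02d", substr(labels$target, 1, 1),
                                labels$participant_idx)
  labels$participant_idx <- NULL
  n_ep <- nrow(labels)

  amp <- ifelse(labels$stimulus == "painful", cfg$lpp_amp_pain,
                cfg$lpp_amp_nonpain) +
    ifelse(labels$stimulus == "painful" & labels$target == "rtpj" &
             labels$tdcs == "real", cfg$lpp_effect_rtpj, 0)

  hump <- lpp_hump(t)
  pre_idx <- which(t < 0)
  data <- array(0, dim = c(n_ep, n_ch, n_samp))
  signal_ch <- outer(montage$weight, hump)        # channels x samples
  with_seed(child_seed(cfg$seed, "epochs_study1"), {
    chunk <- 256L                                 # epochs per noise batch
    for (st in seq(1L, n_ep, by = chunk)) {
      en <- min(n_ep, st + chunk - 1L)
      n_blk <- en - st + 1L
      if (cfg$eeg_noise_sd > 0) {
        nz <- one_over_f_noise(n_samp, n_ch * n_blk) * cfg$eeg_noise_sd
        nz <- array(nz, dim = c(n_samp, n_ch, n_blk))
        pre_mean <- colMeans(nz[pre_idx, , , drop = FALSE])  # ch x ep
        nz <- sweep(nz, c(2, 3), pre_mean)
        data[st:en, , ] <- aperm(nz, c(3, 2, 1))
      }
      for (ep in st:en) {
        data[ep, , ] <- data[ep, , ] + amp[ep] * signal_ch
      }
    }
  })

  epochs <- epoch_set(data, fs = fs, t_start = -1,
                      channel_names = montage$channel,
                      trial_labels = labels)
  truth <- cbind(labels, lpp_amplitude = amp)
  list(epochs = epochs, truth = truth)
}
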