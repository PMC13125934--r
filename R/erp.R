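#' Zero-phase band-pass filter for continuous EEG
#'
#' Removes the channel mean, then applies a 4th-order Butterworth
#' band-pass forward and backward (`signal::filtfilt`), giving zero phase
#' distortion and approximately unit passband gain.
#'
#' @param x numeric matrix, channels x samples (a single channel may be
#'   passed as a vector).
#' @param fs sampling rate, Hz.
#' @param low,high band edges, Hz; must satisfy `0 < low < high < fs/2`.
#' @return Filtered data with the same shape as `x`.
#' @export
eeg_bandpass <- function(x, fs, low = 0.1, high = 30) {
  assert_that(low > 0 && low < high && high < fs / 2,
              "band edges must satisfy 0 < low < high < fs/2",
              class = "mmempathy_validation_error")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(x, 1, function(ch) {
    signal::filtfilt(bf, ch - mean(ch))
  }))
  if (vec) out <- drop(out)
  out
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' Extracts one fixed-length epoch per onset. Onsets whose window would
#' fall outside the recording are excluded and counted (message), never
#' silently shifted.
#'
#' @param x channels x samples matrix (or vector, one channel).
#' @param fs sampling rate, Hz.
#' @param onsets stimulus onset times, s from recording start.
#' @param window `c(start, end)` in s relative to onset (default
#'   `c(-1, 3)`).
#' @param channel_names channel labels.
#' @param trial_labels optional `data.frame`, one row per onset.
#' @return An [epoch_set()]; excluded onsets are dropped from both data
#'   and labels, with the count in attribute `n_excluded`.
#' @export
eeg_epoch <- function(x, fs, onsets, window = c(-1, 3),
                      channel_names = NULL, trial_labels = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(nrow(x)))
  }
  n_samp_epoch <- as.integer(round((window[2] - window[1]) * fs)) + 1L
  start_idx <- as.integer(round((onsets + window[1]) * fs)) + 1L
  ok <- start_idx >= 1 & (start_idx + n_samp_epoch - 1L) <= ncol(x)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(n_excluded, " onset(s) excluded: epoch window outside recording")
  }
  assert_that(any(ok), "no onset leaves a complete epoch inside the recording",
              class = "mmempathy_data_error")
  keep <- which(ok)
  data <- array(0, dim = c(length(keep), nrow(x), n_samp_epoch))
  for (i in seq_along(keep)) {
    idx <- start_idx[keep[i]] + seq_len(n_samp_epoch) - 1L
    data[i, , ] <- x[, idx, drop = FALSE]
  }
  labels <- if (is.null(trial_labels)) {
    data.frame(onset = onsets[keep])
  } else {
    trial_labels[keep, , drop = FALSE]
  }
  out <- epoch_set(data, fs = fs, t_start = window[1],
                   channel_names = channel_names, trial_labels = labels)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Baseline-correct epochs against a prestimulus interval
#'
#' Subtracts, per epoch and channel, the mean over the baseline interval
#' (default the full -1000..0 ms prestimulus window). Idempotent.
#'
#' @param epochs an [epoch_set()].
#' @param interval `c(start, end)` in s relative to onset.
#' @return The corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, interval = c(-1, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  t <- epoch_times(epochs)
  idx <- which(t >= interval[1] & t < interval[2])
  assert_that(length(idx) > 0, "baseline interval contains no samples",
              class = "mmempathy_validation_error")
  base <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - as.vector(base)   # recycles over samples
  epochs
}

#' Mask epochs exceeding a peak-to-peak amplitude threshold
#'
#' An automatic stand-in for visual artifact screening: any epoch whose
#' peak-to-peak amplitude on any channel exceeds `threshold` microvolts is
#' marked in `reject_mask` (data are kept; downstream averaging skips
#' masked epochs). The rejection count is reported via `message`.
#'
#' @param epochs an [epoch_set()].
#' @param threshold peak-to-peak limit, microvolts (> 0).
#' @return The [epoch_set()] with an updated `reject_mask`.
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  assert_that(threshold > 0, "threshold must be > 0",
              class = "mmempathy_validation_error")
  d <- dim(epochs$data)
  m <- epochs$data
  dim(m) <- c(d[1] * d[2], d[3])           # rows = (epoch, channel) pairs
  mx <- m[, 1]
  mn <- m[, 1]
  for (j in seq_len(d[3])[-1]) {
    mx <- pmax(mx, m[, j])
    mn <- pmin(mn, m[, j])
  }
  bad <- rowSums(matrix(mx - mn > threshold, d[1], d[2])) > 0
  epochs$reject_mask <- epochs$reject_mask | bad
  message(sum(bad), " epoch(s) exceeded ", threshold,
          " uV peak-to-peak and were masked")
  epochs
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at every sample, the mean across channels from each channel,
#' so the channel mean of the output is zero. Linear, hence commutes with
#' baseline correction. Requires at least two channels.
#'
#' @param epochs an [epoch_set()].
#' @return The re-referenced [epoch_set()].
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  assert_that(dim(epochs$data)[2] >= 2,
              "common average reference needs >= 2 channels",
              class = "mmempathy_validation_error")
  ch_mean <- colMeans(aperm(epochs$data, c(2, 1, 3)))  # epochs x samples
  d <- dim(epochs$data)
  epochs$data <- epochs$data -
    aperm(array(ch_mean, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs
}

#' Average unmasked epochs within condition cells
#'
#' @param epochs an [epoch_set()].
#' @param by names of `trial_labels` columns defining the condition cells.
#' @return A list with `waveforms` (named list of channels x samples mean
#'   waveforms), `cells` (a `data.frame` of cell labels with per-cell
#'   epoch counts) and `missing_cells` (labels of requested cells with no
#'   unmasked epoch).
#' @export
condition_average <- function(epochs, by = c("stimulus")) {
  stopifnot(inherits(epochs, "epoch_set"))
  labs <- epochs$trial_labels
  assert_that(all(by %in% names(labs)),
              "grouping columns missing from trial_labels",
              class = "mmempathy_validation_error")
  key <- do.call(paste, c(labs[by], sep = "|"))
  cells <- unique(labs[, by, drop = FALSE])
  rownames(cells) <- NULL
  cell_key <- do.call(paste, c(cells[by], sep = "|"))
  keep <- !epochs$reject_mask
  waveforms <- list()
  n_used <- integer(nrow(cells))
  missing <- character(0)
  for (i in seq_len(nrow(cells))) {
    idx <- which(key == cell_key[i] & keep)
    n_used[i] <- length(idx)
    if (length(idx) == 0) {
      missing <- c(missing, cell_key[i])
      next
    }
    waveforms[[cell_key[i]]] <-
      colMeans(epochs$data[idx, , , drop = FALSE], dims = 1)
  }
  cells$n_epochs <- n_used
  list(waveforms = waveforms, cells = cells, missing_cells = missing,
       fs = epochs$fs, t_start = epochs$t_start,
       channel_names = epochs$channel_names)
}

#' Extract early and late LPP amplitudes from mean waveforms
#'
#' The late positive potential is quantified as the mean voltage over the
#' centroparietal channels CP1 and CP2 within two post-stimulus windows:
#' 500-1000 ms (early LPP) and 1000-3000 ms (late LPP). Windows are
#' half-open `[start, end)` in seconds; the channel average is taken
#' before the time average (the order is irrelevant for means and fixed
#' for determinism).
#'
#' @param averages result of [condition_average()].
#' @param channels channel labels to average over.
#' @param windows named list of `c(start, end)` windows in s.
#' @return A `data.frame` with one row per condition cell and one column
#'   per window (`early_lpp`, `late_lpp` for the defaults).
#' @export
extract_lpp <- function(averages,
                        channels = c("CP1", "CP2"),
                        windows = list(early_lpp = c(0.5, 1.0),
                                       late_lpp = c(1.0, 3.0))) {
  missing_ch <- setdiff(channels, averages$channel_names)
  assert_that(length(missing_ch) == 0,
              "channel(s) not in montage: ",
              paste(missing_ch, collapse = ", "),
              class = "mmempathy_validation_error")
  ch_idx <- match(channels, averages$channel_names)
  n_samp <- if (length(averages$waveforms)) {
    ncol(averages$waveforms[[1]])
  } else 0L
  t <- averages$t_start + (seq_len(n_samp) - 1) / averages$fs
  out <- averages$cells
  label_cols <- setdiff(names(out), "n_epochs")
  cell_key <- do.call(paste, c(out[label_cols], sep = "|"))
  for (w in names(windows)) {
    win <- windows[[w]]
    idx <- which(t >= win[1] & t < win[2])
    assert_that(length(idx) > 0, "window ", w, " contains no samples",
                class = "mmempathy_validation_error")
    vals <- rep(NA_real_, nrow(out))
    for (i in seq_len(nrow(out))) {
      wf <- averages$waveforms[[cell_key[i]]]
      if (!is.null(wf)) {
        vals[i] <- mean(colMeans(wf[ch_idx, idx, drop = FALSE]))
      }
    }
    out[[w]] <- vals
  }
  out
}

#' Painful-minus-nonpainful LPP difference
#'
#' Computes the neural empathic-responsiveness index: the elementwise
#' difference (painful - nonpainful) of LPP amplitudes between matched
#' condition cells.
#'
#' @param features_pain,features_nonpain `data.frame`s of LPP features for
#'   the painful and nonpainful conditions with identical cell labels
#'   (every column except the amplitude/count columns).
#' @param value_cols columns to subtract.
#' @return A `data.frame` of cell labels plus `<col>_delta` columns.
#' @export
delta_lpp <- function(features_pain, features_nonpain,
                      value_cols = c("early_lpp", "late_lpp")) {
  label_cols <- setdiff(names(features_pain),
                        c(value_cols, "n_epochs", "stimulus"))
  m <- merge(features_pain[c(label_cols, value_cols)],
             features_nonpain[c(label_cols, value_cols)],
             by = label_cols, suffixes = c("_pain", "_nonpain"))
  assert_that(nrow(m) == nrow(features_pain) &&
                nrow(m) == nrow(features_nonpain),
              "cell labels of the two condition tables do not match",
              class = "mmempathy_validation_error")
  out <- m[label_cols]
  for (v in value_cols) {
    out[[paste0(v, "_delta")]] <- m[[paste0(v, "_pain")]] -
      m[[paste0(v, "_nonpain")]]
  }
  out
}
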