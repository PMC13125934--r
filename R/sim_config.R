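#' Simulation configuration for synthetic empathy cohorts
#'
#' Bundles every tunable parameter of the synthetic cohort generator into a
#' validated object. The generator emulates two designs:
#'
#' * `design = "study1"`: a 2 (stimulation target: lDLPFC vs rTPJ, between
#'   participants) x 2 (tDCS type: real vs sham) x 2 (task: somatic vs
#'   affective) x 2 (stimulus: painful vs nonpainful) pain-empathy design
#'   with two 0-10 ratings per trial ("other" and "self" unpleasantness) and
#'   centroparietal ERP epochs spanning -1000..3000 ms.
#' * `design = "study2"`: a 3 (group: lDLPFC vs rTPJ vs sham, between
#'   participants) x 3 (valence: positive vs negative vs neutral) x 2 (time:
#'   pre vs post stimulation) narrative-empathy design with four 1-9 ratings
#'   per ~2-min trial and continuous ECG/RR series whose low-frequency
#'   (0.1 Hz) and high-frequency (0.25 Hz) autonomic structure is
#'   controllable per cell.
#'
#' Effect parameters are expressed on the latent (standard-deviation) scale
#' for ratings and in microvolts / milliseconds for the physiological
#' signals; setting all of them to zero yields a fully null cohort, the
#' basis of the chance-calibration tests.
#'
#' @param design `"study1"` or `"study2"`.
#' @param n_participants_per_group participants per between-subject group
#'   (default 38 for study1, 40 for study2, the per-group sizes of the
#'   emulated designs).
#' @param n_trials_per_cell trials per within-subject design cell
#'   (default 30 for study1, 4 for study2).
#' @param rating_effect_pain latent shift (SD units) of painful vs
#'   nonpainful ratings (study1).
#' @param rating_effect_rtpj additional latent shift of the "other" rating
#'   under real rTPJ stimulation (study1).
#' @param rating_effect_valence latent shift separating emotional from
#'   neutral clips on the rating scales (study2).
#' @param rating_effect_rtpj_cognitive post-stimulation latent boost on the
#'   two cognitive scales (content/emotion understanding) in the rTPJ group
#'   (study2).
#' @param lpp_amp_pain,lpp_amp_nonpain LPP plateau amplitude (microvolts)
#'   for painful / nonpainful epochs.
#' @param lpp_effect_rtpj microvolts added to painful-trial amplitude in
#'   real-rTPJ cells.
#' @param eeg_fs EEG sampling rate, Hz (>= 100).
#' @param eeg_noise_sd SD (microvolts) of the 1/f-shaped EEG background.
#' @param n_channels number of EEG channels in the reduced montage
#'   (fixed 8-channel centroparietal montage; argument kept for validation).
#' @param ecg_fs ECG sampling rate, Hz (>= 100).
#' @param mean_rr mean RR interval, ms (400-1500).
#' @param lf_amp,hf_amp RR modulation depth (ms) of the 0.10 Hz and 0.25 Hz
#'   sinusoids.
#' @param rr_noise_sd SD (ms) of Gaussian beat-to-beat jitter.
#' @param hrv_effect_ldlpfc multiplicative post-stimulation increase of RR
#'   modulation depth and jitter in the lDLPFC group (1 = no effect).
#' @param ecg_noise_sd additive white-noise SD on the ECG trace, as a
#'   fraction of the R-wave amplitude.
#' @param ecg_wander_amp baseline-wander amplitude (mV) at `ecg_wander_hz`.
#' @param ecg_wander_hz baseline-wander frequency, Hz (< 0.5).
#' @param rating_scale_max upper bound of the study2 rating scale
#'   (default 9; lower bound is 1).
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config("study1", n_participants_per_group = 4,
#'                   n_trials_per_cell = 6, seed = 1)
#' cfg$design
#' @export
sim_config <- function(design = c("study1", "study2"),
                       n_participants_per_group = NULL,
                       n_trials_per_cell = NULL,
                       rating_effect_pain = 1.5,
                       rating_effect_rtpj = 0.5,
                       rating_effect_valence = 1.0,
                       rating_effect_rtpj_cognitive = 0.5,
                       lpp_amp_pain = 6,
                       lpp_amp_nonpain = 3,
                       lpp_effect_rtpj = 2,
                       eeg_fs = 250,
                       eeg_noise_sd = 10,
                       n_channels = 8,
                       ecg_fs = 1000,
                       mean_rr = 800,
                       lf_amp = 30,
                       hf_amp = 25,
                       rr_noise_sd = 15,
                       hrv_effect_ldlpfc = 1.3,
                       ecg_noise_sd = 0.02,
                       ecg_wander_amp = 0.1,
                       ecg_wander_hz = 0.3,
                       rating_scale_max = 9,
                       seed = 1L) {
  design <- match.arg(design)
  if (is.null(n_participants_per_group)) {
    n_participants_per_group <- if (design == "study1") 38L else 40L
  }
  if (is.null(n_trials_per_cell)) {
    n_trials_per_cell <- if (design == "study1") 30L else 4L
  }
  cfg <- list(
    design = design,
    n_participants_per_group = as.integer(n_participants_per_group),
    n_trials_per_cell = as.integer(n_trials_per_cell),
    rating_effect_pain = rating_effect_pain,
    rating_effect_rtpj = rating_effect_rtpj,
    rating_effect_valence = rating_effect_valence,
    rating_effect_rtpj_cognitive = rating_effect_rtpj_cognitive,
    lpp_amp_pain = lpp_amp_pain,
    lpp_amp_nonpain = lpp_amp_nonpain,
    lpp_effect_rtpj = lpp_effect_rtpj,
    eeg_fs = eeg_fs,
    eeg_noise_sd = eeg_noise_sd,
    n_channels = as.integer(n_channels),
    ecg_fs = ecg_fs,
    mean_rr = mean_rr,
    lf_amp = lf_amp,
    hf_amp = hf_amp,
    rr_noise_sd = rr_noise_sd,
    hrv_effect_ldlpfc = hrv_effect_ldlpfc,
    ecg_noise_sd = ecg_noise_sd,
    ecg_wander_amp = ecg_wander_amp,
    ecg_wander_hz = ecg_wander_hz,
    rating_scale_max = as.integer(rating_scale_max),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_participants_per_group >= 1,
              "n_participants_per_group must be >= 1",
              class = "mmempathy_config_error")
  assert_that(cfg$n_trials_per_cell >= 1, "n_trials_per_cell must be >= 1",
              class = "mmempathy_config_error")
  assert_that(cfg$eeg_fs >= 100, "eeg_fs must be >= 100 Hz",
              class = "mmempathy_config_error")
  assert_that(cfg$ecg_fs >= 100, "ecg_fs must be >= 100 Hz (QRS resolution)",
              class = "mmempathy_config_error")
  assert_that(cfg$mean_rr >= 400 && cfg$mean_rr <= 1500,
              "mean_rr must lie in [400, 1500] ms",
              class = "mmempathy_config_error")
  assert_that(cfg$lf_amp >= 0 && cfg$hf_amp >= 0 && cfg$rr_noise_sd >= 0,
              "modulation depths and jitter must be >= 0",
              class = "mmempathy_config_error")
  ## worst-case post-stimulation scaling must keep RR physiological
  boost <- max(1, cfg$hrv_effect_ldlpfc)
  floor_rr <- cfg$mean_rr -
    boost * (cfg$lf_amp + cfg$hf_amp + 3 * cfg$rr_noise_sd)
  assert_that(floor_rr > 250,
              "mean_rr - (lf_amp + hf_amp + 3*rr_noise_sd) must exceed ",
              "250 ms (non-physiological RR otherwise)",
              class = "mmempathy_config_error")
  assert_that(cfg$hrv_effect_ldlpfc > 0, "hrv_effect_ldlpfc must be > 0",
              class = "mmempathy_config_error")
  assert_that(cfg$rating_scale_max >= 2, "rating_scale_max must be >= 2",
              class = "mmempathy_config_error")
  assert_that(cfg$ecg_wander_hz < 0.5, "baseline wander must be < 0.5 Hz",
              class = "mmempathy_config_error")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$design, "\n")
  cat("  participants/group:", x$n_participants_per_group,
      " trials/cell:", x$n_trials_per_cell, " seed:", x$seed, "\n")
  invisible(x)
}

#' Read / write a simulation configuration as JSON
#'
#' The JSON file mirrors the `sim_config` fields one-for-one, so a run can
#' be re-executed bit-identically from its saved configuration.
#'
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, fields)
}
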