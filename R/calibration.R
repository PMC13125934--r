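#' Chance-level calibration of the binary pain decoder
#'
#' Verifies the 50% chance line of the painful-vs-nonpainful decoder by
#' simulation: a Study-1-style cohort is generated with every condition
#' effect set to zero, its feature matrix (two rating means, early/late
#' LPP) is assembled once, and leave-one-out cross-validation is run over
#' `n_reps` label permutations, averaging accuracy over the five
#' classifier families. Under the null the mean accuracy must sit at the
#' chance level up to Monte-Carlo error.
#'
#' @param n_reps number of label-permutation repetitions.
#' @param seed master seed (fans out to data and permutation streams).
#' @param families classifier families to average over.
#' @param n_participants_per_group,n_trials_per_cell cohort size; the
#'   defaults give 80 balanced feature rows.
#' @return A list: `mean_accuracy` (%), `per_rep` (per-repetition means),
#'   `n_rows`, `families`.
#' @export
null_decoding_accuracy_study1 <- function(
    n_reps = 100, seed = 1,
    families = c("LR", "KNN", "RF", "SVM", "NB"),
    n_participants_per_group = 5, n_trials_per_cell = 10) {
  cfg <- sim_config("study1",
                    n_participants_per_group = n_participants_per_group,
                    n_trials_per_cell = n_trials_per_cell,
                    rating_effect_pain = 0, rating_effect_rtpj = 0,
                    lpp_amp_pain = 3, lpp_amp_nonpain = 3,
                    lpp_effect_rtpj = 0,
                    seed = child_seed(seed, "null_study1_data"))
  ratings <- simulate_ratings_study1(cfg)
  lpp <- lpp_cell_features(simulate_epochs_study1(cfg)$epochs,
                           reject_threshold = Inf)
  fm <- assemble_features_study1(ratings, lpp)
  per_rep <- vapply(seq_len(n_reps), function(r) {
    perm <- fm
    perm$label <- with_seed(child_seed(seed, paste0("perm1_", r)),
                            sample(fm$label))
    mean(vapply(families, function(f) {
      loocv(perm, classifier_spec(f, seed = child_seed(seed, f)))$accuracy
    }, 0))
  }, 0)
  list(mean_accuracy = mean(per_rep), per_rep = per_rep,
       n_rows = nrow(fm$x), families = families)
}

#' Chance-level calibration of the three-class valence decoder
#'
#' Analogue of [null_decoding_accuracy_study1()] for the narrative
#' design: a Study-2-style cohort with all valence and stimulation
#' effects disabled, features = four rating-scale means plus the HRV
#' indices, leave-one-out cross-validation over label permutations,
#' accuracy averaged over the reported classifier subset (LR, RF, NB).
#' The expected null level is the 33.3% three-class chance line.
#'
#' @param n_reps number of label-permutation repetitions.
#' @param seed master seed.
#' @param families classifier families to average over.
#' @param n_participants_per_group participants per stimulation group.
#' @param duration_s RR-series duration per cell, s.
#' @return As [null_decoding_accuracy_study1()].
#' @export
null_decoding_accuracy_study2 <- function(
    n_reps = 100, seed = 1, families = c("LR", "RF", "NB"),
    n_participants_per_group = 6, duration_s = 120) {
  cfg <- sim_config("study2",
                    n_participants_per_group = n_participants_per_group,
                    n_trials_per_cell = 4,
                    rating_effect_valence = 0,
                    rating_effect_rtpj_cognitive = 0,
                    hrv_effect_ldlpfc = 1,
                    seed = child_seed(seed, "null_study2_data"))
  ratings <- simulate_ratings_study2(cfg)
  hrv <- simulate_hrv_table_study2(cfg, duration_s = duration_s)
  fm <- assemble_features_study2(ratings, hrv, time = "pre")
  per_rep <- vapply(seq_len(n_reps), function(r) {
    perm <- fm
    perm$label <- with_seed(child_seed(seed, paste0("perm2_", r)),
                            sample(fm$label))
    mean(vapply(families, function(f) {
      loocv(perm, classifier_spec(f, seed = child_seed(seed, f)))$accuracy
    }, 0))
  }, 0)
  list(mean_accuracy = mean(per_rep), per_rep = per_rep,
       n_rows = nrow(fm$x), families = families)
}
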