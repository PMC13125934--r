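# Shared small-cohort configurations used across test files.

tiny_study1 <- function(seed = 1, ...) {
  sim_config("study1", n_participants_per_group = 3, n_trials_per_cell = 5,
             seed = seed, ...)
}

null_study1 <- function(seed = 1, ...) {
  sim_config("study1", n_participants_per_group = 3, n_trials_per_cell = 5,
             rating_effect_pain = 0, rating_effect_rtpj = 0,
             lpp_amp_pain = 3, lpp_amp_nonpain = 3, lpp_effect_rtpj = 0,
             seed = seed, ...)
}

tiny_study2 <- function(seed = 1, ...) {
  sim_config("study2", n_participants_per_group = 3, n_trials_per_cell = 3,
             seed = seed, ...)
}

null_study2 <- function(seed = 1, ...) {
  sim_config("study2", n_participants_per_group = 3, n_trials_per_cell = 3,
             rating_effect_valence = 0, rating_effect_rtpj_cognitive = 0,
             hrv_effect_ldlpfc = 1, seed = seed, ...)
}

## population (divide-by-n) SD, mirroring the package's convention
sd_pop_ref <- function(x) sqrt(mean((x - mean(x))^2))

## brute-force rank AUC: P(X > Y) + 0.5 P(X = Y) over all pairs
rank_auc <- function(signal, noise) {
  cmp <- outer(signal, noise, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

## match detected against true peak times within tol (ms); returns
## sensitivity and positive predictivity
score_peaks <- function(detected, truth, tol = 10) {
  sens <- mean(vapply(truth, function(tt) min(abs(detected - tt)), 0) <= tol)
  ppv <- mean(vapply(detected, function(tt) min(abs(truth - tt)), 0) <= tol)
  c(sensitivity = sens, ppv = ppv)
}
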