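## Ordinal ratings are generated by discretising a latent normal variable
## into equal-width bins: latent = participant intercept + condition shift +
## unit-SD trial noise, cut into K (or K+1) bins of width 0.5 latent SD.
## A condition shift of s latent SD therefore moves the expected rating by
## about 2*s scale points near the middle of the scale.

latent_to_rating <- function(z, lo, hi) {
  nbin <- hi - lo + 1L
  half <- nbin * 0.25          # bin width 0.5, centered on latent 0
  pmin(hi, pmax(lo, lo + floor((z + half) / 0.5)))
}

#' Simulate trial-level pain-empathy ratings (picture design)
#'
#' Generates the full factorial rating table of the picture-based
#' pain-empathy design: participant x target group (lDLPFC/rTPJ) x tDCS
#' type (real/sham) x task (somatic/affective) x stimulus
#' (painful/nonpainful), with `n_trials_per_cell` trials per cell and two
#' integer ratings per trial on a 0-10 scale: the protagonist's
#' unpleasantness ("other", cognitive evaluation) and the observer's own
#' unpleasantness ("self", affective sharing).
#'
#' Painful trials are shifted by `rating_effect_pain` latent SD on both
#' scales; in real-rTPJ cells, painful-trial "other" ratings receive an
#' additional `rating_effect_rtpj` shift, encoding a selective cognitive
#' empathy enhancement.
#'
#' @param cfg a [sim_config()] with `design = "study1"`.
#' @return A long-format `data.frame` (one row per trial x scale) with
#'   columns `participant`, `target`, `tdcs`, `task`, `stimulus`, `trial`,
#'   `scale`, `rating`.
#' @export
simulate_ratings_study1 <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_that(cfg$design == "study1",
              "simulate_ratings_study1 requires design = 'study1'",
              class = "mmempathy_config_error")
  n_pp <- cfg$n_participants_per_group
  n_tr <- cfg$n_trials_per_cell
  targets <- c("ldlpfc", "rtpj")
  grid <- expand.grid(
    trial = seq_len(n_tr),
    stimulus = c("painful", "nonpainful"),
    task = c("somatic", "affective"),
    tdcs = c("real", "sham"),
    participant_idx = seq_len(n_pp),
    target = targets,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$participant <- sprintf("%s_%02d", substr(grid$target, 1, 1),
                              grid$participant_idx)

  with_seed(child_seed(cfg$seed, "ratings_study1"), {
    intercept <- rnorm(n_pp * length(targets), sd = 0.5)
    names(intercept) <- sprintf(
      "%s_%02d", rep(substr(targets, 1, 1), each = n_pp),
      rep(seq_len(n_pp), times = length(targets)))
    out <- lapply(c("other", "self"), function(sc) {
      shift <- ifelse(grid$stimulus == "painful", cfg$rating_effect_pain, 0)
      if (sc == "other") {
        boost <- grid$stimulus == "painful" & grid$target == "rtpj" &
          grid$tdcs == "real"
        shift <- shift + ifelse(boost, cfg$rating_effect_rtpj, 0)
      }
      z <- intercept[grid$participant] + shift + rnorm(nrow(grid))
      data.frame(
        participant = grid$participant, target = grid$target,
        tdcs = grid$tdcs, task = grid$task, stimulus = grid$stimulus,
        trial = grid$trial, scale = sc,
        rating = as.integer(latent_to_rating(z, 0L, 10L)),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate trial-level narrative-empathy ratings (video design)
#'
#' Generates the rating table of the autobiographical-narrative design:
#' participant x group (lDLPFC/rTPJ/sham) x valence
#' (positive/negative/neutral) x time (pre/post stimulation), with
#' `n_trials_per_cell` trials per cell and four integer ratings per trial
#' on a 1-9 scale: content understanding and emotion understanding
#' (cognitive empathy), empathic concern and emotional contagion
#' (affective empathy).
#'
#' Emotional (positive/negative) clips are shifted by
#' `rating_effect_valence` latent SD relative to neutral on the cognitive
#' scales; on the affective scales negative clips carry the full shift and
#' positive clips half of it. Post-stimulation trials in the rTPJ group add
#' `rating_effect_rtpj_cognitive` on the two cognitive scales only.
#'
#' @param cfg a [sim_config()] with `design = "study2"`.
#' @return A long-format `data.frame` with columns `participant`, `group`,
#'   `valence`, `time`, `trial`, `scale`, `rating`.
#' @export
simulate_ratings_study2 <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_that(cfg$design == "study2",
              "simulate_ratings_study2 requires design = 'study2'",
              class = "mmempathy_config_error")
  n_pp <- cfg$n_participants_per_group
  n_tr <- cfg$n_trials_per_cell
  k_max <- cfg$rating_scale_max
  groups <- c("ldlpfc", "rtpj", "sham")
  scales <- c("content", "emotion", "concern", "contagion")
  grid <- expand.grid(
    trial = seq_len(n_tr),
    time = c("pre", "post"),
    valence = c("positive", "negative", "neutral"),
    participant_idx = seq_len(n_pp),
    group = groups,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$participant <- sprintf("%s_%02d", substr(grid$group, 1, 2),
                              grid$participant_idx)

  with_seed(child_seed(cfg$seed, "ratings_study2"), {
    intercept <- rnorm(n_pp * length(groups), sd = 0.5)
    names(intercept) <- sprintf(
      "%s_%02d", rep(substr(groups, 1, 2), each = n_pp),
      rep(seq_len(n_pp), times = length(groups)))
    out <- lapply(scales, function(sc) {
      cognitive <- sc %in% c("content", "emotion")
      shift <- if (cognitive) {
        ifelse(grid$valence == "neutral", 0, cfg$rating_effect_valence)
      } else {
        ifelse(grid$valence == "negative", cfg$rating_effect_valence,
               ifelse(grid$valence == "positive",
                      0.5 * cfg$rating_effect_valence, 0))
      }
      if (cognitive) {
        boost <- grid$group == "rtpj" & grid$time == "post"
        shift <- shift + ifelse(boost, cfg$rating_effect_rtpj_cognitive, 0)
      }
      z <- intercept[grid$participant] + shift + rnorm(nrow(grid))
      data.frame(
        participant = grid$participant, group = grid$group,
        valence = grid$valence, time = grid$time, trial = grid$trial,
        scale = sc, rating = as.integer(latent_to_rating(z, 1L, k_max)),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Write / read a rating table as tidy CSV
#'
#' @param ratings a rating table from [simulate_ratings_study1()] or
#'   [simulate_ratings_study2()] (one row per trial-rating).
#' @param path file path.
#' @return `write_ratings` returns `path` invisibly; `read_ratings` the
#'   `data.frame`.
#' @export
write_ratings <- function(ratings, path) {
  write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
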