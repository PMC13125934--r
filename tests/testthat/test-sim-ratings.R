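test_that("rating tables are reproducible and cover the factorial design", {
  cfg <- tiny_study1(seed = 7)
  r1 <- simulate_ratings_study1(cfg)
  r2 <- simulate_ratings_study1(cfg)
  expect_identical(r1, r2)

  cells <- unique(r1[, c("tdcs", "task", "stimulus")])
  expect_equal(nrow(cells), 8)            # 2 x 2 x 2 within-subject cells
  counts <- table(r1$participant, r1$scale)
  expect_true(all(counts == 8 * cfg$n_trials_per_cell))
  expect_equal(length(unique(r1$participant)),
               2 * cfg$n_participants_per_group)
  expect_true(all(r1$rating %in% 0:10))

  cfg2 <- tiny_study2(seed = 7)
  s1 <- simulate_ratings_study2(cfg2)
  expect_identical(s1, simulate_ratings_study2(cfg2))
  expect_equal(nrow(unique(s1[, c("valence", "time")])), 6)
  expect_true(all(s1$rating %in% 1:9))
  expect_setequal(unique(s1$scale),
                  c("content", "emotion", "concern", "contagion"))
})

test_that("null configurations produce no painful-vs-nonpainful shift", {
  diffs <- vapply(1:20, function(s) {
    r <- simulate_ratings_study1(null_study1(seed = s))
    r <- r[r$scale == "other", ]
    mean(r$rating[r$stimulus == "painful"]) -
      mean(r$rating[r$stimulus == "nonpainful"])
  }, 0)
  expect_lt(abs(mean(diffs)), 0.15)       # Monte-Carlo error around 0
})

test_that("a strong pain effect separates every participant's medians", {
  hits <- vapply(1:30, function(s) {
    cfg <- tiny_study1(seed = s, rating_effect_pain = 3)
    r <- simulate_ratings_study1(cfg)
    r <- r[r$scale == "other", ]
    by_pp <- split(r, r$participant)
    all(vapply(by_pp, function(d) {
      median(d$rating[d$stimulus == "painful"]) >=
        median(d$rating[d$stimulus == "nonpainful"])
    }, TRUE))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the rTPJ cognitive boost is recovered in study2 change scores", {
  delta_gap <- vapply(1:25, function(s) {
    cfg <- tiny_study2(seed = s, rating_effect_rtpj_cognitive = 2)
    r <- simulate_ratings_study2(cfg)
    r <- r[r$scale == "content", ]
    ag <- aggregate(rating ~ group + time, data = r, FUN = mean)
    d <- function(g) {
      ag$rating[ag$group == g & ag$time == "post"] -
        ag$rating[ag$group == g & ag$time == "pre"]
    }
    d("rtpj") - d("sham")
  }, 0)
  expect_gte(mean(delta_gap > 0), 0.95)

  ## null: change scores centered at zero in all groups
  null_d <- vapply(1:20, function(s) {
    r <- simulate_ratings_study2(null_study2(seed = s))
    ag <- aggregate(rating ~ time, data = r, FUN = mean)
    ag$rating[ag$time == "post"] - ag$rating[ag$time == "pre"]
  }, 0)
  expect_lt(abs(mean(null_d)), 0.1)
})

test_that("design mismatches and invalid parameters are rejected", {
  expect_error(simulate_ratings_study1(tiny_study2()),
               class = "mmempathy_config_error")
  expect_error(simulate_ratings_study2(tiny_study1()),
               class = "mmempathy_config_error")
  expect_error(sim_config("study1", n_trials_per_cell = 0),
               class = "mmempathy_config_error")
  expect_error(sim_config("study2", mean_rr = 300),
               class = "mmempathy_config_error")
  expect_error(sim_config("study2", mean_rr = 500, lf_amp = 150,
                          hf_amp = 100, rr_noise_sd = 20),
               class = "mmempathy_config_error")
})

test_that("configurations round-trip through JSON", {
  cfg <- tiny_study2(seed = 99, lf_amp = 12.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  expect_equal(read_sim_config(path), cfg)
})
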