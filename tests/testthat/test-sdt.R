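test_that("rating ROC curves match brute-force criterion counting", {
  signal <- c(2, 5, 5, 8)
  noise <- c(1, 3, 5, 6)
  curve <- roc_from_ratings(signal, noise, scale_max = 10)
  ## oracle: enumerate every criterion by hand
  for (cr in 10:0) {
    i <- which(curve$criteria == cr)
    expect_equal(curve$hit_rates[i], mean(signal >= cr))
    expect_equal(curve$fa_rates[i], mean(noise >= cr))
  }
  expect_equal(curve$hit_rates[1], 0)   # (0,0) anchor
  expect_equal(curve$fa_rates[length(curve$fa_rates)], 1)  # (1,1) anchor
  expect_equal(auc_trapezoid(curve), 0.625)  # = rank statistic 10/16

  ident <- roc_from_ratings(c(5, 5, 5), c(5, 5, 5))
  expect_equal(ident$hit_rates, ident$fa_rates)
  expect_equal(auc_trapezoid(ident), 0.5)

  perfect <- roc_from_ratings(c(10, 10), c(0, 0))
  expect_true(any(perfect$fa_rates == 0 & perfect$hit_rates == 1))
  expect_equal(auc_trapezoid(perfect), 1)
})

test_that("trapezoidal AUC equals the rank statistic on random draws", {
  set.seed(42)
  for (i in 1:300) {
    k <- sample(3:10, 1)
    sig <- sample(0:k, sample(2:30, 1), replace = TRUE)
    noi <- sample(0:k, sample(2:30, 1), replace = TRUE)
    curve <- roc_from_ratings(sig, noi, scale_max = k)
    expect_equal(auc_trapezoid(curve), rank_auc(sig, noi),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone transforms and additive bias", {
  set.seed(7)
  for (i in 1:20) {
    sig <- sample(0:10, 15, replace = TRUE)
    noi <- sample(0:10, 15, replace = TRUE)
    base <- auc_trapezoid(roc_from_ratings(sig, noi, scale_max = 10))
    ## strictly increasing relabelling of the scale 0..10 -> 0..20
    map <- sort(sample(0:20, 11))
    expect_equal(
      auc_trapezoid(roc_from_ratings(map[sig + 1], map[noi + 1],
                                     scale_max = 20)),
      base)
    ## constant shift with the scale widened instead of clipped
    expect_equal(
      auc_trapezoid(roc_from_ratings(sig + 4, noi + 4, scale_max = 14)),
      base)
  }
})

test_that("rating validation rejects empty and out-of-range input", {
  expect_error(roc_from_ratings(integer(0), c(1, 2)),
               class = "mmempathy_data_error")
  expect_error(roc_from_ratings(c(1, 11), c(1, 2), scale_max = 10),
               class = "mmempathy_validation_error")
  expect_error(roc_from_ratings(c(1, 2.5), c(1, 2), scale_max = 10),
               class = "mmempathy_validation_error")
})

test_that("per-cell AUC flags insufficient cells instead of dropping them", {
  cfg <- tiny_study1(seed = 3)
  r <- simulate_ratings_study1(cfg)
  ## starve one cell of its painful trials
  drop <- r$participant == "l_01" & r$tdcs == "real" &
    r$task == "somatic" & r$stimulus == "painful"
  out <- auc_by_cell(r[!drop, ], "other")
  starved <- out$participant == "l_01" & out$tdcs == "real" &
    out$task == "somatic"
  expect_true(all(out$insufficient[starved]))
  expect_true(all(is.na(out$auc[starved])))
  expect_false(any(out$insufficient[!starved]))
  expect_true(all(out$auc[!starved] >= 0 & out$auc[!starved] <= 1))
  expect_equal(nrow(out), 3 * 2 * 2 * 2)   # every cell reported
})

test_that("a positive pain effect pushes cell AUCs above one half", {
  aucs <- vapply(1:10, function(s) {
    r <- simulate_ratings_study1(tiny_study1(seed = s,
                                             rating_effect_pain = 1.5))
    mean(auc_by_cell(r, "other")$auc)
  }, 0)
  expect_true(all(aucs > 0.5))
  null_aucs <- vapply(1:15, function(s) {
    r <- simulate_ratings_study1(null_study1(seed = s))
    mean(auc_by_cell(r, "other")$auc)
  }, 0)
  expect_lt(abs(mean(null_aucs) - 0.5), 0.03)
})
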