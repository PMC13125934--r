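blob_features <- function(n_per_class = 10, sep = 10, seed = 1,
                          classes = c("a", "b")) {
  set.seed(seed)
  k <- length(classes)
  df <- data.frame(
    f1 = rnorm(n_per_class * k) + rep(sep * seq_len(k), each = n_per_class),
    f2 = rnorm(n_per_class * k) + rep(sep * seq_len(k), each = n_per_class),
    label = rep(classes, each = n_per_class),
    participant = sprintf("p%02d", seq_len(n_per_class * k)))
  feature_matrix(df, c("f1", "f2"))
}

test_that("every classifier family solves a separable problem perfectly", {
  fm <- blob_features()
  for (fam in c("LR", "KNN", "RF", "SVM", "NB")) {
    r <- loocv(fm, classifier_spec(fam, seed = 1))
    expect_equal(r$accuracy, 100)
    expect_equal(r$kappa, 1)
    expect_equal(r$roc$macro_auc, 1)
  }
  ## three-class case
  fm3 <- blob_features(classes = c("a", "b", "c"))
  r3 <- loocv(fm3, classifier_spec("LR", seed = 1))
  expect_equal(r3$accuracy, 100)
  expect_length(r3$roc$per_class, 3)
})

test_that("held-out samples never influence their own model", {
  ## flip one label in otherwise separable data: the LOOCV model for that
  ## row is fit without it, so it must predict the row's true blob class,
  ## not the flipped label
  fm <- blob_features()
  df <- fm$meta
  df$label[1] <- "b"
  flipped <- feature_matrix(df, c("f1", "f2"))
  r <- loocv(flipped, classifier_spec("LR", seed = 1))
  expect_equal(as.character(r$predictions$prediction[1]), "a")
})

test_that("permuted labels give chance-level accuracy", {
  fm <- blob_features(n_per_class = 20, sep = 0, seed = 3)
  set.seed(11)
  accs <- replicate(10, {
    m <- fm
    m$label <- sample(fm$label)
    loocv(m, classifier_spec("LR", seed = 1))$accuracy
  })
  expect_lt(abs(mean(accs) - 50), 12)
})

test_that("stochastic families are reproducible under a fixed seed", {
  fm <- blob_features(sep = 1, seed = 5)
  r1 <- loocv(fm, classifier_spec("RF", seed = 42))
  r2 <- loocv(fm, classifier_spec("RF", seed = 42))
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("Cohen's kappa matches its closed form", {
  expect_equal(cohens_kappa(matrix(c(40, 10, 10, 40), 2)), 0.6)
  expect_equal(cohens_kappa(diag(c(5, 9, 3))), 1)
  ## independence: confusion equal to the outer product of its margins
  m <- outer(c(2, 3), c(4, 6)) / 5
  expect_equal(cohens_kappa(m), 0)
  expect_warning(k <- cohens_kappa(matrix(c(7, 0, 0, 0), 2)), "p_e")
  expect_equal(k, 0)
  expect_error(cohens_kappa(matrix(0, 2, 2)),
               class = "mmempathy_validation_error")
})

test_that("one-vs-rest ROC behaves at its anchors", {
  labels <- factor(c("a", "a", "b", "b", "c", "c"))
  one_hot <- diag(3)[as.integer(labels), ]
  colnames(one_hot) <- levels(labels)
  r <- roc_multiclass(one_hot, labels)
  expect_equal(unname(vapply(r$per_class, `[[`, 0, "auc")), rep(1, 3))
  expect_equal(r$macro_auc, 1)

  ## binary consistency: the two one-vs-rest curves carry the same area
  lab2 <- factor(rep(c("x", "y"), each = 10))
  set.seed(2)
  sc <- cbind(x = rnorm(20), y = rnorm(20))
  sc[, "y"] <- -sc[, "x"]
  r2 <- roc_multiclass(sc, lab2)
  expect_equal(r2$per_class$x$auc, r2$per_class$y$auc)
})

test_that("ensemble summaries average exactly over the named subset", {
  fm <- blob_features(sep = 1, seed = 7)
  fams <- c("LR", "KNN", "RF", "SVM", "NB")
  reports <- lapply(fams, function(f) loocv(fm, classifier_spec(f, 1)))
  s_all <- ensemble_summary(reports)
  expect_equal(s_all$accuracy,
               mean(vapply(reports, `[[`, 0, "accuracy")))
  s_sub <- ensemble_summary(reports, c("LR", "RF", "NB"))
  expect_equal(s_sub$accuracy,
               mean(vapply(reports[c(1, 3, 5)], `[[`, 0, "accuracy")))
  expect_error(ensemble_summary(reports, character(0)),
               class = "mmempathy_validation_error")
  expect_error(ensemble_summary(reports[1:2], c("LR", "NB")),
               class = "mmempathy_validation_error")
})

test_that("feature assembly is complete, labelled and missing-safe", {
  cfg <- null_study1(seed = 2)
  ratings <- simulate_ratings_study1(cfg)
  lpp <- lpp_cell_features(simulate_epochs_study1(cfg)$epochs,
                           reject_threshold = Inf)
  fm <- assemble_features_study1(ratings, lpp)
  ## one row per participant x tdcs x task x stimulus
  expect_equal(nrow(fm$x), 2 * cfg$n_participants_per_group * 2 * 2 * 2)
  expect_setequal(colnames(fm$x),
                  c("rating_self", "rating_other", "early_lpp", "late_lpp"))
  expect_setequal(levels(fm$label), c("painful", "nonpainful"))

  ## rows with missing features are dropped and counted
  df <- fm$meta
  df$early_lpp[3] <- NA
  fm2 <- feature_matrix(df, colnames(fm$x))
  expect_equal(nrow(fm2$x), nrow(fm$x) - 1)
  expect_equal(attr(fm2, "n_dropped"), 1)
})
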