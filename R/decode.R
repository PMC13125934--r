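#' Feature matrix for decoding
#'
#' Wraps a `data.frame` of per-sample features, class labels and
#' participant identifiers. Rows containing missing feature values are
#' dropped at construction with the count recorded in attribute
#' `n_dropped` - decoding never imputes. Features enter classifiers on
#' their original scale; no standardisation or normalisation is applied
#' anywhere in the decoding chain.
#'
#' @param df `data.frame` holding features and metadata.
#' @param feature_cols names of the feature columns.
#' @param label_col name of the class-label column.
#' @param group_col name of the participant-identifier column.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(df, feature_cols, label_col = "label",
                           group_col = "participant") {
  assert_that(all(c(feature_cols, label_col, group_col) %in% names(df)),
              "feature/label/group columns missing from data",
              class = "mmempathy_validation_error")
  complete <- stats::complete.cases(df[feature_cols])
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  assert_that(nrow(df) > 0, "no complete rows left after dropping ",
              "missing features", class = "mmempathy_data_error")
  out <- structure(
    list(x = as.matrix(df[feature_cols]),
         label = factor(df[[label_col]]),
         group = as.character(df[[group_col]]),
         meta = df),
    class = "feature_matrix")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features; classes: %s\n",
              nrow(x$x), ncol(x$x),
              paste(levels(x$label), collapse = ", ")))
  invisible(x)
}

#' Classifier specification
#'
#' One of the five classifier families used for decoding, with frozen
#' default hyperparameters (the defaults are deliberately conventional
#' and fully reproducible): ridge-penalised logistic regression
#' (`lambda = 0.01`, no standardisation), k-nearest neighbours (`k = 5`,
#' Euclidean), random forest (500 trees, seeded), RBF support vector
#' machine (scores via a logistic transform of decision values) and
#' Gaussian naive Bayes.
#'
#' @param family `"LR"`, `"KNN"`, `"RF"`, `"SVM"` or `"NB"`.
#' @param seed seed for stochastic families (RF).
#' @param ... hyperparameter overrides (`lambda`, `k`, `ntree`, `gamma`,
#'   `cost`).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("LR", "KNN", "RF", "SVM", "NB"),
                            seed = 1L, ...) {
  family <- match.arg(family)
  hp <- utils::modifyList(
    list(lambda = 0.01, k = 5, ntree = 500, gamma = NULL, cost = 1),
    list(...))
  structure(list(family = family, seed = as.integer(seed),
                 hyperparameters = hp),
            class = "classifier_spec")
}

## fit on training rows, return per-class scores for test rows
## (rows: test samples; columns: class levels of the full problem)
fit_and_score <- function(spec, x_train, y_train, x_test, lev) {
  hp <- spec$hyperparameters
  n_test <- nrow(x_test)
  scores <- matrix(0, n_test, length(lev), dimnames = list(NULL, lev))
  y_train <- factor(y_train, levels = lev)
  present <- levels(droplevels(y_train))
  if (spec$family == "LR") {
    fam <- if (length(present) == 2) "binomial" else "multinomial"
    ## small-sample warnings are routine at LOOCV scale; a short
    ## decreasing lambda path is fitted (glmnet is unreliable with a
    ## single lambda) and predictions taken at the target penalty
    fit <- suppressWarnings(
      glmnet::glmnet(x_train, y_train, family = fam, alpha = 0,
                     lambda = hp$lambda * c(100, 10, 1),
                     standardize = FALSE))
    pr <- predict(fit, x_test, type = "response", s = hp$lambda)
    if (fam == "binomial") {
      scores[, present[2]] <- pr[, 1]
      scores[, present[1]] <- 1 - pr[, 1]
    } else {
      pr <- pr[, , 1, drop = FALSE]
      scores[, colnames(pr)] <- pr[, , 1]
    }
  } else if (spec$family == "KNN") {
    k <- min(hp$k, nrow(x_train))
    for (i in seq_len(n_test)) {
      d <- sqrt(colSums((t(x_train) - x_test[i, ])^2))
      nb <- y_train[order(d)[seq_len(k)]]        # stable order: ties by row
      tab <- table(nb) / k
      scores[i, names(tab)] <- as.numeric(tab)
    }
  } else if (spec$family == "RF") {
    fit <- with_seed(spec$seed, {
      randomForest::randomForest(x_train, droplevels(y_train),
                                 ntree = hp$ntree)
    })
    pr <- predict(fit, x_test, type = "prob")
    scores[, colnames(pr)] <- pr
  } else if (spec$family == "SVM") {
    fit <- e1071::svm(x_train, droplevels(y_train), kernel = "radial",
                      cost = hp$cost,
                      gamma = hp$gamma %||% (1 / ncol(x_train)),
                      scale = FALSE)
    pred <- predict(fit, x_test, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    ## pairwise "A/B" decision values -> logistic one-vs-one votes
    for (cn in colnames(dv)) {
      pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
      p <- stats::plogis(dv[, cn])
      scores[, pair[1]] <- scores[, pair[1]] + p
      scores[, pair[2]] <- scores[, pair[2]] + (1 - p)
    }
    scores <- scores / pmax(rowSums(scores), .Machine$double.eps)
  } else if (spec$family == "NB") {
    df_train <- as.data.frame(x_train)
    fit <- e1071::naiveBayes(df_train, droplevels(y_train))
    pr <- predict(fit, as.data.frame(x_test), type = "raw")
    scores[, colnames(pr)] <- pr
  }
  scores
}

#' Leave-one-out cross-validated decoding
#'
#' Predicts every sample exactly once with a model never trained on it.
#' The default unit is one row (leave-one-row-out); with
#' `unit = "participant"` all rows of the held-out sample's participant
#' are removed from the training set together (leave-one-participant-out,
#' immune to within-participant row correlation), while still scoring one
#' row per fold. Folds whose training set lost a class entirely are
#' flagged and excluded from ROC computation.
#'
#' @param features a [feature_matrix()].
#' @param spec a [classifier_spec()].
#' @param unit `"row"` or `"participant"`.
#' @return An object of class `decode_report`: per-fold predictions and
#'   class scores, `accuracy` (%), `kappa`, `confusion`, `roc` (see
#'   [roc_multiclass()]), `family`, and the count of flagged folds.
#' @export
loocv <- function(features, spec, unit = c("row", "participant")) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(spec, "classifier_spec"))
  unit <- match.arg(unit)
  x <- features$x
  y <- features$label
  lev <- levels(y)
  assert_that(all(table(y) >= 2), "need >= 2 samples per class",
              class = "mmempathy_data_error")
  n <- nrow(x)
  scores <- matrix(NA_real_, n, length(lev), dimnames = list(NULL, lev))
  flagged <- logical(n)
  for (i in seq_len(n)) {
    train <- if (unit == "row") {
      setdiff(seq_len(n), i)
    } else {
      which(features$group != features$group[i])
    }
    if (length(unique(y[train])) < length(lev)) {
      flagged[i] <- TRUE
    }
    scores[i, ] <- fit_and_score(spec, x[train, , drop = FALSE], y[train],
                                 x[i, , drop = FALSE], lev)
  }
  pred <- factor(lev[max.col(scores, ties.method = "first")], levels = lev)
  confusion <- table(truth = y, prediction = pred)
  acc <- 100 * mean(pred == y)
  roc <- if (all(flagged)) NULL else {
    roc_multiclass(scores[!flagged, , drop = FALSE], y[!flagged])
  }
  structure(
    list(family = spec$family, unit = unit,
         predictions = data.frame(truth = y, prediction = pred),
         scores = scores, accuracy = acc,
         kappa = cohens_kappa(confusion), confusion = confusion,
         roc = roc, n_flagged_folds = sum(flagged)),
    class = "decode_report")
}

#' @export
print.decode_report <- function(x, ...) {
  cat(sprintf("<decode_report> %s: accuracy %.1f%%, kappa %.3f",
              x$family, x$accuracy, x$kappa),
      if (!is.null(x$roc)) sprintf(", macro AUC %.3f", x$roc$macro_auc),
      "\n", sep = "")
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / total` and chance agreement
#' `p_e = sum(row_margin * col_margin) / total^2`. When `p_e = 1` (all
#' mass in a single cell) kappa is defined as 0 with a warning.
#'
#' @param confusion square matrix of counts (truth x prediction).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  assert_that(nrow(confusion) == ncol(confusion) && all(confusion >= 0) &&
                sum(confusion) > 0,
              "confusion must be a square nonnegative matrix with ",
              "positive total", class = "mmempathy_validation_error")
  total <- sum(confusion)
  p_o <- sum(diag(confusion)) / total
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (p_e >= 1) {
    warning("chance agreement p_e = 1; kappa defined as 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

## one-vs-rest ROC from continuous scores for a single positive class
roc_binary_scores <- function(score, is_pos) {
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(score[is_pos] >= s), 0)
  fpr <- vapply(thr, function(s) mean(score[!is_pos] >= s), 0)
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  o <- order(fpr, tpr)
  list(fpr = fpr[o], tpr = tpr[o],
       auc = sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2))
}

#' One-vs-rest multiclass ROC curves with macro-averaged area
#'
#' Builds one ROC curve per class by thresholding that class's score
#' against all other classes pooled; the macro-average area is the mean
#' of the per-class areas. With two classes this reduces to the standard
#' single ROC (the two one-vs-rest curves are mirror images with equal
#' area). Classes lacking a positive or a negative sample are skipped and
#' listed in `skipped`.
#'
#' @param scores numeric matrix, samples x classes (columns named by
#'   class).
#' @param labels true class labels.
#' @return A list with `per_class` (named list of `fpr`, `tpr`, `auc`),
#'   `macro_auc` and `skipped`.
#' @export
roc_multiclass <- function(scores, labels) {
  labels <- factor(labels, levels = colnames(scores))
  assert_that(all(is.finite(scores)), "scores must be finite",
              class = "mmempathy_validation_error")
  per_class <- list()
  skipped <- character(0)
  for (cl in colnames(scores)) {
    is_pos <- labels == cl
    if (!any(is_pos) || all(is_pos)) {
      skipped <- c(skipped, cl)
      next
    }
    per_class[[cl]] <- roc_binary_scores(scores[, cl], is_pos)
  }
  assert_that(length(per_class) > 0, "no class with both positive and ",
              "negative samples", class = "mmempathy_data_error")
  list(per_class = per_class,
       macro_auc = mean(vapply(per_class, `[[`, 0, "auc")),
       skipped = skipped)
}

#' Average decoding performance over a named classifier subset
#'
#' @param reports list of [loocv()] reports computed on the same feature
#'   matrix.
#' @param families classifier families to average over (default: all
#'   present).
#' @return A list with `families`, `accuracy`, `kappa`, `macro_auc`
#'   (means over the subset) and `per_family`, the contributing values.
#' @export
ensemble_summary <- function(reports, families = NULL) {
  fams <- vapply(reports, `[[`, "", "family")
  if (is.null(families)) families <- fams
  assert_that(length(families) > 0, "empty classifier subset",
              class = "mmempathy_validation_error")
  assert_that(all(families %in% fams),
              "requested families missing from reports",
              class = "mmempathy_validation_error")
  sel <- reports[match(families, fams)]
  per <- data.frame(
    family = families,
    accuracy = vapply(sel, `[[`, 0, "accuracy"),
    kappa = vapply(sel, `[[`, 0, "kappa"),
    macro_auc = vapply(sel, function(r) {
      if (is.null(r$roc)) NA_real_ else r$roc$macro_auc
    }, 0)
  )
  list(families = families,
       accuracy = mean(per$accuracy),
       kappa = mean(per$kappa),
       macro_auc = mean(per$macro_auc, na.rm = TRUE),
       per_family = per)
}

#' Assemble decoding features for the pain-empathy design
#'
#' One row per participant x tDCS-type x task x stimulus cell with the
#' cell-mean self and other ratings and the early/late LPP amplitudes;
#' the class label is the stimulus (painful vs nonpainful). Cells present
#' in only one of the two tables are dropped with the count in attribute
#' `n_unmatched`.
#'
#' @param ratings a rating table ([simulate_ratings_study1()] format).
#' @param lpp an LPP feature table ([extract_lpp()] on per-cell averages,
#'   with `participant`, `target`, `tdcs`, `task`, `stimulus` columns).
#' @return A [feature_matrix()] with features `rating_self`,
#'   `rating_other`, `early_lpp`, `late_lpp` and label column `label`.
#' @export
assemble_features_study1 <- function(ratings, lpp) {
  keys <- c("participant", "target", "tdcs", "task", "stimulus")
  agg <- stats::aggregate(rating ~ participant + target + tdcs + task +
                            stimulus + scale, data = ratings, FUN = mean)
  wide <- stats::reshape(agg, idvar = keys, timevar = "scale",
                         direction = "wide")
  names(wide) <- sub("^rating\\.", "rating_", names(wide))
  merged <- merge(wide, lpp[, c(keys, "early_lpp", "late_lpp")], by = keys)
  n_unmatched <- (nrow(wide) - nrow(merged)) + (nrow(lpp) - nrow(merged))
  assert_that(nrow(merged) > 0, "no matching cells between ratings and LPP",
              class = "mmempathy_data_error")
  merged$label <- merged$stimulus
  out <- feature_matrix(
    merged,
    feature_cols = c("rating_self", "rating_other", "early_lpp",
                     "late_lpp"))
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Assemble decoding features for the narrative design
#'
#' One row per participant x valence at the requested time point, with
#' the four rating-scale means plus the HRV indices; the class label is
#' the valence (positive / negative / neutral).
#'
#' @param ratings a rating table ([simulate_ratings_study2()] format).
#' @param hrv an HRV table with `participant`, `group`, `valence`, `time`
#'   columns plus the [hrv_profile()] index columns.
#' @param time `"pre"` or `"post"`.
#' @param hrv_cols HRV index columns to include as features.
#' @return A [feature_matrix()] with label column `label`.
#' @export
assemble_features_study2 <- function(ratings, hrv, time = c("pre", "post"),
                                     hrv_cols = c("hr", "sdnn", "rmssd",
                                                  "pnn50", "lf_power",
                                                  "hf_power", "lf_hf",
                                                  "sampen", "sd1", "sd2",
                                                  "sd1_sd2")) {
  time <- match.arg(time)
  keys <- c("participant", "group", "valence")
  r <- ratings[ratings$time == time, , drop = FALSE]
  h <- hrv[hrv$time == time, , drop = FALSE]
  assert_that(nrow(r) > 0 && nrow(h) > 0,
              "no rows for time point '", time, "'",
              class = "mmempathy_data_error")
  agg <- stats::aggregate(rating ~ participant + group + valence + scale,
                          data = r, FUN = mean)
  wide <- stats::reshape(agg, idvar = keys, timevar = "scale",
                         direction = "wide")
  names(wide) <- sub("^rating\\.", "rating_", names(wide))
  merged <- merge(wide, h[, c(keys, hrv_cols)], by = keys)
  n_unmatched <- (nrow(wide) - nrow(merged)) + (nrow(h) - nrow(merged))
  assert_that(nrow(merged) > 0, "no matching cells between ratings and HRV",
              class = "mmempathy_data_error")
  merged$label <- merged$valence
  rating_cols <- grep("^rating_", names(merged), value = TRUE)
  out <- feature_matrix(merged, feature_cols = c(rating_cols, hrv_cols))
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "time") <- time
  out
}
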