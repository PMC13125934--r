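#' Rating-based signal-detection ROC curve
#'
#' Treats each possible rating value as an implicit decision criterion:
#' for criterion `c` in `{>=0, >=1, ..., >=K}`, trials at or above `c` in
#' the signal (painful) condition count as hits and in the noise
#' (nonpainful) condition as false alarms. The resulting
#' (false-alarm, hit) points, augmented with the (0,0) and (1,1) anchors,
#' form the rating ROC curve. Sweeping every value of the declared scale
#' (not only observed values) makes curves comparable across cells; the
#' area is identical either way.
#'
#' @param signal_ratings integer ratings from the signal condition.
#' @param noise_ratings integer ratings from the noise condition.
#' @param scale_max top of the rating scale `K` (criteria sweep `0..K`).
#' @param scale_min bottom of the rating scale.
#' @return An object of class `roc_curve`: a list with `criteria`,
#'   `hit_rates`, `fa_rates` (anchored, ordered by descending criterion),
#'   `n_signal`, `n_noise`.
#' @export
roc_from_ratings <- function(signal_ratings, noise_ratings, scale_max = 10,
                             scale_min = 0) {
  assert_that(length(signal_ratings) > 0 && length(noise_ratings) > 0,
              "both rating vectors must be non-empty",
              class = "mmempathy_data_error")
  ok <- function(x) all(x >= scale_min & x <= scale_max & x == round(x))
  assert_that(ok(signal_ratings) && ok(noise_ratings),
              "ratings must be integers within [", scale_min, ", ",
              scale_max, "]", class = "mmempathy_validation_error")
  criteria <- seq(scale_max, scale_min)   # descending: strictest first
  hit <- vapply(criteria, function(cr) mean(signal_ratings >= cr), 0)
  fa <- vapply(criteria, function(cr) mean(noise_ratings >= cr), 0)
  structure(
    list(criteria = c(Inf, criteria, -Inf),
         hit_rates = c(0, hit, 1),
         fa_rates = c(0, fa, 1),
         n_signal = length(signal_ratings),
         n_noise = length(noise_ratings)),
    class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d criteria, n_signal = %d, n_noise = %d\n",
              length(x$criteria) - 2, x$n_signal, x$n_noise))
  invisible(x)
}

#' Nonparametric AUC by trapezoidal integration of a rating ROC curve
#'
#' Integrates the anchored ROC curve with the trapezoid rule after sorting
#' points by false-alarm rate (then hit rate, for deterministic handling
#' of ties). For rating data this equals the Mann-Whitney rank statistic
#' `P(X_signal > Y_noise) + 0.5 P(X_signal = Y_noise)` exactly: tied
#' ratings contribute through the trapezoid over the tied segment. An AUC
#' of 0.5 indicates no discrimination, 1 perfect discrimination,
#' independent of response bias.
#'
#' @param curve a [roc_from_ratings()] result.
#' @return The AUC, a single number in `[0, 1]`.
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  o <- order(curve$fa_rates, curve$hit_rates)
  fa <- curve$fa_rates[o]
  hit <- curve$hit_rates[o]
  assert_that(!is.unsorted(hit),
              "ROC curve is not monotone: hit rates must be ",
              "non-decreasing along the sorted curve",
              class = "mmempathy_internal_error")
  sum(diff(fa) * (head(hit, -1) + tail(hit, -1)) / 2)
}

#' Per-cell AUC sweep over a rating table
#'
#' Computes the rating-based AUC (painful vs nonpainful) for every
#' participant x tDCS-type x task cell of a pain-empathy rating table, for
#' the requested rating scale. Cells missing a condition or with fewer
#' than two trials per condition are flagged (`insufficient = TRUE`, AUC
#' `NA`), never silently dropped.
#'
#' @param ratings a long-format rating table (see
#'   [simulate_ratings_study1()]).
#' @param scale `"other"` or `"self"`.
#' @param scale_max top of the rating scale.
#' @return A `data.frame` with one row per cell: design labels, `auc`,
#'   `n_signal`, `n_noise`, `insufficient`.
#' @export
auc_by_cell <- function(ratings, scale = c("other", "self"),
                        scale_max = 10) {
  scale <- match.arg(scale)
  r <- ratings[ratings$scale == scale, , drop = FALSE]
  assert_that(nrow(r) > 0, "no rows for rating scale '", scale, "'",
              class = "mmempathy_data_error")
  cells <- unique(r[, c("participant", "target", "tdcs", "task")])
  rownames(cells) <- NULL
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- r[r$participant == cell$participant & r$tdcs == cell$tdcs &
               r$task == cell$task, ]
    sig <- sub$rating[sub$stimulus == "painful"]
    noi <- sub$rating[sub$stimulus == "nonpainful"]
    if (length(sig) < 2 || length(noi) < 2) {
      data.frame(cell, auc = NA_real_, n_signal = length(sig),
                 n_noise = length(noi), insufficient = TRUE)
    } else {
      curve <- roc_from_ratings(sig, noi, scale_max = scale_max)
      data.frame(cell, auc = auc_trapezoid(curve), n_signal = length(sig),
                 n_noise = length(noi), insufficient = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$rating_scale <- scale
  rownames(out) <- NULL
  out
}
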