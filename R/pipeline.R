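## End-to-end orchestration: simulate -> preprocess -> features -> SDT /
## HRV -> change scores -> decode -> report. Each stage logs its counts
## (epochs rejected, intervals corrected, rows dropped) in the manifest.

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sprintf("%x", child_seed(7, as.character(s)))
}

#' Per-cell LPP features from an epoch set
#'
#' Baseline-corrects, masks high-amplitude epochs, averages unmasked
#' epochs within participant x target x tDCS x task x stimulus cells and
#' extracts early/late LPP amplitudes at CP1/CP2.
#'
#' @param epochs an [epoch_set()] with design labels in `trial_labels`.
#' @param reject_threshold peak-to-peak rejection threshold, microvolts;
#'   `Inf` disables rejection.
#' @return A `data.frame` of cell labels with `early_lpp` and `late_lpp`
#'   columns; the rejection count is in attribute `n_rejected`.
#' @export
lpp_cell_features <- function(epochs, reject_threshold = 100) {
  epochs <- baseline_correct(epochs)
  n_rej <- 0L
  if (is.finite(reject_threshold)) {
    epochs <- suppressMessages(reject_artifacts(epochs, reject_threshold))
    n_rej <- sum(epochs$reject_mask)
  }
  av <- condition_average(
    epochs, by = c("participant", "target", "tdcs", "task", "stimulus"))
  out <- extract_lpp(av)
  attr(out, "n_rejected") <- n_rej
  out
}

#' HRV profiles for every cell of the narrative design
#'
#' Simulates one RR series per participant x valence x time cell (each
#' from its own child seed) and computes the full [hrv_profile()]. The
#' post-stimulation lDLPFC boost configured in `cfg` is applied inside
#' [simulate_rri()].
#'
#' @param cfg a [sim_config()] with `design = "study2"`.
#' @param duration_s recording duration per cell, s.
#' @return A `data.frame`: cell labels plus the HRV index columns.
#' @export
simulate_hrv_table_study2 <- function(cfg, duration_s = 120) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_that(cfg$design == "study2", "requires design = 'study2'",
              class = "mmempathy_config_error")
  groups <- c("ldlpfc", "rtpj", "sham")
  cells <- expand.grid(
    time = c("pre", "post"),
    valence = c("positive", "negative", "neutral"),
    participant_idx = seq_len(cfg$n_participants_per_group),
    group = groups,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  cells$participant <- sprintf("%s_%02d", substr(cells$group, 1, 2),
                               cells$participant_idx)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sim <- simulate_rri(
      cfg, duration_s = duration_s,
      cell = list(group = cell$group, time = cell$time),
      stream = paste("rri", cell$participant, cell$valence, cell$time,
                     sep = "_"))
    prof <- hrv_profile(sim$rri)
    cbind(cell[c("participant", "group", "valence", "time")], prof)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Post-minus-pre change scores over matched cells
#'
#' @param pre,post `data.frame`s holding the same cells at the two time
#'   points.
#' @param keys columns identifying a cell.
#' @param value_cols columns to difference.
#' @return A `data.frame` of cell labels plus `<col>_delta` columns;
#'   cells present at only one time point get `NA` deltas and
#'   `missing = TRUE`.
#' @export
change_scores <- function(pre, post, keys, value_cols) {
  m <- merge(pre[, c(keys, value_cols)], post[, c(keys, value_cols)],
             by = keys, suffixes = c("_pre", "_post"), all = TRUE)
  out <- m[, keys, drop = FALSE]
  for (v in value_cols) {
    out[[paste0(v, "_delta")]] <- m[[paste0(v, "_post")]] -
      m[[paste0(v, "_pre")]]
  }
  out$missing <- !stats::complete.cases(
    out[, paste0(value_cols, "_delta"), drop = FALSE])
  out
}

decode_by_subset <- function(features, subset_cols, families, seed,
                             unit = "row") {
  meta <- features$meta
  subsets <- if (length(subset_cols)) {
    unique(meta[, subset_cols, drop = FALSE])
  } else {
    data.frame(all = "all")
  }
  rownames(subsets) <- NULL
  res <- list()
  for (i in seq_len(nrow(subsets))) {
    keep <- rep(TRUE, nrow(meta))
    for (cc in subset_cols) keep <- keep & meta[[cc]] == subsets[i, cc]
    sub_fm <- feature_matrix(
      meta[keep, , drop = FALSE],
      feature_cols = colnames(features$x))
    reports <- lapply(families, function(f) {
      loocv(sub_fm, classifier_spec(f, seed = seed), unit = unit)
    })
    res[[i]] <- list(subset = subsets[i, , drop = FALSE],
                     reports = reports,
                     summary = ensemble_summary(reports, families))
  }
  res
}

write_manifest <- function(path, cfg, seed, counts) {
  manifest <- list(
    package = "mmempathy",
    version = as.character(utils::packageVersion("mmempathy")),
    seed = seed,
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full pain-empathy (picture) pipeline on a synthetic cohort
#'
#' Simulates ratings and ERP epochs, extracts per-cell AUCs (self and
#' other scales), LPP features and painful-minus-nonpainful deltas,
#' assembles the multimodal feature matrix and decodes painful vs
#' nonpainful with leave-one-out cross-validation, overall and within
#' each target x tDCS-type subset.
#'
#' @param cfg a [sim_config()] with `design = "study1"`.
#' @param out_dir optional output directory; when given, all tables are
#'   written as CSV/JSON together with a run manifest.
#' @param families classifier families for decoding.
#' @param reject_threshold epoch rejection threshold, microvolts.
#' @return A list (`ratings`, `auc_other`, `auc_self`, `lpp`, `delta_lpp`,
#'   `features`, `decoding`, `decoding_by_cell`, `manifest_counts`).
#' @export
run_study1 <- function(cfg, out_dir = NULL,
                       families = c("LR", "KNN", "RF", "SVM", "NB"),
                       reject_threshold = 100) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_that(cfg$design == "study1", "run_study1 needs design = 'study1'",
              class = "mmempathy_config_error")
  ratings <- simulate_ratings_study1(cfg)
  sim <- simulate_epochs_study1(cfg)
  lpp <- lpp_cell_features(sim$epochs, reject_threshold = reject_threshold)
  auc_other <- auc_by_cell(ratings, "other")
  auc_self <- auc_by_cell(ratings, "self")
  dl <- delta_lpp(
    lpp[lpp$stimulus == "painful", ],
    lpp[lpp$stimulus == "nonpainful", ])
  features <- assemble_features_study1(ratings, lpp)
  overall <- decode_by_subset(features, character(0), families, cfg$seed)
  by_cell <- decode_by_subset(features, c("target", "tdcs"), families,
                              cfg$seed)
  counts <- list(
    n_epochs_rejected = attr(lpp, "n_rejected"),
    n_feature_rows_dropped = attr(features, "n_dropped"),
    n_cells_insufficient = sum(auc_other$insufficient) +
      sum(auc_self$insufficient)
  )
  bundle <- list(ratings = ratings, auc_other = auc_other,
                 auc_self = auc_self, lpp = lpp, delta_lpp = dl,
                 features = features, decoding = overall[[1]],
                 decoding_by_cell = by_cell, manifest_counts = counts,
                 cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ratings(ratings, file.path(out_dir, "ratings.csv"))
    write.csv(lpp, file.path(out_dir, "lpp.csv"), row.names = FALSE)
    write.csv(rbind(auc_other, auc_self), file.path(out_dir, "auc.csv"),
              row.names = FALSE)
    write.csv(dl, file.path(out_dir, "delta_lpp.csv"), row.names = FALSE)
    write.csv(features$meta, file.path(out_dir, "features.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      lapply(by_cell, function(b) {
        c(as.list(b$subset), b$summary[c("accuracy", "kappa", "macro_auc")])
      }),
      file.path(out_dir, "decoding_by_cell.json"), auto_unbox = TRUE,
      digits = NA)
    write_manifest(file.path(out_dir, "manifest.json"), cfg, cfg$seed,
                   counts)
  }
  bundle
}

#' Run the full narrative (video) pipeline on a synthetic cohort
#'
#' Simulates ratings and per-cell RR series, computes HRV profiles,
#' post-minus-pre change scores for every rating scale and HRV index, and
#' decodes event valence (positive / negative / neutral) from ratings
#' plus HRV separately at the pre and post time points, overall and per
#' stimulation group.
#'
#' @param cfg a [sim_config()] with `design = "study2"`.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param families classifier families for decoding (default: the
#'   subset that behaves stably on this feature space).
#' @param duration_s RR recording duration per cell, s.
#' @return A list (`ratings`, `hrv`, `rating_changes`, `hrv_changes`,
#'   `decoding` with `$pre`/`$post`, `decoding_by_group`,
#'   `manifest_counts`).
#' @export
run_study2 <- function(cfg, out_dir = NULL,
                       families = c("LR", "RF", "NB"),
                       duration_s = 120) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_that(cfg$design == "study2", "run_study2 needs design = 'study2'",
              class = "mmempathy_config_error")
  ratings <- simulate_ratings_study2(cfg)
  hrv <- simulate_hrv_table_study2(cfg, duration_s = duration_s)

  rmean <- stats::aggregate(rating ~ participant + group + valence + time +
                              scale, data = ratings, FUN = mean)
  rwide <- stats::reshape(rmean,
                          idvar = c("participant", "group", "valence",
                                    "time"),
                          timevar = "scale", direction = "wide")
  names(rwide) <- sub("^rating\\.", "rating_", names(rwide))
  rating_cols <- grep("^rating_", names(rwide), value = TRUE)
  hrv_cols <- c("hr", "sdnn", "rmssd", "pnn50", "lf_power", "hf_power",
                "lf_hf", "sampen", "sd1", "sd2", "sd1_sd2")
  keys <- c("participant", "group", "valence")
  rating_changes <- change_scores(
    rwide[rwide$time == "pre", ], rwide[rwide$time == "post", ],
    keys = keys, value_cols = rating_cols)
  hrv_changes <- change_scores(
    hrv[hrv$time == "pre", ], hrv[hrv$time == "post", ],
    keys = keys, value_cols = hrv_cols)

  decoding <- list()
  by_group <- list()
  for (tp in c("pre", "post")) {
    fm <- assemble_features_study2(ratings, hrv, time = tp)
    decoding[[tp]] <- decode_by_subset(fm, character(0), families,
                                       cfg$seed)[[1]]
    by_group[[tp]] <- decode_by_subset(fm, "group", families, cfg$seed)
  }
  counts <- list(
    n_rating_cells_missing = sum(rating_changes$missing),
    n_hrv_cells_missing = sum(hrv_changes$missing)
  )
  bundle <- list(ratings = ratings, hrv = hrv,
                 rating_changes = rating_changes,
                 hrv_changes = hrv_changes, decoding = decoding,
                 decoding_by_group = by_group, manifest_counts = counts,
                 cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ratings(ratings, file.path(out_dir, "ratings.csv"))
    write.csv(hrv, file.path(out_dir, "hrv.csv"), row.names = FALSE)
    write.csv(rating_changes, file.path(out_dir, "rating_changes.csv"),
              row.names = FALSE)
    write.csv(hrv_changes, file.path(out_dir, "hrv_changes.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      lapply(c("pre", "post"), function(tp) {
        list(time = tp,
             overall = decoding[[tp]]$summary[c("accuracy", "kappa",
                                                "macro_auc")],
             by_group = lapply(by_group[[tp]], function(b) {
               c(as.list(b$subset),
                 b$summary[c("accuracy", "kappa", "macro_auc")])
             }))
      }),
      file.path(out_dir, "decoding.json"), auto_unbox = TRUE, digits = NA)
    write_manifest(file.path(out_dir, "manifest.json"), cfg, cfg$seed,
                   counts)
  }
  bundle
}

#' Summarise a pipeline bundle as tidy cell-mean tables
#'
#' Produces the reporting shapes of the analysis: AUC means (+/- SEM) by
#' target and tDCS type, LPP deltas by target and tDCS type, HRV change
#' scores by group, decoding accuracy with its chance line, plus the
#' logged rejection/correction counts. Regenerable deterministically from
#' the bundle.
#'
#' @param bundle output of [run_study1()] or [run_study2()].
#' @return A named list of `data.frame`s.
#' @export
summarize_bundle <- function(bundle) {
  mean_sem <- function(df, value, by) {
    ag <- stats::aggregate(df[[value]], df[by],
                           function(v) c(mean = mean(v, na.rm = TRUE),
                                         sem = sd(v) / sqrt(sum(!is.na(v)))))
    cbind(ag[by], setNames(as.data.frame(ag$x),
                           paste0(value, c("_mean", "_sem"))))
  }
  out <- list(counts = as.data.frame(bundle$manifest_counts))
  if (!is.null(bundle$auc_other)) {     # picture design
    out$auc_other <- mean_sem(bundle$auc_other, "auc", c("target", "tdcs"))
    out$auc_self <- mean_sem(bundle$auc_self, "auc", c("target", "tdcs"))
    out$delta_lpp <- mean_sem(bundle$delta_lpp, "late_lpp_delta",
                              c("target", "tdcs"))
    out$decoding <- do.call(rbind, lapply(bundle$decoding_by_cell,
      function(b) cbind(b$subset,
                        accuracy = b$summary$accuracy,
                        kappa = b$summary$kappa,
                        chance = 50)))
  }
  if (!is.null(bundle$hrv_changes)) {   # narrative design
    for (v in c("sdnn_delta", "rmssd_delta", "sd1_delta")) {
      out[[v]] <- mean_sem(bundle$hrv_changes, v, "group")
    }
    out$decoding <- do.call(rbind, lapply(c("pre", "post"), function(tp) {
      do.call(rbind, lapply(bundle$decoding_by_group[[tp]], function(b) {
        cbind(time = tp, b$subset, accuracy = b$summary$accuracy,
              kappa = b$summary$kappa, chance = 100 / 3)
      }))
    }))
  }
  out
}
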