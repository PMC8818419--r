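# Orchestration of the two end-to-end flows:
#   training:  record -> detect -> segment -> screen -> reduce -> train/CV
#   inference: record -> detect -> segment -> [screen] -> reduce -> predict

#' Pipeline configuration
#'
#' One flat block of the tunable parameters of every stage, with the
#' package defaults filled in.
#'
#' Screening modes: `"within_class"` (default) runs the K = 2 minority
#' screen separately inside each labeled class, so outlier truncations are
#' removed without ever discarding a whole class; the minority cluster of
#' a class is dropped only when its size is below `screen_ratio` times the
#' majority's (a near-even split means the class is homogeneous and K-means
#' is merely bisecting noise).  `"global"` runs one K = 2 screen over all
#' beats and drops the minority cluster outright (the literal rule,
#' appropriate for unlabeled material dominated by one class); `"none"`
#' disables screening.
#'
#' @param window_ms truncation window (ms).
#' @param apply_filters apply periodicity / QRS-duration filters during
#'   segmentation.
#' @param tol_frac periodicity tolerance.
#' @param screen screening mode, see above.
#' @param screen_ratio minority/majority size ratio below which the
#'   within-class minority cluster is discarded (default 0.5).
#' @param delta_j K-means stopping threshold (`NULL` = `1e-4 * width`).
#' @param n_components PCA retention (integer count or variance fraction).
#' @param H RBF hidden-unit count.
#' @param solver RBF weight solver.
#' @param epsilon RMS jump-out accuracy (gradient solver).
#' @param decision_threshold classification threshold.
#' @param k_folds cross-validation fold count.
#' @param seed master RNG seed for all seeded stages.
#' @param detection a [pt_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_ms = 500, apply_filters = FALSE,
                            tol_frac = 0.15,
                            screen = c("within_class", "global", "none"),
                            screen_ratio = 0.5,
                            delta_j = NULL, n_components = 0.95, H = 10,
                            solver = "least_squares", epsilon = 1e-2,
                            decision_threshold = 0.5, k_folds = 5,
                            seed = 1L, detection = pt_config()) {
  structure(list(window_ms = window_ms, apply_filters = apply_filters,
                 tol_frac = tol_frac, screen = match.arg(screen),
                 screen_ratio = screen_ratio,
                 delta_j = delta_j, n_components = n_components, H = H,
                 solver = solver, epsilon = epsilon,
                 decision_threshold = decision_threshold,
                 k_folds = k_folds, seed = seed, detection = detection),
            class = "pipeline_config")
}

# detect + segment one or more records and stack the beat matrices
.records_to_beats <- function(records, cfg) {
  if (inherits(records, "ecg_record")) records <- list(records)
  mats <- lapply(records, function(rec) {
    delin <- delineate_record(rec, config = cfg$detection)
    truncate_beats(rec, delin, window_ms = cfg$window_ms,
                   apply_filters = cfg$apply_filters,
                   tol_frac = cfg$tol_frac)
  })
  rows <- do.call(rbind, lapply(mats, `[[`, "rows"))
  labels <- unlist(lapply(mats, function(m) {
    if (is.null(m$labels)) rep(NA_character_, nrow(m$rows))
    else as.character(m$labels)
  }))
  r_index <- unlist(lapply(mats, function(m) {
    if (is.null(m$r_index)) rep(NA_integer_, nrow(m$rows)) else m$r_index
  }))
  if (all(is.na(labels))) labels <- NULL
  beat_matrix(rows, records[[1]]$fs, labels = labels, r_index = r_index)
}

.screen_beats <- function(beats, cfg) {
  n0 <- nrow(beats$rows)
  if (cfg$screen == "none" || n0 < 4) {
    return(list(kept = beats, n_discarded = 0L))
  }
  if (cfg$screen == "within_class" && !is.null(beats$labels)) {
    kept_sel <- logical(n0)
    for (cl in levels(beats$labels)) {
      sel <- which(!is.na(beats$labels) & beats$labels == cl)
      if (length(sel) < 4) { kept_sel[sel] <- TRUE; next }
      Xc <- beats$rows[sel, , drop = FALSE]
      res <- beats_kmeans(Xc, k = 2, delta_j = cfg$delta_j, seed = cfg$seed)
      sizes <- tabulate(res$assignments, 2)
      # discard the minority cluster only when it is genuinely minority:
      # a near-even split means the class is homogeneous and K = 2 is
      # just bisecting noise, so everything is kept
      if (min(sizes) < cfg$screen_ratio * max(sizes)) {
        keep_id <- which.max(sizes)
        kept_sel[sel[res$assignments == keep_id]] <- TRUE
      } else {
        kept_sel[sel] <- TRUE
      }
    }
    kept <- beat_matrix(beats$rows[kept_sel, , drop = FALSE], beats$fs,
                        labels = beats$labels[kept_sel],
                        r_index = beats$r_index[kept_sel])
    return(list(kept = kept, n_discarded = n0 - sum(kept_sel)))
  }
  res <- beats_kmeans(beats, k = 2, delta_j = cfg$delta_j, seed = cfg$seed)
  scr <- screen_minority(beats, res)
  list(kept = scr$kept, n_discarded = nrow(scr$discarded$rows))
}

#' Run the training flow
#'
#' Executes detection, segmentation, screening, PCA reduction, RBF
#' training and k-fold cross-validated evaluation on one or more annotated
#' records, logging per-stage beat counts.
#'
#' @param records an [ecg_record()] or list of records (all at one
#'   sampling rate, with beat annotations for labels).
#' @param cfg a [pipeline_config()].
#' @return list of class `training_flow`: `beats` (post-screening
#'   [beat_matrix()]), `pca` (`pca_model`), `scores`, `model`
#'   (`rbf_model` trained on all kept beats), `cv` (`cv_result`),
#'   `counts` (per-stage bookkeeping: detected, window-dropped/filtered,
#'   screened out, kept).
#' @export
run_training_flow <- function(records, cfg = pipeline_config()) {
  if (inherits(records, "ecg_record")) records <- list(records)
  n_detected <- 0L
  for (rec in records) {
    n_detected <- n_detected +
      length(delineate_record(rec, config = cfg$detection)$r)
  }
  beats <- .records_to_beats(records, cfg)
  n_segmented <- nrow(beats$rows)
  if (is.null(beats$labels) || all(is.na(beats$labels))) {
    stop_fmt("run_training_flow: records carry no beat labels")
  }
  labeled <- !is.na(beats$labels)
  beats <- beat_matrix(beats$rows[labeled, , drop = FALSE], beats$fs,
                       labels = beats$labels[labeled],
                       r_index = beats$r_index[labeled])
  scr <- .screen_beats(beats, cfg)
  kept <- scr$kept
  pca <- fit_pca(kept, n_components = cfg$n_components)
  scores <- pca_transform(pca, kept)
  cv <- cross_validate(scores, kept$labels, k = cfg$k_folds, H = cfg$H,
                       seed = cfg$seed, solver = cfg$solver,
                       epsilon = cfg$epsilon,
                       decision_threshold = cfg$decision_threshold)
  model <- rbf_train(scores, kept$labels, H = cfg$H, seed = cfg$seed,
                     solver = cfg$solver, epsilon = cfg$epsilon,
                     decision_threshold = cfg$decision_threshold)
  structure(list(beats = kept, pca = pca, scores = scores, model = model,
                 cv = cv,
                 counts = list(detected = n_detected,
                               dropped_window_or_filters = n_detected - n_segmented,
                               unlabeled = n_segmented - sum(labeled),
                               screened_out = scr$n_discarded,
                               kept = nrow(kept$rows))),
            class = "training_flow")
}

#' @export
print.training_flow <- function(x, ...) {
  cts <- x$counts
  cat(sprintf(paste0("<training_flow> %d beats detected, %d dropped ",
                     "(window/filters), %d unlabeled, %d screened out, %d kept\n"),
              cts$detected, cts$dropped_window_or_filters, cts$unlabeled,
              cts$screened_out, cts$kept))
  cat(sprintf("PCA: %d components; RBF: %d hidden units\n",
              x$pca$n_components, length(x$model$widths)))
  print(x$cv)
  invisible(x)
}

#' Run the inference flow
#'
#' Applies saved PCA and RBF models to a new record: detection,
#' segmentation, optional screening, projection, thresholded
#' classification.
#'
#' @param record an [ecg_record()].
#' @param pca a fitted `pca_model`.
#' @param model a trained `rbf_model`.
#' @param cfg a [pipeline_config()]; screening is applied at inference
#'   only when `cfg$screen == "global"` (its training-time default
#'   `"within_class"` needs labels and is skipped here).
#' @return data frame with one row per classified beat: `r_index`,
#'   `score`, `class`.  Zero detected beats yield an empty data frame with
#'   a warning.
#' @export
run_inference_flow <- function(record, pca, model, cfg = pipeline_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(pca, "pca_model"),
            inherits(model, "rbf_model"))
  delin <- delineate_record(record, config = cfg$detection)
  if (length(delin$r) == 0) {
    warning("run_inference_flow: no beats detected")
    return(data.frame(r_index = integer(0), score = numeric(0),
                      class = character(0)))
  }
  beats <- truncate_beats(record, delin, window_ms = cfg$window_ms,
                          apply_filters = cfg$apply_filters,
                          tol_frac = cfg$tol_frac)
  if (cfg$screen == "global" && nrow(beats$rows) >= 4) {
    res <- beats_kmeans(beats, k = 2, delta_j = cfg$delta_j, seed = cfg$seed)
    beats <- screen_minority(beats, res)$kept
  }
  if (nrow(beats$rows) == 0) {
    warning("run_inference_flow: no beats left after segmentation")
    return(data.frame(r_index = integer(0), score = numeric(0),
                      class = character(0)))
  }
  if (ncol(beats$rows) != length(pca$mean)) {
    stop_fmt("run_inference_flow: beat width %d does not match PCA width %d",
             ncol(beats$rows), length(pca$mean))
  }
  scores <- pca_transform(pca, beats)
  s <- rbf_forward(model, scores)
  data.frame(r_index = beats$r_index,
             score = s,
             class = as.character(
               factor(ifelse(s >= model$decision_threshold,
                             "normal", "abnormal"),
                      levels = c("normal", "abnormal"))),
             stringsAsFactors = FALSE)
}
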