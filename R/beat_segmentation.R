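# R-anchored fixed-width beat truncation and the physiological consistency
# filters: beat-period band check, per-beat periodicity of Q/R/S marker
# trains, QRS-duration bounds, and the Q-to-T interval.

#' Estimate the beat period from R-R intervals
#'
#' The period is the median of consecutive R-R intervals (robust to a
#' single dropped or spurious detection).  A resting rhythm corresponds to
#' 600--1000 ms; estimates outside that band are flagged.
#'
#' @param delineation a `qrs_delineation` (needs `>= 2` R peaks).
#' @param fs sampling frequency; defaults to the delineation's.
#' @return list of class `period_estimate`: `T_ms` (median period, ms),
#'   `intervals_ms` (consecutive R-R intervals), `out_of_band` (logical).
#' @export
estimate_period <- function(delineation, fs = delineation$fs) {
  r <- delineation$r
  if (length(r) < 2) {
    stop_fmt("estimate_period: need >= 2 R peaks, got %d", length(r))
  }
  iv <- samples_to_ms(diff(r), fs)
  t_ms <- stats::median(iv)
  structure(list(T_ms = t_ms, intervals_ms = iv,
                 out_of_band = (t_ms < 600 || t_ms > 1000)),
            class = "period_estimate")
}

# consecutive-difference test on one marker train: beat i fails when a
# defined consecutive difference on either side deviates from the period
# by more than tol.  Differences involving an absent (NA) marker are not
# evaluated; `mandatory` additionally fails beats whose own marker is NA.
.train_ok <- function(idx, t_ms, fs, tol_ms, mandatory = FALSE) {
  n <- length(idx)
  ok <- rep(TRUE, n)
  if (n == 0) return(ok)
  if (mandatory) ok[is.na(idx)] <- FALSE
  if (n < 2) return(ok)
  d <- samples_to_ms(diff(idx), fs)         # d[i] = idx[i+1] - idx[i]
  bad <- !is.na(d) & abs(d - t_ms) > tol_ms
  for (i in seq_len(n)) {
    if (i > 1 && bad[i - 1]) ok[i] <- FALSE
    if (i < n && bad[i]) ok[i] <- FALSE
  }
  ok
}

#' Per-beat periodicity check
#'
#' A beat passes when every available consecutive difference among its Q,
#' R and S marker trains is within `tol_frac * T_ms` of the period.  First
#' and last beats are judged only on their defined side.  Exact equality
#' never holds in sampled data, hence the relative tolerance.
#'
#' @param delineation a `qrs_delineation`.
#' @param T_ms beat period in ms (see [estimate_period()]).
#' @param tol_frac relative tolerance (default 0.15).
#' @param fs sampling frequency; defaults to the delineation's.
#' @return logical vector, one entry per beat.
#' @export
check_periodicity <- function(delineation, T_ms, tol_frac = 0.15,
                              fs = delineation$fs) {
  tol_ms <- tol_frac * T_ms
  n <- length(delineation$r)
  if (n == 0) return(logical(0))
  .train_ok(delineation$r, T_ms, fs, tol_ms, mandatory = TRUE) &
    .train_ok(delineation$q, T_ms, fs, tol_ms) &
    .train_ok(delineation$s, T_ms, fs, tol_ms)
}

#' QRS-duration check
#'
#' A beat passes when its QRS duration `S - Q`, in milliseconds, lies in
#' the physiological band `[60, 100]`.  Beats missing either marker fail.
#'
#' @inheritParams check_periodicity
#' @param bounds_ms lower/upper QRS duration bounds (ms).
#' @return logical vector, one entry per beat.
#' @export
check_qrs_duration <- function(delineation, fs = delineation$fs,
                               bounds_ms = c(60, 100)) {
  q <- delineation$q
  s <- delineation$s
  dur <- samples_to_ms(s - q, fs)
  ok <- !is.na(dur) & dur >= bounds_ms[1] & dur <= bounds_ms[2]
  ok[is.na(ok)] <- FALSE
  ok
}

#' Q-to-T interval per beat
#'
#' `rt = (T - Q) * 1000 / fs` in milliseconds; `NA` when either marker is
#' absent.  Tracks ventricular contraction time and hence heart rate.
#'
#' @inheritParams check_periodicity
#' @return numeric vector of intervals in ms.
#' @export
qt_interval <- function(delineation, fs = delineation$fs) {
  samples_to_ms(delineation$t - delineation$q, fs)
}

#' Truncate a record into fixed-width beat windows
#'
#' Cuts the half-open window `[R_i, R_i + m)` with `m = round(0.5 * fs)`
#' samples (500 ms) for every R peak.  Beats whose window overruns the
#' record are dropped.  With `apply_filters = TRUE`, beats failing the
#' periodicity check or the QRS-duration bounds are dropped as well.  When
#' the record carries annotations, each kept row is labeled from the
#' nearest beat annotation within 150 ms.
#'
#' @param record an [ecg_record()].
#' @param delineation a `qrs_delineation` for that record.
#' @param window_ms window width in ms (default 500).
#' @param apply_filters drop beats failing the consistency filters.
#' @param tol_frac periodicity tolerance passed to [check_periodicity()].
#' @return a [beat_matrix()]; `r_index` records each row's source R peak.
#' @export
truncate_beats <- function(record, delineation, window_ms = 500,
                           apply_filters = FALSE, tol_frac = 0.15) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  m <- round(window_ms / 1000 * fs)
  r <- delineation$r
  keep <- rep(TRUE, length(r))
  if (length(r) == 0) {
    return(beat_matrix(matrix(numeric(0), 0, m), fs))
  }
  keep <- (r + m - 1) <= length(record$samples)
  if (apply_filters && length(r) >= 2) {
    per <- estimate_period(delineation, fs)
    keep <- keep &
      check_periodicity(delineation, per$T_ms, tol_frac = tol_frac, fs = fs) &
      check_qrs_duration(delineation, fs = fs)
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    return(beat_matrix(matrix(numeric(0), 0, m), fs))
  }
  rows <- t(vapply(r[idx], function(i) record$samples[i:(i + m - 1L)],
                   numeric(m)))
  labels <- NULL
  ann <- record$annotations
  if (!is.null(ann) && nrow(ann) > 0) {
    ann <- ann[is_beat_symbol(ann$symbol), , drop = FALSE]
    if (nrow(ann) > 0) {
      tol <- ms_to_samples(150, fs)
      labels <- vapply(r[idx], function(ri) {
        d <- abs(ann$sample - ri)
        j <- which.min(d)
        if (d[j] <= tol) as.character(beat_class(ann$symbol[j])) else NA_character_
      }, NA_character_)
    }
  }
  beat_matrix(rows, fs, labels = labels, r_index = r[idx])
}
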