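# Pan-Tompkins QRS detection: integer-coefficient low-/high-pass cascade,
# two-sample derivative, squaring, moving-window integration, and adaptive
# dual-threshold peak search with search-back.
#
# The integer filters realize their 11 Hz / 5 Hz corner frequencies only at
# the 200 Hz design rate, so detection resamples the input to 200 Hz
# (linear interpolation) and maps accepted peak indices back to the
# original sampling grid.

.PT_FS <- 200  # design rate of the integer-coefficient filters (Hz)

.stage_out <- function(samples, stage) {
  structure(list(samples = as.numeric(samples), stage = stage),
            class = "pt_stage")
}

#' Pan-Tompkins filter stages
#'
#' The five causal stages of the detection cascade.  Each preserves input
#' length; samples before the start of the record read as zero (zero-padded
#' warm-up).
#'
#' * `pt_lowpass()`: recursive low-pass
#'   `y(n) = 2 y(n-1) - y(n-2) + x(n) - 2 x(n-6) + x(n-12)`
#'   (11 Hz corner at 200 Hz, DC gain 36, nominal delay 5 samples).
#' * `pt_highpass()`: the delay-based high-pass
#'   `y(n) = x(n-16) - p(n)/32` with the running sum
#'   `p(n) = p(n-1) + x(n) - x(n-32)` (5 Hz corner at 200 Hz, zero DC gain,
#'   nominal delay 16 samples).
#' * `pt_derivative()`: two-sample difference `y(n) = x(n) - x(n-2)`; a
#'   five-point variant `y(n) = (2x(n) + x(n-1) - x(n-3) - 2x(n-4))/8` is
#'   available via `five_point = TRUE`.
#' * `pt_square()`: elementwise square.
#' * `pt_integrate()`: causal moving average over
#'   `round(window_ms * fs / 1000)` samples (default 150 ms).
#'
#' @param x numeric sample vector.
#' @param fs sampling frequency in Hz (only `pt_integrate()` uses it).
#' @param five_point use the five-point derivative instead of the
#'   two-sample difference.
#' @param window_ms integration window in milliseconds.
#' @return a `pt_stage` object with fields `samples` (same length as `x`)
#'   and `stage`.
#' @name pt_filters
NULL

#' @rdname pt_filters
#' @export
pt_lowpass <- function(x, fs = .PT_FS) {
  x <- as.numeric(x)
  if (length(x) == 0) return(.stage_out(numeric(0), "lowpass"))
  xp <- c(numeric(12), x)
  u <- xp[13:length(xp)] - 2 * xp[7:(length(xp) - 6)] + xp[1:(length(xp) - 12)]
  y <- stats::filter(u, c(2, -1), method = "recursive", init = c(0, 0))
  .stage_out(as.numeric(y), "lowpass")
}

#' @rdname pt_filters
#' @export
pt_highpass <- function(x, fs = .PT_FS) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0) return(.stage_out(numeric(0), "highpass"))
  xp <- c(numeric(32), x)
  cs <- cumsum(xp)
  p <- cs[33:length(cs)] - cs[seq_len(n)]   # running sum of the last 32 samples
  x16 <- c(numeric(16), x)[seq_len(n)]
  .stage_out(x16 - p / 32, "highpass")
}

#' @rdname pt_filters
#' @export
pt_derivative <- function(x, five_point = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0) return(.stage_out(numeric(0), "derivative"))
  pad <- function(k) c(numeric(k), x)[seq_len(n)]
  y <- if (five_point) {
    (2 * x + pad(1) - pad(3) - 2 * pad(4)) / 8
  } else {
    x - pad(2)
  }
  .stage_out(y, "derivative")
}

#' @rdname pt_filters
#' @export
pt_square <- function(x) {
  .stage_out(as.numeric(x)^2, "squared")
}

#' @rdname pt_filters
#' @export
pt_integrate <- function(x, fs = .PT_FS, window_ms = 150) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0) return(.stage_out(numeric(0), "integrated"))
  w <- max(1L, ms_to_samples(window_ms, fs))
  cs <- cumsum(c(numeric(w), x))
  y <- (cs[(w + 1):(w + n)] - cs[seq_len(n)]) / w
  .stage_out(y, "integrated")
}

# Full cascade at the design rate; returns all stages.
.pt_cascade <- function(x, fs = .PT_FS, window_ms = 150,
                        five_point = FALSE) {
  lp <- pt_lowpass(x, fs)
  hp <- pt_highpass(lp$samples, fs)
  dv <- pt_derivative(hp$samples, five_point = five_point)
  sq <- pt_square(dv$samples)
  mw <- pt_integrate(sq$samples, fs, window_ms)
  list(lowpass = lp, highpass = hp, derivative = dv, squared = sq,
       integrated = mw)
}

.resample <- function(x, fs_from, fs_to) {
  if (fs_from == fs_to) return(as.numeric(x))
  n_out <- max(2L, round(length(x) * fs_to / fs_from))
  t_out <- (seq_len(n_out) - 1) / fs_to
  stats::approx(x = (seq_along(x) - 1) / fs_from, y = x, xout = t_out,
                rule = 2)$y
}

#' Band-pass an ECG signal with the detector's filter cascade
#'
#' Applies the low-pass and high-pass stages at the 200 Hz design rate,
#' compensates their 21-sample nominal group delay so that deflections stay
#' aligned with the input, and resamples back to the original grid.
#'
#' @param x numeric sample vector.
#' @param fs sampling frequency of `x` in Hz.
#' @return numeric vector, same length as `x`.
#' @export
pt_bandpass <- function(x, fs) {
  x200 <- .resample(x, fs, .PT_FS)
  bp <- pt_highpass(pt_lowpass(x200)$samples)$samples
  bp <- c(bp[-seq_len(min(21L, length(bp)))],
          numeric(min(21L, length(bp))))        # delay compensation
  .resample(bp, .PT_FS, fs)[seq_along(x)]
}

#' Detection configuration
#'
#' Constants of the adaptive dual-threshold search.  Running signal/noise
#' peak estimates are exponential averages with weight `peak_weight` on the
#' newest peak; the acceptance threshold is
#' `noise + threshold_frac * (signal - noise)`; search-back rescans at half
#' that threshold when more than `searchback_factor` times the running
#' average RR interval elapses without a detection.
#'
#' @param window_ms moving-integration window (ms).
#' @param refractory_ms minimum spacing between accepted beats (ms).
#' @param t_wave_ms window after a beat in which a low-slope peak is
#'   rejected as a T wave (ms).
#' @param peak_weight exponential running-estimate weight for new peaks.
#' @param threshold_frac fraction of the signal-noise gap added to the
#'   noise level to form the acceptance threshold.
#' @param searchback_factor multiple of the average RR interval that
#'   triggers search-back.
#' @param five_point use the five-point derivative.
#' @return list of class `pt_config`.
#' @export
pt_config <- function(window_ms = 150, refractory_ms = 200, t_wave_ms = 360,
                      peak_weight = 0.125, threshold_frac = 0.25,
                      searchback_factor = 1.66, five_point = FALSE) {
  structure(list(window_ms = window_ms, refractory_ms = refractory_ms,
                 t_wave_ms = t_wave_ms, peak_weight = peak_weight,
                 threshold_frac = threshold_frac,
                 searchback_factor = searchback_factor,
                 five_point = five_point),
            class = "pt_config")
}

.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Detect R peaks
#'
#' Runs the full Pan-Tompkins cascade at 200 Hz, classifies candidate peaks
#' of the integrated signal with two adaptive thresholds (exponential
#' running signal/noise estimates), applies a refractory period and T-wave
#' slope discrimination, performs a search-back pass at half threshold when
#' an expected beat is missed, and refines each accepted peak first to the
#' band-passed signal and then to the local maximum of the raw signal on
#' the original sampling grid.
#'
#' @param record an [ecg_record()], or a numeric vector (then `fs` is
#'   required).
#' @param fs sampling frequency when `record` is a bare vector.
#' @param config a [pt_config()].
#' @return a `qrs_delineation` object: fields `r` (strictly increasing
#'   R-peak sample indices on the input grid), `q`, `s`, `t` (per-beat
#'   indices, `NA` when absent), `fs`, and `thresholds` (data frame tracing
#'   the running signal/noise/threshold values at each candidate peak).
#' @export
detect_r_peaks <- function(record, fs = NULL, config = pt_config()) {
  if (inherits(record, "ecg_record")) {
    x <- record$samples
    fs <- record$fs
  } else {
    x <- as.numeric(record)
    if (is.null(fs)) stop_fmt("detect_r_peaks: fs required for a bare vector")
  }
  if (length(x) < 2 * fs) {
    stop_fmt("detect_r_peaks: need >= 2 s of signal for the learning phase (got %.2f s)",
             length(x) / fs)
  }
  x200 <- .resample(x, fs, .PT_FS)
  stages <- .pt_cascade(x200, .PT_FS, config$window_ms, config$five_point)
  y <- stages$integrated$samples
  dv <- stages$derivative$samples
  refractory <- ms_to_samples(config$refractory_ms, .PT_FS)
  twave_win <- ms_to_samples(config$t_wave_ms, .PT_FS)

  cand <- .local_maxima(y)
  if (length(cand) == 0 || max(y) <= 0) {
    return(.delineation(integer(0), fs, trace = NULL))
  }

  # learning phase: first 2 s initialize the running estimates
  learn <- y[seq_len(2 * .PT_FS)]
  spk <- max(learn)
  npk <- mean(learn)
  w <- config$peak_weight
  thr <- function() npk + config$threshold_frac * (spk - npk)

  accepted <- integer(0)
  acc_slope <- numeric(0)
  rr_hist <- numeric(0)
  trace <- vector("list", length(cand))
  slope_at <- function(p) max(abs(dv[max(1, p - 15):p]))

  accept_peak <- function(p) {
    accepted <<- c(accepted, p)
    acc_slope <<- c(acc_slope, slope_at(p))
    if (length(accepted) >= 2) {
      rr <- diff(utils::tail(accepted, 2))
      rr_hist <<- utils::tail(c(rr_hist, rr), 8)
    }
  }

  for (j in seq_along(cand)) {
    p <- cand[j]
    pk <- y[p]
    is_signal <- FALSE
    if (length(accepted) > 0 && p - accepted[length(accepted)] < refractory) {
      trace[[j]] <- c(p, pk, spk, npk, thr(), 0)
      next  # inside refractory: ignore entirely
    }
    if (pk > thr()) {
      is_signal <- TRUE
      # T-wave discrimination: close to previous beat with less than half
      # its slope -> noise
      if (length(accepted) > 0 &&
          p - accepted[length(accepted)] < twave_win &&
          slope_at(p) < 0.5 * acc_slope[length(acc_slope)]) {
        is_signal <- FALSE
      }
    }
    if (is_signal) {
      spk <- w * pk + (1 - w) * spk
      accept_peak(p)
    } else {
      npk <- w * pk + (1 - w) * npk
      # search-back: expected beat overdue -> rescan at half threshold
      if (length(accepted) > 0 && length(rr_hist) > 0) {
        rr_avg <- mean(rr_hist)
        if (p - accepted[length(accepted)] > config$searchback_factor * rr_avg) {
          seg <- cand[cand > accepted[length(accepted)] + refractory & cand <= p]
          seg <- seg[y[seg] > thr() / 2]
          if (length(seg) > 0) {
            pb <- seg[which.max(y[seg])]
            spk <- 0.25 * y[pb] + 0.75 * spk
            accept_peak(pb)
            accepted <- sort(accepted)
          }
        }
      }
    }
    trace[[j]] <- c(p, pk, spk, npk, thr(), as.numeric(is_signal))
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  trace <- as.data.frame(trace)
  names(trace) <- c("peak_index", "peak_value", "signal_level", "noise_level",
                    "threshold", "accepted")

  if (length(accepted) == 0) {
    return(.delineation(integer(0), fs, trace = trace))
  }

  # refine: integrated peak -> band-passed peak (undo ~ filter + window
  # delay), then map to the original grid and snap to the raw local maximum
  bp <- stages$highpass$samples
  w200 <- ms_to_samples(config$window_ms, .PT_FS)
  r200 <- vapply(sort(unique(accepted)), function(p) {
    lo <- max(1L, p - w200 - 10L)
    as.integer(lo + which.max(bp[lo:p]) - 1L)
  }, integer(1))
  r200 <- pmax(1L, r200 - 21L)  # undo the low+high-pass nominal group delay
  r_orig <- round((r200 - 1) * fs / .PT_FS) + 1
  half <- ms_to_samples(40, fs)
  r <- vapply(r_orig, function(p) {
    lo <- max(1L, p - half)
    hi <- min(length(x), p + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  r <- sort(unique(r))
  # enforce the refractory period on the final grid
  if (length(r) > 1) {
    keep <- c(TRUE, diff(r) >= ms_to_samples(config$refractory_ms, fs))
    while (!all(keep)) {
      r <- r[keep]
      keep <- c(TRUE, diff(r) >= ms_to_samples(config$refractory_ms, fs))
    }
  }
  .delineation(r, fs, trace = trace)
}

.delineation <- function(r, fs, q = NULL, s = NULL, t = NULL, trace = NULL) {
  n <- length(r)
  blank <- rep(NA_integer_, n)
  structure(list(r = as.integer(r), q = if (is.null(q)) blank else q,
                 s = if (is.null(s)) blank else s,
                 t = if (is.null(t)) blank else t,
                 fs = fs, thresholds = trace),
            class = "qrs_delineation")
}

#' @export
print.qrs_delineation <- function(x, ...) {
  cat(sprintf("<qrs_delineation> %d R peaks @ %g Hz (%d delineated Q/S)\n",
              length(x$r), x$fs, sum(!is.na(x$q) & !is.na(x$s))))
  invisible(x)
}

#' Delineate Q, S and T waves around known R peaks
#'
#' Q is the minimum on `(R - 80 ms, R)`, S the minimum on `(R, R + 80 ms)`,
#' and T the largest-magnitude sample on `(S + 40 ms, R + 400 ms)` clipped
#' at the next R peak.  A wave whose search window would leave the record
#' is reported absent (`NA`) for that beat.
#'
#' @param x_bandpassed band-passed (or clean) signal the windows are
#'   evaluated on, e.g. from [pt_bandpass()].
#' @param r_indices strictly increasing R-peak sample indices.
#' @param fs sampling frequency in Hz.
#' @return `qrs_delineation` with `q`, `s`, `t` filled in.
#' @export
delineate_qst <- function(x_bandpassed, r_indices, fs) {
  x <- as.numeric(x_bandpassed)
  n <- length(x)
  r <- as.integer(r_indices)
  if (length(r) > 1 && is.unsorted(r, strictly = TRUE)) {
    stop_fmt("delineate_qst: r_indices must be strictly increasing")
  }
  w80 <- ms_to_samples(80, fs)
  w40 <- ms_to_samples(40, fs)
  w400 <- ms_to_samples(400, fs)
  q <- s <- tt <- rep(NA_integer_, length(r))
  for (i in seq_along(r)) {
    ri <- r[i]
    if (ri - w80 >= 1) {
      win <- (ri - w80):(ri - 1)
      q[i] <- win[which.min(x[win])]
    }
    if (ri + w80 <= n) {
      win <- (ri + 1):(ri + w80)
      s[i] <- win[which.min(x[win])]
    }
    if (!is.na(s[i])) {
      lo <- s[i] + w40
      hi <- ri + w400
      if (i < length(r)) hi <- min(hi, r[i + 1] - 1)
      hi <- min(hi, n)
      if (lo <= hi) {
        win <- lo:hi
        tt[i] <- win[which.max(abs(x[win]))]
      }
    }
  }
  .delineation(r, fs, q = q, s = s, t = tt)
}

#' Detect and delineate in one call
#'
#' Convenience wrapper: [detect_r_peaks()] followed by [delineate_qst()] on
#' the delay-compensated band-passed signal.
#'
#' @inheritParams detect_r_peaks
#' @return `qrs_delineation` with R, Q, S, T indices.
#' @export
delineate_record <- function(record, fs = NULL, config = pt_config()) {
  det <- detect_r_peaks(record, fs, config)
  x <- if (inherits(record, "ecg_record")) record$samples else as.numeric(record)
  fs <- det$fs
  if (length(det$r) == 0) return(det)
  bp <- pt_bandpass(x, fs)
  out <- delineate_qst(bp, det$r, fs)
  out$thresholds <- det$thresholds
  out
}
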