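#' Synthesis configuration for the ECG generator
#'
#' Bundles the parameters of the Gaussian-bump beat model and its noise
#' terms.  The defaults describe a resting adult rhythm sampled at the
#' MIT-BIH rate: beat periods inside the 600--1000 ms band (60--100 bpm)
#' and a normal QRS duration inside 60--100 ms.  Noise terms model the two
#' dominant contaminants of surface ECG: narrowband powerline interference
#' (50 Hz) and low-frequency baseline wander (0.05--2 Hz), plus white
#' sensor noise.
#'
#' @param fs sampling frequency in Hz.
#' @param duration_s record duration in seconds; must cover at least one
#'   beat period.
#' @param heart_rate_bpm heart rate, beats per minute (60--120 supported).
#' @param qrs_width_ms QRS duration of normal beats, ms (60--100).
#' @param abnormal_fraction fraction of beats drawn as the abnormal
#'   (ventricular-like) morphology, in `[0, 1]`.
#' @param powerline_amp amplitude (mV) of the powerline sinusoid.
#' @param powerline_hz powerline frequency, default 50 Hz.
#' @param baseline_amp amplitude (mV) of the baseline-wander sinusoid.
#' @param baseline_hz baseline-wander frequency in `[0.05, 2]` Hz.
#' @param white_sigma standard deviation (mV) of additive white noise.
#' @param seed integer RNG seed; identical seeds give identical records.
#' @return a list of class `synthesis_config`.
#' @export
synthesis_config <- function(fs = 360, duration_s = 30, heart_rate_bpm = 75,
                             qrs_width_ms = 80, abnormal_fraction = 0,
                             powerline_amp = 0.05, powerline_hz = 50,
                             baseline_amp = 0.1, baseline_hz = 0.3,
                             white_sigma = 0.02, seed = 1L) {
  if (heart_rate_bpm < 60 || heart_rate_bpm > 120) {
    stop_fmt("synthesis_config: heart_rate_bpm %g outside [60, 120]",
             heart_rate_bpm)
  }
  if (qrs_width_ms < 60 || qrs_width_ms > 100) {
    stop_fmt("synthesis_config: qrs_width_ms %g outside [60, 100]",
             qrs_width_ms)
  }
  if (abnormal_fraction < 0 || abnormal_fraction > 1) {
    stop_fmt("synthesis_config: abnormal_fraction outside [0, 1]")
  }
  if (baseline_hz < 0.05 || baseline_hz > 2) {
    stop_fmt("synthesis_config: baseline_hz %g outside [0.05, 2]", baseline_hz)
  }
  structure(list(fs = fs, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm,
                 qrs_width_ms = qrs_width_ms,
                 abnormal_fraction = abnormal_fraction,
                 powerline_amp = powerline_amp, powerline_hz = powerline_hz,
                 baseline_amp = baseline_amp, baseline_hz = baseline_hz,
                 white_sigma = white_sigma, seed = seed),
            class = "synthesis_config")
}

# Per-beat Gaussian bump parameters, times in ms relative to the R peak.
# R is the narrowest, largest-magnitude deflection by construction; Q and S
# flank it so that the delineated S - Q span equals the configured QRS
# duration.  The abnormal morphology widens the QRS to 140 ms and inverts
# the T wave, mimicking a ventricular ectopic beat.
.beat_bumps <- function(qrs_ms, abnormal = FALSE) {
  if (abnormal) {
    qrs_ms <- 140
    t_amp <- -0.3
    r_amp <- 0.85
  } else {
    t_amp <- 0.3
    r_amp <- 1.0
  }
  data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    center = c(-180, -0.45 * qrs_ms, 0, 0.55 * qrs_ms, 300),
    sigma  = c(25, qrs_ms / 12, qrs_ms / 10, qrs_ms / 12, 60),
    amp    = c(0.15, -0.15, r_amp, -0.25, t_amp)
  )
}

#' Generate a synthetic single-lead ECG record
#'
#' Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) on a periodic
#' R-peak grid; the R bump is strictly the narrowest and largest, so in a
#' noiseless record the per-beat amplitude maximum coincides with the
#' annotated R index.  Abnormal beats (symbol `"V"`) widen the QRS to
#' 140 ms and invert the T wave.  Powerline, baseline-wander and white
#' noise are added as configured.  Output is deterministic in the seed.
#'
#' @param cfg a [synthesis_config()].
#' @return [ecg_record()] with annotations at the true R peaks (`"N"` or
#'   `"V"`).
#' @export
generate_record <- function(cfg) {
  stopifnot(inherits(cfg, "synthesis_config"))
  fs <- cfg$fs
  period_s <- 60 / cfg$heart_rate_bpm
  if (cfg$duration_s < period_s) {
    stop_fmt("generate_record: duration %.2f s shorter than one beat period %.2f s",
             cfg$duration_s, period_s)
  }
  n <- round(cfg$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  first_r <- 0.35                      # leave room for the P wave
  r_times <- seq(first_r, cfg$duration_s - 0.45, by = period_s)
  n_beats <- length(r_times)
  with_seed(cfg$seed, {
    abn <- stats::runif(n_beats) < cfg$abnormal_fraction
    x <- numeric(n)
    for (k in seq_len(n_beats)) {
      bumps <- .beat_bumps(cfg$qrs_width_ms, abn[k])
      ctr <- r_times[k] + bumps$center / 1000
      sd_s <- bumps$sigma / 1000
      lo <- max(1L, floor((r_times[k] - 0.5) * fs))
      hi <- min(n, ceiling((r_times[k] + 0.6) * fs))
      idx <- lo:hi
      for (b in seq_len(nrow(bumps))) {
        x[idx] <- x[idx] +
          bumps$amp[b] * exp(-((t[idx] - ctr[b])^2) / (2 * sd_s[b]^2))
      }
    }
    if (cfg$powerline_amp > 0) {
      x <- x + cfg$powerline_amp * sin(2 * pi * cfg$powerline_hz * t)
    }
    if (cfg$baseline_amp > 0) {
      x <- x + cfg$baseline_amp * sin(2 * pi * cfg$baseline_hz * t)
    }
    if (cfg$white_sigma > 0) {
      x <- x + stats::rnorm(n, sd = cfg$white_sigma)
    }
    ann <- data.frame(sample = round(r_times * fs) + 1L,
                      symbol = ifelse(abn, "V", "N"),
                      stringsAsFactors = FALSE)
    ecg_record(x, fs, lead_name = "synthetic", annotations = ann)
  })
}

#' Generate a labeled table of truncated beats
#'
#' Builds a synthetic record containing exactly `n_normal + n_abnormal`
#' beats whose class sequence is a seeded permutation, then cuts the
#' half-open window `[R, R + width)` around each true R peak.  At the
#' default settings the two class morphologies are separable: the
#' between-class mean distance exceeds the within-class mean distance.
#'
#' @param n_normal,n_abnormal beat counts per class; total must be `>= 1`.
#' @param width window width in samples.
#' @param cfg a [synthesis_config()]; its `abnormal_fraction` is ignored in
#'   favor of the exact requested counts.
#' @return a labeled [beat_matrix()] with `n_normal + n_abnormal` rows.
#' @export
generate_beat_table <- function(n_normal, n_abnormal, width,
                                cfg = synthesis_config()) {
  total <- n_normal + n_abnormal
  if (total < 1) stop_fmt("generate_beat_table: zero beats requested")
  if (width <= 0) stop_fmt("generate_beat_table: width must be positive")
  period_s <- 60 / cfg$heart_rate_bpm
  need_s <- 0.35 + total * period_s + 0.6 + width / cfg$fs
  cfg2 <- cfg
  cfg2$duration_s <- need_s
  cfg2$abnormal_fraction <- 0   # class sequence assigned below instead
  rec <- generate_record(cfg2)
  r_idx <- rec$annotations$sample
  if (length(r_idx) < total) {
    stop_fmt("generate_beat_table: internal error, %d beats generated for %d requested",
             length(r_idx), total)
  }
  r_idx <- r_idx[seq_len(total)]
  classes <- with_seed(cfg$seed,
                       sample(rep(c(FALSE, TRUE), c(n_normal, n_abnormal))))
  # regenerate with the chosen per-beat morphology: rebuild bump sums for
  # abnormal beats by subtracting the normal beat and adding the abnormal one
  fs <- cfg$fs
  n <- length(rec$samples)
  t <- (seq_len(n) - 1) / fs
  x <- rec$samples
  for (k in which(classes)) {
    rt <- (r_idx[k] - 1) / fs
    lo <- max(1L, floor((rt - 0.5) * fs))
    hi <- min(n, ceiling((rt + 0.6) * fs))
    idx <- lo:hi
    for (mode in c("sub", "add")) {
      bumps <- .beat_bumps(cfg$qrs_width_ms, abnormal = (mode == "add"))
      sgn <- if (mode == "add") 1 else -1
      ctr <- rt + bumps$center / 1000
      sd_s <- bumps$sigma / 1000
      for (b in seq_len(nrow(bumps))) {
        x[idx] <- x[idx] +
          sgn * bumps$amp[b] * exp(-((t[idx] - ctr[b])^2) / (2 * sd_s[b]^2))
      }
    }
  }
  rows <- t(vapply(r_idx, function(i) x[i:(i + width - 1L)], numeric(width)))
  beat_matrix(rows, fs,
              labels = ifelse(classes, "abnormal", "normal"),
              r_index = r_idx)
}
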