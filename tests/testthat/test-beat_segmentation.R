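make_delin <- function(r, fs = 360, q = NULL, s = NULL, t = NULL) {
  ecgflow:::.delineation(r, fs, q = q, s = s, t = t)
}

test_that("period estimation is the median R-R interval", {
  d <- make_delin(c(1L, 361L, 721L), fs = 360)
  pe <- estimate_period(d)
  expect_equal(pe$T_ms, 1000)
  expect_false(pe$out_of_band)

  # one dropout: median robust
  r <- cumsum(c(1, 800, 800, 2000) * 360 / 1000)
  pe2 <- estimate_period(make_delin(as.integer(r), fs = 360))
  expect_equal(pe2$T_ms, 800)

  expect_error(estimate_period(make_delin(5L)), ">= 2 R peaks")
  pe3 <- estimate_period(make_delin(c(1L, 100L, 199L), fs = 360))
  expect_true(pe3$out_of_band)
})

test_that("periodicity mask passes periodic trains and flags displacements", {
  fs <- 360
  r <- seq(1L, by = 360L, length.out = 8)
  d <- make_delin(r, fs)
  expect_true(all(check_periodicity(d, 1000)))

  # displace one beat by 0.3 T: it and its neighbor fail
  r2 <- r
  r2[4] <- r2[4] + round(0.3 * 360)
  mask <- check_periodicity(make_delin(r2, fs), 1000)
  expect_false(mask[4])
  expect_false(mask[5])   # the 4->5 interval is shortened by 0.3 T
  expect_false(mask[3])   # the 3->4 interval is lengthened by 0.3 T
  expect_true(all(mask[c(1, 2, 6, 7, 8)]))

  # two-beat record: each judged on its single defined side
  m2 <- check_periodicity(make_delin(c(1L, 361L), fs), 1000)
  expect_true(all(m2))
  m3 <- check_periodicity(make_delin(c(1L, 181L), fs), 1000)
  expect_false(any(m3))
})

test_that("periodicity also audits the Q and S trains when present", {
  fs <- 360
  r <- seq(100L, by = 360L, length.out = 5)
  q <- r - 13L
  s <- r + 16L
  d <- make_delin(r, fs, q = q, s = s)
  expect_true(all(check_periodicity(d, 1000)))
  q2 <- q
  q2[3] <- q2[3] + 150L   # Q train breaks periodicity around beat 3
  mask <- check_periodicity(make_delin(r, fs, q = q2, s = s), 1000)
  expect_false(mask[3])
})

test_that("mask loosening is monotone in the tolerance", {
  set.seed(4)
  r <- as.integer(cumsum(c(100, round(360 * runif(10, 0.8, 1.2)))))
  d <- make_delin(r, 360)
  m_tight <- check_periodicity(d, 1000, tol_frac = 0.10)
  m_loose <- check_periodicity(d, 1000, tol_frac = 0.30)
  expect_true(all(m_loose[m_tight]))
})

test_that("QRS duration gate applies the 60-100 ms band", {
  fs <- 360
  d <- make_delin(c(100L, 460L), fs,
                  q = c(71L, NA), s = c(100L, 490L))
  # beat 1: 29 samples = 80.6 ms -> pass; beat 2: missing Q -> fail
  expect_equal(check_qrs_duration(d), c(TRUE, FALSE))
  d2 <- make_delin(100L, fs, q = 50L, s = 100L)   # 138.9 ms -> fail
  expect_false(check_qrs_duration(d2))
  d3 <- make_delin(100L, fs, q = 90L, s = 108L)   # 50 ms -> fail (short)
  expect_false(check_qrs_duration(d3))
})

test_that("Q-to-T interval arithmetic and monotonicity in the T position", {
  fs <- 360
  d <- make_delin(50L, fs, q = 1L, t = 145L)
  expect_equal(qt_interval(d), 400)
  d2 <- make_delin(50L, fs, q = 1L, t = NA_integer_)
  expect_true(is.na(qt_interval(d2)))
  # delineating hand-built beats: moving the T bump later lengthens rt
  bump <- function(t0, amp, sd, n, fs) {
    tt <- (seq_len(n) - 1) / fs
    amp * exp(-((tt - t0)^2) / (2 * sd^2))
  }
  beat_at <- function(t_off) {
    n <- 2 * fs
    bump(0.5, 1, 0.01, n, fs) + bump(0.46, -0.2, 0.008, n, fs) +
      bump(0.54, -0.2, 0.008, n, fs) + bump(0.5 + t_off, 0.3, 0.05, n, fs)
  }
  r <- as.integer(round(0.5 * fs) + 1)
  rt_near <- qt_interval(delineate_qst(beat_at(0.25), r, fs))
  rt_far <- qt_interval(delineate_qst(beat_at(0.35), r, fs))
  expect_gt(rt_far, rt_near)
})

test_that("truncation cuts 500 ms windows and drops overruns", {
  fs <- 360
  cfg <- quiet_config(duration_s = 10, heart_rate_bpm = 60, fs = fs)
  rec <- generate_record(cfg)
  del <- delineate_record(rec)
  bm <- truncate_beats(rec, del)
  expect_equal(ncol(bm$rows), round(0.5 * fs))
  # last annotated beat at 3367 + 180 <= 3600: all 10 fit
  expect_equal(nrow(bm$rows), 10)
  expect_true(all(bm$labels == "normal"))

  # shorten the record so the last window overruns -> that beat is dropped
  rec2 <- ecg_record(rec$samples[1:(max(del$r) + round(0.1 * fs))], fs,
                     annotations = rec$annotations)
  bm2 <- truncate_beats(rec2, del)
  expect_equal(nrow(bm2$rows), 9)

  # window width is a pure function of fs
  for (f2 in c(128, 250, 360, 500)) {
    r0 <- ecg_record(sin(seq_len(f2 * 3) / 5), f2)
    d0 <- ecgflow:::.delineation(c(f2, 2L * f2), f2)
    expect_equal(ncol(truncate_beats(r0, d0)$rows), round(0.5 * f2))
  }
})

test_that("consistency filters remove wide-QRS beats from a mixed record", {
  cfg <- synthesis_config(fs = 360, duration_s = 14, heart_rate_bpm = 60,
                          abnormal_fraction = 0.3, powerline_amp = 0,
                          baseline_amp = 0, white_sigma = 0, seed = 12)
  rec <- generate_record(cfg)
  stopifnot(any(rec$annotations$symbol == "V"),
            any(rec$annotations$symbol == "N"))
  del <- delineate_qst(rec$samples, rec$annotations$sample, rec$fs)
  filtered <- truncate_beats(rec, del, apply_filters = TRUE)
  plain <- truncate_beats(rec, del, apply_filters = FALSE)
  wide <- rec$annotations$symbol == "V"
  # every abnormal (140 ms QRS) beat fails the duration gate
  expect_true(all(!rec$annotations$sample[wide] %in% filtered$r_index))
  expect_true(all(filtered$labels == "normal"))
  expect_gt(nrow(plain$rows), nrow(filtered$rows))
})

test_that("labels attach only within the 150 ms matching window", {
  fs <- 360
  x <- numeric(4 * fs)
  ann <- data.frame(sample = c(400L, 1200L), symbol = c("N", "V"))
  rec <- ecg_record(x, fs, annotations = ann)
  del <- ecgflow:::.delineation(c(405L, 900L), fs)
  bm <- truncate_beats(rec, del)
  expect_equal(as.character(bm$labels), c("normal", NA))
})
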