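test_that("record constructor enforces its invariants", {
  expect_error(ecg_record(numeric(0), 360), "non-empty")
  expect_error(ecg_record(1:10, 0), "positive")
  expect_error(ecg_record(1:10, 360,
                          annotations = data.frame(sample = 11, symbol = "N")),
               "outside")
  expect_error(ecg_record(1:10, 360,
                          annotations = data.frame(sample = c(5, 5),
                                                   symbol = c("N", "N"))),
               "strictly increasing")
  rec <- ecg_record(c(0, 1, 0), 360)
  expect_s3_class(rec, "ecg_record")
  expect_equal(length(rec$samples), 3)
})

test_that("label collapse is total on beat symbols and excludes non-beats", {
  beats <- c("N", "S", "V", "F", "Q")
  cls <- beat_class(beats)
  expect_false(anyNA(cls))
  expect_equal(as.character(cls), c("normal", rep("abnormal", 4)))
  nonbeats <- c("U", "X", "O", "+", "~")
  expect_true(all(is.na(beat_class(nonbeats))))
  expect_equal(is_beat_symbol(c(beats, nonbeats)),
               rep(c(TRUE, FALSE), c(5, 5)))
})

test_that("CSV records parse, reject bad lines, and round-trip exactly", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0", "1", "0"), p)
  rec <- read_csv_record(p, fs = 360)
  expect_equal(rec$samples, c(0, 1, 0))
  expect_equal(rec$fs, 360)

  writeLines(character(0), p)
  expect_error(read_csv_record(p, 360), "no samples")

  writeLines(c("0", "oops", "1"), p)
  expect_error(read_csv_record(p, 360), "line 2")

  cfg <- noisy_config(duration_s = 5, seed = 3,
                      abnormal_fraction = 0.5)
  orig <- generate_record(cfg)
  write_csv_record(orig, p)
  back <- read_csv_record(p, orig$fs)
  expect_identical(back$samples, orig$samples)
  expect_identical(back$annotations$sample, orig$annotations$sample)
  expect_identical(back$annotations$symbol, orig$annotations$symbol)
})

test_that("WFDB triplets round-trip within ADC quantization", {
  stem <- file.path(withr::local_tempdir(), "rec01")
  cfg <- noisy_config(duration_s = 6, heart_rate_bpm = 75, seed = 5,
                      abnormal_fraction = 0.3)
  orig <- generate_record(cfg)
  write_wfdb_record(orig, stem, gain = 200)
  back <- read_wfdb_record(stem)
  expect_equal(back$fs, orig$fs)
  expect_equal(length(back$samples), length(orig$samples))
  # format 212 at gain 200: half a quantization step is 1/400 mV
  expect_lt(max(abs(back$samples - orig$samples)), 1 / 400 + 1e-12)
  expect_identical(back$annotations$sample, orig$annotations$sample)
  expect_identical(back$annotations$symbol, orig$annotations$symbol)
  expect_equal(back$units_per_mv, 200)
})

test_that("WFDB reader reports missing and malformed inputs", {
  d <- withr::local_tempdir()
  expect_error(read_wfdb_record(file.path(d, "ghost")), "missing header")
  stem <- file.path(d, "rec02")
  rec <- ecg_record(sin(seq(0, 20, length.out = 800)), fs = 360)
  write_wfdb_record(rec, stem)
  expect_error(read_wfdb_record(stem, channel = 2), "channel 2")
  # annotation beyond the signal end is an invariant violation
  writeLines(c("rec03 1 360 10", "rec03.dat 212 200(0)/mV 12 0 0 0 0 MLII"),
             file.path(d, "rec03.hea"))
  writeBin(as.raw(rep(0, 15)), file.path(d, "rec03.dat"))
  ecgflow:::.write_atr(data.frame(sample = 50, symbol = "N"),
                       file.path(d, "rec03.atr"))
  expect_error(read_wfdb_record(file.path(d, "rec03")), "beyond")
})

test_that("long annotation gaps survive the .atr SKIP encoding", {
  d <- withr::local_tempdir()
  ann <- data.frame(sample = c(100L, 80000L, 80500L),
                    symbol = c("N", "V", "N"))
  ecgflow:::.write_atr(ann, file.path(d, "skip.atr"))
  back <- ecgflow:::.read_atr(file.path(d, "skip.atr"))
  expect_identical(back$sample, ann$sample)
  expect_identical(back$symbol, ann$symbol)
})

test_that("beat matrices round-trip bitwise through text", {
  p <- withr::local_tempfile()
  set.seed(42)
  m <- matrix(rnorm(6 * 9), 6, 9)
  bm <- beat_matrix(m, fs = 360,
                    labels = rep(c("normal", "abnormal"), 3))
  write_beat_matrix(bm, p)
  back <- read_beat_matrix(p, 360)
  expect_identical(back$rows, bm$rows, ignore_attr = TRUE)
  expect_equal(as.character(back$labels), as.character(bm$labels))

  # unlabeled, 2 beats of width 3 -> 2 lines x 3 fields
  bm2 <- beat_matrix(matrix(1:6, 2, 3, byrow = TRUE), fs = 360)
  write_beat_matrix(bm2, p)
  expect_equal(lengths(strsplit(readLines(p), ",")), c(3, 3))

  # empty matrix round-trips to an empty matrix
  bm0 <- beat_matrix(matrix(numeric(0), 0, 5), fs = 360)
  write_beat_matrix(bm0, p)
  expect_equal(nrow(read_beat_matrix(p, 360)$rows), 0)

  writeLines(c("1,2,3", "1,2"), p)
  expect_error(read_beat_matrix(p, 360), "ragged")
})

test_that("beat_matrix rejects mismatched metadata", {
  expect_error(beat_matrix(matrix(0, 2, 3), 360, labels = "normal"),
               "labels")
  expect_error(beat_matrix(matrix(0, 2, 3), 360, r_index = 1L), "r_index")
})
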