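#' Construct a single-lead ECG record
#'
#' The pipeline's normalized record container: a real-valued amplitude
#' sequence (millivolts when gain is known, ADC units otherwise), its
#' sampling frequency, and optional reference beat annotations.
#'
#' All sample indices in this package are 1-based and windows are half-open
#' `[start, end)` in the sense that a window of width `m` anchored at index
#' `i` covers `i, i + 1, ..., i + m - 1`.
#'
#' @param samples numeric vector of amplitudes; must be non-empty.
#' @param fs sampling frequency in Hz, `> 0`.
#' @param lead_name lead label, e.g. `"MLII"` or `"LA"`.
#' @param annotations optional `data.frame` with columns `sample` (1-based
#'   index into `samples`, strictly increasing) and `symbol` (one-character
#'   beat / non-beat code, e.g. `"N"`, `"V"`).
#' @param units_per_mv optional ADC gain (ADC units per millivolt).
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, lead_name = "MLII", annotations = NULL,
                       units_per_mv = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop_fmt("ecg_record: samples must be non-empty")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop_fmt("ecg_record: fs must be a single positive number, got %s",
             paste(fs, collapse = ","))
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (!all(c("sample", "symbol") %in% names(annotations))) {
      stop_fmt("ecg_record: annotations need columns 'sample' and 'symbol'")
    }
    annotations$sample <- as.integer(annotations$sample)
    annotations$symbol <- as.character(annotations$symbol)
    if (nrow(annotations) > 0) {
      if (any(annotations$sample < 1) ||
          any(annotations$sample > length(samples))) {
        stop_fmt("ecg_record: annotation sample index outside [1, %d]",
                 length(samples))
      }
      if (is.unsorted(annotations$sample, strictly = TRUE)) {
        stop_fmt("ecg_record: annotation samples must be strictly increasing")
      }
    }
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), lead_name = lead_name,
         annotations = annotations, units_per_mv = units_per_mv),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> lead %s: %d samples @ %g Hz (%.1f s), %d annotations\n",
              x$lead_name, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Beat labels

.beat_symbols    <- c("N", "S", "V", "F", "Q")
.nonbeat_symbols <- c("U", "X", "O", "+", "~", "|", "\"", "[", "]", "!")

#' Collapse beat symbols to binary classes
#'
#' Beat symbols follow the AAMI alphabet: `N` (normal), `S`
#' (supraventricular), `V` (ventricular), `F` (fusion), `Q` (unclassifiable).
#' `N` maps to `"normal"`; every other beat symbol maps to `"abnormal"`.
#' Non-beat symbols (`U`, `X`, `O` and rhythm/quality codes) carry no class
#' and come back as `NA`; they are excluded from beat sets.
#'
#' @param symbols character vector of annotation symbols.
#' @return factor with levels `c("normal", "abnormal")`; `NA` for non-beat
#'   symbols.
#' @export
beat_class <- function(symbols) {
  out <- ifelse(symbols == "N", "normal",
                ifelse(symbols %in% .beat_symbols, "abnormal", NA_character_))
  factor(out, levels = c("normal", "abnormal"))
}

#' @rdname beat_class
#' @export
is_beat_symbol <- function(symbols) symbols %in% .beat_symbols

# ---------------------------------------------------------------------------
# CSV record dialect: one numeric sample per line, optional second field
# holding an annotation symbol anchored at that sample.

#' Read an ECG record from CSV
#'
#' One numeric sample per line; an optional second comma-separated field
#' carries an annotation symbol at that sample.  Blank lines are ignored.
#'
#' @param path file path.
#' @param fs sampling frequency in Hz (CSV carries no header).
#' @param lead_name lead label for the returned record.
#' @return [ecg_record()]
#' @export
read_csv_record <- function(path, fs, lead_name = "MLII") {
  if (!file.exists(path)) stop_fmt("read_csv_record: no such file: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) stop_fmt("read_csv_record: no samples in %s", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1]]
    stop_fmt("read_csv_record: non-numeric sample at line %d of %s", bad, path)
  }
  has_sym <- vapply(parts, function(p) length(p) >= 2 && nzchar(trimws(p[2])),
                    logical(1))
  ann <- NULL
  if (any(has_sym)) {
    ann <- data.frame(sample = which(has_sym),
                      symbol = vapply(parts[has_sym],
                                      function(p) trimws(p[2]), ""),
                      stringsAsFactors = FALSE)
  }
  ecg_record(vals, fs, lead_name = lead_name, annotations = ann)
}

#' Write an ECG record to CSV
#'
#' Inverse of [read_csv_record()]: one sample per line, with the annotation
#' symbol appended as a second field on annotated samples.
#'
#' @param record an [ecg_record()].
#' @param path output file path.
#' @export
write_csv_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  lines <- format(record$samples, digits = 17, trim = TRUE, scientific = FALSE)
  ann <- record$annotations
  if (!is.null(ann) && nrow(ann) > 0) {
    lines[ann$sample] <- paste0(lines[ann$sample], ",", ann$symbol)
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# WFDB record triplets (.hea / .dat format 212 / .atr): a compact reader
# and writer for the subset MIT-BIH style records use.  Format 212 packs
# two 12-bit two's-complement samples into 3 bytes; annotations are
# 2-byte words with a 6-bit type code and a 10-bit sample increment.

# MIT annotation codes for the symbols this pipeline understands.
.mit_codes <- c(N = 1L, V = 5L, F = 6L, A = 8L, S = 9L, Q = 13L,
                U = 21L, X = 35L, O = 38L)

.parse_hea <- function(hea_path) {
  if (!file.exists(hea_path)) {
    stop_fmt("read_wfdb_record: missing header file %s", hea_path)
  }
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop_fmt("read_wfdb_record: corrupt header %s", hea_path)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3) stop_fmt("read_wfdb_record: corrupt header line in %s", hea_path)
  n_sig <- suppressWarnings(as.integer(top[2]))
  fs <- suppressWarnings(as.numeric(sub("/.*$", "", top[3])))
  n_samp <- if (length(top) >= 4) suppressWarnings(as.integer(top[4])) else NA_integer_
  if (is.na(n_sig) || is.na(fs) || fs <= 0) {
    stop_fmt("read_wfdb_record: corrupt header %s", hea_path)
  }
  sig <- lapply(lines[1 + seq_len(n_sig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 2) stop_fmt("read_wfdb_record: corrupt signal line in %s", hea_path)
    # file fmt gain(baseline)/units ... ; description is the trailing field
    gain_tok <- if (length(f) >= 3) f[3] else "200"
    baseline <- 0
    if (grepl("\\(", gain_tok)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_tok))
    }
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_tok)))
    list(file = f[1], fmt = f[2], gain = gain, baseline = baseline,
         desc = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA)
  })
  list(record = top[1], n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sig)
}

.read_dat_212 <- function(dat_path, n_sig, n_samp) {
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  n_pairs <- length(raw) %/% 3
  b <- matrix(as.integer(raw[seq_len(3 * n_pairs)]), nrow = 3)
  s1 <- b[1, ] + bitwShiftL(bitwAnd(b[2, ], 0x0F), 8)
  s2 <- b[3, ] + bitwShiftL(bitwAnd(bitwShiftR(b[2, ], 4), 0x0F), 8)
  s1 <- ifelse(s1 > 2047, s1 - 4096, s1)
  s2 <- ifelse(s2 > 2047, s2 - 4096, s2)
  flat <- as.vector(rbind(s1, s2))
  total <- n_sig * n_samp
  if (length(flat) < total) {
    stop_fmt("read_wfdb_record: %s holds %d samples, header declares %d",
             dat_path, length(flat), total)
  }
  matrix(flat[seq_len(total)], nrow = n_sig)  # row = channel (interleaved)
}

.read_atr <- function(atr_path) {
  raw <- readBin(atr_path, "raw", n = file.size(atr_path))
  n_words <- length(raw) %/% 2
  lo <- as.integer(raw[2 * seq_len(n_words) - 1])
  hi <- as.integer(raw[2 * seq_len(n_words)])
  code <- bitwShiftR(hi, 2)
  incr <- bitwShiftL(bitwAnd(hi, 0x03), 8) + lo
  t <- 0
  out_t <- numeric(0); out_c <- integer(0)
  i <- 1L
  code_to_sym <- stats::setNames(names(.mit_codes), .mit_codes)
  while (i <= n_words) {
    ci <- code[i]
    if (ci == 0L && incr[i] == 0L) break      # EOF word
    if (ci == 59L && incr[i] == 0L) {         # SKIP: 32-bit jump, high 16 first
      if (i + 2L > n_words) break
      t <- t + (lo[i + 1L] + 256 * hi[i + 1L]) * 65536 +
        (lo[i + 2L] + 256 * hi[i + 2L])
      i <- i + 3L
      next
    } else if (ci >= 60L) {                   # NUM/SUB/CHN/AUX modifiers: skip
      if (ci == 63L) i <- i + (incr[i] + incr[i] %% 2L) %/% 2L
      i <- i + 1L
      next
    } else {
      t <- t + incr[i]
      out_t <- c(out_t, t)
      out_c <- c(out_c, ci)
    }
    i <- i + 1L
  }
  if (length(out_t) == 0) return(NULL)
  sym <- code_to_sym[as.character(out_c)]
  sym[is.na(sym)] <- "O"
  data.frame(sample = as.integer(out_t) + 1L, symbol = unname(sym),
             stringsAsFactors = FALSE)
}

#' Read a WFDB record triplet
#'
#' Reads a `.hea` header, a format-212 `.dat` signal file and, when present,
#' a `.atr` MIT annotation file, and normalizes one channel into an
#' [ecg_record()].  Amplitudes are converted to millivolts when the header
#' carries an ADC gain.
#'
#' @param path_stem path without extension (e.g. `"data/100"`).
#' @param channel 1-based channel to extract (default the first).
#' @return [ecg_record()]; `annotations` is `NULL` when no `.atr` exists.
#' @export
read_wfdb_record <- function(path_stem, channel = 1L) {
  hea <- .parse_hea(paste0(path_stem, ".hea"))
  if (channel < 1 || channel > hea$n_sig) {
    stop_fmt("read_wfdb_record: channel %d not in record with %d signals",
             channel, hea$n_sig)
  }
  fmt <- hea$signals[[channel]]$fmt
  if (fmt != "212") {
    stop_fmt("read_wfdb_record: unsupported signal format '%s' (only 212)", fmt)
  }
  dat_path <- file.path(dirname(path_stem), hea$signals[[channel]]$file)
  if (!file.exists(dat_path)) {
    stop_fmt("read_wfdb_record: missing signal file %s", dat_path)
  }
  adc <- .read_dat_212(dat_path, hea$n_sig, hea$n_samp)
  gain <- hea$signals[[channel]]$gain
  baseline <- hea$signals[[channel]]$baseline
  x <- adc[channel, ]
  if (is.finite(gain) && gain > 0) x <- (x - baseline) / gain
  atr_path <- paste0(path_stem, ".atr")
  ann <- if (file.exists(atr_path)) .read_atr(atr_path) else NULL
  if (!is.null(ann) && nrow(ann) > 0 && max(ann$sample) > length(x)) {
    stop_fmt("read_wfdb_record: annotation at sample %d beyond signal end %d",
             max(ann$sample), length(x))
  }
  desc <- hea$signals[[channel]]$desc
  ecg_record(x, hea$fs,
             lead_name = if (is.na(desc)) "ch1" else desc,
             annotations = ann,
             units_per_mv = if (is.finite(gain) && gain > 0) gain else NULL)
}

#' Write a WFDB record triplet
#'
#' Writes a single-channel format-212 `.hea`/`.dat` pair (and a `.atr`
#' annotation file when the record carries annotations).  Amplitudes are
#' quantized to integer ADC units at `gain` units per millivolt, so a
#' read-back reproduces the signal to within half a quantization step.
#'
#' @param record an [ecg_record()].
#' @param path_stem output path without extension.
#' @param gain ADC units per millivolt (default 200, the MIT-BIH value).
#' @export
write_wfdb_record <- function(record, path_stem, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  adc <- as.integer(round(record$samples * gain))
  adc <- pmax(pmin(adc, 2047L), -2048L)
  n <- length(adc)
  rec_name <- basename(path_stem)
  hea <- c(sprintf("%s 1 %g %d", rec_name, record$fs, n),
           sprintf("%s.dat 212 %g(0)/mV 12 0 %d 0 0 %s",
                   rec_name, gain, adc[1], record$lead_name))
  writeLines(hea, paste0(path_stem, ".hea"))
  if (n %% 2 == 1) adc <- c(adc, 0L)  # pad to sample pair
  u <- ifelse(adc < 0, adc + 4096L, adc)
  s1 <- u[seq(1, length(u), by = 2)]
  s2 <- u[seq(2, length(u), by = 2)]
  bytes <- as.raw(rbind(bitwAnd(s1, 0xFF),
                        bitwOr(bitwShiftL(bitwAnd(s2, 0xF00) %/% 256, 4),
                               bitwAnd(s1, 0xF00) %/% 256),
                        bitwAnd(s2, 0xFF)))
  writeBin(as.vector(bytes), paste0(path_stem, ".dat"))
  ann <- record$annotations
  if (!is.null(ann) && nrow(ann) > 0) {
    .write_atr(ann, paste0(path_stem, ".atr"))
  }
  invisible(path_stem)
}

.write_atr <- function(ann, atr_path) {
  codes <- .mit_codes[ann$symbol]
  codes[is.na(codes)] <- .mit_codes[["O"]]
  t0 <- ann$sample - 1L
  incr <- diff(c(0L, t0))
  word2 <- function(lo8, hi8) as.raw(c(lo8, hi8))
  chunks <- vector("list", length(incr) + 1L)
  for (i in seq_along(incr)) {
    d <- as.integer(incr[i])
    w <- raw(0)
    if (d > 1023L) {
      # SKIP pseudo-annotation (code 59, interval 0), then the 32-bit jump
      # with its high 16 bits first, each half little-endian
      hi16 <- d %/% 65536L
      lo16 <- d %% 65536L
      w <- c(word2(0L, bitwShiftL(59L, 2)),
             word2(hi16 %% 256L, hi16 %/% 256L),
             word2(lo16 %% 256L, lo16 %/% 256L))
      d <- 0L
    }
    w <- c(w, word2(bitwAnd(d, 0xFF),
                    bitwOr(bitwShiftL(codes[[i]], 2), bitwShiftR(d, 8))))
    chunks[[i]] <- w
  }
  chunks[[length(incr) + 1L]] <- as.raw(c(0, 0))  # EOF
  writeBin(do.call(c, chunks), atr_path)
  invisible(atr_path)
}

# ---------------------------------------------------------------------------
# Beat matrices

#' Construct a beat matrix
#'
#' Fixed-width truncated beat windows, one row per beat, with optional
#' binary labels and the source R index of each row.
#'
#' @param rows numeric matrix, one beat window per row; all rows the same
#'   width.
#' @param fs sampling frequency the windows were cut at.
#' @param labels optional factor/character of `"normal"` / `"abnormal"`, one
#'   per row.
#' @param r_index optional integer vector of source R-peak sample indices.
#' @return object of class `beat_matrix`.
#' @export
beat_matrix <- function(rows, fs, labels = NULL, r_index = NULL) {
  rows <- as.matrix(rows)
  if (nrow(rows) > 0) storage.mode(rows) <- "double"
  if (!is.null(labels)) {
    labels <- factor(as.character(labels), levels = c("normal", "abnormal"))
    if (length(labels) != nrow(rows)) {
      stop_fmt("beat_matrix: %d labels for %d rows", length(labels), nrow(rows))
    }
  }
  if (!is.null(r_index) && length(r_index) != nrow(rows)) {
    stop_fmt("beat_matrix: %d r_index values for %d rows",
             length(r_index), nrow(rows))
  }
  structure(list(rows = rows, fs = fs, labels = labels,
                 r_index = if (is.null(r_index)) NULL else as.integer(r_index)),
            class = "beat_matrix")
}

#' @export
print.beat_matrix <- function(x, ...) {
  nl <- if (is.null(x$labels)) "unlabeled" else {
    paste(table(x$labels), collapse = "/")
  }
  cat(sprintf("<beat_matrix> %d beats x %d samples @ %g Hz (%s)\n",
              nrow(x$rows), ncol(x$rows), x$fs, nl))
  invisible(x)
}

#' @export
dim.beat_matrix <- function(x) dim(x$rows)

#' Write a beat matrix as delimited text
#'
#' One beat per line, comma-separated samples, with the label appended as a
#' trailing field when labels are present.  Round-trips losslessly through
#' [read_beat_matrix()].
#'
#' @param beats a [beat_matrix()].
#' @param path output file path.
#' @export
write_beat_matrix <- function(beats, path) {
  stopifnot(inherits(beats, "beat_matrix"))
  m <- beats$rows
  if (nrow(m) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- apply(m, 1, function(r) {
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ",")
  })
  if (!is.null(beats$labels)) {
    lines <- paste0(lines, ",", as.character(beats$labels))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a beat matrix written by [write_beat_matrix()]
#'
#' @param path file path.
#' @param fs sampling frequency to attach.
#' @return a [beat_matrix()]; empty file yields a 0-row matrix.
#' @export
read_beat_matrix <- function(path, fs) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(beat_matrix(matrix(numeric(0), nrow = 0, ncol = 0), fs))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1) {
    stop_fmt("read_beat_matrix: ragged rows in %s", path)
  }
  last <- vapply(parts, function(p) p[[length(p)]], "")
  labeled <- all(last %in% c("normal", "abnormal"))
  labels <- NULL
  if (labeled) {
    labels <- last
    parts <- lapply(parts, function(p) p[-length(p)])
  }
  m <- do.call(rbind, lapply(parts, as.numeric))
  if (anyNA(m)) stop_fmt("read_beat_matrix: non-numeric field in %s", path)
  beat_matrix(m, fs, labels = labels)
}
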