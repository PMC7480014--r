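#' Read and write multi-channel ECG records
#'
#' Two on-disk formats are supported:
#'
#' * `"csv"`: a plain CSV of one column per channel, with a JSON sidecar
#'   (`<path>.json`) holding the sampling rate and optional R-peak
#'   annotations. Round trips are value-exact.
#' * `"wfdb"`: a minimal reader/writer for the WFDB physiological-signal
#'   format, header (`.hea`) plus 16-bit little-endian sample file
#'   (`.dat`), the layout used by public ECG databases. Amplitudes are
#'   quantized by the per-channel ADC gain stored in the header, so round
#'   trips are exact to ADC resolution. R-peaks, when present, are stored
#'   in a plain-text `.rpeaks.csv` companion rather than a binary
#'   annotation file.
#'
#' @param path file path; for `"wfdb"`, the record path without extension.
#' @param format `"csv"` or `"wfdb"` (guessed from the extension when
#'   reading if omitted).
#' @param channels optional channel subset to keep after reading, e.g.
#'   `c(1, 3, 4, 5)` for six-channel abdominal recordings.
#' @return `read_record()` returns an [mcecg]; `write_record()` returns
#'   `path` invisibly.
#' @export
read_record <- function(path, format = NULL, channels = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path)) "csv"
    else if (file.exists(paste0(path, ".hea"))) "wfdb"
    else abort(sprintf("cannot guess format of '%s'; pass `format`.", path))
  }
  out <- switch(format,
    csv = .read_csv_record(path),
    wfdb = .read_wfdb_record(path),
    abort(sprintf("unsupported format '%s'.", format))
  )
  if (!is.null(channels))
    out <- mcecg(out$samples[, channels, drop = FALSE], out$fs, out$r_peaks)
  out
}

#' @rdname read_record
#' @param signal an [mcecg] to write.
#' @export
write_record <- function(signal, path, format = c("csv", "wfdb")) {
  stopifnot(inherits(signal, "mcecg"))
  format <- match.arg(format)
  if (format == "csv") .write_csv_record(signal, path)
  else .write_wfdb_record(signal, path)
  invisible(path)
}

.write_csv_record <- function(signal, path) {
  # full 17-digit representation so the round trip is value-exact
  df <- as.data.frame(apply(signal$samples, 2L, sprintf, fmt = "%.17g"))
  names(df) <- paste0("ch", seq_len(ncol(signal$samples)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(fs = signal$fs)
  if (!is.null(signal$r_peaks)) meta$r_peaks <- signal$r_peaks
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

.read_csv_record <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    abort(sprintf("metadata sidecar '%s' is missing (fs unknown).", meta_path))
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) abort("metadata sidecar lacks `fs`.")
  mcecg(as.matrix(df), meta$fs, meta$r_peaks)
}

.write_wfdb_record <- function(signal, path) {
  rec <- basename(path)
  n <- n_samples(signal)
  k <- n_channels(signal)
  # per-channel gain: map the amplitude range into +/- 32000 counts
  gains <- apply(signal$samples, 2L, function(x) {
    m <- max(abs(x))
    if (m == 0) 1 else 32000 / m
  })
  counts <- matrix(0L, nrow = n, ncol = k)
  for (ch in seq_len(k))
    counts[, ch] <- as.integer(round(signal$samples[, ch] * gains[ch]))
  hdr <- c(
    sprintf("%s %d %g %d", rec, k, signal$fs, n),
    sprintf("%s.dat 16 %.6f 16 0 %d 0 0 ch%d", rec, gains, counts[1L, ],
            seq_len(k))
  )
  writeLines(hdr, paste0(path, ".hea"))
  interleaved <- as.integer(t(counts))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(interleaved, con, size = 2L, endian = "little")
  if (!is.null(signal$r_peaks))
    utils::write.csv(data.frame(sample = signal$r_peaks),
                     paste0(path, ".rpeaks.csv"), row.names = FALSE)
}

.read_wfdb_record <- function(path) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) abort(sprintf("header '%s' does not exist.", hea))
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(top) < 4L) abort("malformed WFDB header line.")
  k <- as.integer(top[2L])
  fs <- as.numeric(top[3L])
  n <- as.integer(top[4L])
  if (!is.finite(fs) || fs <= 0) abort("WFDB header lacks a valid sampling rate.")
  sig <- lines[2L:(1L + k)]
  fields <- strsplit(trimws(sig), "\\s+")
  fmt <- vapply(fields, `[[`, "", 2L)
  if (!all(fmt == "16")) abort("only WFDB format 16 is supported.")
  gains <- vapply(fields, function(f) as.numeric(sub("\\(.*", "", f[3L])),
                  numeric(1))
  gains[!is.finite(gains) | gains == 0] <- 200 # WFDB default gain
  dat <- vapply(fields, `[[`, "", 1L)
  if (length(unique(dat)) != 1L) abort("multi-file WFDB records are not supported.")
  con <- file(file.path(dirname(path), dat[1L]), "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n * k, size = 2L, signed = TRUE,
                 endian = "little")
  counts <- matrix(raw, ncol = k, byrow = TRUE)
  samples <- sweep(counts, 2L, gains, `/`)
  rp_path <- paste0(path, ".rpeaks.csv")
  rp <- if (file.exists(rp_path)) utils::read.csv(rp_path)$sample else NULL
  mcecg(samples, fs, rp)
}
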