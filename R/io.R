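#' Read an ECG record from CSV or WFDB
#'
#' The CSV dialect is: an optional leading comment line `# fs=<Hz>`, a
#' header row, an optional first column `time` (seconds), and one numeric
#' column per lead (assumed mV). The WFDB reader supports format-16 signal
#' files (16-bit two's-complement, little-endian, interleaved) with the
#' gain/baseline fields of the `.hea` header honoured, so values are
#' returned in mV whenever the header declares a gain.
#'
#' @param path file path: the CSV file, or the WFDB `.hea` header (or the
#'   record name without extension).
#' @param format `"csv"` or `"wfdb"`; inferred from the extension when
#'   missing.
#' @param fs sampling rate in Hz, required for CSV files that carry neither
#'   a `# fs=` comment nor a `time` column.
#' @return an [ecg_record].
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb"), fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.hea$", path) || file.exists(paste0(path, ".hea"))) "wfdb" else "csv"
  }
  switch(format, csv = read_ecg_csv(path, fs = fs), wfdb = read_ecg_wfdb(path))
}

read_ecg_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*fs\\s*=", first)) {
    fs_hdr <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", first))
    if (is.finite(fs_hdr)) fs <- fs_hdr
  }
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!nrow(dat)) abort("Empty ECG CSV.")
  t0 <- 0
  if ("time" %in% names(dat)) {
    tt <- dat$time
    if (is.null(fs)) {
      dt <- diff(tt)
      if (length(dt) == 0L || any(dt <= 0)) abort("Cannot infer fs from the time column.")
      fs <- 1 / median(dt)
    }
    t0 <- tt[1L]
    dat$time <- NULL
  }
  if (is.null(fs)) abort("Sampling rate unknown: supply `fs` or a `# fs=<Hz>` header comment.")
  if (fs <= 0) abort("`fs` must be positive.")
  if (anyNA(dat)) abort("ECG CSV contains NA samples.")
  ecg_record(as.matrix(dat), fs = fs, t0 = t0)
}

#' Write an ECG record to CSV or WFDB
#'
#' CSV output is the dialect [read_ecg] reads back (comment line with fs,
#' then `time` plus lead columns). WFDB output writes a format-16 `.dat`
#' with a fixed gain of 1000 ADC units/mV, so the round trip is exact to
#' 1e-3 mV.
#'
#' @param rec an [ecg_record].
#' @param path output path; for WFDB, the record name (with or without
#'   `.hea`).
#' @param format `"csv"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_ecg <- function(rec, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, open = "wb")
    writeLines(sprintf("# fs=%.10g", record_fs(rec)), con)
    close(con)
    readr::write_csv(tibble::as_tibble(unclass(rec)), path, append = TRUE,
                     col_names = TRUE, progress = FALSE)
  } else {
    write_ecg_wfdb(rec, path)
  }
  invisible(path)
}

# --- minimal WFDB (format 16) support --------------------------------------

read_ecg_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) abort(paste0("No such WFDB header: ", hea))
  lines <- grep("^\\s*(#|$)", readLines(hea), invert = TRUE, value = TRUE)
  rl <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rl) < 3L) abort("Unparseable WFDB record line.")
  nsig <- as.integer(rl[2L])
  fs <- as.numeric(sub("/.*", "", rl[3L]))  # strip counter frequency
  nsamp <- if (length(rl) >= 4L) as.integer(rl[4L]) else NA_integer_
  if (!is.finite(fs) || fs <= 0) abort("WFDB header declares a non-positive sampling rate.")
  sig <- lines[1L + seq_len(nsig)]
  parse_sig <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt <- sub("x\\d+$", "", tok[2L])
    gain_tok <- if (length(tok) >= 3L) tok[3L] else "200"
    units <- if (grepl("/", gain_tok)) sub("^[^/]*/", "", gain_tok) else "mV"
    gb <- sub("/.*", "", gain_tok)
    baseline <- 0
    if (grepl("\\(", gb)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gb))
      gb <- sub("\\(.*", "", gb)
    }
    gain <- as.numeric(gb)
    if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default ADC gain
    desc <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = " ") else NA_character_
    list(file = tok[1L], fmt = fmt, gain = gain, baseline = baseline,
         units = units, desc = desc)
  }
  info <- lapply(sig, parse_sig)
  fmts <- unique(vapply(info, `[[`, "", "fmt"))
  if (!identical(fmts, "16")) abort(paste0("Only WFDB format 16 is supported (got ", paste(fmts, collapse = ","), ")."))
  datf <- file.path(dirname(hea), info[[1L]]$file)
  if (!file.exists(datf)) abort(paste0("Missing WFDB signal file: ", datf))
  raw <- readBin(datf, "integer", n = file.size(datf) / 2L, size = 2L,
                 endian = "little", signed = TRUE)
  nsamp_file <- length(raw) %/% nsig
  if (!is.na(nsamp) && nsamp > 0L) nsamp_file <- min(nsamp_file, nsamp)
  m <- matrix(raw[seq_len(nsamp_file * nsig)], ncol = nsig, byrow = TRUE)
  phys <- vapply(seq_len(nsig), function(j) {
    (m[, j] - info[[j]]$baseline) / info[[j]]$gain
  }, numeric(nsamp_file))
  if (!is.matrix(phys)) phys <- matrix(phys, ncol = nsig)
  nm <- vapply(seq_len(nsig), function(j) {
    d <- info[[j]]$desc
    if (is.na(d) || !nzchar(d)) paste0("sig", j) else gsub("\\s+", "_", d)
  }, character(1))
  ecg_record(phys, fs = fs, lead_names = nm)
}

write_ecg_wfdb <- function(rec, path, gain = 1000) {
  base <- sub("\\.hea$", "", path)
  recname <- basename(base)
  m <- as_lead_matrix(rec)
  nsig <- ncol(m)
  adc <- round(m * gain)
  if (any(abs(adc) > 32767)) abort("Signal exceeds the 16-bit range at gain 1000 ADU/mV.")
  hea <- c(
    sprintf("%s %d %.10g %d", recname, nsig, record_fs(rec), nrow(m)),
    sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s", recname, gain, lead_names(rec))
  )
  writeLines(hea, paste0(base, ".hea"))
  inter <- as.integer(t(adc))
  writeBin(inter, paste0(base, ".dat"), size = 2L, endian = "little")
  invisible(base)
}

# --- beat annotation I/O ----------------------------------------------------

#' Write beat annotations to disk
#'
#' `csv` writes columns `time_s`, `source`, `quality`. `wfdb_ann` writes a
#' plain-text annotation table (columns: sample index, annotation mnemonic,
#' aux = quality flag) keyed to a sampling rate, mirroring the text form
#' consumed by the WFDB `wrann` utility; the binary MIT annotation format is
#' not produced.
#'
#' @param beats a [beat_times].
#' @param path output file path.
#' @param format `"csv"` or `"wfdb_ann"`.
#' @param fs sampling rate (Hz) used to express times as sample indices;
#'   required for `"wfdb_ann"`.
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path, format = c("csv", "wfdb_ann"), fs = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(
      tibble::tibble(time_s = beats$time, source = beats$source,
                     quality = beats$quality),
      path, progress = FALSE
    )
  } else {
    if (is.null(fs)) abort("`fs` is required for wfdb_ann output.")
    code <- c(normal = "N", ectopic = "V", artifact = "|")[beats$quality]
    lines <- c(
      sprintf("# fs=%.10g source=%s", fs, if (nrow(beats)) beats$source[1L] else "fetal"),
      sprintf("%d %s %s", as.integer(round(beats$time * fs)), code, beats$quality)
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read beat annotations written by [write_beats]
#'
#' @inheritParams write_beats
#' @return a [beat_times].
#' @export
read_beats <- function(path, format = c("csv", "wfdb_ann")) {
  format <- match.arg(format)
  if (format == "csv") {
    d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           time_s = readr::col_double(),
                           source = readr::col_character(),
                           quality = readr::col_character()
                         ))
    src <- if (nrow(d)) d$source[1L] else "fetal"
    beat_times(d$time_s, source = src, quality = if (nrow(d)) d$quality else character(0))
  } else {
    lines <- readLines(path)
    hdr <- lines[1L]
    fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", hdr))
    src <- sub(".*source=(\\w+).*", "\\1", hdr)
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    if (!length(body)) return(beat_times(numeric(0), source = src))
    tok <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    beat_times(as.numeric(tok[, 1L]) / fs, source = src, quality = tok[, 3L])
  }
}
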