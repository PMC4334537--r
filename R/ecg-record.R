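#' Uniformly sampled multichannel ECG record
#'
#' An `ecg_record` is a tibble with a `time` column (seconds from record
#' start) and one numeric column per lead, carrying the sampling rate as an
#' attribute. All leads share the sample grid; voltages are in millivolts
#' where the source metadata allows the conversion.
#'
#' @param samples numeric matrix (samples in rows, leads in columns) or a
#'   data frame of lead columns.
#' @param fs sampling rate in Hz, positive scalar.
#' @param lead_names character vector of lead labels; defaults to column
#'   names or `"lead1"`, `"lead2"`, ...
#' @param t0 start time in seconds (default 0).
#' @return a tibble of class `ecg_record`.
#' @examples
#' rec <- ecg_record(cbind(a = sin(1:100 / 5), b = cos(1:100 / 5)), fs = 100)
#' record_duration(rec)
#' @export
ecg_record <- function(samples, fs, lead_names = NULL, t0 = 0) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1L)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive finite scalar (Hz).")
  }
  if (anyNA(samples)) abort("ECG samples must not contain NA; reject or gap-fill before construction.")
  if (is.null(lead_names)) lead_names <- colnames(samples)
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_len(ncol(samples)))
  if (length(lead_names) != ncol(samples)) abort("`lead_names` length must match the number of leads.")
  n <- nrow(samples)
  out <- tibble::as_tibble(as.data.frame(samples))
  names(out) <- lead_names
  out <- tibble::add_column(out, time = t0 + (seq_len(n) - 1L) / fs, .before = 1L)
  attr(out, "fs") <- as.numeric(fs)
  class(out) <- c("ecg_record", class(out))
  out
}

#' @rdname ecg_record
#' @param rec an `ecg_record`.
#' @export
record_fs <- function(rec) {
  fs <- attr(rec, "fs")
  if (is.null(fs)) abort("Not an `ecg_record`: missing sampling-rate attribute.")
  fs
}

#' @rdname ecg_record
#' @export
record_duration <- function(rec) nrow(rec) / record_fs(rec)

#' @rdname ecg_record
#' @export
lead_names <- function(rec) setdiff(names(rec), "time")

#' Extract one lead as a bare numeric vector
#'
#' @param rec an `ecg_record`.
#' @param lead lead name or positional index (1-based, excluding `time`).
#' @return numeric vector of voltages.
#' @export
lead_signal <- function(rec, lead = 1L) {
  nms <- lead_names(rec)
  if (is.numeric(lead)) {
    if (lead < 1L || lead > length(nms)) abort("Lead index out of range.")
    lead <- nms[lead]
  }
  if (!lead %in% nms) abort(paste0("No lead named '", lead, "'."))
  rec[[lead]]
}

as_lead_matrix <- function(rec) {
  as.matrix(rec[lead_names(rec)])
}

#' Derive all bipolar leads from electrode channels
#'
#' Forms every pairwise voltage difference between the record's channels,
#' in the abdominal-electrode montage sense: four signal electrodes against
#' a shared reference yield choose(4, 2) = 6 bipolar leads. Lead `A_B` is
#' the potential of `A` minus the potential of `B`, so swapping the pair
#' flips the sign.
#'
#' @param rec an `ecg_record` with at least two channels.
#' @return an `ecg_record` with `choose(n, 2)` leads named `"<A>_<B>"`.
#' @examples
#' rec <- ecg_record(cbind(A = sin(1:50), B = sin(1:50)), fs = 50)
#' derive_bipolar_leads(rec) # single identically-zero lead A_B
#' @export
derive_bipolar_leads <- function(rec) {
  nms <- lead_names(rec)
  if (length(nms) < 2L) abort("Need at least 2 channels to derive bipolar leads.")
  pairs <- utils::combn(nms, 2L)
  m <- as_lead_matrix(rec)
  out <- apply(pairs, 2L, function(p) m[, p[1L]] - m[, p[2L]])
  colnames(out) <- apply(pairs, 2L, paste, collapse = "_")
  ecg_record(out, fs = record_fs(rec), t0 = rec$time[1L])
}

#' Rank leads by a maternal-QRS signal-quality score
#'
#' Scores each lead by the ratio of the median maternal-R detection
#' amplitude to the median absolute deviation of the beat-detection
#' function (an SNR proxy), computed on the 5-40 Hz band-passed lead. A
#' clean lead concentrates detection-function mass at sparse R peaks, so
#' the ratio is large; broadband noise inflates the MAD and deflates the
#' score. All-flat leads score 0 with a warning.
#'
#' @param rec an `ecg_record`.
#' @param band band-pass corners (Hz) applied before scoring.
#' @return a tibble with columns `lead`, `lead_name`, `score`, sorted by
#'   decreasing score; ties broken by lead index.
#' @export
rank_leads_by_quality <- function(rec, band = c(5, 40)) {
  nms <- lead_names(rec)
  if (length(nms) == 0L) abort("Record has no leads.")
  fs <- record_fs(rec)
  score_one <- function(x) {
    if (all(abs(x - x[1L]) < .Machine$double.eps * 100)) return(0)
    d <- detection_function(x, fs, band = band)
    pk <- local_maxima(d)
    if (length(pk) == 0L) return(0)
    # amplitude of the beats the detector would lock onto
    amp <- median(quantile(d[pk], probs = 0.9, names = FALSE))
    s <- mad(d)
    if (s <= 0) return(0)
    amp / s
  }
  scores <- vapply(nms, function(nm) score_one(rec[[nm]]), numeric(1))
  if (all(scores == 0)) warn("All leads flat or featureless; quality scores are all 0.")
  tibble::tibble(lead = seq_along(nms), lead_name = nms, score = unname(scores)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$lead)
}
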