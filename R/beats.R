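#' Ordered beat (R-peak) event times
#'
#' A `beat_times` object is a tibble with columns `time` (seconds, strictly
#' increasing), `source` (`"maternal"` or `"fetal"`) and `quality`
#' (`"normal"`, `"ectopic"` or `"artifact"`). Consecutive events must be
#' separated by more than the absolute refractory period of the heart.
#'
#' @param times numeric vector of event times in seconds, strictly
#'   increasing.
#' @param source `"maternal"` or `"fetal"`.
#' @param quality per-beat flag, recycled; one of `"normal"`, `"ectopic"`,
#'   `"artifact"`.
#' @param refractory minimum allowed separation between consecutive beats
#'   (s); default 0.2.
#' @param ... further per-beat columns (e.g. detection amplitude), each of
#'   the same length as `times`.
#' @return a tibble of class `beat_times`.
#' @examples
#' beat_times(c(0.5, 1.3, 2.1), source = "maternal")
#' @export
beat_times <- function(times, source = c("maternal", "fetal"),
                       quality = "normal", refractory = 0.2, ...) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) abort("Beat times must be finite.")
  if (is.unsorted(times, strictly = TRUE)) abort("Beat times must be strictly increasing.")
  if (length(times) > 1L && any(diff(times) <= refractory)) {
    abort(sprintf("Consecutive beats closer than the refractory period (%.3f s).", refractory))
  }
  quality <- rep_len(as.character(quality), length(times))
  bad <- setdiff(unique(quality), c("normal", "ectopic", "artifact"))
  if (length(bad)) abort(paste0("Unknown quality flag: ", paste(bad, collapse = ", ")))
  extra <- list(...)
  out <- tibble::tibble(time = times, source = source, quality = quality)
  for (nm in names(extra)) out[[nm]] <- rep_len(extra[[nm]], length(times))
  class(out) <- c("beat_times", class(out))
  attr(out, "refractory") <- refractory
  out
}

n_beats <- function(beats) nrow(beats)

# Keep only beats whose time falls inside [t0, t1].
clip_beats <- function(beats, t0, t1) {
  keep <- beats$time >= t0 & beats$time <= t1
  out <- beats[keep, , drop = FALSE]
  class(out) <- class(beats)
  attr(out, "refractory") <- attr(beats, "refractory")
  out
}

#' Match detected beats against reference beats
#'
#' Greedy one-to-one matching within a tolerance window, used to score a
#' detector against ground truth: each reference beat may claim at most one
#' detection within `tol` seconds (nearest first).
#'
#' @param detected,reference `beat_times` or numeric vectors of times (s).
#' @param tol matching window in seconds (default 0.05).
#' @return a list with `n_matched`, `sensitivity` (matched / reference),
#'   `ppv` (matched / detected) and logical index vectors `det_matched`,
#'   `ref_matched`.
#' @export
match_beats <- function(detected, reference, tol = 0.05) {
  td <- if (is.data.frame(detected)) detected$time else as.numeric(detected)
  tr <- if (is.data.frame(reference)) reference$time else as.numeric(reference)
  det_used <- logical(length(td))
  ref_used <- logical(length(tr))
  if (length(td) && length(tr)) {
    # all candidate pairs within tol, closest first, greedy one-to-one
    cand <- do.call(rbind, lapply(seq_along(tr), function(i) {
      j <- which(abs(td - tr[i]) <= tol)
      if (!length(j)) return(NULL)
      cbind(i = i, j = j, d = abs(td[j] - tr[i]))
    }))
    if (!is.null(cand)) {
      cand <- cand[order(cand[, "d"]), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, "i"]; j <- cand[k, "j"]
        if (!ref_used[i] && !det_used[j]) {
          ref_used[i] <- TRUE
          det_used[j] <- TRUE
        }
      }
    }
  }
  n <- sum(ref_used)
  list(
    n_matched = n,
    sensitivity = if (length(tr)) n / length(tr) else NA_real_,
    ppv = if (length(td)) n / length(td) else NA_real_,
    det_matched = det_used,
    ref_matched = ref_used
  )
}
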