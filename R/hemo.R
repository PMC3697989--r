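#' Detect systolic peaks in an arterial-pressure waveform
#'
#' Beat-to-beat analysis starts from the systolic peaks.  Candidate
#' peaks are strict local maxima that rise above a rolling median of the
#' signal by a prominence threshold (a fraction of the signal
#' interquartile range); a refractory period of `60/max_hr` seconds then
#' suppresses the smaller of two competing candidates, which bounds the
#' detected rate by `max_hr`.
#'
#' @param signal an [ap_signal()] (or anything with `$samples` and
#'   `$fs`), at least 2 s long.
#' @param min_hr,max_hr physiologic heart-rate band, beats/min.  The rat
#'   defaults span resting bradycardia to stress tachycardia.
#' @param prominence prominence threshold as a fraction of the signal
#'   IQR above the rolling median.
#' @return Integer vector of peak sample indices (possibly empty, with a
#'   `diagnostic` attribute when nothing is found).
#' @export
detect_beats <- function(signal, min_hr = 200, max_hr = 500,
                         prominence = 0.3) {
  x <- signal$samples
  fs <- signal$fs
  if (length(x) / fs < 2) stop("signal must be at least 2 s long")
  stopifnot(min_hr > 0, min_hr < max_hr)

  iqr <- IQR(x)
  if (iqr <= 0) {
    out <- integer(0)
    attr(out, "diagnostic") <- "flat signal: no pulsatility"
    return(out)
  }
  k <- min(2L * floor(fs / 2) + 1L, 2L * floor((length(x) - 1) / 2) + 1L)
  base <- runmed(x, k)                        # ~1 s rolling median
  thr <- base + prominence * iqr
  dx <- diff(x)
  cand <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L  # local maxima
  cand <- cand[x[cand] > thr[cand]]
  if (length(cand) == 0L) {
    out <- integer(0)
    attr(out, "diagnostic") <- "no peaks above prominence threshold"
    return(out)
  }
  refrac <- round(fs * 60 / max_hr)
  keep <- cand[1]
  for (i in cand[-1]) {
    last <- keep[length(keep)]
    if (i - last >= refrac) {
      keep <- c(keep, i)
    } else if (x[i] > x[last]) {
      keep[length(keep)] <- i                 # larger peak wins the window
    }
  }
  keep
}

#' Per-beat pressure and heart-rate series
#'
#' Converts a waveform plus its systolic peak indices into the per-beat
#' series used throughout the pipeline.  Each beat window runs from a
#' systolic peak to the diastolic trough preceding the next upstroke:
#' SAP is the window maximum, DAP the trough (the minimum between
#' successive systolic peaks), MAP the time-average of the waveform
#' over the window, and HR = 60/RR.  Partial edge beats (before the
#' first and after the last peak) are discarded.
#'
#' @param signal an [ap_signal()].
#' @param peaks integer peak indices from [detect_beats()]; at least 2.
#' @return A `beat_series` data frame with columns `beat_time_s`, `sap`,
#'   `dap`, `map`, `rr`, `hr` and attribute `mean_beat_rate` (Hz).
#' @export
beat_series <- function(signal, peaks) {
  x <- signal$samples
  fs <- signal$fs
  peaks <- as.integer(peaks)
  if (length(peaks) < 2L) stop("need at least 2 detected beats")
  n <- length(peaks) - 1L
  sap <- dap <- map <- numeric(n)
  for (i in seq_len(n)) {
    seg <- x[peaks[i]:(peaks[i + 1L] - 1L)]
    m <- which.min(seg)            # diastolic trough before the next upstroke
    w <- seg[seq_len(m)]           # this beat: systolic peak -> trough
    sap[i] <- max(w); dap[i] <- seg[m]; map[i] <- mean(w)
  }
  rr <- diff(peaks) / fs
  out <- data.frame(beat_time_s = (peaks[-length(peaks)] - 1L) / fs,
                    sap = sap, dap = dap, map = map,
                    rr = rr, hr = 60 / rr)
  attr(out, "mean_beat_rate") <-
    (length(peaks) - 1L) / ((peaks[length(peaks)] - peaks[1L]) / fs)
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Summarise a beat series
#'
#' Recording-level means of SAP, DAP, MAP and HR, plus the systogram
#' (the per-beat SAP sequence) handed to the spectral module.
#'
#' @param series a [beat_series()].
#' @return A list of class `hemo_summary`: `sap`, `dap`, `map`, `hr`
#'   (means), `n_beats`, `mean_beat_rate` (Hz) and `systogram`.
#' @export
summarize_hemodynamics <- function(series) {
  if (!nrow(series)) stop("empty beat series")
  structure(list(
    sap = mean(series$sap), dap = mean(series$dap),
    map = mean(series$map), hr = mean(series$hr),
    n_beats = nrow(series),
    mean_beat_rate = attr(series, "mean_beat_rate"),
    systogram = series$sap
  ), class = "hemo_summary")
}

#' @export
print.hemo_summary <- function(x, ...) {
  cat(sprintf(
    "<hemo_summary> %d beats | SAP %.1f  DAP %.1f  MAP %.1f mmHg | HR %.1f bpm\n",
    x$n_beats, x$sap, x$dap, x$map, x$hr))
  invisible(x)
}
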