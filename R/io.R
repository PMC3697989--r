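#' Read and write waveform and beat-series CSV files
#'
#' Waveforms travel as two-column CSV (`time_s`, `pressure_mmHg`); the
#' sampling rate is inferred from the time column unless given.  Beat
#' series use the columns produced by [beat_series()].
#'
#' @param path file path.
#' @param fs sampling rate in Hz; inferred from the median time step
#'   when `NULL`.
#' @return `read_waveform_csv()` returns an [ap_signal()];
#'   `read_beat_series_csv()` a `beat_series` data frame.
#' @export
read_waveform_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "pressure_mmHg") %in% names(d)))
    stop("expected columns time_s, pressure_mmHg")
  if (is.null(fs)) fs <- 1 / median(diff(d$time_s))
  ap_signal(d$pressure_mmHg, fs)
}

#' @param signal an [ap_signal()].
#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(signal, path) {
  n <- length(signal$samples)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1L) / signal$fs,
               pressure_mmHg = signal$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' @param series a `beat_series` from [beat_series()].
#' @rdname read_waveform_csv
#' @export
write_beat_series_csv <- function(series, path) {
  d <- as.data.frame(series)
  d$mean_beat_rate <- attr(series, "mean_beat_rate")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_waveform_csv
#' @export
read_beat_series_csv <- function(path) {
  d <- utils::read.csv(path)
  rate <- if ("mean_beat_rate" %in% names(d)) d$mean_beat_rate[1] else NULL
  d$mean_beat_rate <- NULL
  attr(d, "mean_beat_rate") <- rate
  class(d) <- c("beat_series", "data.frame")
  d
}
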