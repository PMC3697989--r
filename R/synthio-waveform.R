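#' Arterial-pressure signal container
#'
#' A raw arterial-pressure recording: a vector of pressure samples in
#' mmHg together with its sampling rate.
#'
#' @param samples numeric vector of pressure samples (mmHg), finite.
#' @param fs sampling frequency in Hz.
#' @return An object of class `ap_signal` with elements `samples`, `fs`
#'   and `duration_s`.
#' @export
ap_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("pressure samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  structure(
    list(samples = samples, fs = fs, duration_s = length(samples) / fs),
    class = "ap_signal"
  )
}

#' @export
print.ap_signal <- function(x, ...) {
  cat(sprintf("<ap_signal> %d samples @ %g Hz (%.1f s), range %.1f-%.1f mmHg\n",
              length(x$samples), x$fs, x$duration_s,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Simulate a pulsatile arterial-pressure waveform
#'
#' Generates a rat-scale pulsatile pressure signal: each beat is a
#' quarter-sine systolic upstroke from diastolic to systolic pressure
#' followed by an exponential diastolic decay.  Low-frequency
#' (Mayer-wave, ~0.4 Hz) and high-frequency (respiratory, ~1.5 Hz)
#' oscillations amplitude-modulate the per-beat systolic values, on top
#' of white beat-to-beat noise, so that the systogram carries LF/HF
#' spectral components of known variance (`lf_sd_mmHg^2` and
#' `hf_sd_mmHg^2` respectively; a sinusoid of standard deviation s has
#' amplitude s*sqrt(2)).
#'
#' The ground truth needed to validate downstream estimators is attached
#' as `attr(, "truth")`: true heart rate, pressure levels, injected band
#' variances and the per-beat systolic target series.
#'
#' @param duration_s recording length, seconds.
#' @param fs waveform sampling rate, Hz; must exceed twice the beat
#'   frequency (in practice use >= 100 Hz).
#' @param hr_bpm heart rate, beats/min.
#' @param sap_mmHg,dap_mmHg systolic and diastolic pressure levels.
#' @param lf_freq_hz,lf_sd_mmHg LF modulation frequency and standard
#'   deviation (variance injected into the LF band = `lf_sd_mmHg^2`).
#' @param hf_freq_hz,hf_sd_mmHg HF modulation frequency and SD.
#' @param noise_sd_mmHg white beat-to-beat systolic noise SD.
#' @param seed integer seed; identical seeds give identical waveforms.
#' @return An [ap_signal()] with a `truth` attribute.
#' @examples
#' w <- sim_ap_waveform(10, 500, hr_bpm = 325, seed = 1)
#' attr(w, "truth")$n_beats
#' @export
sim_ap_waveform <- function(duration_s, fs, hr_bpm = 325,
                            sap_mmHg = 122, dap_mmHg = 95,
                            lf_freq_hz = 0.4, lf_sd_mmHg = 0,
                            hf_freq_hz = 1.5, hf_sd_mmHg = 0,
                            noise_sd_mmHg = 0, seed = NULL) {
  stopifnot(duration_s > 0, hr_bpm > 0,
            sap_mmHg > dap_mmHg, dap_mmHg > 0,
            lf_sd_mmHg >= 0, hf_sd_mmHg >= 0, noise_sd_mmHg >= 0)
  beat_hz <- hr_bpm / 60
  if (fs <= 2 * beat_hz)
    stop(sprintf("fs = %g Hz is too low for hr = %g bpm (need fs > %g Hz)",
                 fs, hr_bpm, 2 * beat_hz))
  with_seed(seed, {
    period <- 60 / hr_bpm
    n_beats <- floor(duration_s / period + 1e-9)
    n_total <- ceiling(duration_s / period)          # incl. partial last beat
    onset <- (seq_len(n_total) - 1L) * period
    phi_lf <- runif(1, 0, 2 * pi)
    phi_hf <- runif(1, 0, 2 * pi)
    sys <- sap_mmHg +
      sqrt(2) * lf_sd_mmHg * sin(2 * pi * lf_freq_hz * onset + phi_lf) +
      sqrt(2) * hf_sd_mmHg * sin(2 * pi * hf_freq_hz * onset + phi_hf) +
      rnorm(n_total, 0, noise_sd_mmHg)
    sys <- pmax(sys, dap_mmHg + 1)                   # sap > dap always

    t <- (seq_len(round(duration_s * fs)) - 1L) / fs
    k <- pmin(floor(t / period) + 1L, n_total)
    tau <- t - (k - 1L) * period
    tau_up <- 0.15 * period                          # systolic upstroke time
    tau_d <- (period - tau_up) / 4                   # diastolic decay constant
    pp <- sys[k] - dap_mmHg
    p <- ifelse(tau <= tau_up,
                dap_mmHg + pp * sin(pi * tau / (2 * tau_up)),
                dap_mmHg + pp * exp(-(tau - tau_up) / tau_d))
    sig <- ap_signal(p, fs)
    attr(sig, "truth") <- list(
      hr_bpm = hr_bpm, sap_mmHg = sap_mmHg, dap_mmHg = dap_mmHg,
      n_beats = n_beats, beat_period_s = period,
      lf_freq_hz = lf_freq_hz, lf_var = lf_sd_mmHg^2,
      hf_freq_hz = hf_freq_hz, hf_var = hf_sd_mmHg^2,
      noise_var = noise_sd_mmHg^2,
      sys_series = sys[seq_len(n_beats)]
    )
    sig
  })
}
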