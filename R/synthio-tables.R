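#' Simulate an insulin-tolerance-test glucose series
#'
#' Exponential glucose decay `g0 * 2^(-t / t_half)` plus Gaussian noise,
#' clipped at 1 mg/dL, sampled at the classic ITT times (baseline and
#' 4, 8, 12, 16 min after the insulin bolus).  `t_half = Inf` yields a
#' constant (non-decaying) series.
#'
#' @param g0 baseline glucose, mg/dL (> 0).
#' @param t_half glucose half-life, min (> 0; may be `Inf`).
#' @param noise_sd measurement noise SD, mg/dL.
#' @param times sampling times, min, strictly increasing.
#' @param seed integer seed.
#' @return Data frame `time_min`, `glucose_mg_dl`, with a `truth`
#'   attribute carrying `t_half` and the implied Kitt (%/min).
#' @export
sim_itt <- function(g0, t_half, noise_sd = 0,
                    times = c(0, 4, 8, 12, 16), seed = NULL) {
  stopifnot(g0 > 0, t_half > 0, noise_sd >= 0, length(times) >= 2)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  with_seed(seed, {
    g <- g0 * 2^(-times / t_half) + rnorm(length(times), 0, noise_sd)
    out <- data.frame(time_min = times, glucose_mg_dl = pmax(g, 1))
    attr(out, "truth") <- list(
      g0 = g0, t_half = t_half,
      kitt = if (is.finite(t_half)) 100 * 0.693 / t_half else 0)
    out
  })
}

#' Simulate a vasoactive-drug bolus trial
#'
#' Linear reflex heart-rate responses: `delta_hr = gain * delta_map +`
#' Gaussian noise, one row per bolus.  Pressor trials (phenylephrine)
#' have positive `delta_map` and, physiologically, a negative gain
#' (bradycardia); depressor trials (nitroprusside) have negative
#' `delta_map`.
#'
#' @param gain true reflex gain, bpm/mmHg (finite).
#' @param delta_map_values per-bolus MAP changes, mmHg (non-empty).
#' @param noise_sd HR response noise SD, bpm.
#' @param drug `"pressor"` or `"depressor"`; inferred from the sign of
#'   the MAP changes when omitted.
#' @param seed integer seed.
#' @return A `baro_trial` data frame: `drug`, `dose_mg_per_kg`,
#'   `delta_map`, `delta_hr`, with `attr(,"truth")$gain`.
#' @export
sim_baro_trial <- function(gain, delta_map_values, noise_sd = 0,
                           drug = NULL, seed = NULL) {
  if (!is.finite(gain)) stop("`gain` must be finite")
  if (length(delta_map_values) == 0) stop("empty bolus list")
  stopifnot(noise_sd >= 0)
  if (is.null(drug))
    drug <- if (mean(delta_map_values) >= 0) "pressor" else "depressor"
  drug <- match.arg(drug, c("pressor", "depressor"))
  n <- length(delta_map_values)
  # nominal dose ladders: phenylephrine 0.25-32, nitroprusside 0.05-1.6 mg/kg
  dose <- if (drug == "pressor") pmin(0.25 * 2^(seq_len(n) - 1), 32)
          else pmin(0.05 * 2^(seq_len(n) - 1), 1.6)
  with_seed(seed, {
    out <- data.frame(
      drug = drug, dose_mg_per_kg = dose,
      delta_map = delta_map_values,
      delta_hr = gain * delta_map_values + rnorm(n, 0, noise_sd))
    class(out) <- c("baro_trial", "data.frame")
    attr(out, "truth") <- list(gain = gain)
    out
  })
}
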