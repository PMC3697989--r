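#' Filter bolus responses by the MAP window
#'
#' Only boluses whose absolute MAP change lies in the closed window
#' (default 5-40 mmHg) enter the gain estimate; responses too small are
#' noise-dominated and too-large ones leave the linear reflex range.
#'
#' @param trial a `baro_trial` data frame (columns `delta_map`,
#'   `delta_hr`; see [sim_baro_trial()]).
#' @param window closed interval of acceptable `|delta_map|`, mmHg.
#' @return The retained rows with attribute `n_dropped`; an error if no
#'   bolus survives.
#' @export
filter_responses <- function(trial, window = c(5, 40)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (!nrow(trial)) stop("empty trial")
  keep <- abs(trial$delta_map) >= window[1] &
          abs(trial$delta_map) <= window[2]
  if (!any(keep))
    stop(sprintf("no bolus with |delta MAP| in [%g, %g] mmHg",
                 window[1], window[2]))
  out <- trial[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "truth") <- attr(trial, "truth")
  class(out) <- class(trial)
  out
}

#' Baroreflex sensitivity gain from a bolus trial
#'
#' The gain is the mean over retained boluses of the per-bolus ratio
#' `delta_hr / delta_map` (bpm/mmHg); a regression-slope variant is
#' available for sensitivity analysis.  Pressor trials yield the
#' bradycardic response (BR, reported signed, typically negative);
#' depressor trials yield the tachycardic response (TR, reported as a
#' positive magnitude, the usual tabulation convention).
#'
#' @param trial a `baro_trial`; filtered internally via
#'   [filter_responses()].
#' @param method `"ratio"` (mean of per-bolus ratios, default) or
#'   `"slope"` (least-squares slope of `delta_hr` on `delta_map`).
#' @param window MAP response window passed to [filter_responses()].
#' @return A list of class `reflex_gain`: `gain` (reported convention),
#'   `signed` (raw mean ratio/slope), `drug`, `n`, `method`.
#' @export
reflex_gain <- function(trial, method = c("ratio", "slope"),
                        window = c(5, 40)) {
  method <- match.arg(method)
  kept <- filter_responses(trial, window)
  signed <- if (method == "ratio") {
    mean(kept$delta_hr / kept$delta_map)
  } else {
    unname(coef(lm(delta_hr ~ delta_map, data = kept))[2])
  }
  drug <- as.character(kept$drug[1])
  structure(list(
    gain = if (drug == "depressor") abs(signed) else signed,
    signed = signed, drug = drug, n = nrow(kept), method = method
  ), class = "reflex_gain")
}

#' @export
print.reflex_gain <- function(x, ...) {
  cat(sprintf("<reflex_gain> %s (%s): %.3f bpm/mmHg from %d boluses\n",
              if (x$drug == "pressor") "BR" else "TR",
              x$method, x$gain, x$n))
  invisible(x)
}
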