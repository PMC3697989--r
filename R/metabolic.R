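#' Insulin-sensitivity rate constant (Kitt) from an ITT
#'
#' Glucose disappearance after an insulin bolus is exponential during
#' the linear phase of decline, so the decay rate `k` is the
#' least-squares slope of `ln(glucose)` against time over the fit
#' window (default 4-16 min, excluding the baseline sample).  Then
#' `t_half = ln(2) / k` and `Kitt = 100 * 0.693 / t_half` in %/min.
#' A raw-scale linear fit is available as a sensitivity variant, with
#' the half-life taken from the fitted glucose at the window start.
#' Non-decaying series yield `Kitt = 0` with a flag rather than a
#' negative value.
#'
#' @param times sampling times, min, strictly increasing.
#' @param glucose glucose readings, mg/dL (> 0).
#' @param window fit window `[min, max]` in minutes; needs >= 3 points.
#' @param scale `"log"` (default, ln-linear fit) or `"linear"`.
#' @return A list of class `kitt_result`: `k` (1/min), `t_half` (min),
#'   `kitt` (%/min), `r_squared`, `n`, `window`, `scale`, `non_decay`.
#' @examples
#' itt <- sim_itt(100, t_half = 13.86)
#' kitt(itt$time_min, itt$glucose_mg_dl)$kitt   # 5.0 %/min
#' @export
kitt <- function(times, glucose, window = c(4, 16),
                 scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (is.data.frame(times)) {            # accept a sim_itt() frame directly
    glucose <- times$glucose_mg_dl
    times <- times$time_min
  }
  stopifnot(length(times) == length(glucose), all(glucose > 0))
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 3) stop("need at least 3 points inside the fit window")
  t <- times[sel]
  g <- glucose[sel]
  if (scale == "log") {
    fit <- lm(log(g) ~ t)
    k <- -unname(coef(fit)[2])
  } else {
    fit <- lm(g ~ t)
    m <- -unname(coef(fit)[2])                       # mg/dL per min
    g_start <- unname(predict(fit, data.frame(t = window[1])))
    k <- if (m > 0) log(2) / (0.5 * g_start / m) else m
  }
  y <- if (scale == "log") log(g) else g
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  if (k <= 0) {
    res <- list(k = k, t_half = Inf, kitt = 0, r_squared = r2,
                n = sum(sel), window = window, scale = scale,
                non_decay = TRUE)
  } else {
    t_half <- log(2) / k
    res <- list(k = k, t_half = t_half, kitt = 100 * 0.693 / t_half,
                r_squared = r2, n = sum(sel), window = window,
                scale = scale, non_decay = FALSE)
  }
  structure(res, class = "kitt_result")
}

#' @export
print.kitt_result <- function(x, ...) {
  cat(sprintf("<kitt_result> Kitt %.2f %%/min (t1/2 %.2f min, R2 %.3f%s)\n",
              x$kitt, x$t_half, x$r_squared,
              if (x$non_decay) ", non-decaying" else ""))
  invisible(x)
}

#' Daily caloric intake from chow and fructose water
#'
#' Bookkeeping for the fructose-overload model: chow provides
#' 2.89 kcal/g and dissolved fructose 4.0 kcal/g, with the fructose
#' mass derived from the drunk volume and the solution concentration
#' (default 100 g/L).
#'
#' @param chow_g chow consumed, g/day (vectorised).
#' @param fructose_ml fructose solution drunk, mL/day.
#' @param conc_g_per_l fructose concentration, g/L.
#' @return Data frame: `chow_g`, `fructose_g`, `kcal_chow`,
#'   `kcal_fructose`, `total_kcal`.
#' @export
caloric_intake <- function(chow_g, fructose_ml, conc_g_per_l = 100) {
  if (any(chow_g < 0) || any(fructose_ml < 0) || conc_g_per_l < 0)
    stop("intakes must be non-negative")
  fructose_g <- fructose_ml * conc_g_per_l / 1000
  data.frame(
    chow_g = chow_g, fructose_g = fructose_g,
    kcal_chow = 2.89 * chow_g, kcal_fructose = 4.0 * fructose_g,
    total_kcal = 2.89 * chow_g + 4.0 * fructose_g)
}
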