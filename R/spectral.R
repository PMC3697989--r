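#' LF/HF band edges for rat systolic-pressure variability
#'
#' Low-frequency (sympathetic / Mayer-wave) and high-frequency
#' (respiratory) bands of the rat systogram spectrum.  The bands must
#' tile: `lf[2] == hf[1]`.
#'
#' @param lf,hf numeric length-2 band edges in Hz.
#' @return A list of class `band_definition`.
#' @export
band_definition <- function(lf = c(0.2, 0.6), hf = c(0.6, 3.0)) {
  stopifnot(length(lf) == 2, length(hf) == 2,
            lf[1] < lf[2], hf[1] < hf[2])
  if (!isTRUE(all.equal(lf[2], hf[1])))
    stop("LF upper edge must equal HF lower edge")
  structure(list(lf = lf, hf = hf), class = "band_definition")
}

#' Split a systogram into overlapping segments
#'
#' The per-beat SAP series is divided into fixed-length segments with
#' fractional overlap (default 300 beats, 50 %); a trailing remainder
#' shorter than one hop is dropped.  A series shorter than one segment
#' falls back to a single full-length segment with a warning.
#'
#' @param x numeric systogram (per-beat SAP values).
#' @param length segment length in beats.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return List of numeric segments.
#' @export
segment_systogram <- function(x, length = 300, overlap = 0.5) {
  stopifnot(length >= 2, overlap >= 0, overlap < 1)
  n <- base::length(x)
  if (n < length) {
    warning(sprintf(
      "series (%d beats) shorter than one %d-beat segment; using it whole",
      n, length))
    return(list(x))
  }
  hop <- max(1L, round(length * (1 - overlap)))
  starts <- seq(1L, n - length + 1L, by = hop)
  lapply(starts, function(s) x[s:(s + length - 1L)])
}

#' Levinson-Durbin recursion
#'
#' Solves the Yule-Walker equations for an AR(p) model from the
#' autocovariance sequence.  Coefficients are in predictor form,
#' `x_t = sum_k a_k x_{t-k} + e_t`, so for an AR(1) with `r = c(1, .5)`
#' the recursion gives `a1 = 0.5`.  The prediction-error variance is
#' `sigma2 = r0 * prod(1 - k_i^2)` and its whole path over orders
#' `0..p` is retained for Akaike order selection.
#'
#' @param r autocovariance sequence `r0..r_p` (at least `p + 1` values,
#'   `r0 > 0`).
#' @param p model order (>= 0).
#' @return An object of class `ar_model`: `order`, `a` (coefficients),
#'   `k` (reflection coefficients), `sigma2`, and `sigma2_path`
#'   (sigma2 at orders `0..p`).
#' @export
levinson_durbin <- function(r, p) {
  r <- as.numeric(r)
  stopifnot(p >= 0, length(r) >= p + 1)
  if (r[1] <= 0) stop("autocovariance r0 must be positive")
  a <- numeric(0)
  kk <- numeric(0)
  e <- r[1]
  path <- numeric(p + 1)
  path[1] <- e
  for (m in seq_len(p)) {
    acc <- r[m + 1]
    if (m > 1) acc <- acc - sum(a * r[m:2])
    k_m <- acc / e
    if (!is.finite(k_m) || abs(k_m) >= 1 + 1e-10)
      stop("autocovariance sequence is not positive definite")
    a_new <- c(a, 0) - k_m * c(rev(a), -1)
    a <- a_new
    kk <- c(kk, k_m)
    e <- e * (1 - k_m^2)
    if (e < 0) stop("autocovariance sequence is not positive definite")
    path[m + 1] <- e
  }
  structure(list(order = p, a = a, k = kk, sigma2 = e, sigma2_path = path),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> order %d, sigma2 = %.4g\n", x$order, x$sigma2))
  invisible(x)
}

# biased (divide-by-N) autocovariance of a mean-detrended segment;
# bias guarantees a positive-semidefinite sequence
acov_biased <- function(x, lag_max) {
  as.numeric(acf(x, lag.max = lag_max, type = "covariance",
                 demean = TRUE, plot = FALSE)$acf)
}

#' Akaike order selection for an AR segment
#'
#' Fits AR models of order `p_min..p_max` by a single Levinson-Durbin
#' pass on the biased autocovariance of the mean-detrended segment and
#' picks the order minimising `AIC(p) = N log(sigma2_p) + 2 (p + 1)`;
#' ties go to the smaller order.  A zero-variance (constant) segment
#' returns `p_min` with a flag.
#'
#' @param x numeric segment, longer than `2 * p_max`.
#' @param p_min,p_max order search range.
#' @return List: `order`, `aic` (vector over the range), `zero_variance`.
#' @export
select_order <- function(x, p_min = 4, p_max = 24) {
  n <- length(x)
  stopifnot(p_min >= 1, p_min <= p_max)
  if (n <= 2 * p_max)
    stop(sprintf("segment length %d too short for p_max = %d", n, p_max))
  r <- acov_biased(x, p_max)
  if (r[1] <= .Machine$double.eps * max(1, mean(x)^2))
    return(list(order = p_min, aic = NULL, zero_variance = TRUE))
  fit <- levinson_durbin(r, p_max)
  s2 <- fit$sigma2_path[(p_min:p_max) + 1L]
  s2 <- pmax(s2, .Machine$double.xmin)
  aic <- n * log(s2) + 2 * ((p_min:p_max) + 1)
  list(order = (p_min:p_max)[which.min(aic)], aic = aic,
       zero_variance = FALSE)
}

#' One-sided AR power spectral density
#'
#' Evaluates `PSD(f) = 2 sigma2 / (fs |1 - sum_k a_k e^(-i 2 pi f k / fs)|^2)`
#' on a uniform grid over `[0, fs/2]`; the factor 2 folds the two-sided
#' density so the one-sided integral equals the process variance.
#'
#' @param model an [ar_model()] (must be stable: all characteristic
#'   roots outside the unit circle).
#' @param fs sampling rate of the modelled series, Hz (for a systogram
#'   this is the mean beat rate in beats/s).
#' @param n_freq number of grid points.
#' @return An object of class `ar_spectrum`: `freq`, `psd`, `fs`,
#'   `order`, `sigma2`.
#' @export
ar_spectrum <- function(model, fs, n_freq = 1024) {
  stopifnot(inherits(model, "ar_model"), fs > 0, n_freq >= 16)
  a <- model$a
  if (length(a)) {
    roots <- polyroot(c(1, -a))
    if (any(Mod(roots) <= 1 + 1e-8)) stop("unstable AR model")
  }
  freq <- seq(0, fs / 2, length.out = n_freq)
  if (length(a)) {
    kmat <- outer(freq, seq_along(a), function(f, k)
      exp(-2i * pi * f * k / fs))
    denom <- Mod(1 - as.vector(kmat %*% a))^2
  } else {
    denom <- rep(1, n_freq)
  }
  structure(list(freq = freq, psd = 2 * model$sigma2 / (fs * denom),
                 fs = fs, order = model$order, sigma2 = model$sigma2),
            class = "ar_spectrum")
}

#' Integrate a spectrum over a frequency band
#'
#' Trapezoidal integral of the PSD over `[band[1], band[2]]`, with
#' interpolated band edges.  Bands reaching past Nyquist are clipped
#' with a warning.
#'
#' @param spectrum an [ar_spectrum()] or any list with `freq` and `psd`.
#' @param band numeric length-2, Hz.
#' @return Band power (same units as variance, e.g. mmHg^2).
#' @export
band_power <- function(spectrum, band) {
  stopifnot(length(band) == 2, band[1] < band[2], band[1] >= 0)
  f <- spectrum$freq
  p <- spectrum$psd
  nyq <- max(f)
  if (band[2] > nyq + 1e-12) {
    warning(sprintf("band edge %g Hz beyond Nyquist %g Hz; clipped",
                    band[2], nyq))
    band[2] <- nyq
  }
  if (band[1] >= band[2]) return(0)
  sel <- f > band[1] & f < band[2]
  ff <- c(band[1], f[sel], band[2])
  pp <- c(approx(f, p, band[1])$y, p[sel], approx(f, p, band[2])$y)
  pracma::trapz(ff, pp)
}

#' Autoregressive systolic-pressure variability analysis
#'
#' The systogram is treated as an evenly sampled series at the mean
#' beat rate (beats/s), split into 300-beat segments with 50 % overlap,
#' and each mean-detrended segment is fitted with a Levinson-Durbin AR
#' model at an Akaike-selected order.  Segment spectra are averaged and
#' the LF (0.2-0.6 Hz) and HF (0.6-3.0 Hz) powers integrated from the
#' averaged spectrum.  The headline variance is the time-domain sample
#' variance of the full (mean-detrended) systogram.
#'
#' @param x a [beat_series()], a `hemo_summary`, or a numeric systogram
#'   (per-beat SAP, mmHg).
#' @param mean_beat_rate beats per second; required when `x` is numeric,
#'   otherwise taken from the object.
#' @param segment_length,overlap segmentation policy, in beats.
#' @param p_min,p_max AR order search range.
#' @param n_freq spectral grid size (a dense grid keeps the integrals of
#'   narrow LF peaks accurate).
#' @param bands a [band_definition()].
#' @return An object of class `sap_spectrum`: `freq`, `psd` (averaged),
#'   `variance` (time-domain, mmHg^2), `total_power` (spectral
#'   integral), `lf_power`, `hf_power`, `orders` (per segment),
#'   `n_segments`, `mean_beat_rate`, `bands`.
#' @export
sap_variability <- function(x, mean_beat_rate = NULL,
                            segment_length = 300, overlap = 0.5,
                            p_min = 4, p_max = 24, n_freq = 4096,
                            bands = band_definition()) {
  if (inherits(x, "hemo_summary")) {
    mean_beat_rate <- x$mean_beat_rate
    x <- x$systogram
  } else if (inherits(x, "beat_series")) {
    mean_beat_rate <- attr(x, "mean_beat_rate")
    x <- x$sap
  }
  x <- as.numeric(x)
  if (is.null(mean_beat_rate) || mean_beat_rate <= 0)
    stop("`mean_beat_rate` (beats/s) is required for a bare systogram")
  if (length(x) < 2) stop("systogram needs at least 2 beats")

  variance <- var(x)
  segs <- segment_systogram(x, segment_length, overlap)
  fs <- mean_beat_rate
  freq <- seq(0, fs / 2, length.out = n_freq)
  psd_sum <- numeric(n_freq)
  orders <- integer(length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    pm <- min(p_max, floor((length(s) - 1) / 2))
    sel <- select_order(s, p_min = min(p_min, pm), p_max = pm)
    orders[i] <- sel$order
    if (sel$zero_variance) next                    # flat segment: zero PSD
    fit <- levinson_durbin(acov_biased(s, sel$order), sel$order)
    psd_sum <- psd_sum + ar_spectrum(fit, fs, n_freq)$psd
  }
  psd <- psd_sum / length(segs)
  sp <- list(freq = freq, psd = psd)
  # at rat beat rates the 3 Hz HF edge can exceed the systogram Nyquist
  # (fs/2); the band is then read up to Nyquist
  bp <- function(b) {
    b <- pmin(b, fs / 2)
    if (b[1] >= b[2]) 0 else band_power(sp, b)
  }
  structure(list(
    freq = freq, psd = psd, variance = variance,
    total_power = pracma::trapz(freq, psd),
    lf_power = bp(bands$lf),
    hf_power = bp(bands$hf),
    orders = orders, n_segments = length(segs),
    mean_beat_rate = mean_beat_rate, bands = bands
  ), class = "sap_spectrum")
}

#' @export
print.sap_spectrum <- function(x, ...) {
  cat(sprintf(
    "<sap_spectrum> %d segment(s), AR orders %s | Var %.2f  LF %.2f  HF %.2f mmHg^2\n",
    x$n_segments, paste(x$orders, collapse = "/"),
    x$variance, x$lf_power, x$hf_power))
  invisible(x)
}
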