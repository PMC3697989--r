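# Independent oracles used across the suite.

# Yule-Walker solution by a generic dense linear solve (oracle for the
# Levinson-Durbin recursion)
yw_solve <- function(r, p) {
  solve(stats::toeplitz(r[1:p]), r[2:(p + 1)])
}

# random strictly positive-definite autocovariance: spectral point
# masses plus a white floor
random_pd_acov <- function(p, n_mass = 3) {
  f <- runif(n_mass, 0.02, 0.48)
  w <- runif(n_mass, 0.2, 2)
  r <- sapply(0:p, function(k) sum(w * cos(2 * pi * f * k)))
  r[1] <- r[1] + runif(1, 0.2, 1)
  r
}

# random stable AR(p) built from poles of bounded modulus, so spectra
# stay resolvable on a finite frequency grid
random_stable_ar <- function(p, r_max = 0.95) {
  poles <- complex(0)
  left <- p
  while (left > 0) {
    if (left >= 2 && runif(1) < 0.7) {
      r <- runif(1, 0.3, r_max)
      th <- runif(1, 0.1, pi - 0.1)
      poles <- c(poles, complex(modulus = r, argument = th),
                 complex(modulus = r, argument = -th))
      left <- left - 2
    } else {
      poles <- c(poles, complex(real = runif(1, -r_max, r_max)))
      left <- left - 1
    }
  }
  cf <- 1
  for (pl in poles) cf <- c(cf, 0) - pl * c(0, cf)  # product of (1 - pole z)
  -Re(cf[-1])                                       # A(z) = 1 - sum a_k z^k
}

# theoretical variance of a stable AR(p) with unit innovation variance
ar_process_variance <- function(a, sigma2 = 1) {
  p <- length(a)
  if (p == 0) return(sigma2)
  rho <- stats::ARMAacf(ar = a, lag.max = p)
  sigma2 / (1 - sum(a * rho[2:(p + 1)]))
}

# studentized-range CDF by direct numerical integration (oracle for
# qtukey-based SNK critical values)
srange_cdf <- function(q, k, df) {
  p_range <- function(u) {
    vapply(u, function(ui) {
      if (ui <= 0) return(0)
      k * stats::integrate(function(z)
        stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - ui))^(k - 1),
        -Inf, Inf, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  f_s <- function(s)
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) * exp(-df * s^2 / 2)
  stats::integrate(function(s) f_s(s) * p_range(q * s),
                   0, Inf, rel.tol = 1e-7)$value
}

srange_quantile <- function(p, k, df) {
  stats::uniroot(function(q) srange_cdf(q, k, df) - p,
                 c(0.5, 10), tol = 1e-6)$root
}
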