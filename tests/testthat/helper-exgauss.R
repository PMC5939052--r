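# Shared fixtures: reference parameter sets used across the suite.

# maxLKHD parameters for the young go/nogo and elder go/nogo conditions
young_gng <- list(mu = 451.09, sigma = 47.33, tau = 146.81)
elder_gng <- list(mu = 524.49, sigma = 85.67, tau = 306.65)

# canonical simulation condition for synthetic RT data (ms)
sim_pars <- list(mu = 500, sigma = 50, tau = 150)

# parameter triple for a given asymmetry lambda at location M, scale S
lambda_pars <- function(lamb, M = 500, S = 150) {
  list(mu = M - S * lamb, sigma = S * sqrt(1 - lamb^2), tau = S * lamb)
}

# integration window wide enough for absolute tail error ~1e-12
exg_window <- function(p) {
  M <- p$mu + p$tau
  S <- sqrt(p$sigma^2 + p$tau^2)
  c(M - 12 * S, M + 40 * S)
}

# convolution-integral oracle for the density: integral over the Gaussian
# component of gauss * shifted exponential (independent of the package path).
# The Gaussian factor kills the integrand outside mu +/- 12 sigma, so the
# window is truncated there to keep the adaptive quadrature on the peak.
conv_pdf <- function(x, p) {
  vapply(x, function(xi) {
    lo <- p$mu - 12 * p$sigma
    hi <- min(xi, p$mu + 12 * p$sigma)
    if (hi <= lo) return(0)
    stats::integrate(function(u) dnorm(u, p$mu, p$sigma) *
                       dexp(xi - u, rate = 1 / p$tau),
                     lower = lo, upper = hi,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, numeric(1))
}

# log-space oracle built on R's Gaussian log upper-tail (an independent
# numeric route from the compiled erfc/asymptotic evaluation), valid deep in
# both tails: ln erfc(u) = ln 2 + ln P(Z > u * sqrt(2))
pnorm_log_pdf <- function(x, p) {
  u <- ((p$mu - x) / p$sigma + p$sigma / p$tau) / sqrt(2)
  -log(2 * p$tau) + (p$mu - x) / p$tau + p$sigma^2 / (2 * p$tau^2) +
    log(2) + pnorm(u * sqrt(2), lower.tail = FALSE, log.p = TRUE)
}
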