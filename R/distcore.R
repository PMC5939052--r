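# Distribution core: stable pdf/CDF/quantile of the ex-Gaussian in the
# (mu, sigma, tau) and standardized lambda parameterizations, conversions
# between parameters and moments, and the low-level numerics (root finding,
# fixed-order Gauss-Legendre quadrature) they rely on.

exg_stop <- function(msg, class = "exg_domain_error") {
  stop(errorCondition(msg, class = c(class, "exg_error")))
}

check_params <- function(mu, sigma, tau) {
  if (length(mu) != 1L || length(sigma) != 1L || length(tau) != 1L ||
      !is.finite(mu) || !is.finite(sigma) || !is.finite(tau))
    exg_stop("mu, sigma and tau must be finite scalars")
  if (sigma <= 0)
    exg_stop("sigma must be > 0 (sigma = 0 is the degenerate pure-exponential limit)")
  if (tau <= 0)
    exg_stop("tau must be > 0 (tau = 0 is the degenerate pure-Gaussian limit)")
  invisible(TRUE)
}

check_lambda <- function(lamb) {
  if (length(lamb) != 1L || !is.finite(lamb))
    exg_stop("lambda must be a finite scalar")
  if (lamb <= 0 || lamb >= 1)
    exg_stop(paste0("lambda must lie strictly in (0, 1): lambda = 0 is the ",
                    "Gaussian limit (use gauss_pdf/gauss_cdf), lambda = 1 ",
                    "the pure exponential"))
  invisible(TRUE)
}

#' Gaussian density and distribution function
#'
#' Thin domain-checked wrappers around [stats::dnorm()] and [stats::pnorm()],
#' provided so that the Gaussian component of the ex-Gaussian model carries
#' the same argument conventions and error behaviour as the rest of the
#' toolkit.
#'
#' @param x numeric vector of evaluation points (ms).
#' @param mu mean of the Gaussian component (ms).
#' @param sigma standard deviation, must be > 0 (ms).
#' @return `gauss_pdf` the density, `gauss_cdf` the left-tail probability.
#' @examples
#' gauss_pdf(0, 0, 1)   # 1/sqrt(2*pi)
#' gauss_cdf(500, 500, 50)  # 0.5
#' @export
gauss_pdf <- function(x, mu = 0, sigma = 1) {
  if (!is.finite(sigma) || sigma <= 0) exg_stop("sigma must be > 0")
  dnorm(x, mean = mu, sd = sigma)
}

#' @rdname gauss_pdf
#' @export
gauss_cdf <- function(x, mu = 0, sigma = 1) {
  if (!is.finite(sigma) || sigma <= 0) exg_stop("sigma must be > 0")
  pnorm(x, mean = mu, sd = sigma)
}

#' The ex-Gaussian distribution
#'
#' Density, distribution function, and quantile function of the ex-Gaussian
#' (exponentially modified Gaussian) law: the distribution of Z = X + Y with
#' X ~ Gaussian(mu, sigma) and Y ~ Exponential(mean tau). The density is
#'
#' \deqn{f(x) = \frac{1}{2\tau}\exp\!\Big(\frac{\mu - x}{\tau} +
#'   \frac{\sigma^2}{2\tau^2}\Big)\,
#'   \mathrm{erfc}\!\Big(\frac{(\mu - x)/\sigma + \sigma/\tau}{\sqrt{2}}\Big)}
#'
#' Direct evaluation of the exp–erfc product overflows when the erfc argument
#' is large (far left tail, or small tau relative to sigma); all evaluation
#' is therefore done in log space with \eqn{\ln \mathrm{erfc}} computed from
#' the Gaussian log upper-tail, which keeps log-densities finite for any
#' finite argument. This matters for maximum likelihood on samples with
#' extreme observations, whose log-density must be finite to be compared.
#'
#' `qexgauss` inverts the CDF by safeguarded root finding: the initial
#' bracket \eqn{[M - 10S, M + 20S]} (M, S the distribution mean and SD) is
#' doubled outward until it straddles the target probability, then refined
#' with [find_zero()].
#'
#' @param x,q numeric vector of quantiles (ms).
#' @param p numeric vector of probabilities, strictly inside (0, 1).
#' @param mu Gaussian component location (ms).
#' @param sigma Gaussian component SD, > 0 (ms).
#' @param tau exponential component mean, > 0 (ms).
#' @param log,log.p logical; return (or accept) log scale values.
#' @param lower.tail logical; if FALSE, probabilities are right tails.
#' @return `dexgauss` the density (or log-density), `pexgauss` probabilities,
#'   `qexgauss` quantiles in ms.
#' @seealso [dexgauss_lambda()] for the standardized parameterization,
#'   [pars_to_stats()] for the moment description.
#' @examples
#' dexgauss(600, mu = 500, sigma = 50, tau = 150)
#' pexgauss(1472.84, 451.09, 47.33, 146.81)   # ~0.999
#' qexgauss(0.999, 451.09, 47.33, 146.81)     # ~1472.84 ms
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  check_params(mu, sigma, tau)
  lp <- cpp_exg_logpdf(as.numeric(x), mu, sigma, tau)
  if (log) lp else exp(lp)
}

#' @rdname dexgauss
#' @export
pexgauss <- function(q, mu, sigma, tau, lower.tail = TRUE, log.p = FALSE) {
  check_params(mu, sigma, tau)
  pr <- cpp_exg_cdf(as.numeric(q), mu, sigma, tau)
  if (!lower.tail) pr <- 1 - pr
  if (log.p) log(pr) else pr
}

#' @rdname dexgauss
#' @export
qexgauss <- function(p, mu, sigma, tau, lower.tail = TRUE) {
  check_params(mu, sigma, tau)
  if (!lower.tail) p <- 1 - p
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    exg_stop("p must lie strictly in (0, 1)")
  M <- mu + tau
  S <- sqrt(sigma^2 + tau^2)
  vapply(p, function(pi) {
    lo <- M - 10 * S
    hi <- M + 20 * S
    f <- function(x) cpp_exg_cdf(x, mu, sigma, tau) - pi
    k <- 0L
    while (f(lo) > 0 && k < 60L) { lo <- lo - (hi - lo); k <- k + 1L }
    k <- 0L
    while (f(hi) < 0 && k < 60L) { hi <- hi + (hi - lo); k <- k + 1L }
    find_zero(f, lo, hi, tol = 1e-12)
  }, numeric(1))
}

#' Standardized ex-Gaussian family indexed by its asymmetry
#'
#' The ex-Gaussian rescaled to mean 0 and SD 1 forms a one-parameter family
#' indexed by lambda = tau / sqrt(sigma^2 + tau^2), the asymmetry: lambda -> 0
#' is the Gaussian limit, lambda -> 1 the exponential limit, and the skewness
#' is K = 2 lambda^3. Rather than evaluating a separately transcribed
#' standardized formula, the functions substitute mu = -lambda,
#' sigma = sqrt(1 - lambda^2), tau = lambda into the canonical forms, which
#' standardizes by construction.
#'
#' @param z numeric vector of standard coordinates, z = (x - M)/S.
#' @param lamb asymmetry, strictly in (0, 1).
#' @param log,log.p,lower.tail as in [dexgauss()].
#' @return density or probability at `z`.
#' @examples
#' dexgauss_lambda(0, lamb = 0.5)
#' pexgauss_lambda(2, lamb = 0.9)
#' @export
dexgauss_lambda <- function(z, lamb, log = FALSE) {
  check_lambda(lamb)
  dexgauss(z, mu = -lamb, sigma = sqrt(1 - lamb^2), tau = lamb, log = log)
}

#' @rdname dexgauss_lambda
#' @export
pexgauss_lambda <- function(z, lamb, lower.tail = TRUE, log.p = FALSE) {
  check_lambda(lamb)
  pexgauss(z, mu = -lamb, sigma = sqrt(1 - lamb^2), tau = lamb,
           lower.tail = lower.tail, log.p = log.p)
}

#' Convert between ex-Gaussian parameters and distribution moments
#'
#' The ex-Gaussian mean, SD and skewness are M = mu + tau,
#' S = sqrt(sigma^2 + tau^2) and K = 2 (tau/S)^3. The inverse goes through
#' the asymmetry lambda = (K/2)^(1/3): mu = M - S lambda,
#' sigma = S sqrt(1 - lambda^2), tau = S lambda. The inversion exists only
#' for 0 < K < 2; at K >= 2 sigma would not be real (skewness 2 is the pure
#' exponential bound), so `stats_to_pars` raises a domain error — this is
#' exactly the regime where the method of moments fails on skewed RT data.
#'
#' @param mu,sigma,tau ex-Gaussian parameters (ms, ms, ms).
#' @param M,S,K distribution mean (ms), SD (ms) and skewness.
#' @return a named numeric vector: `pars_to_stats` gives `c(M, S, K)`,
#'   `stats_to_pars` gives `c(mu, sigma, tau)`.
#' @examples
#' pars_to_stats(524.49, 85.67, 306.65)
#' stats_to_pars(831.14, 318.95, 1.75)
#' @export
pars_to_stats <- function(mu, sigma, tau) {
  check_params(mu, sigma, tau)
  S <- sqrt(sigma^2 + tau^2)
  c(M = mu + tau, S = S, K = 2 * (tau / S)^3)
}

#' @rdname pars_to_stats
#' @export
stats_to_pars <- function(M, S, K) {
  if (!is.finite(M) || !is.finite(S) || !is.finite(K))
    exg_stop("M, S and K must be finite")
  if (S <= 0) exg_stop("S must be > 0")
  if (K >= 2)
    exg_stop(paste0("skewness K = ", format(K), " >= 2: no ex-Gaussian has ",
                    "skewness at or above the exponential bound, sigma ",
                    "would not be real"), class = "exg_moments_error")
  if (K <= 0)
    exg_stop(paste0("skewness K = ", format(K), " <= 0: the ex-Gaussian is ",
                    "strictly right-skewed"), class = "exg_moments_error")
  lamb <- (K / 2)^(1 / 3)
  c(mu = M - S * lamb, sigma = S * sqrt(1 - lamb^2), tau = S * lamb)
}

#' Find a root of a univariate function on a bracketing interval
#'
#' Deterministic, derivative-free safeguarded root finder: bisection with a
#' secant-step acceleration (the secant proposal is used whenever it falls
#' inside the current bracket, otherwise the step bisects). Stops when
#' |fn(root)| <= tol or the bracket width falls below tol.
#'
#' @param fn function of one numeric argument.
#' @param lower,upper bracket endpoints with `fn(lower) * fn(upper) <= 0`.
#' @param tol stopping tolerance on |fn| and on the bracket width.
#' @param max_iter iteration cap.
#' @return the root, a length-one numeric.
#' @examples
#' find_zero(function(x) x^2 - 4, 0, 10)
#' @export
find_zero <- function(fn, lower, upper, tol = 1e-10, max_iter = 200L) {
  if (!(lower < upper)) exg_stop("lower must be < upper")
  flo <- fn(lower); fhi <- fn(upper)
  if (!is.finite(flo) || !is.finite(fhi))
    exg_stop("fn must be finite at the bracket endpoints")
  if (flo == 0) return(lower)
  if (fhi == 0) return(upper)
  if (flo * fhi > 0)
    exg_stop("fn does not change sign on [lower, upper]",
             class = "exg_bracket_error")
  lo <- lower; hi <- upper
  for (i in seq_len(max_iter)) {
    # secant proposal, safeguarded to the interior of the bracket
    xs <- lo - flo * (hi - lo) / (fhi - flo)
    xm <- (lo + hi) / 2
    x <- if (is.finite(xs) && xs > lo && xs < hi) xs else xm
    # never let the bracket shrink too slowly: alternate with bisection
    if (abs(x - xm) > 0.45 * (hi - lo)) x <- xm
    fx <- fn(x)
    if (!is.finite(fx)) { x <- xm; fx <- fn(x) }
    if (abs(fx) <= tol || (hi - lo) <= tol) return(x)
    if (flo * fx <= 0) { hi <- x; fhi <- fx } else { lo <- x; flo <- fx }
  }
  (lo + hi) / 2
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch (eigen-decomposition
# of the Jacobi matrix); cached per order.
gl_cache <- new.env(parent = emptyenv())
gl_rule <- function(order) {
  key <- as.character(order)
  if (!is.null(gl_cache[[key]])) return(gl_cache[[key]])
  if (order == 1L) {
    rule <- list(x = 0, w = 2)
  } else {
    i <- seq_len(order - 1L)
    bb <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, order, order)
    J[cbind(i, i + 1L)] <- bb
    J[cbind(i + 1L, i)] <- bb
    e <- eigen(J, symmetric = TRUE)
    rule <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
  }
  gl_cache[[key]] <- rule
  rule
}

#' Fixed-order Gauss-Legendre quadrature
#'
#' Composite Gauss-Legendre integration of `fn` over \[a, b\]: the interval is
#' split into `panels` equal panels and an `order`-point rule is applied to
#' each. A single panel of order n is exact for polynomials up to degree
#' 2n - 1. Used internally for the moment and normalization identities of the
#' ex-Gaussian; improper integrals are truncated by the caller (the
#' exponential right tail makes \[M - 12S, M + 40S\] sufficient for absolute
#' errors below 1e-10).
#'
#' @param fn vectorized function of one numeric argument.
#' @param a,b integration limits, a < b, both finite.
#' @param order points per panel (default 64).
#' @param panels number of equal panels (default 1).
#' @return the quadrature estimate of the integral.
#' @examples
#' integrate_gl(function(x) x^5, 0, 1, order = 3)  # exactly 1/6
#' @export
integrate_gl <- function(fn, a, b, order = 64L, panels = 1L) {
  if (!is.finite(a) || !is.finite(b) || a >= b)
    exg_stop("need finite a < b")
  if (order < 1L) exg_stop("order must be >= 1")
  rule <- gl_rule(as.integer(order))
  edges <- seq(a, b, length.out = panels + 1L)
  total <- 0
  for (k in seq_len(panels)) {
    lo <- edges[k]; hi <- edges[k + 1L]
    xs <- (hi - lo) / 2 * rule$x + (hi + lo) / 2
    total <- total + (hi - lo) / 2 * sum(rule$w * fn(xs))
  }
  total
}
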