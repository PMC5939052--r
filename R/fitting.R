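# Estimation: sample/histogram moments, the histogram builder, the two
# gradient objectives (histogram least squares and log-likelihood) with
# analytic gradients, the adaptive steepest descent/ascent engine, and the
# three fitting procedures built on them.

#' Optimizer options for the steepest descent/ascent engine
#'
#' @param step0 initial step scale; if `NULL`, the fitting functions use
#'   1e-3 times the sample SD, so step sizes start on the scale of the data.
#' @param tol stopping tolerance: iteration stops once the gradient norm
#'   falls below `tol * max(1, |objective|)`.
#' @param max_iter iteration cap.
#' @return a list of class `exg_opts`.
#' @export
exg_opts <- function(step0 = NULL, tol = 1e-8, max_iter = 20000L) {
  if (!is.null(step0) && (!is.finite(step0) || step0 <= 0))
    exg_stop("step0 must be > 0")
  if (!is.finite(tol) || tol <= 0) exg_stop("tol must be > 0")
  if (!is.finite(max_iter) || max_iter < 1) exg_stop("max_iter must be >= 1")
  structure(list(step0 = step0, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "exg_opts")
}

check_sample <- function(x, n_min = 1L) {
  x <- as.numeric(x)
  if (length(x) < n_min || any(!is.finite(x)))
    exg_stop(sprintf("sample must hold at least %d finite values", n_min),
             class = "exg_degenerate_error")
  x
}

#' Sample mean, standard deviation and skewness
#'
#' Population (divide-by-N) moments: M is the mean, S the population SD, K
#' the third standardized central moment. Population rather than N-1 moments
#' are used because the method of moments equates sample moments directly to
#' the distribution moments M = mu + tau, S^2 = sigma^2 + tau^2,
#' K = 2 (tau/S)^3.
#'
#' @param x numeric vector of observations (ms), n >= 3.
#' @return named numeric vector `c(M, S, K)`.
#' @examples
#' sample_stats(c(1, 2, 3))  # M = 2, S = sqrt(2/3), K = 0
#' @export
sample_stats <- function(x) {
  x <- check_sample(x, 3L)
  M <- mean(x)
  S <- sqrt(mean((x - M)^2))
  if (S == 0)
    exg_stop("constant sample: moments are degenerate",
             class = "exg_degenerate_error")
  c(M = M, S = S, K = mean(((x - M) / S)^3))
}

#' Build a density-normalized histogram of a sample
#'
#' Equal-width bins spanning \[min(x), max(x)\]; heights are densities
#' (count / (n * width)), so `sum(density * width) == 1`. The default bin
#' count is `round(2 * sqrt(n))` — e.g. 20 bins for n = 100 and 98 bins for
#' n = 2396 — which is the default used throughout the least-squares fits.
#'
#' @param x numeric observations (ms), n >= 2, non-constant.
#' @param nbins number of bins (>= 2); default `round(2 * sqrt(length(x)))`.
#' @return a list of class `exg_hist` with fields `edges` (length nbins + 1),
#'   `centers`, `widths`, `density`, `counts` and `n_source`.
#' @examples
#' h <- build_histogram(exgauss_sample(400, 500, 50, 150, seed = 1))
#' sum(h$density * h$widths)  # 1
#' @export
build_histogram <- function(x, nbins = NULL) {
  x <- check_sample(x, 2L)
  rng <- range(x)
  if (rng[1] == rng[2])
    exg_stop("constant sample: histogram range is zero",
             class = "exg_degenerate_error")
  n <- length(x)
  if (is.null(nbins)) nbins <- round(2 * sqrt(n))
  nbins <- as.integer(nbins)
  if (nbins < 2L) exg_stop("nbins must be >= 2")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins)
  widths <- diff(edges)
  structure(list(edges = edges,
                 centers = (edges[-1L] + edges[-(nbins + 1L)]) / 2,
                 widths = widths,
                 density = counts / (n * widths),
                 counts = counts,
                 n_source = n),
            class = "exg_hist")
}

#' Moments of a binned sample
#'
#' M, S, K computed from bin centers weighted by `density * width`. Agrees
#' with [sample_stats()] up to binning error (within about one bin width).
#'
#' @param hist an `exg_hist` from [build_histogram()].
#' @return named numeric vector `c(M, S, K)`.
#' @export
histogram_stats <- function(hist) {
  if (!inherits(hist, "exg_hist")) exg_stop("hist must be an exg_hist")
  w <- hist$density * hist$widths
  if (sum(w > 0) < 2L)
    exg_stop("all mass in one bin: moments are degenerate",
             class = "exg_degenerate_error")
  M <- sum(w * hist$centers)
  S <- sqrt(sum(w * (hist$centers - M)^2))
  c(M = M, S = S, K = sum(w * ((hist$centers - M) / S)^3))
}

#' Fit by the method of moments
#'
#' Equates the sample M, S, K to the distribution moments and inverts
#' through [stats_to_pars()]. Fails with a domain error when the sample
#' skewness is at or above 2 (or non-positive), where no real sigma exists —
#' a situation routinely produced by a few extreme reaction times.
#'
#' @param x numeric observations (ms), n >= 3.
#' @return an `exg_fit` object (see [fit_mle()]).
#' @export
fit_moments <- function(x) {
  st <- sample_stats(x)
  p <- stats_to_pars(st[["M"]], st[["S"]], st[["K"]])
  new_fit(p, method = "moments", objective = NA_real_, converged = TRUE,
          n_iter = 0L, grad_norm = 0)
}

new_fit <- function(p, method, objective, converged, n_iter, grad_norm,
                    nbins = NULL) {
  structure(list(mu = unname(p[1]), sigma = unname(p[2]), tau = unname(p[3]),
                 method = method, objective = objective,
                 converged = isTRUE(converged), n_iter = as.integer(n_iter),
                 grad_norm = grad_norm, nbins = nbins),
            class = "exg_fit")
}

#' @export
print.exg_fit <- function(x, ...) {
  st <- pars_to_stats(x$mu, x$sigma, x$tau)
  cat(sprintf("ex-Gaussian fit (%s)\n", x$method))
  cat(sprintf("  mu = %.6g  sigma = %.6g  tau = %.6g\n", x$mu, x$sigma, x$tau))
  cat(sprintf("  M  = %.6g  S     = %.6g  K   = %.6g\n",
              st[["M"]], st[["S"]], st[["K"]]))
  if (!is.na(x$objective))
    cat(sprintf("  objective = %.8g  converged = %s  iterations = %d  |grad| = %.3g\n",
                x$objective, x$converged, x$n_iter, x$grad_norm))
  invisible(x)
}

#' Gradient objectives for the two density fits
#'
#' `lkhd_value_grad` returns the log-likelihood
#' \eqn{\ln L = \sum_i \ln f(x_i; \mu, \sigma, \tau)} and its analytic
#' gradient in (mu, sigma, tau); evaluation is in log space, so extreme
#' observations contribute finite terms. `sqr_value_grad` returns the
#' histogram least-squares objective — the sum over bins of
#' (density_i - f(center_i))^2 — and its analytic gradient.
#'
#' @param x numeric observations (ms).
#' @param hist an `exg_hist` from [build_histogram()].
#' @param mu,sigma,tau evaluation point in parameter space.
#' @return list with `value` (scalar) and `grad` (length-3 numeric, order
#'   mu, sigma, tau).
#' @export
lkhd_value_grad <- function(x, mu, sigma, tau) {
  check_params(mu, sigma, tau)
  x <- check_sample(x, 1L)
  cpp_lkhd(x, mu, sigma, tau)
}

#' @rdname lkhd_value_grad
#' @export
sqr_value_grad <- function(hist, mu, sigma, tau) {
  if (!inherits(hist, "exg_hist")) exg_stop("hist must be an exg_hist")
  check_params(mu, sigma, tau)
  cpp_sqr(hist$centers, hist$density, mu, sigma, tau)
}

#' Steepest descent/ascent with an adaptive scalar step
#'
#' Follows the gradient with step `p <- p +/- eta * grad`. A step is accepted
#' only if the objective improves; accepted steps double `eta`, rejected ones
#' halve it and retry, and steps that would drive sigma or tau non-positive
#' count as rejections. Iteration stops when the gradient norm falls below
#' `tol * max(1, |objective|)`, when no further improving step exists at any
#' step size, or at `max_iter`; the `converged` flag reports only the
#' gradient criterion. Deterministic given (`value_grad`, `init`, `opts`).
#'
#' The compiled fitting paths ([fit_mle()], [fit_lsq()]) run this same
#' schedule; this R entry point accepts an arbitrary objective.
#'
#' @param value_grad function taking a length-3 numeric parameter vector and
#'   returning `list(value =, grad =)`.
#' @param init length-3 numeric starting point (mu, sigma, tau order; the
#'   positivity guard applies to components 2 and 3).
#' @param sense `"max"` for ascent, `"min"` for descent.
#' @param opts an [exg_opts()] list; `step0` defaults to 1 here.
#' @param positive logical length-3; which components must stay > 0.
#' @return an `exg_fit`-like list with `par`, `value`, `n_iter`,
#'   `grad_norm`, `converged`.
#' @export
steepest_extremum <- function(value_grad, init, sense = c("max", "min"),
                              opts = exg_opts(),
                              positive = c(FALSE, TRUE, TRUE)) {
  sense <- match.arg(sense)
  s <- if (sense == "max") 1 else -1
  p <- as.numeric(init)
  vg <- value_grad(p)
  if (!is.finite(vg$value))
    exg_stop("objective is not finite at the initial parameters")
  eta <- if (is.null(opts$step0)) 1 else opts$step0
  it <- 0L
  converged <- FALSE
  gnorm <- sqrt(sum(vg$grad^2))
  while (it < opts$max_iter) {
    if (gnorm <= opts$tol * max(1, abs(vg$value))) { converged <- TRUE; break }
    it <- it + 1L
    accepted <- FALSE
    for (h in seq_len(200L)) {
      q <- p + s * eta * vg$grad
      if (all(q[positive] > 0)) {
        vq <- value_grad(q)
        if (is.finite(vq$value) &&
            (if (s > 0) vq$value > vg$value else vq$value < vg$value)) {
          p <- q; vg <- vq
          gnorm <- sqrt(sum(vg$grad^2))
          eta <- eta * 2
          accepted <- TRUE
          break
        }
      }
      eta <- eta / 2
      if (eta <= 0 || !is.finite(eta)) break
    }
    if (!accepted) break
  }
  if (gnorm <= opts$tol * max(1, abs(vg$value))) converged <- TRUE
  list(par = p, value = vg$value, n_iter = it, grad_norm = gnorm,
       converged = converged)
}

# shared init policy: method of moments, falling back to the lambda = 0.8
# point of the moment inversion when the sample skewness is out of range
default_init <- function(x) {
  init <- tryCatch({
    f <- fit_moments(x)
    c(f$mu, f$sigma, f$tau)
  }, exg_moments_error = function(e) NULL)
  if (is.null(init)) {
    st <- sample_stats(x)
    init <- c(st[["M"]] - 0.8 * st[["S"]], 0.6 * st[["S"]], 0.8 * st[["S"]])
  }
  init
}

run_cpp_fit <- function(type, a, b, init, sense, x_scale, opts, method,
                        nbins = NULL) {
  step0 <- if (is.null(opts$step0)) 1e-3 * x_scale else opts$step0
  r <- cpp_steepest(type, a, b, init, sense, step0, opts$tol, opts$max_iter)
  new_fit(r$par, method = method, objective = r$value,
          converged = r$converged, n_iter = r$n_iter,
          grad_norm = r$grad_norm, nbins = nbins)
}

#' Fit the ex-Gaussian by maximum likelihood or histogram least squares
#'
#' `fit_mle` maximizes the log-likelihood by steepest ascent; `fit_lsq`
#' builds a density-normalized histogram (default `round(2 * sqrt(n))` bins)
#' and minimizes the sum of squared differences between bin densities and the
#' theoretical density at bin centers by steepest descent. Both start from
#' the method-of-moments estimate when it exists, otherwise from the
#' lambda = 0.8 fallback (M - 0.8 S, 0.6 S, 0.8 S) — the high-skew regime in
#' which moments fail. Non-convergence within `max_iter` is reported through
#' `converged = FALSE`, not an error.
#'
#' @param x numeric observations (ms), n >= 3.
#' @param nbins histogram bin count for `fit_lsq` (default 2 sqrt(n) rule).
#' @param hist optionally, a pre-built `exg_hist` for `fit_lsq` (overrides
#'   `x` and `nbins` for the objective; useful for fitting an externally
#'   constructed density).
#' @param init optional length-3 starting values (mu, sigma, tau).
#' @param opts an [exg_opts()] control list.
#' @return an object of class `exg_fit`: fields `mu`, `sigma`, `tau`,
#'   `method`, `objective` (log-likelihood or sum of squares), `converged`,
#'   `n_iter`, `grad_norm`, and for `fit_lsq` the `nbins` used.
#' @examples
#' rt <- exgauss_sample(2000, 500, 50, 150, seed = 11)
#' fit_mle(rt)
#' fit_lsq(rt)
#' @export
fit_mle <- function(x, init = NULL, opts = exg_opts()) {
  x <- check_sample(x, 3L)
  if (is.null(init)) init <- default_init(x)
  run_cpp_fit(1L, x, numeric(0), init, 1L, sample_stats(x)[["S"]], opts,
              method = "maxLKHD")
}

#' @rdname fit_mle
#' @export
fit_lsq <- function(x = NULL, nbins = NULL, hist = NULL, init = NULL,
                    opts = exg_opts()) {
  if (is.null(hist)) {
    x <- check_sample(x, 3L)
    hist <- build_histogram(x, nbins)
  } else if (!inherits(hist, "exg_hist")) {
    exg_stop("hist must be an exg_hist")
  }
  if (is.null(init)) {
    init <- if (!is.null(x)) default_init(x) else {
      st <- histogram_stats(hist)
      tryCatch(unname(stats_to_pars(st[["M"]], st[["S"]], st[["K"]])),
               exg_moments_error = function(e)
                 c(st[["M"]] - 0.8 * st[["S"]], 0.6 * st[["S"]],
                   0.8 * st[["S"]]))
    }
  }
  scale <- if (!is.null(x)) sample_stats(x)[["S"]] else
    histogram_stats(hist)[["S"]]
  run_cpp_fit(2L, hist$centers, hist$density, init, -1L, scale, opts,
              method = "minSQR", nbins = length(hist$centers))
}
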