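# Goodness of fit: KS statistic, parametric-bootstrap p-value, tail-quantile
# trimming and the histogram bin-count sensitivity scan.

#' Kolmogorov-Smirnov distance between a sample and an ex-Gaussian
#'
#' The classical one-sample statistic
#' D = max_i max(|i/N - F(x_(i))|, |(i-1)/N - F(x_(i))|) with F the
#' ex-Gaussian CDF. Because it needs no binning, D is the parametrization-free
#' distance used for bootstrap goodness of fit. Alongside D the scaled value
#' N * D is returned, the convention used when reporting KS values for RT
#' datasets of a fixed size; all decisions in this package use D (data and
#' bootstrap replicates share N, so any fixed monotone rescaling gives the
#' same p-value).
#'
#' @param x numeric observations (ms).
#' @param mu,sigma,tau ex-Gaussian parameters of the reference distribution.
#' @return named numeric vector `c(D, scaled)` with `scaled = length(x) * D`.
#' @examples
#' rt <- exgauss_sample(500, 500, 50, 150, seed = 3)
#' ks_statistic(rt, 500, 50, 150)
#' @export
ks_statistic <- function(x, mu, sigma, tau) {
  check_params(mu, sigma, tau)
  x <- check_sample(x, 1L)
  n <- length(x)
  Fx <- pexgauss(sort(x), mu, sigma, tau)
  i <- seq_len(n)
  D <- max(pmax(abs(i / n - Fx), abs((i - 1) / n - Fx)))
  c(D = D, scaled = n * D)
}

fit_by_method <- function(x, method, nbins = NULL, opts = exg_opts()) {
  switch(method,
         maxLKHD = fit_mle(x, opts = opts),
         minSQR = fit_lsq(x, nbins = nbins, opts = opts),
         exg_stop("method must be 'maxLKHD' or 'minSQR'"))
}

#' Parametric-bootstrap p-value for an ex-Gaussian fit
#'
#' Generalization of the power-law bootstrap of Clauset and colleagues to the
#' ex-Gaussian: (1) fit the sample by `method` and record its KS distance to
#' the fitted distribution; (2) repeatedly draw samples of the same size from
#' that fitted distribution, refit each with the same procedure (including
#' the same histogram bin rule for minSQR), and record each replicate's KS
#' distance to its own refit; (3) p is the fraction of replicates whose KS
#' distance is at least the empirical one. A large p means samples genuinely
#' drawn from the fitted model look at least as discrepant as the data, so
#' the ex-Gaussian hypothesis stands; p is reported as a plain fraction, so
#' 0 is possible.
#'
#' @param x numeric observations (ms).
#' @param method `"maxLKHD"` (default) or `"minSQR"`.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed for the replicate draws.
#' @param nbins histogram bin count for minSQR fits (default 2 sqrt(n) rule,
#'   re-applied to each replicate).
#' @param opts an [exg_opts()] control list used for every fit.
#' @return an object of class `exg_gof` with fields `method`, `ks_D`,
#'   `ks_scaled`, `B`, `p`, `null_mean`, `null_sd` (mean and SD of the
#'   scaled replicate KS values), `null_ks` (the replicate D values),
#'   `n_warn` (replicate refits that hit the iteration cap; their
#'   best-effort KS still counts), `seed`, and the empirical `fit`.
#' @examples
#' rt <- exgauss_sample(300, 500, 50, 150, seed = 5)
#' bootstrap_pvalue(rt, B = 50, seed = 9)
#' @export
bootstrap_pvalue <- function(x, method = c("maxLKHD", "minSQR"), B = 1000L,
                             seed = 0L, nbins = NULL, opts = exg_opts()) {
  method <- match.arg(method)
  x <- check_sample(x, 3L)
  if (!is.finite(B) || B < 1) exg_stop("B must be >= 1")
  B <- as.integer(B)
  n <- length(x)
  fit <- fit_by_method(x, method, nbins = nbins, opts = opts)
  ks_emp <- ks_statistic(x, fit$mu, fit$sigma, fit$tau)
  state <- rng_state(seed)
  ks_b <- numeric(B)
  n_warn <- 0L
  for (b in seq_len(B)) {
    xb <- exgauss_rv(state, n, fit$mu, fit$sigma, fit$tau)
    fb <- fit_by_method(xb, method, nbins = nbins, opts = opts)
    if (!fb$converged) n_warn <- n_warn + 1L
    ks_b[b] <- ks_statistic(xb, fb$mu, fb$sigma, fb$tau)[["D"]]
  }
  structure(list(method = method,
                 ks_D = ks_emp[["D"]],
                 ks_scaled = ks_emp[["scaled"]],
                 B = B,
                 p = mean(ks_b >= ks_emp[["D"]]),
                 null_mean = mean(n * ks_b),
                 null_sd = stats::sd(n * ks_b),
                 null_ks = ks_b,
                 n_warn = n_warn,
                 seed = as.integer(seed),
                 fit = fit),
            class = "exg_gof")
}

#' @export
print.exg_gof <- function(x, ...) {
  cat(sprintf("ex-Gaussian bootstrap goodness of fit (%s)\n", x$method))
  cat(sprintf("  KS D = %.6g (scaled N*D = %.4f)\n", x$ks_D, x$ks_scaled))
  cat(sprintf("  p = %.3f from B = %d replicates (null N*D = %.2f +/- %.2f)\n",
              x$p, x$B, x$null_mean, x$null_sd))
  if (x$n_warn > 0)
    cat(sprintf("  %d replicate refits hit the iteration cap\n", x$n_warn))
  invisible(x)
}

#' Tail cutoff points of a fitted ex-Gaussian
#'
#' The quantile pair (q, 1 - q): beyond these points each tail holds a
#' fraction q of the fitted distribution. With the default q = 0.001 the
#' upper point answers "beyond which RT should no more than 0.1% of
#' measurements fall, if the fit is right".
#'
#' @param mu,sigma,tau ex-Gaussian parameters.
#' @param q tail fraction per side, in (0, 0.5).
#' @return named numeric vector `c(low, high)` in ms.
#' @examples
#' tail_cutoffs(451.09, 47.33, 146.81, q = 0.001)  # high ~ 1472.84 ms
#' @export
tail_cutoffs <- function(mu, sigma, tau, q = 0.001) {
  check_params(mu, sigma, tau)
  if (!is.finite(q) || q <= 0 || q >= 0.5)
    exg_stop("q must lie strictly in (0, 0.5)")
  c(low = qexgauss(q, mu, sigma, tau),
    high = qexgauss(1 - q, mu, sigma, tau))
}

#' Trim a sample at fitted tail quantiles
#'
#' Principled outlier removal for RT data: a maximum-likelihood pre-fit
#' estimates the distribution, the (q, 1 - q) quantiles of that fit define
#' the cutoffs, and observations strictly outside them are removed — in a
#' single pass, with no iteration. Points exactly at a cutoff are kept.
#' `q = 0` is an explicit no-op that removes nothing.
#'
#' @param x numeric observations (ms).
#' @param q tail fraction per side, in \[0, 0.5).
#' @param opts an [exg_opts()] control list for the pre-fit.
#' @return an object of class `exg_trim`: fields `q`, `low_cut`, `high_cut`,
#'   `removed_low`, `removed_high`, `kept` (the retained sample, original
#'   order) and `prefit` (the maxLKHD pre-fit, `NULL` when q = 0).
#' @examples
#' rt <- exgauss_sample(2000, 500, 50, 150, seed = 2)
#' trim_sample(rt, q = 0.001)
#' @export
trim_sample <- function(x, q = 0.001, opts = exg_opts()) {
  x <- check_sample(x, 3L)
  if (!is.finite(q) || q < 0 || q >= 0.5)
    exg_stop("q must lie in [0, 0.5)")
  if (q == 0) {
    return(structure(list(q = 0, low_cut = -Inf, high_cut = Inf,
                          removed_low = 0L, removed_high = 0L, kept = x,
                          prefit = NULL), class = "exg_trim"))
  }
  prefit <- fit_mle(x, opts = opts)
  if (!prefit$converged)
    stop(errorCondition("maxLKHD pre-fit did not converge",
                        class = c("exg_prefit_error", "exg_error"),
                        fit = prefit))
  cuts <- tail_cutoffs(prefit$mu, prefit$sigma, prefit$tau, q)
  keep <- x >= cuts[["low"]] & x <= cuts[["high"]]
  structure(list(q = q, low_cut = cuts[["low"]], high_cut = cuts[["high"]],
                 removed_low = sum(x < cuts[["low"]]),
                 removed_high = sum(x > cuts[["high"]]),
                 kept = x[keep], prefit = prefit),
            class = "exg_trim")
}

#' @export
print.exg_trim <- function(x, ...) {
  cat(sprintf("tail trim at q = %g per side\n", x$q))
  cat(sprintf("  cutoffs [%.2f, %.2f] ms\n", x$low_cut, x$high_cut))
  cat(sprintf("  removed %d low + %d high of %d; kept %d\n",
              x$removed_low, x$removed_high,
              length(x$kept) + x$removed_low + x$removed_high,
              length(x$kept)))
  invisible(x)
}

#' Sensitivity of the least-squares fit to the histogram bin count
#'
#' Refits the sample by minSQR over a list of bin counts, optionally
#' attaching a (reduced-replicate) bootstrap p-value per bin count. With too
#' few bins the fitted parameters fluctuate; once the bin count is reasonable
#' relative to n (around 40 for n near a thousand) they stabilize — the scan
#' makes that arbitrary-looking choice inspectable.
#'
#' @param x numeric observations (ms).
#' @param nbins_list integer vector of bin counts (each >= 2).
#' @param B optional bootstrap replicate count; if `NULL` (default), no
#'   p-values are computed.
#' @param seed integer seed for the optional bootstrap.
#' @param opts an [exg_opts()] control list.
#' @return a data.frame with one row per requested bin count: `nbins`, `mu`,
#'   `sigma`, `tau`, `converged`, and `p` when `B` is given; fit failures
#'   leave NA parameters in their row.
#' @examples
#' rt <- exgauss_sample(1200, 450, 45, 105, seed = 4)
#' bin_scan(rt, c(10, 40, 80))
#' @export
bin_scan <- function(x, nbins_list, B = NULL, seed = 0L, opts = exg_opts()) {
  x <- check_sample(x, 3L)
  nbins_list <- as.integer(nbins_list)
  if (length(nbins_list) < 1L || any(nbins_list < 2L))
    exg_stop("each nbins must be >= 2")
  rows <- lapply(seq_along(nbins_list), function(i) {
    nb <- nbins_list[i]
    row <- data.frame(nbins = nb, mu = NA_real_, sigma = NA_real_,
                      tau = NA_real_, converged = NA, p = NA_real_)
    fit <- tryCatch(fit_lsq(x, nbins = nb, opts = opts),
                    exg_error = function(e) NULL)
    if (!is.null(fit)) {
      row$mu <- fit$mu; row$sigma <- fit$sigma; row$tau <- fit$tau
      row$converged <- fit$converged
      if (!is.null(B)) {
        row$p <- bootstrap_pvalue(x, method = "minSQR", B = B,
                                  seed = seed + i, nbins = nb,
                                  opts = opts)$p
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(B)) out$p <- NULL
  out
}
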