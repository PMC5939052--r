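test_that("Gaussian wrappers evaluate the normal law and reject bad sigma", {
  expect_equal(gauss_pdf(0, 0, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(gauss_pdf(5, 5, 2), 1 / (2 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(gauss_cdf(500, 500, 37), 0.5, tolerance = 1e-12)
  expect_equal(gauss_cdf(1, 0, 1) - gauss_cdf(-1, 0, 1), 0.6826895,
               tolerance = 1e-6)
  expect_equal(gauss_cdf(2, 0, 1),
               integrate_gl(function(x) gauss_pdf(x), -10, 2, panels = 8),
               tolerance = 1e-10)
  expect_error(gauss_pdf(0, 0, 0), class = "exg_domain_error")
  expect_error(gauss_cdf(0, 0, -1), class = "exg_domain_error")
})

test_that("density matches the Gaussian-exponential convolution oracle", {
  p <- list(mu = 0, sigma = 1, tau = 1)
  xs <- c(-2, 0, 1, 3, 8)
  expect_equal(dexgauss(xs, p$mu, p$sigma, p$tau), conv_pdf(xs, p),
               tolerance = 1e-9)
  p2 <- sim_pars
  xs2 <- c(420, 500, 650, 900, 1400)
  expect_equal(dexgauss(xs2, p2$mu, p2$sigma, p2$tau), conv_pdf(xs2, p2),
               tolerance = 1e-9)
})

test_that("density is overflow-safe in the far tails", {
  expect_lt(dexgauss(-50, 0, 1, 1), 1e-100)
  expect_false(is.nan(dexgauss(-50, 0, 1, 1)))
  lp <- dexgauss(seq(-1e4, 1e5, length.out = 2000),
                 500, 50, 150, log = TRUE)
  expect_true(all(is.finite(lp)))
  # log density agrees with the Gaussian-tail oracle deep in both tails,
  # where the plain convolution integral underflows double precision
  expect_equal(dexgauss(-50, 0, 1, 1, log = TRUE),
               pnorm_log_pdf(-50, list(mu = 0, sigma = 1, tau = 1)),
               tolerance = 1e-10)
  expect_equal(dexgauss(c(-200, 5000), 500, 50, 150, log = TRUE),
               pnorm_log_pdf(c(-200, 5000),
                             list(mu = 500, sigma = 50, tau = 150)),
               tolerance = 1e-10)
  expect_equal(exp(dexgauss(0, 0, 1, 1, log = TRUE)), dexgauss(0, 0, 1, 1),
               tolerance = 1e-12)
})

test_that("density normalizes to one across the asymmetry range", {
  for (lamb in c(0.05, 0.2, 0.5, 0.8, 0.95)) {
    p <- lambda_pars(lamb)
    w <- exg_window(p)
    Z <- integrate_gl(function(x) dexgauss(x, p$mu, p$sigma, p$tau),
                      w[1], w[2], panels = 32)
    expect_equal(Z, 1, tolerance = 1e-8)
  }
})

test_that("quadrature moments reproduce the mean, variance and skewness", {
  for (lamb in c(0.2, 0.5, 0.8)) {
    p <- lambda_pars(lamb)
    st <- pars_to_stats(p$mu, p$sigma, p$tau)
    w <- exg_window(p)
    f <- function(x) dexgauss(x, p$mu, p$sigma, p$tau)
    m1 <- integrate_gl(function(x) x * f(x), w[1], w[2], panels = 32)
    m2 <- integrate_gl(function(x) (x - st[["M"]])^2 * f(x), w[1], w[2],
                       panels = 32)
    m3 <- integrate_gl(function(x) ((x - st[["M"]]) / st[["S"]])^3 * f(x),
                       w[1], w[2], panels = 32)
    expect_equal(m1, st[["M"]], tolerance = 1e-6)
    expect_equal(sqrt(m2), st[["S"]], tolerance = 1e-6)
    expect_equal(m3, st[["K"]], tolerance = 1e-6)
  }
})

test_that("CDF has the right limits, monotonicity and derivative", {
  p <- young_gng
  expect_equal(pexgauss(1472.84, p$mu, p$sigma, p$tau), 0.999,
               tolerance = 1e-4)
  expect_equal(pexgauss(-1e6, p$mu, p$sigma, p$tau), 0)
  expect_equal(pexgauss(1e7, p$mu, p$sigma, p$tau), 1)
  xs <- seq(100, 2500, length.out = 200)
  expect_true(all(diff(pexgauss(xs, p$mu, p$sigma, p$tau)) >= 0))
  # central finite difference of the CDF matches the density
  probes <- seq(250, 1600, length.out = 20)
  h <- 1e-3
  fd <- (pexgauss(probes + h, p$mu, p$sigma, p$tau) -
           pexgauss(probes - h, p$mu, p$sigma, p$tau)) / (2 * h)
  expect_equal(fd, dexgauss(probes, p$mu, p$sigma, p$tau), tolerance = 1e-6)
  # and the CDF agrees with quadrature of the density
  expect_equal(pexgauss(1, 0, 1, 1),
               integrate_gl(function(x) dexgauss(x, 0, 1, 1), -30, 1,
                            panels = 16),
               tolerance = 1e-8)
})

test_that("lambda parameterization is the substitution identity", {
  for (z in c(-2, 0, 2)) {
    expect_equal(dexgauss_lambda(z, 0.5),
                 dexgauss(z, -0.5, sqrt(0.75), 0.5), tolerance = 1e-12)
    expect_equal(pexgauss_lambda(z, 0.5),
                 pexgauss(z, -0.5, sqrt(0.75), 0.5), tolerance = 1e-12)
  }
  expect_equal(pexgauss_lambda(50, 0.9), 1, tolerance = 1e-12)
  expect_equal(pexgauss_lambda(0, 0.9),
               integrate_gl(function(z) dexgauss_lambda(z, 0.9), -15, 0,
                            panels = 16),
               tolerance = 1e-8)
  expect_error(dexgauss_lambda(0, 0), class = "exg_domain_error")
  expect_error(dexgauss_lambda(0, 1), class = "exg_domain_error")
})

test_that("standardized family has mean zero, unit variance, skewness 2*lamb^3", {
  for (lamb in seq(0.1, 0.9, by = 0.2)) {
    f <- function(z) dexgauss_lambda(z, lamb)
    m1 <- integrate_gl(function(z) z * f(z), -14, 42, panels = 32)
    m2 <- integrate_gl(function(z) z^2 * f(z), -14, 42, panels = 32)
    m3 <- integrate_gl(function(z) z^3 * f(z), -14, 42, panels = 32)
    expect_equal(m1, 0, tolerance = 1e-8)
    expect_equal(m2, 1, tolerance = 1e-8)
    # third raw moment of a standardized law equals its skewness
    expect_equal(m3, 2 * lamb^3, tolerance = 1e-6)
  }
})

test_that("small asymmetry approaches the standard normal", {
  z <- seq(-5, 5, length.out = 1001)
  d <- abs(dexgauss_lambda(z, 0.01) - dnorm(z))
  expect_lt(max(d), 1e-4)
  # at lambda = 0.2 the distance stays below 1% of the normal peak
  d2 <- abs(dexgauss_lambda(z, 0.2) - dnorm(z))
  expect_lt(max(d2), 0.01 * dnorm(0))
})

test_that("parameter/moment conversions match the published fits", {
  st <- pars_to_stats(524.49, 85.67, 306.65)
  expect_equal(unname(st), c(831.14, 318.39, 1.79), tolerance = 0.01 / 300)
  st2 <- pars_to_stats(453.52, 48.52, 140.29)
  expect_equal(st2[["M"]], 593.80, tolerance = 0.01 / 500)
  expect_equal(st2[["S"]], 148.44, tolerance = 0.01 / 100)
  expect_equal(st2[["K"]], 1.69, tolerance = 0.005)
  pr <- stats_to_pars(831.14, 318.95, 1.75)
  expect_equal(unname(pr), c(526.06, 93.02, 305.08), tolerance = 0.15 / 90)
  # Gaussian limit: tau -> 0 sends (M, S, K) -> (mu, sigma, 0)
  st3 <- pars_to_stats(500, 50, 1e-6)
  expect_equal(unname(st3), c(500, 50, 0), tolerance = 1e-6)
})

test_that("moment inversion round-trips and rejects impossible skewness", {
  p0 <- c(500, 50, 150)
  st <- pars_to_stats(p0[1], p0[2], p0[3])
  expect_equal(unname(stats_to_pars(st[["M"]], st[["S"]], st[["K"]])), p0,
               tolerance = 1e-10)
  set.seed(7)
  for (i in 1:20) {
    p <- c(runif(1, 100, 900), runif(1, 10, 200), runif(1, 10, 500))
    st <- pars_to_stats(p[1], p[2], p[3])
    expect_equal(unname(stats_to_pars(st[["M"]], st[["S"]], st[["K"]])), p,
                 tolerance = 1e-10)
    expect_true(st[["K"]] > 0 && st[["K"]] < 2)
  }
  expect_error(stats_to_pars(597.90, 169.90, 2.71),
               class = "exg_moments_error")
  expect_error(stats_to_pars(600, 170, -0.5), class = "exg_moments_error")
})

test_that("quantile function inverts the CDF", {
  p <- list(mu = 0, sigma = 1, tau = 1)
  for (pr in c(1e-4, 0.001, 0.5, 0.999)) {
    x <- qexgauss(pr, p$mu, p$sigma, p$tau)
    expect_equal(pexgauss(x, p$mu, p$sigma, p$tau), pr, tolerance = 1e-9)
  }
  expect_equal(pexgauss(qexgauss(0.75, 0, 1, 1), 0, 1, 1), 0.75,
               tolerance = 1e-9)
  # median against bisection on a quadrature-integrated CDF (oracle path)
  cdf_quad <- function(x) integrate_gl(function(t) dexgauss(t, 0, 1, 1),
                                       -30, x, panels = 16)
  med_oracle <- find_zero(function(x) cdf_quad(x) - 0.5, -5, 10, tol = 1e-10)
  expect_equal(qexgauss(0.5, 0, 1, 1), med_oracle, tolerance = 1e-6)
  expect_error(qexgauss(0, 0, 1, 1), class = "exg_domain_error")
  expect_error(qexgauss(1.2, 0, 1, 1), class = "exg_domain_error")
})

test_that("root finder solves brackets and reports missing sign changes", {
  expect_equal(find_zero(function(x) x^2 - 4, 0, 10), 2, tolerance = 1e-10)
  expect_equal(find_zero(cos, 0, 3), pi / 2, tolerance = 1e-10)
  p <- sim_pars
  M <- p$mu + p$tau; S <- sqrt(p$sigma^2 + p$tau^2)
  r <- find_zero(function(x) pexgauss(x, p$mu, p$sigma, p$tau) - 0.9,
                 M - 10 * S, M + 20 * S, tol = 1e-12)
  expect_equal(r, qexgauss(0.9, p$mu, p$sigma, p$tau), tolerance = 1e-6)
  expect_error(find_zero(function(x) x^2 + 1, -1, 1),
               class = "exg_bracket_error")
})

test_that("Gauss-Legendre quadrature is exact for polynomials", {
  expect_equal(integrate_gl(function(x) x, 0, 1, order = 1), 0.5,
               tolerance = 1e-14)
  expect_equal(integrate_gl(function(x) x^5, 0, 1, order = 3), 1 / 6,
               tolerance = 1e-14)
  expect_equal(integrate_gl(dnorm, -8, 8, order = 64, panels = 4), 1,
               tolerance = 1e-12)
  expect_error(integrate_gl(dnorm, 1, 0), class = "exg_domain_error")
})

test_that("invalid parameters raise domain errors everywhere", {
  expect_error(dexgauss(0, 0, -1, 1), class = "exg_domain_error")
  expect_error(dexgauss(0, 0, 1, 0), class = "exg_domain_error")
  expect_error(pexgauss(0, 0, 0, 1), class = "exg_domain_error")
  expect_error(qexgauss(0.5, 0, 1, -2), class = "exg_domain_error")
  expect_error(pars_to_stats(0, 1, Inf), class = "exg_domain_error")
  expect_error(stats_to_pars(500, -1, 1), class = "exg_domain_error")
})
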