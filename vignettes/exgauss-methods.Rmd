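---
title: "Modelling reaction times with the ex-Gaussian distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reaction times with the ex-Gaussian distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exgauss)
```

## The model

Reaction times (RTs) are positively skewed: a roughly Gaussian bulk with a
long right tail. The ex-Gaussian distribution models an RT as the sum
$Z = X + Y$ of a Gaussian component $X \sim N(\mu, \sigma)$ and an
exponential component $Y$ with mean $\tau$, giving the density

$$f(x) = \frac{1}{2\tau}\exp\!\Big(\frac{\mu - x}{\tau} +
  \frac{\sigma^2}{2\tau^2}\Big)\,
  \mathrm{erfc}\!\Big(\frac{(\mu-x)/\sigma + \sigma/\tau}{\sqrt 2}\Big).$$

$\mu$ and $\sigma$ are **not** the distribution's mean and SD; those are
$M = \mu + \tau$, $S = \sqrt{\sigma^2 + \tau^2}$, and the skewness is
$K = 2(\tau/S)^3$, bounded by 0 (Gaussian limit, $\sigma \gg \tau$) and 2
(exponential limit, $\sigma \ll \tau$). Standardizing to mean 0 and SD 1
leaves a one-parameter family indexed by the asymmetry
$\lambda = \tau/S = (K/2)^{1/3} \in (0,1)$; `dexgauss_lambda()` evaluates it
by substituting $\mu = -\lambda$, $\sigma = \sqrt{1-\lambda^2}$,
$\tau = \lambda$ into the canonical form rather than using a separately
transcribed standardized formula, so standardization holds by construction.
Below $\lambda \approx 0.2$ the family is within 1% of the standard normal.
All quantities are in milliseconds and are never rescaled.

## Numerical evaluation

The textbook exp–erfc product overflows once the erfc argument
$u = ((\mu-x)/\sigma + \sigma/\tau)/\sqrt 2$ is large — for instance in the
far left tail, exactly where a maximum-likelihood fit must evaluate the
log-density of an extreme observation. Everything is therefore computed in
log space: $\ln f = -\ln(2\tau) + (\mu-x)/\tau + \sigma^2/(2\tau^2) +
\ln\mathrm{erfc}(u)$, with $\ln\mathrm{erfc}(u)$ from `erfc` directly for
$u < 25$ and from its asymptotic expansion beyond (on the R side, from the
Gaussian log upper-tail). The same treatment stabilizes the second term of
the CDF. As a result `dexgauss(x, ..., log = TRUE)` is finite for any finite
`x`, and log-likelihoods never degenerate to `-Inf` because of one outlier.

Quantiles have no closed form; `qexgauss()` brackets the CDF with
$[M - 10S,\; M + 20S]$ (doubled outward if needed — the exponential tail
makes $20S$ ample for tail areas down to $10^{-9}$) and refines with
`find_zero()`, a deterministic bisection/secant hybrid. Integrals used in
the test oracles go through `integrate_gl()`, composite fixed-order
Gauss–Legendre (64 nodes per panel, nodes by Golub–Welsch) on
$[M - 12S,\, M + 40S]$, which holds tail-truncation error below $10^{-10}$.

Degenerate limits are rejected, not approximated: $\tau \le 0$ (pure
Gaussian) and $\sigma \le 0$ (pure exponential) raise domain errors naming
the limit, as does $\lambda \notin (0,1)$; the Gaussian case is served
explicitly by `gauss_pdf()`/`gauss_cdf()`.

## Estimation

Three estimators are provided, deliberately mirroring each other's
interfaces:

* **Method of moments** (`fit_moments()`): invert $(M, S, K)$ of the sample
  through $\lambda = (K/2)^{1/3}$. Sample moments are population
  (divide-by-$N$) moments, because the method equates them directly to the
  distribution moments. It is fast but biased, and it *fails* whenever the
  sample skewness reaches 2 — which a handful of extreme RTs readily
  causes; the failure is a typed error, not a silent fix-up.
* **Histogram least squares** (`fit_lsq()`, "minSQR"): minimize the sum of
  squared differences between density-normalized bin heights and the
  theoretical density at bin centers. Densities (not counts) make the
  objective scale-free in $N$; bins are equal-width with the
  $\mathrm{round}(2\sqrt N)$ default (100 observations → 20 bins,
  2396 → 98).
* **Maximum likelihood** (`fit_mle()`, "maxLKHD"): maximize
  $\ln L = \sum_i \ln f(x_i)$ directly on the observations, no binning.

Both gradient fits use analytic gradients and the same steepest
descent/ascent engine: step $p \leftarrow p \pm \eta\, \nabla$, with $\eta$
doubled after an accepted (improving) step and halved otherwise, and steps
that would push $\sigma$ or $\tau$ non-positive treated as rejections (no
reparameterization). Iteration stops when $\lVert\nabla\rVert \le
\mathrm{tol} \cdot \max(1, |\mathrm{objective}|)$ with tol $10^{-8}$,
`max_iter` 20000 and initial step $10^{-3} S$ — constants exposed in
`exg_opts()`. The doubling/halving schedule behaves like a crude line
search; in practice fits converge in a few dozen iterations and agree with
a quasi-Newton optimizer to better than 0.01 in each parameter. Both fits
start from the moments estimate; when moments fail ($K \ge 2$) they start
from the $\lambda = 0.8$ point $(M - 0.8S,\ 0.6S,\ 0.8S)$, a deliberate
high-skew fallback since moment failure occurs precisely on very skewed
samples. Non-convergence is reported via `converged = FALSE`, never by an
exception. The hot paths (objectives and the iteration loop) are compiled;
`steepest_extremum()` is the same algorithm in R for arbitrary objectives,
and the two are pinned to each other in the tests.

## Goodness of fit and trimming

Accepting fitted parameters means accepting the null hypothesis that the
data come from that ex-Gaussian. `bootstrap_pvalue()` generalizes the
parametric-bootstrap approach known from power-law fitting: the distance
measure is the Kolmogorov–Smirnov statistic (binning-free, and not the
quantity either fit optimizes, avoiding bias); replicates of the empirical
size are drawn from the fitted law and refitted *by the same procedure*
(including the same bin rule for minSQR), and $p$ is the plain fraction of
replicates whose KS distance to their own refit reaches the empirical one —
so $p = 0$ is representable, and $p$ lies on the $1/B$ lattice. `B`
defaults to 1000. Reports carry $D$, the size-scaled $N \cdot D$ convention,
and the replicate null summary; because data and replicates share $N$, any
fixed monotone rescaling of the statistic leaves $p$ unchanged (asserted in
the tests via the stored replicate values).

`trim_sample()` replaces arbitrary RT cutoffs with model-based ones: a
maximum-likelihood pre-fit, cutoffs at the fitted $(q, 1-q)$ quantiles
(default $q = 0.1\%$ per side), one removal pass, no iteration; points
exactly at a cutoff are kept (immaterial for continuous data, fixed for
determinism), and `q = 0` is an explicit no-op. Each `q` re-runs its own
pre-fit. `bin_scan()` exposes the one arbitrary choice in minSQR — the bin
count — by refitting across a list of counts: parameters fluctuate while
bins are too few and stabilize once the count is reasonable (around 40 for
$n$ near a thousand).

## Synthetic data

`exgauss_sample(n, mu, sigma, tau, seed)` draws Gaussian-plus-exponential
sums from one seeded Mersenne-Twister stream (Gaussian by CDF inversion,
exponential by $-\tau\ln u$); every stochastic operation in the package
takes an explicit seed or stream, so any reported number is re-runnable.
The generator emulates ideal ex-Gaussian RT data. It does **not** emulate
several features of real RT experiments: response deadlines that censor the
right tail (which bias the KS statistic, since the empirical distribution
is then not the full law), anticipatory responses, sequential dependence
between trials, or mixture-of-strategy bimodality. Passing tests on this
generator therefore validate the estimators and the bootstrap calibration
under the model, not the adequacy of the ex-Gaussian for any particular
experiment — that adequacy question is exactly what `bootstrap_pvalue()` is
for on real data.

## Test problem sizes

The suite validates, among others: density/CDF against an independent
convolution-integral oracle and a Gaussian-tail log-space oracle; moment
identities by quadrature across $\lambda \in \{0.05, \dots, 0.95\}$
($10^{-6}$); analytic gradients against central differences ($10^{-6}$
relative); parameter recovery over 50 seeds at $n = 5000$ (mean estimate
within 3 Monte-Carlo SEs of truth for both gradient methods); bootstrap
$p$-value calibration over 100 datasets of $n = 250$ at $B = 200$ (mean $p$
in $[0.40, 0.60]$ and batch KS-vs-uniform at the 1% level); and bin-scan
stabilization on $n = 1200$ (SD of $\hat\tau$ over 40–120 bins below that
over 5–20 bins). $n = 250$ per bootstrap dataset is a realistic
single-condition RT block and keeps the 20k-refit batch economical; the
replicate counts match the reduced settings the checks are specified at.

## Known limitations

* No standard errors or confidence intervals on fitted parameters.
* Steepest descent is first-order: on nearly-Gaussian samples
  ($\lambda \to 0$) the likelihood surface becomes ill-conditioned in
  $(\sigma, \tau)$ and convergence slows; the `converged` flag and
  `grad_norm` are honest about it.
* The KS bootstrap assumes uncensored data; right-censored designs (hard
  response deadlines) violate it and show up as spuriously small $p$.
* Quantiles are root-found, not closed-form: ~microseconds each, which only
  matters if you need millions.
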