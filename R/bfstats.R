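# Default-prior Bayes-factor tests and within-subject standard errors.
#
# t-tests use the JZS construction: a Cauchy prior (default scale 0.707)
# on the standardised effect size, integrated out by adaptive quadrature
# via the Zellner-Siow g-representation.  The correlation Bayes factor
# places a stretched-beta prior on the population correlation and uses the
# exact sampling density of Pearson's r.

new_bf_result <- function(bf10, test, n, n2 = NA_integer_, prior_scale) {
  out <- tibble::tibble(
    bf10 = bf10, test = test, n = as.integer(n), n2 = as.integer(n2),
    prior_scale = prior_scale, band = interpret_bf(bf10)
  )
  class(out) <- c("wr_bf", class(out))
  out
}

# JZS Bayes factor from a t statistic; N is the effective sample size
# multiplying g, nu the degrees of freedom.
jzs_bf_from_t <- function(t, N, nu, prior_scale) {
  log_f <- function(g) {
    -0.5 * log1p(N * g) - (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu))
  }
  log_f0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  # inverse-gamma(1/2, r^2/2) prior density on g
  log_pi_g <- function(g) {
    0.5 * log(prior_scale^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
      prior_scale^2 / (2 * g)
  }
  # substitute g = r^2 h: h follows inverse-gamma(1/2, 1/2), so the
  # integrand stays well-scaled for any prior scale
  log_pi_h <- function(h) {
    -0.5 * log(2) - lgamma(0.5) - 1.5 * log(h) - 1 / (2 * h)
  }
  integrand <- function(h) {
    exp(log_f(prior_scale^2 * h) - log_f0 + log_pi_h(h))
  }
  int <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)
  int$value
}

#' JZS Bayes-factor t-test
#'
#' Bayes factor BF10 for a one-sample/paired or two-sample t-test with a
#' zero-centred Cauchy prior on the standardised effect size, computed by
#' adaptive quadrature (no Monte Carlo error).
#'
#' @param x Numeric sample (or paired differences if `y` is `NULL`).
#' @param y Optional second sample.
#' @param paired If `TRUE`, `x - y` is tested against zero.
#' @param prior_scale Cauchy scale of the effect-size prior (default
#'   0.707).
#' @param mu Null value subtracted from `x` (one-sample only).
#' @return A one-row tibble of class `wr_bf`: `bf10`, `test`, `n`, `n2`,
#'   `prior_scale`, `band`.
#' @export
bf_ttest <- function(x, y = NULL, paired = FALSE, prior_scale = 0.707,
                     mu = 0) {
  x <- x[is.finite(x)]
  if (!is.null(y)) y <- y[is.finite(y)]
  if (paired) {
    if (is.null(y) || length(x) != length(y)) {
      stop("bf_ttest(): paired test needs equal-length samples", call. = FALSE)
    }
    x <- x - y
    y <- NULL
  }
  if (is.null(y)) {
    n <- length(x)
    if (n < 2) stop("bf_ttest(): need at least 2 observations", call. = FALSE)
    if (stats::sd(x) == 0) stop("bf_ttest(): zero-variance input", call. = FALSE)
    t <- (mean(x) - mu) / (stats::sd(x) / sqrt(n))
    bf <- jzs_bf_from_t(t, N = n, nu = n - 1, prior_scale = prior_scale)
    new_bf_result(bf, if (paired) "paired" else "one-sample", n,
                  prior_scale = prior_scale)
  } else {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stop("bf_ttest(): need at least 2 per group", call. = FALSE)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    if (sp2 == 0) stop("bf_ttest(): zero-variance input", call. = FALSE)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    bf <- jzs_bf_from_t(t, N = n1 * n2 / (n1 + n2), nu = n1 + n2 - 2,
                        prior_scale = prior_scale)
    new_bf_result(bf, "independent", n1, n2, prior_scale)
  }
}

#' Interpret a Bayes factor
#'
#' Classification bands: BF10 > 100 extreme, 30-100 very strong, 10-30
#' strong, 3-10 moderate evidence for H1; 1/3-3 anecdotal/inconclusive;
#' below 1/3 evidence for H0 with the reciprocal bands, and BF10 < 0.01
#' extreme evidence for H0.
#'
#' @param bf10 Positive Bayes factor(s).
#' @return Character vector of band labels.
#' @export
interpret_bf <- function(bf10) {
  if (any(bf10 <= 0)) stop("interpret_bf(): bf10 must be positive", call. = FALSE)
  dplyr::case_when(
    bf10 > 100 ~ "extreme H1",
    bf10 > 30 ~ "very strong H1",
    bf10 > 10 ~ "strong H1",
    bf10 > 3 ~ "moderate H1",
    bf10 >= 1 / 3 ~ "anecdotal",
    bf10 > 1 / 10 ~ "moderate H0",
    bf10 > 1 / 30 ~ "strong H0",
    bf10 >= 0.01 ~ "very strong H0",
    TRUE ~ "extreme H0"
  )
}

# Gauss hypergeometric 2F1 by series; valid for 0 <= z < 1 with c > a + b
hyp2f1 <- function(a, b, cc, z, tol = 1e-15, max_terms = 10000L) {
  term <- 1
  s <- 1
  for (k in 0:(max_terms - 1)) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) return(s)
  }
  s
}

# exact sampling density of Pearson's r given rho (n >= 4); vectorised
# over r and rho
log_dr_given_rho <- function(r, rho, n) {
  h <- mapply(function(ri, pi_) hyp2f1(0.5, 0.5, n - 0.5, (1 + pi_ * ri) / 2),
              r, rho)
  log(n - 2) + lgamma(n - 1) + (n - 1) / 2 * log1p(-rho^2) +
    (n - 4) / 2 * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log1p(-rho * r) + log(h)
}

#' Default-prior Bayes factor for a Pearson correlation
#'
#' Stretched-beta prior of width `prior_scale` on the population
#' correlation (width 1 is uniform on (-1, 1)), combined with the exact
#' sampling density of the observed correlation coefficient; the
#' marginalisation is computed by adaptive quadrature.
#'
#' @param x,y Numeric vectors (n >= 4).
#' @param prior_scale Width of the stretched-beta prior (default 1).
#' @return A one-row tibble of class `wr_bf`.
#' @export
bf_correlation <- function(x, y, prior_scale = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("bf_correlation(): need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("bf_correlation(): constant input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  a <- 1 / prior_scale
  log_prior <- function(rho) {
    stats::dbeta((rho + 1) / 2, a, a, log = TRUE) - log(2)
  }
  l0 <- log_dr_given_rho(r, 0, n)
  integrand <- function(rho) {
    vapply(rho, function(p) {
      exp(log_dr_given_rho(r, p, n) - l0 + log_prior(p))
    }, 1)
  }
  int <- stats::integrate(integrand, -1, 1, rel.tol = 1e-10)
  out <- new_bf_result(int$value, "correlation", n, prior_scale = prior_scale)
  out$r <- r
  out
}

#' Prior-sensitivity curve for a Bayes-factor t-test
#'
#' Recomputes [bf_ttest()] on a grid of Cauchy prior scales.
#'
#' @inheritParams bf_ttest
#' @param scale_grid Vector of positive prior scales.
#' @return A tibble with one row per scale: `prior_scale`, `bf10`, `band`.
#' @export
bf_sensitivity <- function(x, y = NULL, paired = FALSE,
                           scale_grid = seq(0.1, 1.5, by = 0.1)) {
  if (any(scale_grid <= 0)) {
    stop("bf_sensitivity(): prior scales must be positive", call. = FALSE)
  }
  purrr::map_dfr(scale_grid, function(s) {
    res <- bf_ttest(x, y, paired = paired, prior_scale = s)
    tibble::tibble(prior_scale = s, bf10 = res$bf10, band = res$band)
  })
}

#' Loftus-Masson within-subject standard errors
#'
#' Normalises out between-subject variability by subtracting each
#' subject's mean across conditions and adding back the grand mean, then
#' computes the per-condition standard error of the mean on the normalised
#' values.
#'
#' @param values Numeric matrix or data frame, subjects in rows and
#'   conditions in columns; no missing cells.
#' @return A tibble with columns `condition`, `mean`, `sem`.
#' @export
within_subject_sem <- function(values) {
  m <- as.matrix(values)
  if (nrow(m) < 2) stop("within_subject_sem(): need >= 2 subjects", call. = FALSE)
  if (any(!is.finite(m))) {
    stop("within_subject_sem(): incomplete design (missing cells)", call. = FALSE)
  }
  norm <- m - rowMeans(m) + mean(m)
  tibble::tibble(
    condition = if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else colnames(m),
    mean = colMeans(m),
    sem = apply(norm, 2L, stats::sd) / sqrt(nrow(m))
  )
}
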