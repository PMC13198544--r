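# WAIC model comparison.
#
# WAIC is computed from the trials x draws matrix of pointwise posterior
# log-likelihoods: lppd = sum_i log mean_s exp(ll_is), with the variance
# form of the effective-parameter penalty p_waic = sum_i var_s(ll_is), and
# waic = -2 (lppd - p_waic).  Delta-WAIC ranks candidate models against the
# best (lowest-WAIC) one.

#' Watanabe-Akaike information criterion
#'
#' @param pointwise Numeric matrix of pointwise log-likelihoods, trials in
#'   rows and posterior draws in columns (see [pointwise_loglik()]).
#' @return A one-row tibble of class `wr_waic` with columns `lppd`,
#'   `p_waic`, `waic` and `se` (standard error over trial-wise
#'   contributions).
#' @export
waic <- function(pointwise) {
  pointwise <- as.matrix(pointwise)
  if (!is.numeric(pointwise) || any(!is.finite(pointwise))) {
    stop("waic(): pointwise log-likelihoods must be finite", call. = FALSE)
  }
  n <- nrow(pointwise)
  s <- ncol(pointwise)
  if (s < 1L) stop("waic(): need at least one posterior draw", call. = FALSE)
  if (s == 1L) {
    warning("waic(): single posterior draw; p_waic is 0", call. = FALSE)
  }
  # row-wise log-mean-exp, stabilised by the row maximum
  mx <- apply(pointwise, 1L, max)
  lppd_i <- mx + log(rowMeans(exp(pointwise - mx)))
  p_i <- if (s == 1L) rep(0, n) else apply(pointwise, 1L, stats::var)
  elpd_i <- lppd_i - p_i
  out <- tibble::tibble(
    lppd = sum(lppd_i),
    p_waic = sum(p_i),
    waic = -2 * (sum(lppd_i) - sum(p_i)),
    se = 2 * sqrt(n * stats::var(elpd_i))
  )
  class(out) <- c("wr_waic", class(out))
  out
}

#' Delta-WAIC across a set of models
#'
#' The difference between each model's WAIC and the WAIC of the
#' best-fitting model (the one with the lowest WAIC); the best model has a
#' delta of exactly 0.
#'
#' @param results A list of [waic()] results (optionally named), or a
#'   numeric vector of WAIC values.
#' @return A tibble with columns `model`, `waic`, `p_waic` (NA when only
#'   raw WAICs are given) and `delta_waic`, sorted by `delta_waic`.
#' @export
delta_waic <- function(results) {
  if (is.numeric(results)) {
    tb <- tibble::tibble(
      model = if (is.null(names(results))) as.character(seq_along(results)) else names(results),
      waic = as.numeric(results),
      p_waic = NA_real_
    )
  } else {
    if (inherits(results, "wr_waic")) results <- list(results)
    tb <- dplyr::bind_rows(lapply(results, tibble::as_tibble))
    tb$model <- if (is.null(names(results))) as.character(seq_len(nrow(tb))) else names(results)
    tb <- dplyr::select(tb, "model", "waic", "p_waic")
  }
  if (!nrow(tb)) stop("delta_waic(): need at least one model", call. = FALSE)
  tb$delta_waic <- tb$waic - min(tb$waic)
  dplyr::arrange(tb, .data$delta_waic)
}

#' Compare fitted model variants by WAIC
#'
#' Computes the pointwise log-likelihood matrix of each fit on `data`,
#' its WAIC, and the delta-WAIC ranking.
#'
#' @param data The trial table the models were fitted to.
#' @param fits Named list of [fit_hierarchical()] results.
#' @param thin Keep every `thin`-th retained draw for the pointwise matrix.
#' @return A tibble as in [delta_waic()], plus columns `lppd` and `se`.
#' @export
compare_models <- function(data, fits, thin = 1L) {
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$spec$variant, "")
  }
  ws <- lapply(fits, function(f) waic(pointwise_loglik(data, f, thin = thin)))
  ranked <- delta_waic(ws)
  extra <- dplyr::bind_rows(lapply(ws, tibble::as_tibble))
  extra$model <- names(ws)
  dplyr::left_join(ranked, dplyr::select(extra, "model", "lppd", "se"),
                   by = "model")
}
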