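# Exact per-trial joint likelihood of the 6-dimensional response vector,
# marginalising over every latent state the forward model can produce.
#
# Two code paths compute the same quantity: a compiled, per-object
# factorised marginalisation (used by everything performance-critical via
# `loglik_trials()`), and an explicit enumeration of the full latent
# support (`enumerate_latents()` + `state_loglik()`), which exists for
# transparency, classification and cross-checking.

#' von Mises log-density (per radian)
#'
#' @param x,mu Angles in degrees.
#' @param kappa Concentration (>= 0); `kappa = 0` is the circular uniform.
#' @return Log-density per radian, so that the density integrates to 1 over
#'   the circle.
#' @export
von_mises_logpdf <- function(x, mu, kappa) {
  if (any(kappa < 0)) stop("von_mises_logpdf(): kappa must be >= 0", call. = FALSE)
  kappa * cos(deg2rad(x - mu)) - log(2 * pi) -
    (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

log_unif <- -log(2 * pi)

# -- full latent enumeration ------------------------------------------------

# guess-state table for one object: rows (obj_guess, gc, gl) with prior
# factors as functions of (gf, go); cued trials use the collapsed 3-state
# version on the report dimension.
object_guess_states <- function(gf, go, rep_dim) {
  if (rep_dim == "both") {
    list(
      obj_guess = c(TRUE, FALSE, FALSE, FALSE, FALSE),
      gc = c(TRUE, TRUE, TRUE, FALSE, FALSE),
      gl = c(TRUE, TRUE, FALSE, TRUE, FALSE),
      prior = c(go,
                (1 - go) * gf * gf,
                (1 - go) * gf * (1 - gf),
                (1 - go) * (1 - gf) * gf,
                (1 - go) * (1 - gf) * (1 - gf))
    )
  } else {
    flag <- c(TRUE, TRUE, FALSE)
    none <- c(FALSE, FALSE, FALSE)
    list(
      obj_guess = c(TRUE, FALSE, FALSE),
      gc = if (rep_dim == "colour") flag else none,
      gl = if (rep_dim == "location") flag else none,
      prior = c(go, (1 - go) * gf, (1 - go) * (1 - gf))
    )
  }
}

#' Enumerate the full latent support of a condition
#'
#' Lists every latent trial state the forward model can produce under the
#' given parameters — report-order permutation (uncued only), binding-error
#' configuration, and per-object guess flags — together with its prior
#' probability.  The priors sum to 1.
#'
#' @param params A [model_params()] object.
#' @param condition One of [CONDITIONS].
#' @param drop_zero Drop states with zero prior probability (default TRUE).
#' @return A list with elements `states` (list of `wr_latent`) and `prior`
#'   (numeric vector).
#' @export
enumerate_latents <- function(params, condition = "uncued_CL", drop_zero = TRUE) {
  check_condition(condition)
  rep_dim <- report_dimension(condition)
  uncued <- rep_dim == "both"
  err_cfg <- list(
    list(kind = "none", pair = NULL, dir = NULL, prior = 1 - params$p_swap - params$p_cyclic_swap),
    list(kind = "swap", pair = SWAP_PAIRS[1, ], dir = NULL, prior = params$p_swap / 3),
    list(kind = "swap", pair = SWAP_PAIRS[2, ], dir = NULL, prior = params$p_swap / 3),
    list(kind = "swap", pair = SWAP_PAIRS[3, ], dir = NULL, prior = params$p_swap / 3),
    list(kind = "cyclic", pair = NULL, dir = 1L, prior = params$p_cyclic_swap / 2),
    list(kind = "cyclic", pair = NULL, dir = 2L, prior = params$p_cyclic_swap / 2)
  )
  perm_ids <- if (uncued) 1:6 else NA_integer_
  n_tot <- length(perm_ids) * 6L * (if (uncued) 125L else 27L)
  states <- vector("list", n_tot)
  prior <- numeric(n_tot)
  k <- 0L
  for (pid in perm_ids) {
    w_perm <- if (uncued) params$order_weights[pid] else 1
    for (cfg in err_cfg) {
      gtab <- lapply(1:3, function(o) {
        g <- guess_rates(params, cfg$kind,
                         in_swap = cfg$kind == "swap" && o %in% cfg$pair)
        object_guess_states(g[["gf"]], g[["go"]], rep_dim)
      })
      idx <- expand.grid(i1 = seq_along(gtab[[1]]$prior),
                         i2 = seq_along(gtab[[2]]$prior),
                         i3 = seq_along(gtab[[3]]$prior))
      for (r in seq_len(nrow(idx))) {
        i1 <- idx[[1]][r]; i2 <- idx[[2]][r]; i3 <- idx[[3]][r]
        p_state <- w_perm * cfg$prior *
          gtab[[1]]$prior[i1] * gtab[[2]]$prior[i2] * gtab[[3]]$prior[i3]
        k <- k + 1L
        states[[k]] <- structure(list(
          condition = condition, perm_id = pid,
          error_kind = cfg$kind, swap_pair = cfg$pair, cyclic_dir = cfg$dir,
          obj_guess = c(gtab[[1]]$obj_guess[i1], gtab[[2]]$obj_guess[i2],
                        gtab[[3]]$obj_guess[i3]),
          guess_col = c(gtab[[1]]$gc[i1], gtab[[2]]$gc[i2], gtab[[3]]$gc[i3]),
          guess_loc = c(gtab[[1]]$gl[i1], gtab[[2]]$gl[i2], gtab[[3]]$gl[i3])
        ), class = "wr_latent")
        prior[k] <- p_state
      }
    }
  }
  if (drop_zero) {
    keep <- prior > 0
    states <- states[keep]
    prior <- prior[keep]
  }
  list(states = states, prior = prior)
}

#' Log-likelihood of one trial under one fully specified latent state
#'
#' Sums, over the six response features, the von Mises log-density of the
#' assigned source feature (or `log(1/2pi)` for guessed features).  On cued
#' trials the cue dimension contributes log 1 when the observed cue
#' selection is consistent with the state's slot-to-object mapping, and
#' `-Inf` otherwise.
#'
#' @param trial One-row data frame with stimulus, response and (cued)
#'   cue-selection columns plus `condition`.
#' @param state A `wr_latent` state.
#' @param params A [model_params()] object.
#' @return Scalar log-density.
#' @export
state_loglik <- function(trial, state, params) {
  trial <- as.list(trial)
  asg <- latent_to_assignment(state)
  sc <- as.numeric(trial[paste0("stim_col_", 1:3)])
  sl <- as.numeric(trial[paste0("stim_loc_", 1:3)])
  rc <- as.numeric(trial[paste0("resp_col_", 1:3)])
  rl <- as.numeric(trial[paste0("resp_loc_", 1:3)])
  cued <- is_cued(trial$condition)
  if (cued) {
    perm <- as.integer(trial[paste0("cue_sel_", 1:3)])
    if (any(sort(perm) != 1:3)) {
      stop("cued trial without a valid cue_selection permutation", call. = FALSE)
    }
    if (!is.na(state$perm_id) && any(PERMS[state$perm_id, ] != perm)) {
      return(-Inf)
    }
  } else {
    perm <- PERMS[state$perm_id, ]
  }
  ll <- 0
  for (s in 1:3) {
    o <- perm[s]
    if (trial$condition != "cued_by_colour") {  # colour is reported
      k <- asg$colour_src[o]
      ll <- ll + if (k == 0L) log_unif else
        von_mises_logpdf(rc[s], sc[k], params$kappa_colour)
    }
    if (trial$condition != "cued_by_location") {  # location is reported
      k <- asg$location_src[o]
      ll <- ll + if (k == 0L) log_unif else
        von_mises_logpdf(rl[s], sl[k], params$kappa_location)
    }
    # the cue dimension is an exact copy: density contribution log 1
  }
  ll
}

# -- batched marginal likelihood -------------------------------------------

# build the numeric bundle handed to the compiled likelihood
prepare_loglik_data <- function(data) {
  check_condition(data$condition)
  need <- c(paste0("stim_col_", 1:3), paste0("stim_loc_", 1:3),
            paste0("resp_col_", 1:3), paste0("resp_loc_", 1:3))
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cond <- dplyr::case_when(
    data$condition == "cued_by_colour" ~ 1L,
    data$condition == "cued_by_location" ~ 2L,
    TRUE ~ 0L
  )
  cue <- matrix(0L, nrow(data), 3)
  if (any(cond > 0L)) {
    cue_cols <- as.matrix(data[paste0("cue_sel_", 1:3)])
    storage.mode(cue_cols) <- "integer"
    rows <- which(cond > 0L)
    bad <- rows[apply(cue_cols[rows, , drop = FALSE], 1L, function(r) {
      any(is.na(r)) || any(sort(r) != 1:3)
    })]
    if (length(bad)) {
      stop("invalid cue_selection on cued trial row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    cue[rows, ] <- cue_cols[rows, , drop = FALSE]
  }
  list(
    stim_col = deg2rad(as.matrix(data[paste0("stim_col_", 1:3)])),
    stim_loc = deg2rad(as.matrix(data[paste0("stim_loc_", 1:3)])),
    resp_col = deg2rad(as.matrix(data[paste0("resp_col_", 1:3)])),
    resp_loc = deg2rad(as.matrix(data[paste0("resp_loc_", 1:3)])),
    cond = cond, cue_perm = cue,
    group = param_group(data$condition)
  )
}

# evaluate the bundle under one parameter row per trial
bundle_loglik <- function(bundle, params_mat, orderw_mat, par_index) {
  .wr_loglik_cpp(bundle$stim_col, bundle$stim_loc,
                 bundle$resp_col, bundle$resp_loc,
                 bundle$cond, bundle$cue_perm,
                 as.integer(par_index), params_mat, orderw_mat)
}

#' Marginal log-likelihood of each trial
#'
#' Computes, for every row of `data`, the log marginal likelihood of the
#' observed 6-dimensional response vector (3 colour + 3 location reports;
#' on cued trials, the 3 reported features), summing over all latent report
#' orders, swap/cyclic configurations and guess states.
#'
#' @param data Trial table (see [simulate_dataset()] / [read_trials()]).
#' @param params A single [model_params()] object used for all trials, or a
#'   named list `param_group -> params` covering the groups present.
#' @return Numeric vector of per-trial log-likelihoods.
#' @export
loglik_trials <- function(data, params) {
  bundle <- prepare_loglik_data(data)
  if (inherits(params, "wr_params")) {
    groups <- unique(bundle$group)
    params <- stats::setNames(rep(list(params), length(groups)), groups)
  }
  missing <- setdiff(unique(bundle$group), names(params))
  if (length(missing)) {
    stop("no parameters for group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pm <- do.call(rbind, lapply(params, params_vector))
  ow <- do.call(rbind, lapply(params, function(p) p$order_weights))
  bundle_loglik(bundle, pm, ow, match(bundle$group, names(params)))
}

#' Marginal log-likelihood of one trial
#'
#' Single-trial convenience wrapper around [loglik_trials()]; equals the
#' log-sum-exp over [enumerate_latents()] of prior plus [state_loglik()].
#'
#' @param trial One-row trial table.
#' @param params A [model_params()] object.
#' @return Scalar log marginal likelihood.
#' @export
trial_loglik <- function(trial, params) {
  loglik_trials(trial[1, , drop = FALSE], params)[[1]]
}
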