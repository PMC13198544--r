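# Hierarchical Bayesian estimation.
#
# Subject-level parameters live on transformed scales (log for the two
# concentrations, logit for the ten probabilities, anchored softmax for the
# order weights) and are constrained by a population mean and standard
# deviation per parameter.  Sampling is Metropolis-within-Gibbs: per-subject
# adaptive random-walk updates on the transformed scale with the discrete
# latent states summed out of the likelihood, a conjugate Gibbs draw for
# each population mean, and a log-scale random-walk for each population SD.

PROB_IDX <- 3:12
KAPPA_IDX <- 1:2

#' Model variants
#'
#' Builds the specification of one of the model variants compared by WAIC:
#' * `full` — all 13 parameters, separate for the cued, colour-first and
#'   location-first uncued groups;
#' * `null` — no swapping and no guessing (concentrations and report-order
#'   weights only);
#' * `no_asymmetric` — swaps and baseline guessing allowed, but no guessing
#'   conditional on a swap or cyclic swap, hence no asymmetric
#'   misattribution;
#' * `collapse_cue_uncued` — one parameter set shared by all three groups;
#' * `collapse_order` — the two uncued groups share one parameter set.
#'
#' @param name Variant name.
#' @return An object of class `wr_model_spec` with fields `variant`,
#'   `group_map` (param_group -> effective group) and `frozen` (parameters
#'   pinned to 0).
#' @export
build_variant <- function(name = c("full", "null", "no_asymmetric",
                                   "collapse_cue_uncued", "collapse_order")) {
  name <- match.arg(name)
  group_map <- c(cued = "cued", uncued_CL = "uncued_CL", uncued_LC = "uncued_LC")
  frozen <- character(0)
  if (name == "null") frozen <- PARAM_NAMES[PROB_IDX]
  if (name == "no_asymmetric") {
    frozen <- c("g_feat_swap_non", "g_feat_swap_swp",
                "g_obj_swap_non", "g_obj_swap_swp",
                "g_feat_cyclic", "g_obj_cyclic")
  }
  if (name == "collapse_order") group_map[c("uncued_CL", "uncued_LC")] <- "uncued"
  if (name == "collapse_cue_uncued") group_map[] <- "all"
  structure(list(variant = name, group_map = group_map, frozen = frozen),
            class = "wr_model_spec")
}

#' Number of free parameters per effective group
#'
#' Counts the report-order weight vector as a single parameter, matching
#' the model's 13-parameter description.
#'
#' @param spec A [build_variant()] specification.
#' @return Integer count.
#' @export
n_free_params <- function(spec = build_variant("full")) {
  12L - length(spec$frozen) + 1L
}

#' Population-level prior
#'
#' Weakly informative hyperpriors on the transformed scale: Normal on each
#' population mean and half-Normal on each population SD.  Report-order
#' weights carry a flat Dirichlet prior at the subject level.
#'
#' @param mean_loc,mean_scale Normal prior on transformed population means.
#' @param sd_scale Scale of the half-Normal prior on population SDs.
#' @param kappa_init Initial value for both concentrations (natural scale).
#' @return An object of class `wr_prior`.
#' @export
population_prior <- function(mean_loc = 0, mean_scale = 1.5, sd_scale = 1,
                             kappa_init = 5) {
  structure(list(mean_loc = mean_loc, mean_scale = mean_scale,
                 sd_scale = sd_scale, kappa_init = kappa_init),
            class = "wr_prior")
}

#' MCMC configuration
#'
#' Defaults follow the reference sampling scheme: 5000 adaptation
#' iterations, 10,000 retained iterations, 4 chains (40,000 retained
#' draws).  [mcmc_config_quick()] is a scaled-down configuration for
#' simulation studies and tests.
#'
#' @param n_adapt Adaptation (warm-up) iterations, discarded.
#' @param n_iter Retained iterations per chain.
#' @param n_chains Number of chains.
#' @param thin Keep every `thin`-th retained iteration.
#' @param seed Integer seed.
#' @return An object of class `wr_mcmc`.
#' @export
mcmc_config <- function(n_adapt = 5000L, n_iter = 10000L, n_chains = 4L,
                        thin = 1L, seed = 1L) {
  stopifnot(n_adapt >= 0, n_iter >= 1, n_chains >= 1, thin >= 1)
  structure(list(n_adapt = as.integer(n_adapt), n_iter = as.integer(n_iter),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "wr_mcmc")
}

#' @rdname mcmc_config
#' @export
mcmc_config_quick <- function(n_adapt = 500L, n_iter = 1000L, n_chains = 2L,
                              thin = 1L, seed = 1L) {
  mcmc_config(n_adapt, n_iter, n_chains, thin, seed)
}

softmax_rows <- function(z) {
  e <- exp(cbind(z, 0) - apply(cbind(z, 0), 1L, max))
  e / rowSums(e)
}

natural_matrix <- function(T, frozen_idx) {
  nat <- T
  nat[, KAPPA_IDX] <- exp(T[, KAPPA_IDX, drop = FALSE])
  nat[, PROB_IDX] <- stats::plogis(T[, PROB_IDX, drop = FALSE])
  if (length(frozen_idx)) nat[, frozen_idx] <- 0
  nat
}

rowsum_by <- function(x, index, n) {
  out <- numeric(n)
  s <- rowsum(x, index)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit the hierarchical model
#'
#' Samples the posterior of all subject-level and population-level
#' parameters under a model variant, with the discrete latent states
#' (report order, swap/cyclic configuration, guesses) summed out of the
#' likelihood exactly.
#'
#' @param data Trial table ([simulate_dataset()] / [read_trials()]).
#' @param spec Model variant from [build_variant()].
#' @param prior A [population_prior()].
#' @param mcmc A [mcmc_config()]; use [mcmc_config_quick()] for scaled-down
#'   runs.
#' @param progress Print a progress line per chain.
#' @return An object of class `wr_fit`: retained draws (natural scale for
#'   subject parameters, transformed scale for population parameters),
#'   chain ids, acceptance rates, and the spec/prior/mcmc used.
#' @export
fit_hierarchical <- function(data, spec = build_variant("full"),
                             prior = population_prior(),
                             mcmc = mcmc_config(), progress = FALSE) {
  t0 <- Sys.time()
  stopifnot(inherits(spec, "wr_model_spec"), inherits(mcmc, "wr_mcmc"))
  if (!nrow(data)) stop("fit_hierarchical(): empty dataset", call. = FALSE)
  bundle <- prepare_loglik_data(data)
  subjects <- sort(unique(data$subject))
  n_subj <- length(subjects)
  subj_idx <- match(data$subject, subjects)
  egroup_trial <- unname(spec$group_map[bundle$group])
  egroups <- sort(unique(egroup_trial))
  frozen_idx <- match(spec$frozen, PARAM_NAMES)
  free_idx <- setdiff(1:12, frozen_idx)

  # per-effective-group data bundles
  gb <- lapply(egroups, function(g) {
    rows <- which(egroup_trial == g)
    list(rows = rows,
         stim_col = bundle$stim_col[rows, , drop = FALSE],
         stim_loc = bundle$stim_loc[rows, , drop = FALSE],
         resp_col = bundle$resp_col[rows, , drop = FALSE],
         resp_loc = bundle$resp_loc[rows, , drop = FALSE],
         cond = bundle$cond[rows], cue_perm = bundle$cue_perm[rows, , drop = FALSE],
         par_index = subj_idx[rows],
         has_uncued = any(bundle$cond[rows] == 0L))
  })
  names(gb) <- egroups
  eval_ll <- function(b, nat, ow) {
    .wr_loglik_cpp(b$stim_col, b$stim_loc, b$resp_col, b$resp_loc,
                   b$cond, b$cue_perm, b$par_index, nat, ow)
  }

  n_keep <- mcmc$n_iter %/% mcmc$thin
  set.seed(mcmc$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, mcmc$n_chains)

  run_chain <- function(cseed, chain_id) {
    set.seed(cseed)
    st <- lapply(egroups, function(g) {
      mu <- rep(0, 12)
      mu[KAPPA_IDX] <- log(prior$kappa_init)
      e <- new.env(parent = emptyenv())
      e$T <- matrix(rep(mu, each = n_subj), n_subj, 12)
      e$Z <- matrix(0, n_subj, 5)
      e$mu <- mu
      e$sd <- rep(0.5, 12)
      e$ls_T <- matrix(log(0.3), n_subj, 12)
      e$ls_Z <- rep(log(0.2), n_subj)
      e$ls_sd <- rep(log(0.3), 12)
      e$acc_T <- matrix(0, n_subj, 12)
      e$try_T <- 0
      b <- gb[[g]]
      nat <- natural_matrix(e$T, frozen_idx)
      e$ll_trial <- eval_ll(b, nat, softmax_rows(e$Z))
      if (any(!is.finite(e$ll_trial))) {
        stop("non-finite likelihood at initialization", call. = FALSE)
      }
      e$ll_subj <- rowsum_by(e$ll_trial, b$par_index, n_subj)
      e
    })
    names(st) <- egroups

    draws <- list(
      subj = lapply(egroups, function(g) array(NA_real_, c(n_keep, n_subj, 12))),
      order = lapply(egroups, function(g) array(NA_real_, c(n_keep, n_subj, 6))),
      pop_mean = lapply(egroups, function(g) matrix(NA_real_, n_keep, 12)),
      pop_sd = lapply(egroups, function(g) matrix(NA_real_, n_keep, 12))
    )
    for (nm in names(draws)) names(draws[[nm]]) <- egroups

    total <- mcmc$n_adapt + mcmc$n_iter
    for (it in seq_len(total)) {
      adapting <- it <= mcmc$n_adapt
      gam <- if (adapting) min(0.25, 2 / sqrt(it)) else 0
      for (g in egroups) {
        e <- st[[g]]
        b <- gb[[g]]
        ow <- softmax_rows(e$Z)
        # subject-level scalars
        for (p in free_idx) {
          tcur <- e$T[, p]
          tprop <- tcur + stats::rnorm(n_subj) * exp(e$ls_T[, p])
          Tp <- e$T
          Tp[, p] <- tprop
          natp <- natural_matrix(Tp, frozen_idx)
          ok <- natp[, 3] + natp[, 4] <= 1 + 1e-12
          llp_trial <- eval_ll(b, natp, ow)
          llp_subj <- rowsum_by(llp_trial, b$par_index, n_subj)
          logr <- (llp_subj - e$ll_subj) +
            stats::dnorm(tprop, e$mu[p], e$sd[p], log = TRUE) -
            stats::dnorm(tcur, e$mu[p], e$sd[p], log = TRUE)
          logr[!ok | !is.finite(llp_subj)] <- -Inf
          acc <- log(stats::runif(n_subj)) < logr
          if (any(acc)) {
            e$T[acc, p] <- tprop[acc]
            sel <- b$par_index %in% which(acc)
            e$ll_trial[sel] <- llp_trial[sel]
            e$ll_subj[acc] <- llp_subj[acc]
          }
          if (adapting) {
            e$ls_T[, p] <- e$ls_T[, p] + gam * (as.numeric(acc) - 0.44)
          } else {
            e$acc_T[, p] <- e$acc_T[, p] + as.numeric(acc)
          }
        }
        if (!adapting) e$try_T <- e$try_T + 1
        nat <- natural_matrix(e$T, frozen_idx)
        # report-order weights (only identified by uncued trials)
        if (gb[[g]]$has_uncued) {
          Zp <- e$Z + matrix(stats::rnorm(n_subj * 5), n_subj, 5) * exp(e$ls_Z)
          owp <- softmax_rows(Zp)
          owc <- softmax_rows(e$Z)
          llp_trial <- eval_ll(b, nat, owp)
          llp_subj <- rowsum_by(llp_trial, b$par_index, n_subj)
          logr <- (llp_subj - e$ll_subj) +
            rowSums(log(owp)) - rowSums(log(owc))
          logr[!is.finite(llp_subj)] <- -Inf
          acc <- log(stats::runif(n_subj)) < logr
          if (any(acc)) {
            e$Z[acc, ] <- Zp[acc, , drop = FALSE]
            sel <- b$par_index %in% which(acc)
            e$ll_trial[sel] <- llp_trial[sel]
            e$ll_subj[acc] <- llp_subj[acc]
          }
          if (adapting) e$ls_Z <- e$ls_Z + gam * (as.numeric(acc) - 0.25)
        }
        # population level: conjugate mean, random-walk SD
        for (p in free_idx) {
          prec <- n_subj / e$sd[p]^2 + 1 / prior$mean_scale^2
          m <- (sum(e$T[, p]) / e$sd[p]^2 + prior$mean_loc / prior$mean_scale^2) / prec
          e$mu[p] <- stats::rnorm(1, m, sqrt(1 / prec))
          lsd_prop <- log(e$sd[p]) + stats::rnorm(1) * exp(e$ls_sd[p])
          sdp <- exp(lsd_prop)
          logr <- sum(stats::dnorm(e$T[, p], e$mu[p], sdp, log = TRUE)) -
            sum(stats::dnorm(e$T[, p], e$mu[p], e$sd[p], log = TRUE)) +
            stats::dnorm(sdp, 0, prior$sd_scale, log = TRUE) -
            stats::dnorm(e$sd[p], 0, prior$sd_scale, log = TRUE) +
            lsd_prop - log(e$sd[p])
          if (is.finite(logr) && log(stats::runif(1)) < logr) {
            e$sd[p] <- sdp
            if (adapting) e$ls_sd[p] <- e$ls_sd[p] + gam * (1 - 0.44)
          } else if (adapting) {
            e$ls_sd[p] <- e$ls_sd[p] - gam * 0.44
          }
        }
      }
      if (!adapting && (it - mcmc$n_adapt) %% mcmc$thin == 0L) {
        k <- (it - mcmc$n_adapt) %/% mcmc$thin
        for (g in egroups) {
          e <- st[[g]]
          draws$subj[[g]][k, , ] <- natural_matrix(e$T, frozen_idx)
          draws$order[[g]][k, , ] <- softmax_rows(e$Z)
          draws$pop_mean[[g]][k, ] <- e$mu
          draws$pop_sd[[g]][k, ] <- e$sd
        }
      }
    }
    if (progress) {
      message(sprintf("chain %d done (%d iterations)", chain_id, total))
    }
    acc_rate <- vapply(egroups, function(g) {
      e <- st[[g]]
      if (e$try_T > 0) mean(e$acc_T[, free_idx] / e$try_T) else NA_real_
    }, 1)
    list(draws = draws, acc_rate = acc_rate)
  }

  chains <- lapply(seq_len(mcmc$n_chains),
                   function(cc) run_chain(chain_seeds[cc], cc))

  # bind chains along the draw dimension
  bind1 <- function(get) {
    lapply(setNames(egroups, egroups), function(g) {
      parts <- lapply(chains, function(ch) get(ch$draws, g))
      if (length(dim(parts[[1]])) == 3L) {
        out <- array(NA_real_, c(n_keep * length(parts), dim(parts[[1]])[2:3]))
        for (i in seq_along(parts)) {
          out[(i - 1) * n_keep + seq_len(n_keep), , ] <- parts[[i]]
        }
        out
      } else {
        do.call(rbind, parts)
      }
    })
  }
  draws <- list(
    subj = bind1(function(d, g) d$subj[[g]]),
    order = bind1(function(d, g) d$order[[g]]),
    pop_mean = bind1(function(d, g) d$pop_mean[[g]]),
    pop_sd = bind1(function(d, g) d$pop_sd[[g]])
  )
  structure(list(
    draws = draws,
    chain = rep(seq_len(mcmc$n_chains), each = n_keep),
    subjects = subjects,
    egroups = egroups,
    free_idx = free_idx,
    spec = spec, prior = prior, mcmc = mcmc,
    acc_rate = rowMeans(matrix(vapply(chains, function(ch) ch$acc_rate,
                                      numeric(length(egroups))),
                               nrow = length(egroups))),
    n_trials = nrow(data),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "wr_fit")
}

#' @export
print.wr_fit <- function(x, ...) {
  cat("<wr_fit> variant:", x$spec$variant, "\n")
  cat("  subjects:", length(x$subjects),
      " groups:", paste(x$egroups, collapse = ", "), "\n")
  cat("  draws:", length(x$chain), "retained over", x$mcmc$n_chains,
      "chain(s);", x$n_trials, "trials;",
      sprintf("%.1f s", x$runtime_s), "\n")
  invisible(x)
}

#' Posterior means per subject
#'
#' Arithmetic means of the retained draws on the natural scale, per subject
#' and effective parameter group, for the 12 scalar parameters and the six
#' report-order weights.
#'
#' @param fit A [fit_hierarchical()] result.
#' @return A tibble with columns `subject`, `group`, `parameter`, `mean`.
#' @export
posterior_subject_means <- function(fit) {
  out <- list()
  for (g in fit$egroups) {
    sm <- apply(fit$draws$subj[[g]], c(2, 3), mean)
    om <- apply(fit$draws$order[[g]], c(2, 3), mean)
    out[[g]] <- tibble::tibble(
      subject = rep(fit$subjects, times = 18),
      group = g,
      parameter = rep(c(PARAM_NAMES, paste0("order_w", 1:6)),
                      each = length(fit$subjects)),
      mean = c(sm, om)
    )
  }
  dplyr::bind_rows(out)
}

#' Pointwise log-likelihood matrix
#'
#' Entry (i, s) is the marginal log-likelihood of trial i under posterior
#' draw s, the input to [waic()].
#'
#' @param data Trial table; every subject and parameter group must be
#'   covered by the fit.
#' @param fit A [fit_hierarchical()] result.
#' @param thin Keep every `thin`-th retained draw.
#' @return Numeric matrix, trials x draws.
#' @export
pointwise_loglik <- function(data, fit, thin = 1L) {
  bundle <- prepare_loglik_data(data)
  eg <- unname(fit$spec$group_map[bundle$group])
  missing_g <- setdiff(unique(eg), fit$egroups)
  if (length(missing_g)) {
    stop("fit does not cover group(s): ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  }
  s_idx <- match(data$subject, fit$subjects)
  if (any(is.na(s_idx))) {
    stop("fit does not cover subject(s): ",
         paste(unique(data$subject[is.na(s_idx)]), collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(data.frame(g = eg, s = s_idx))
  par_index <- match(paste(eg, s_idx), paste(keys$g, keys$s))
  draw_ids <- seq(1, dim(fit$draws$subj[[1]])[1], by = thin)
  out <- matrix(NA_real_, nrow(data), length(draw_ids))
  for (d in seq_along(draw_ids)) {
    k <- draw_ids[d]
    pm <- do.call(rbind, lapply(seq_len(nrow(keys)), function(r) {
      fit$draws$subj[[keys$g[r]]][k, keys$s[r], ]
    }))
    ow <- do.call(rbind, lapply(seq_len(nrow(keys)), function(r) {
      fit$draws$order[[keys$g[r]]][k, keys$s[r], ]
    }))
    out[, d] <- bundle_loglik(bundle, pm, ow, par_index)
  }
  out
}

# -- diagnostics ------------------------------------------------------------

split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    n <- floor(length(v) / 2)
    if (n < 2) return(NULL)
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  if (length(halves) < 2) return(NA_real_)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 1)
  W <- mean(vapply(halves, stats::var, 1))
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(x, chain) {
  xs <- split(x, chain)
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  # mean autocorrelation over chains, Geyer initial positive sequence
  maxlag <- min(length(xs[[1]]) - 1, 500)
  rho <- rowMeans(vapply(xs, function(v) {
    a <- stats::acf(v, lag.max = maxlag, plot = FALSE)$acf[-1]
    if (is.na(a[1])) a[] <- 0
    a
  }, numeric(maxlag)))
  s <- 0
  for (k in seq(1, maxlag - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}

#' @rdname fit_hierarchical
#' @param x A `wr_fit` object.
#' @param ... Unused.
#' @export
glance.wr_fit <- function(x, ...) {
  rh <- es <- c()
  for (g in x$egroups) {
    for (p in x$free_idx) {
      v <- x$draws$pop_mean[[g]][, p]
      rh <- c(rh, split_rhat(v, x$chain))
      es <- c(es, ess_basic(v, x$chain))
    }
  }
  tibble::tibble(
    variant = x$spec$variant,
    n_subjects = length(x$subjects),
    n_trials = x$n_trials,
    n_draws = length(x$chain),
    n_chains = x$mcmc$n_chains,
    max_rhat = max(rh, na.rm = TRUE),
    min_ess = min(es, na.rm = TRUE),
    accept_rate = mean(x$acc_rate),
    runtime_s = x$runtime_s
  )
}

#' @rdname fit_hierarchical
#' @param level `"population"` (population means, natural scale) or
#'   `"subject"` (per-subject parameters).
#' @export
tidy.wr_fit <- function(x, level = c("population", "subject"), ...) {
  level <- match.arg(level)
  out <- list()
  to_natural <- function(p, v) {
    if (p %in% KAPPA_IDX) exp(v) else stats::plogis(v)
  }
  if (level == "population") {
    for (g in x$egroups) {
      for (p in x$free_idx) {
        v <- to_natural(p, x$draws$pop_mean[[g]][, p])
        out[[length(out) + 1L]] <- tibble::tibble(
          group = g, term = PARAM_NAMES[p],
          estimate = mean(v), std.error = stats::sd(v),
          conf.low = unname(stats::quantile(v, 0.025)),
          conf.high = unname(stats::quantile(v, 0.975)),
          rhat = split_rhat(x$draws$pop_mean[[g]][, p], x$chain),
          ess = ess_basic(x$draws$pop_mean[[g]][, p], x$chain)
        )
      }
    }
  } else {
    means <- posterior_subject_means(x)
    for (g in x$egroups) {
      qs <- apply(x$draws$subj[[g]], c(2, 3), stats::quantile,
                  probs = c(0.025, 0.975))
      for (p in seq_len(12)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          group = g, subject = x$subjects, term = PARAM_NAMES[p],
          estimate = means$mean[means$group == g &
                                  means$parameter == PARAM_NAMES[p]],
          conf.low = qs[1, , p], conf.high = qs[2, , p]
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
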