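# Decomposition of fitted parameters and data into headline quantities:
# overall swap rates, the symmetric / asymmetric composition of swap
# trials, per-trial error-type posteriors, raw absolute error, and
# report-order biases.
#
# Conditional on a swap, a trial stays a *symmetric misbinding* only if
# neither swapped object is object-guessed and neither has a feature guess
# on the swapped dimension; an object guess within the swap makes it an
# asymmetric misattribution by object guessing, and otherwise a feature
# guess within the swap makes it an asymmetric misattribution by feature
# guessing.  Guesses on the unswapped object do not change the label.

#' Closed-form composition of swap trials
#'
#' From the within-swap guessing parameters, computes the probability that
#' a swap trial is a symmetric misbinding, an asymmetric misattribution by
#' feature guessing, or an asymmetric misattribution by object guessing
#' (total probability over the two swapped objects).
#'
#' @param params A [model_params()] object.
#' @return A one-row tibble: `p_swap_overall`, `frac_symmetric`,
#'   `frac_asym_feature`, `frac_asym_object`, `p_cyclic`.  The three
#'   fractions sum to 1.
#' @export
swap_composition <- function(params) {
  gf <- params$g_feat_swap_swp
  go <- params$g_obj_swap_swp
  sym <- ((1 - go) * (1 - gf))^2
  ao <- 1 - (1 - go)^2
  af <- (1 - go)^2 * (1 - (1 - gf)^2)
  tibble::tibble(
    p_swap_overall = params$p_swap,
    frac_symmetric = sym,
    frac_asym_feature = af,
    frac_asym_object = ao,
    p_cyclic = params$p_cyclic_swap
  )
}

ERROR_CLASSES <- c("correct", "symmetric_swap", "asym_feature", "asym_object",
                   "cyclic", "pure_guess")

# per-trial class posterior for one parameter set; trial as a plain list
classify_one <- function(trial, params) {
  u <- 1 / (2 * pi)
  sc <- as.numeric(trial[paste0("stim_col_", 1:3)])
  sl <- as.numeric(trial[paste0("stim_loc_", 1:3)])
  rc <- as.numeric(trial[paste0("resp_col_", 1:3)])
  rl <- as.numeric(trial[paste0("resp_loc_", 1:3)])
  cond <- trial$condition
  cued <- is_cued(cond)
  vc <- outer(1:3, 1:3, function(s, k) exp(von_mises_logpdf(rc[s], sc[k], params$kappa_colour)))
  vl <- outer(1:3, 1:3, function(s, k) exp(von_mises_logpdf(rl[s], sl[k], params$kappa_location)))
  pn <- 1 - params$p_swap - params$p_cyclic_swap
  mass <- setNames(numeric(6), ERROR_CLASSES)

  # per-object mixture pieces given guessing rates and a colour source;
  # cued trials collapse to the report dimension
  pieces <- function(s, o, src, gf, go) {
    if (!cued) {
      mc <- function(k) gf * u + (1 - gf) * vc[s, k]
      ml <- function(k) gf * u + (1 - gf) * vl[s, k]
      tot <- go * u * u + (1 - go) * mc(src) * ml(o)
      clean_swapdim <- (1 - go) * (1 - gf) * vc[s, src] * ml(o)  # A
      objg <- go * u * u                                         # B
      noflag <- (1 - go) * (1 - gf)^2 * vc[s, src] * vl[s, o]
    } else {
      v <- if (cond == "cued_by_location") vc[s, src] else vl[s, src]
      tot <- (go + (1 - go) * gf) * u + (1 - go) * (1 - gf) * v
      clean_swapdim <- (1 - go) * (1 - gf) * v
      objg <- go * u
      noflag <- clean_swapdim
    }
    c(tot = tot, A = clean_swapdim, B = objg, noflag = noflag)
  }

  perms <- if (cued) {
    list(as.integer(trial[paste0("cue_sel_", 1:3)]))
  } else {
    lapply(1:6, function(p) PERMS[p, ])
  }
  wts <- if (cued) 1 else params$order_weights

  for (ip in seq_along(perms)) {
    perm <- perms[[ip]]
    w <- wts[ip]
    if (w <= 0) next
    slot_of <- order(perm)
    # no binding error
    if (pn > 0) {
      g <- guess_rates(params, "none", FALSE)
      pc_tot <- pc_nf <- 1
      for (o in 1:3) {
        pp <- pieces(slot_of[o], o, o, g[["gf"]], g[["go"]])
        pc_tot <- pc_tot * pp["tot"]
        pc_nf <- pc_nf * pp["noflag"]
      }
      mass["correct"] <- mass["correct"] + w * pn * pc_nf
      mass["pure_guess"] <- mass["pure_guess"] + w * pn * (pc_tot - pc_nf)
    }
    # pairwise swaps
    if (params$p_swap > 0) {
      gs <- guess_rates(params, "swap", TRUE)
      gn <- guess_rates(params, "swap", FALSE)
      for (e in 1:3) {
        pr <- SWAP_PAIRS[e, ]
        sigma <- error_sigma("swap", pr)
        i <- pr[1]; j <- pr[2]; unsw <- setdiff(1:3, pr)
        pi_ <- pieces(slot_of[i], i, sigma[i], gs[["gf"]], gs[["go"]])
        pj <- pieces(slot_of[j], j, sigma[j], gs[["gf"]], gs[["go"]])
        mu_ <- pieces(slot_of[unsw], unsw, unsw, gn[["gf"]], gn[["go"]])[["tot"]]
        base <- w * params$p_swap / 3 * mu_
        sym <- pi_[["A"]] * pj[["A"]]
        ao <- pi_[["B"]] * pj[["tot"]] + pi_[["tot"]] * pj[["B"]] -
          pi_[["B"]] * pj[["B"]]
        af <- pi_[["tot"]] * pj[["tot"]] - sym - ao
        mass["symmetric_swap"] <- mass["symmetric_swap"] + base * sym
        mass["asym_object"] <- mass["asym_object"] + base * ao
        mass["asym_feature"] <- mass["asym_feature"] + base * af
      }
    }
    # cyclic swaps
    if (params$p_cyclic_swap > 0) {
      g <- guess_rates(params, "cyclic", FALSE)
      for (dir in 1:2) {
        sigma <- CYCLES[dir, ]
        pc_tot <- 1
        for (o in 1:3) {
          pc_tot <- pc_tot * pieces(slot_of[o], o, sigma[o],
                                    g[["gf"]], g[["go"]])[["tot"]]
        }
        mass["cyclic"] <- mass["cyclic"] + w * params$p_cyclic_swap / 2 * pc_tot
      }
    }
  }
  mass / sum(mass)
}

#' Posterior error-type classification of trials
#'
#' For every trial, the posterior probability that it was generated without
#' a binding error and without guesses (`correct`), as a symmetric swap, as
#' an asymmetric misattribution via feature or object guessing within the
#' swap, as a cyclic swap, or without a binding error but with at least one
#' guess (`pure_guess`).  Rows sum to 1.
#'
#' @param data Trial table.
#' @param fit Either a [fit_hierarchical()] result (parameters are taken at
#'   the per-subject posterior means) or parameters as accepted by
#'   [loglik_trials()].
#' @return `data` augmented with one `p_<class>` column per error class
#'   and an attribute `at` recording the evaluation point.
#' @export
classify_trials <- function(data, fit) {
  at <- "fixed-params"
  if (inherits(fit, "wr_fit")) {
    at <- "posterior-means"
    means <- posterior_subject_means(fit)
    lookup <- function(subject, group) {
      m <- means[means$subject == subject & means$group == group, ]
      vals <- setNames(m$mean, m$parameter)
      model_params(
        kappa_colour = vals[["kappa_colour"]],
        kappa_location = vals[["kappa_location"]],
        p_swap = vals[["p_swap"]], p_cyclic_swap = vals[["p_cyclic_swap"]],
        g_feature = vals[["g_feature"]], g_object = vals[["g_object"]],
        g_feat_swap_non = vals[["g_feat_swap_non"]],
        g_feat_swap_swp = vals[["g_feat_swap_swp"]],
        g_obj_swap_non = vals[["g_obj_swap_non"]],
        g_obj_swap_swp = vals[["g_obj_swap_swp"]],
        g_feat_cyclic = vals[["g_feat_cyclic"]],
        g_obj_cyclic = vals[["g_obj_cyclic"]],
        order_weights = vals[paste0("order_w", 1:6)]
      )
    }
    eg <- unname(fit$spec$group_map[param_group(data$condition)])
    keys <- unique(data.frame(s = data$subject, g = eg))
    pars <- lapply(seq_len(nrow(keys)), function(r) lookup(keys$s[r], keys$g[r]))
    par_of <- match(paste(data$subject, eg), paste(keys$s, keys$g))
  } else {
    if (inherits(fit, "wr_params")) {
      pars <- list(fit)
      par_of <- rep(1L, nrow(data))
    } else {
      pars <- fit
      par_of <- match(param_group(data$condition), names(fit))
      if (any(is.na(par_of))) {
        stop("parameters missing for some groups", call. = FALSE)
      }
    }
  }
  post <- matrix(NA_real_, nrow(data), 6,
                 dimnames = list(NULL, paste0("p_", ERROR_CLASSES)))
  for (i in seq_len(nrow(data))) {
    post[i, ] <- classify_one(as.list(data[i, ]), pars[[par_of[i]]])
  }
  out <- dplyr::bind_cols(tibble::as_tibble(data), tibble::as_tibble(post))
  attr(out, "at") <- at
  out
}

#' Raw unsigned recall error
#'
#' The absolute error of recall: the unsigned circular difference between
#' target and response angles, taken slot by slot under the identity
#' mapping (no latent reassignment).
#'
#' @param data Trial table.
#' @return A long tibble with columns `subject`, `condition`, `slot`,
#'   `dimension` and `error` (degrees in `[0, 180]`).
#' @export
absolute_error <- function(data) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(data),
                  dplyr::any_of(c("subject", "trial", "condition")),
                  dplyr::matches("^(stim|resp)_(col|loc)_[123]$")),
    dplyr::matches("^(stim|resp)_"),
    names_to = c("role", "dimension", "slot"), names_sep = "_",
    values_to = "angle"
  )
  wide <- tidyr::pivot_wider(long, names_from = "role", values_from = "angle")
  dplyr::mutate(
    wide,
    dimension = dplyr::recode(.data$dimension, col = "colour", loc = "location"),
    slot = as.integer(.data$slot),
    error = abs(circ_dist(.data$resp, .data$stim)),
    stim = NULL, resp = NULL
  )
}

#' Report-order bias on uncued trials
#'
#' Fraction of uncued trials whose first-reported object is the topmost
#' (location closest to straight up) or the leftmost object.  The first
#' reported object is identified as the one whose true location is
#' circularly closest to the first reported location; ties go to the lowest
#' object index.
#'
#' @param data Trial table containing uncued trials.
#' @param up_angle Screen direction treated as "up", degrees (default 90).
#' @param left_angle Screen direction treated as "left", degrees (default
#'   180).
#' @return A one-row tibble: `frac_topmost_first`, `frac_leftmost_first`,
#'   `n_trials`.
#' @export
report_order_bias <- function(data, up_angle = 90, left_angle = 180) {
  unc <- data[!is_cued(data$condition), , drop = FALSE]
  if (!nrow(unc)) stop("report_order_bias(): no uncued trials", call. = FALSE)
  sl <- as.matrix(unc[paste0("stim_loc_", 1:3)])
  first_loc <- unc$resp_loc_1
  d_first <- abs(circ_dist(sl, matrix(first_loc, nrow(unc), 3)))
  first_obj <- apply(d_first, 1L, which.min)
  top_obj <- apply(abs(circ_dist(sl, matrix(up_angle, nrow(unc), 3))), 1L, which.min)
  left_obj <- apply(abs(circ_dist(sl, matrix(left_angle, nrow(unc), 3))), 1L, which.min)
  tibble::tibble(
    frac_topmost_first = mean(first_obj == top_obj),
    frac_leftmost_first = mean(first_obj == left_obj),
    n_trials = nrow(unc)
  )
}

#' Per-subject error summary in the shape of the headline tables
#'
#' Combines per-subject posterior-mean parameters with the closed-form
#' swap composition: overall swap probability, composition fractions (in
#' percent), cyclic rate, and the two concentrations.
#'
#' @param fit A [fit_hierarchical()] result.
#' @return A tibble, one row per subject x group.
#' @export
summarize_errors <- function(fit) {
  means <- posterior_subject_means(fit)
  wide <- tidyr::pivot_wider(means, names_from = "parameter",
                             values_from = "mean")
  comp <- purrr::pmap(
    list(wide$p_swap, wide$p_cyclic_swap,
         wide$g_feat_swap_swp, wide$g_obj_swap_swp),
    function(ps, pc, gf, go) {
      swap_composition(model_params(p_swap = ps, p_cyclic_swap = pc,
                                    g_feat_swap_swp = gf,
                                    g_obj_swap_swp = go))
    }
  )
  dplyr::bind_cols(
    dplyr::select(wide, "subject", "group",
                  "kappa_colour", "kappa_location"),
    dplyr::bind_rows(comp)
  ) |>
    dplyr::mutate(
      pct_swap = 100 * .data$p_swap_overall,
      pct_symmetric = 100 * .data$frac_symmetric,
      pct_asym_feature = 100 * .data$frac_asym_feature,
      pct_asym_object = 100 * .data$frac_asym_object
    )
}
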