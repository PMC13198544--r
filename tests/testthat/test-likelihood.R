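test_that("von Mises log-density has the right limits and normalisation", {
  expect_equal(von_mises_logpdf(123, 45, 0), log(1 / (2 * pi)))
  # at the mode, kappa = 2: log(e^2 / (2 pi I0(2))) via the Bessel function
  expect_equal(von_mises_logpdf(30, 30, 2), 2 - log(2 * pi * besselI(2, 0)),
               tolerance = 1e-12)
  grid <- seq(0, 360, length.out = 3601)[-3601]
  for (k in c(0.5, 5, 50)) {
    dens <- exp(von_mises_logpdf(grid, 180, k))
    expect_equal(sum(dens) * (2 * pi / 3600), 1, tolerance = 1e-6)
  }
  expect_error(von_mises_logpdf(0, 0, -1), "kappa")
})

test_that("latent enumeration collapses to order weights without errors", {
  p <- model_params(order_weights = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1))
  en <- enumerate_latents(p, "uncued_CL")
  expect_length(en$states, 6L)
  expect_equal(sort(en$prior, decreasing = TRUE),
               sort(p$order_weights, decreasing = TRUE))
  ids <- vapply(en$states, function(s) s$perm_id, 1L)
  expect_setequal(ids, 1:6)
})

test_that("enumeration priors sum to one across random parameters", {
  set.seed(10)
  for (i in 1:100) {
    p <- random_params()
    cond <- sample(CONDITIONS, 1)
    en <- enumerate_latents(p, cond, drop_zero = FALSE)
    expect_equal(sum(en$prior), 1, tolerance = 1e-12)
  }
})

test_that("forced swaps split prior mass equally across the three pairs", {
  p <- rich_params()
  p$p_swap <- 1; p$p_cyclic_swap <- 0
  en <- enumerate_latents(p, "uncued_CL")
  pairs <- vapply(en$states, function(s) paste(s$swap_pair, collapse = ""), "")
  mass <- tapply(en$prior, pairs, sum)
  expect_equal(as.numeric(mass), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("state log-likelihood composes feature terms as documented", {
  p <- model_params(kappa_colour = 2, kappa_location = 2)
  st <- fixed_stimuli()
  trial <- dplyr::bind_cols(
    tibble::tibble(subject = 1L, condition = "uncued_CL"), st,
    tibble::tibble(resp_col_1 = st$stim_col_1, resp_col_2 = st$stim_col_2,
                   resp_col_3 = st$stim_col_3, resp_loc_1 = st$stim_loc_1,
                   resp_loc_2 = st$stim_loc_2, resp_loc_3 = st$stim_loc_3,
                   cue_sel_1 = NA_integer_, cue_sel_2 = NA_integer_,
                   cue_sel_3 = NA_integer_)
  )
  identity_state <- structure(list(condition = "uncued_CL", perm_id = 1L,
                                   error_kind = "none", swap_pair = NULL,
                                   cyclic_dir = NULL, obj_guess = rep(FALSE, 3),
                                   guess_col = rep(FALSE, 3),
                                   guess_loc = rep(FALSE, 3)),
                             class = "wr_latent")
  expect_equal(state_loglik(trial, identity_state, p),
               6 * von_mises_logpdf(0, 0, 2), tolerance = 1e-12)
  all_guessed <- identity_state
  all_guessed$guess_col <- all_guessed$guess_loc <- rep(TRUE, 3)
  expect_equal(state_loglik(trial, all_guessed, p), 6 * log(1 / (2 * pi)))
})

test_that("a cued state contradicting the observed cue selection is impossible", {
  set.seed(11)
  trial <- random_trial("cued_by_location")
  p <- rich_params()
  obs_perm <- as.integer(trial[paste0("cue_sel_", 1:3)])
  wrong <- which(apply(permutations3(), 1, function(r) !all(r == obs_perm)))[1]
  st <- structure(list(condition = "cued_by_location", perm_id = wrong,
                       error_kind = "none", swap_pair = NULL, cyclic_dir = NULL,
                       obj_guess = rep(FALSE, 3), guess_col = rep(FALSE, 3),
                       guess_loc = rep(FALSE, 3)), class = "wr_latent")
  expect_identical(state_loglik(trial, st, p), -Inf)
})

test_that("fast marginal likelihood equals the package enumeration", {
  set.seed(12)
  for (cond in CONDITIONS) {
    p <- random_params()
    trial <- random_trial(cond)
    en <- enumerate_latents(p, cond)
    lls <- vapply(en$states, function(s) state_loglik(trial, s, p), 1)
    m <- max(lls + log(en$prior))
    enum_ll <- m + log(sum(exp(lls + log(en$prior) - m)))
    expect_equal(trial_loglik(trial, p), enum_ll, tolerance = 1e-9)
  }
})

test_that("marginal likelihood matches the independent brute-force oracle", {
  set.seed(13)
  for (i in 1:25) {
    cond <- sample(CONDITIONS, 1)
    p <- random_params()
    trial <- random_trial(cond)
    expect_equal(trial_loglik(trial, p), naive_trial_loglik(trial, p),
                 tolerance = 1e-9)
  }
})

test_that("zero concentration collapses the likelihood to the uniform", {
  p <- rich_params()
  p$kappa_colour <- 1e-300  # numerically zero concentration
  p$kappa_location <- 1e-300
  set.seed(14)
  trial <- random_trial("uncued_CL")
  expect_equal(trial_loglik(trial, p), 6 * log(1 / (2 * pi)), tolerance = 1e-9)
})

test_that("more swap probability makes a perfect swap pattern more likely", {
  st <- fixed_stimuli()
  # reciprocal colour exchange between objects 1 and 2, locations correct
  trial <- dplyr::bind_cols(
    tibble::tibble(subject = 1L, condition = "uncued_CL"), st,
    tibble::tibble(resp_col_1 = st$stim_col_2, resp_col_2 = st$stim_col_1,
                   resp_col_3 = st$stim_col_3, resp_loc_1 = st$stim_loc_1,
                   resp_loc_2 = st$stim_loc_2, resp_loc_3 = st$stim_loc_3,
                   cue_sel_1 = NA_integer_, cue_sel_2 = NA_integer_,
                   cue_sel_3 = NA_integer_)
  )
  lls <- sapply(c(0.05, 0.2, 0.5, 0.8), function(ps) {
    p <- model_params(kappa_colour = 30, kappa_location = 30, p_swap = ps)
    trial_loglik(trial, p)
  })
  expect_true(all(diff(lls) > 0))
})

test_that("per-group parameter routing matches per-trial evaluation", {
  set.seed(15)
  pars <- list(cued = random_params(), uncued_CL = random_params(),
               uncued_LC = random_params())
  trials <- dplyr::bind_rows(lapply(CONDITIONS, random_trial))
  ll <- loglik_trials(trials, pars)
  for (i in seq_len(nrow(trials))) {
    expect_equal(ll[i],
                 trial_loglik(trials[i, ],
                              pars[[param_group(trials$condition[i])]]))
  }
  expect_error(loglik_trials(trials, pars[1:2]), "no parameters")
})
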