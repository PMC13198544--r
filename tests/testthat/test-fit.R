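# Small fits only; the scaled-up recovery study lives in test-acceptance.R.

tiny_fit <- function(data, variant = "full", seed = 5, n_adapt = 60,
                     n_iter = 120, n_chains = 2) {
  fit_hierarchical(data, build_variant(variant),
                   mcmc = mcmc_config(n_adapt, n_iter, n_chains, seed = seed))
}

test_that("model variants freeze and share the documented parameters", {
  full <- build_variant("full")
  expect_equal(n_free_params(full), 13L)
  expect_length(full$frozen, 0L)
  null <- build_variant("null")
  expect_setequal(null$frozen,
                  c("p_swap", "p_cyclic_swap", "g_feature", "g_object",
                    "g_feat_swap_non", "g_feat_swap_swp", "g_obj_swap_non",
                    "g_obj_swap_swp", "g_feat_cyclic", "g_obj_cyclic"))
  expect_equal(n_free_params(null), 3L)  # two kappas + order weights
  noasym <- build_variant("no_asymmetric")
  expect_setequal(noasym$frozen,
                  c("g_feat_swap_non", "g_feat_swap_swp", "g_obj_swap_non",
                    "g_obj_swap_swp", "g_feat_cyclic", "g_obj_cyclic"))
  ord <- build_variant("collapse_order")
  expect_equal(unname(ord$group_map[c("uncued_CL", "uncued_LC")]),
               c("uncued", "uncued"))
  expect_equal(unname(ord$group_map["cued"]), "cued")
  all3 <- build_variant("collapse_cue_uncued")
  expect_length(unique(all3$group_map), 1L)
  expect_error(build_variant("bogus"))
})

test_that("sampling is reproducible given the seed", {
  des <- make_design(2, 12, conditions = "uncued_CL", seed = 30)
  d <- simulate_dataset(des, rich_params(), seed = 31)
  f1 <- tiny_fit(d, seed = 7)
  f2 <- tiny_fit(d, seed = 7)
  expect_identical(f1$draws, f2$draws)
  f3 <- tiny_fit(d, seed = 8)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("null fits on clean sharp data push concentrations high", {
  des <- make_design(4, 25, conditions = "uncued_CL", seed = 32)
  d <- simulate_dataset(des, model_params(kappa_colour = 200,
                                          kappa_location = 200), seed = 33)
  f <- tiny_fit(d, variant = "null", n_adapt = 150, n_iter = 250)
  m <- posterior_subject_means(f)
  kap <- m$mean[m$parameter %in% c("kappa_colour", "kappa_location")]
  expect_true(all(kap >= 50))
})

test_that("posterior means match independent averaging of serialized draws", {
  des <- make_design(2, 10, conditions = "uncued_LC", seed = 34)
  d <- simulate_dataset(des, rich_params(), seed = 35)
  f <- tiny_fit(d)
  dir <- withr::local_tempdir()
  write_fit(f, dir)
  long <- readr::read_csv(file.path(dir, "draws_subject.csv"),
                          show_col_types = FALSE)
  indep <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$subject, .data$parameter),
    mean = mean(.data$value), .groups = "drop"
  )
  pm <- posterior_subject_means(f)
  joined <- dplyr::inner_join(pm, indep,
                              by = c("group", "subject", "parameter"),
                              suffix = c("", "_indep"))
  expect_equal(nrow(joined), nrow(pm))
  expect_equal(joined$mean, joined$mean_indep, tolerance = 1e-12)
  # draws respect their constraints
  expect_true(all(f$draws$subj[[1]][, , 3:12] >= 0 &
                    f$draws$subj[[1]][, , 3:12] <= 1))
  expect_equal(apply(f$draws$order[[1]], c(1, 2), sum),
               matrix(1, length(f$chain), 2), tolerance = 1e-12)
})

test_that("fit round-trips through its serialized form", {
  des <- make_design(2, 8, conditions = "uncued_CL", seed = 36)
  d <- simulate_dataset(des, rich_params(), seed = 37)
  f <- tiny_fit(d, n_adapt = 30, n_iter = 60)
  dir <- withr::local_tempdir()
  write_fit(f, dir)
  f2 <- read_fit(dir)
  expect_equal(f2$draws$subj[[1]], f$draws$subj[[1]], tolerance = 1e-12)
  expect_equal(f2$draws$pop_mean[[1]], f$draws$pop_mean[[1]], tolerance = 1e-12)
  expect_equal(f2$subjects, f$subjects)
  expect_equal(f2$spec$variant, f$spec$variant)
})

test_that("pointwise log-likelihood reproduces per-draw evaluation", {
  des <- make_design(2, 6, conditions = c("uncued_CL", "cued_by_colour"),
                     seed = 38)
  d <- simulate_dataset(des, rich_params(), seed = 39)
  f <- tiny_fit(d, n_adapt = 30, n_iter = 10, n_chains = 1)
  pw <- pointwise_loglik(d, f)
  expect_equal(dim(pw), c(nrow(d), 10L))
  # naive double loop over trials and draws
  for (s in c(1L, 7L)) {
    for (i in c(1L, nrow(d))) {
      g <- unname(f$spec$group_map[param_group(d$condition[i])])
      sj <- match(d$subject[i], f$subjects)
      v <- f$draws$subj[[g]][s, sj, ]
      p <- model_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8],
                        v[9], v[10], v[11], v[12],
                        order_weights = f$draws$order[[g]][s, sj, ])
      expect_equal(pw[i, s], trial_loglik(d[i, ], p), tolerance = 1e-10)
    }
  }
  # permuting trials permutes rows identically
  idx <- rev(seq_len(nrow(d)))
  expect_equal(pointwise_loglik(d[idx, ], f), pw[idx, ])
  expect_error(pointwise_loglik(dplyr::mutate(d, subject = subject + 10), f),
               "cover")
})

test_that("a swap-free model is dominated on data full of blatant swaps", {
  # every trial is a perfect symmetric swap at high precision
  st <- fixed_stimuli()
  n <- 40
  d <- dplyr::bind_cols(
    tibble::tibble(subject = rep(1:2, each = n / 2), trial = 1:n,
                   condition = "uncued_CL"),
    st[rep(1, n), ],
    tibble::tibble(resp_col_1 = st$stim_col_2, resp_col_2 = st$stim_col_1,
                   resp_col_3 = st$stim_col_3,
                   resp_loc_1 = st$stim_loc_1, resp_loc_2 = st$stim_loc_2,
                   resp_loc_3 = st$stim_loc_3,
                   cue_sel_1 = NA_integer_, cue_sel_2 = NA_integer_,
                   cue_sel_3 = NA_integer_)
  )
  f_full <- tiny_fit(d, "full", n_adapt = 150, n_iter = 250)
  f_null <- tiny_fit(d, "null", n_adapt = 150, n_iter = 250)
  ll_full <- sum(rowMeans(pointwise_loglik(d, f_full)))
  ll_null <- sum(rowMeans(pointwise_loglik(d, f_null)))
  expect_gt(ll_full, ll_null)
})
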