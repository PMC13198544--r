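test_that("swap composition has the right limits and sums to one", {
  expect_equal(swap_composition(model_params(p_swap = 0.1))$frac_symmetric, 1)
  expect_equal(swap_composition(
    model_params(g_obj_swap_swp = 1))$frac_asym_object, 1)
  set.seed(40)
  for (i in 1:50) {
    p <- random_params()
    comp <- swap_composition(p)
    expect_equal(comp$frac_symmetric + comp$frac_asym_feature +
                   comp$frac_asym_object, 1, tolerance = 1e-10)
    expect_equal(comp$p_swap_overall, p$p_swap)
  }
})

test_that("closed-form composition matches Monte Carlo latent draws", {
  set.seed(41)
  p <- model_params(p_swap = 1, g_feat_swap_swp = 0.3, g_obj_swap_swp = 0.2,
                    g_feat_swap_non = 0.1, g_obj_swap_non = 0.1)
  n <- 20000
  lab <- character(n)
  for (i in seq_len(n)) {
    lat <- sample_latent_state(p, "uncued_CL")
    pair <- lat$swap_pair
    lab[i] <- if (any(lat$obj_guess[pair])) "ao"
      else if (any(lat$guess_col[pair])) "af" else "sym"
  }
  comp <- swap_composition(p)
  mc <- c(sym = mean(lab == "sym"), af = mean(lab == "af"),
          ao = mean(lab == "ao"))
  truth <- c(sym = comp$frac_symmetric, af = comp$frac_asym_feature,
             ao = comp$frac_asym_object)
  for (k in names(mc)) {
    se <- sqrt(truth[k] * (1 - truth[k]) / n)
    expect_lt(abs(mc[k] - truth[k]), 3 * se + 1e-12)
  }
})

test_that("classification posteriors behave on constructed trials", {
  st <- fixed_stimuli()
  p <- model_params(kappa_colour = 100, kappa_location = 100, p_swap = 0.03,
                    p_cyclic_swap = 0.01, g_feature = 0.03, g_object = 0.02,
                    g_feat_swap_swp = 0.2, g_obj_swap_swp = 0.15,
                    g_feat_swap_non = 0.05, g_obj_swap_non = 0.05,
                    g_feat_cyclic = 0.05, g_obj_cyclic = 0.05)
  correct <- dplyr::bind_cols(
    tibble::tibble(subject = 1L, condition = "uncued_CL"), st,
    tibble::tibble(resp_col_1 = st$stim_col_1, resp_col_2 = st$stim_col_2,
                   resp_col_3 = st$stim_col_3, resp_loc_1 = st$stim_loc_1,
                   resp_loc_2 = st$stim_loc_2, resp_loc_3 = st$stim_loc_3,
                   cue_sel_1 = NA_integer_, cue_sel_2 = NA_integer_,
                   cue_sel_3 = NA_integer_)
  )
  out <- classify_trials(correct, p)
  expect_gt(out$p_correct, 0.99)
  swapped <- correct
  swapped$resp_col_1 <- st$stim_col_2
  swapped$resp_col_2 <- st$stim_col_1
  out2 <- classify_trials(swapped, p)
  classes <- paste0("p_", c("correct", "symmetric_swap", "asym_feature",
                            "asym_object", "cyclic", "pure_guess"))
  expect_equal(classes[which.max(as.numeric(out2[1, classes]))],
               "p_symmetric_swap")
})

test_that("classification rows sum to one on simulated data", {
  des <- make_design(2, 50, conditions = c("uncued_CL", "cued_by_location"),
                     seed = 42)
  d <- simulate_dataset(des, rich_params(), seed = 43)
  out <- classify_trials(d, rich_params())
  classes <- paste0("p_", c("correct", "symmetric_swap", "asym_feature",
                            "asym_object", "cyclic", "pure_guess"))
  sums <- rowSums(as.matrix(out[classes]))
  expect_equal(sums, rep(1, nrow(d)), tolerance = 1e-8)
})

test_that("class posteriors aggregate to the generating composition", {
  # on ground-truth swap trials the mean posterior class mass must sit
  # close to the closed-form composition of the generator
  set.seed(44)
  p <- model_params(kappa_colour = 25, kappa_location = 25, p_swap = 0.3,
                    g_feat_swap_swp = 0.3, g_obj_swap_swp = 0.2)
  des <- make_design(1, 1500, conditions = "uncued_CL", seed = 45)
  d <- simulate_dataset(des, p, seed = 46)
  swaps <- d[d$truth_error == "swap", ]
  out <- classify_trials(swaps, p)
  comp <- swap_composition(p)
  denom <- mean(out$p_symmetric_swap + out$p_asym_feature + out$p_asym_object)
  expect_lt(abs(mean(out$p_symmetric_swap) / denom - comp$frac_symmetric), 0.05)
  expect_lt(abs(mean(out$p_asym_feature) / denom - comp$frac_asym_feature), 0.05)
  expect_lt(abs(mean(out$p_asym_object) / denom - comp$frac_asym_object), 0.05)
})

test_that("absolute error is the slotwise unsigned circular difference", {
  st <- fixed_stimuli()
  d <- dplyr::bind_cols(
    tibble::tibble(subject = 1L, trial = 1L, condition = "uncued_CL"), st,
    tibble::tibble(resp_col_1 = st$stim_col_1, resp_col_2 = 190,
                   resp_col_3 = st$stim_col_3 + 30,
                   resp_loc_1 = st$stim_loc_1, resp_loc_2 = st$stim_loc_2,
                   resp_loc_3 = st$stim_loc_3)
  )
  d$stim_col_2 <- 0
  err <- absolute_error(d)
  e_col <- err[err$dimension == "colour", ]
  expect_equal(e_col$error[e_col$slot == 1], 0)
  expect_equal(e_col$error[e_col$slot == 2], 170)  # wraps past 180
  expect_equal(e_col$error[e_col$slot == 3], 30)
  expect_true(all(err$error >= 0 & err$error <= 180))
})

test_that("uniform random responses average about 90 degrees of error", {
  set.seed(47)
  n <- 4000
  d <- tibble::tibble(
    subject = 1L, trial = seq_len(n), condition = "uncued_CL",
    stim_col_1 = runif(n, 0, 360), stim_col_2 = runif(n, 0, 360),
    stim_col_3 = runif(n, 0, 360), stim_loc_1 = runif(n, 0, 360),
    stim_loc_2 = runif(n, 0, 360), stim_loc_3 = runif(n, 0, 360),
    resp_col_1 = runif(n, 0, 360), resp_col_2 = runif(n, 0, 360),
    resp_col_3 = runif(n, 0, 360), resp_loc_1 = runif(n, 0, 360),
    resp_loc_2 = runif(n, 0, 360), resp_loc_3 = runif(n, 0, 360)
  )
  expect_lt(abs(mean(absolute_error(d)$error) - 90), 1.5)
})

test_that("report-order bias detects a topmost-first strategy", {
  set.seed(48)
  n <- 400
  mk <- function(first_is_top) {
    rows <- lapply(seq_len(n), function(i) {
      st <- sample_stimulus_array()
      locs <- as.numeric(st[1, paste0("stim_loc_", 1:3)])
      top <- which.min(abs(circ_dist(locs, 90)))
      first <- if (first_is_top) top else sample.int(3, 1)
      others <- setdiff(1:3, first)
      perm <- c(first, others)
      dplyr::bind_cols(
        tibble::tibble(subject = 1L, condition = "uncued_CL"), st,
        tibble::tibble(resp_col_1 = 0, resp_col_2 = 0, resp_col_3 = 0,
                       resp_loc_1 = locs[perm[1]], resp_loc_2 = locs[perm[2]],
                       resp_loc_3 = locs[perm[3]])
      )
    })
    dplyr::bind_rows(rows)
  }
  expect_equal(report_order_bias(mk(TRUE))$frac_topmost_first, 1.0)
  random_frac <- report_order_bias(mk(FALSE))$frac_topmost_first
  se <- sqrt(1 / 3 * 2 / 3 / n)
  expect_lt(abs(random_frac - 1 / 3), 3 * se)
  cued_only <- mk(TRUE)
  cued_only$condition <- "cued_by_colour"
  expect_error(report_order_bias(cued_only), "uncued")
})
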