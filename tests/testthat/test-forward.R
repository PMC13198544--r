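test_that("latent sampling respects degenerate parameter settings", {
  set.seed(1)
  clean <- model_params()
  for (i in 1:20) {
    lat <- sample_latent_state(clean, "uncued_CL")
    expect_equal(lat$error_kind, "none")
    expect_false(any(lat$obj_guess | lat$guess_col | lat$guess_loc))
  }
  # forced swap with forced object guessing of the swapped pair
  forced <- model_params(p_swap = 1, g_obj_swap_swp = 1)
  for (i in 1:20) {
    lat <- sample_latent_state(forced, "uncued_CL")
    expect_equal(lat$error_kind, "swap")
    expect_true(all(lat$obj_guess[lat$swap_pair]))
    expect_true(all(lat$guess_col[lat$swap_pair] & lat$guess_loc[lat$swap_pair]))
  }
})

test_that("error-kind frequencies follow the categorical weights", {
  set.seed(2)
  p <- model_params(p_swap = 0.3, p_cyclic_swap = 0.1)
  kinds <- replicate(10000, sample_latent_state(p, "uncued_LC")$error_kind)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(kinds == "swap") - 0.3), 3 * se)
  se_c <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(mean(kinds == "cyclic") - 0.1), 3 * se_c)
})

test_that("latent states map to the documented assignment vectors", {
  base <- list(condition = "uncued_CL", perm_id = 1L, error_kind = "none",
               swap_pair = NULL, cyclic_dir = NULL, obj_guess = rep(FALSE, 3),
               guess_col = rep(FALSE, 3), guess_loc = rep(FALSE, 3))
  id <- structure(base, class = "wr_latent")
  expect_equal(latent_to_assignment(id),
               list(colour_src = 1:3, location_src = 1:3))
  sw <- id; sw$error_kind <- "swap"; sw$swap_pair <- c(1L, 2L)
  expect_equal(latent_to_assignment(sw),
               list(colour_src = c(2L, 1L, 3L), location_src = 1:3))
  swg <- sw; swg$guess_col <- c(TRUE, FALSE, FALSE)
  expect_equal(latent_to_assignment(swg),
               list(colour_src = c(0L, 1L, 3L), location_src = 1:3))
})

test_that("swaps are involutions and cyclic rotations have order three", {
  apply_sigma <- function(l) latent_to_assignment(l)$colour_src
  base <- structure(list(condition = "uncued_CL", perm_id = 1L,
                         error_kind = "swap", swap_pair = c(2L, 3L),
                         cyclic_dir = NULL, obj_guess = rep(FALSE, 3),
                         guess_col = rep(FALSE, 3), guess_loc = rep(FALSE, 3)),
                    class = "wr_latent")
  s <- apply_sigma(base)
  expect_equal(s[s], 1:3)  # applying the same swap twice restores identity
  cyc <- base; cyc$error_kind <- "cyclic"; cyc$swap_pair <- NULL; cyc$cyclic_dir <- 1L
  r <- apply_sigma(cyc)
  expect_equal(r[r[r]], 1:3)  # three rotations restore identity
  expect_false(all(r[r] == 1:3))
})

test_that("emission hits targets in the noise-free limit and respects cues", {
  set.seed(3)
  st <- fixed_stimuli()
  sharp <- model_params(kappa_colour = 1e8, kappa_location = 1e8)
  asg <- list(colour_src = 1:3, location_src = 1:3)
  r <- emit_responses(st, asg, 1:3, sharp, "uncued_CL")
  expect_equal(as.numeric(r[1, 1:3]), as.numeric(st[1, 1:3]), tolerance = 0.01)
  expect_equal(as.numeric(r[1, 4:6]), as.numeric(st[1, 4:6]), tolerance = 0.01)
  # cued by location: reported locations equal the original features exactly
  perm <- c(2L, 3L, 1L)
  p <- model_params()
  rc <- emit_responses(st, asg, perm, p, "cued_by_location")
  expect_identical(as.numeric(rc[1, paste0("resp_loc_", 1:3)]),
                   as.numeric(st[1, paste0("stim_loc_", perm)]))
  expect_identical(as.integer(rc[1, paste0("cue_sel_", 1:3)]), perm)
})

test_that("guessed features are uniform on the circle", {
  set.seed(4)
  st <- fixed_stimuli()
  asg <- list(colour_src = c(0L, 0L, 0L), location_src = 1:3)
  draws <- replicate(4000, emit_responses(st, asg, 1:3, model_params(),
                                          "uncued_CL")$resp_col_1)
  ks <- suppressWarnings(ks.test(draws, "punif", 0, 360))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated datasets are reproducible and carry correct ground truth", {
  des <- make_design(2, 15, conditions = c("uncued_CL", "cued_by_colour"),
                     seed = 5)
  p <- model_params(kappa_colour = 1e8, kappa_location = 1e8)
  d <- simulate_dataset(des, p, seed = 6)
  # no errors, huge kappa: every uncued response matches its object exactly
  unc <- d[d$condition == "uncued_CL", ]
  for (i in seq_len(nrow(unc))) {
    perm <- permutations3()[unc$truth_perm[i], ]
    expect_equal(as.numeric(unc[i, paste0("resp_col_", 1:3)]),
                 as.numeric(unc[i, paste0("stim_col_", perm)]),
                 tolerance = 1e-4)
  }
  expect_identical(simulate_dataset(des, p, seed = 6), d)
  expect_false(identical(simulate_dataset(des, p, seed = 7), d))
})

test_that("ground-truth swap counts match the generating rate", {
  des <- make_design(1, 5000, conditions = "uncued_LC", seed = 8)
  d <- simulate_dataset(des, model_params(p_swap = 0.1), seed = 9)
  n_swap <- sum(d$truth_error == "swap")
  se <- sqrt(5000 * 0.1 * 0.9)
  expect_lt(abs(n_swap - 500), 3 * se)
})
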