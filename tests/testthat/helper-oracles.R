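# Test-side helpers: fixtures built in code and independently coded
# brute-force oracles.  The oracle below enumerates the latent support
# with plain nested loops and its own von Mises density, sharing no code
# with the package implementation.

fixed_stimuli <- function() {
  tibble::tibble(
    stim_col_1 = 10, stim_col_2 = 130, stim_col_3 = 250,
    stim_loc_1 = 35, stim_loc_2 = 155, stim_loc_3 = 275
  )
}

rich_params <- function() {
  model_params(
    kappa_colour = 8, kappa_location = 12,
    p_swap = 0.12, p_cyclic_swap = 0.05,
    g_feature = 0.1, g_object = 0.06,
    g_feat_swap_non = 0.08, g_feat_swap_swp = 0.25,
    g_obj_swap_non = 0.05, g_obj_swap_swp = 0.18,
    g_feat_cyclic = 0.1, g_obj_cyclic = 0.07,
    order_weights = c(0.3, 0.2, 0.15, 0.15, 0.1, 0.1)
  )
}

random_params <- function() {
  repeat {
    ps <- stats::runif(1, 0, 0.5)
    pc <- stats::runif(1, 0, 0.3)
    if (ps + pc < 1) break
  }
  w <- stats::rgamma(6, 1)
  model_params(
    kappa_colour = stats::runif(1, 1, 30),
    kappa_location = stats::runif(1, 1, 30),
    p_swap = ps, p_cyclic_swap = pc,
    g_feature = stats::runif(1, 0, 0.4), g_object = stats::runif(1, 0, 0.4),
    g_feat_swap_non = stats::runif(1, 0, 0.5),
    g_feat_swap_swp = stats::runif(1, 0, 0.5),
    g_obj_swap_non = stats::runif(1, 0, 0.5),
    g_obj_swap_swp = stats::runif(1, 0, 0.5),
    g_feat_cyclic = stats::runif(1, 0, 0.5),
    g_obj_cyclic = stats::runif(1, 0, 0.5),
    order_weights = w / sum(w)
  )
}

random_trial <- function(condition = "uncued_CL") {
  tr <- tibble::tibble(
    subject = 1L, trial = 1L, condition = condition,
    stim_col_1 = stats::runif(1, 0, 360), stim_col_2 = stats::runif(1, 0, 360),
    stim_col_3 = stats::runif(1, 0, 360),
    stim_loc_1 = stats::runif(1, 0, 360), stim_loc_2 = stats::runif(1, 0, 360),
    stim_loc_3 = stats::runif(1, 0, 360),
    resp_col_1 = stats::runif(1, 0, 360), resp_col_2 = stats::runif(1, 0, 360),
    resp_col_3 = stats::runif(1, 0, 360),
    resp_loc_1 = stats::runif(1, 0, 360), resp_loc_2 = stats::runif(1, 0, 360),
    resp_loc_3 = stats::runif(1, 0, 360),
    cue_sel_1 = NA_integer_, cue_sel_2 = NA_integer_, cue_sel_3 = NA_integer_
  )
  if (condition %in% c("cued_by_colour", "cued_by_location")) {
    perm <- sample.int(3L)
    tr$cue_sel_1 <- perm[1]; tr$cue_sel_2 <- perm[2]; tr$cue_sel_3 <- perm[3]
    # the cue dimension is copied exactly from the selected features
    if (condition == "cued_by_colour") {
      for (s in 1:3) tr[[paste0("resp_col_", s)]] <- tr[[paste0("stim_col_", perm[s])]]
    } else {
      for (s in 1:3) tr[[paste0("resp_loc_", s)]] <- tr[[paste0("stim_loc_", perm[s])]]
    }
  }
  tr
}

# independent quadrature oracle for the JZS t-test: Cauchy prior on the
# effect size combined with the noncentral-t likelihood (a different route
# than the package's g-representation)
oracle_bf_t <- function(t, N, nu, r) {
  num <- integrate(function(d) {
    suppressWarnings(dt(t, nu, ncp = d * sqrt(N))) * dcauchy(d, 0, r)
  }, -Inf, Inf, rel.tol = 1e-10)$value
  num / dt(t, nu)
}

# all 6 permutations of 1:3 found by filtering the 27 index triples
all_perms3 <- function() {
  g <- as.matrix(expand.grid(a = 1:3, b = 1:3, c = 1:3))
  g[apply(g, 1, function(r) length(unique(r)) == 3L), , drop = FALSE]
}

# brute-force marginal likelihood by naive enumeration
naive_trial_loglik <- function(trial, params) {
  dvm <- function(x, mu, k) {
    exp(k * cos((x - mu) * pi / 180)) / (2 * pi * besselI(k, 0, expon.scaled = TRUE) * exp(k))
  }
  u <- 1 / (2 * pi)
  sc <- as.numeric(trial[paste0("stim_col_", 1:3)])
  sl <- as.numeric(trial[paste0("stim_loc_", 1:3)])
  rc <- as.numeric(trial[paste0("resp_col_", 1:3)])
  rl <- as.numeric(trial[paste0("resp_loc_", 1:3)])
  cond <- trial$condition
  cued <- cond %in% c("cued_by_colour", "cued_by_location")

  errors <- list(
    list(kind = "none", sigma = 1:3, prior = 1 - params$p_swap - params$p_cyclic_swap,
         swapped = c(FALSE, FALSE, FALSE)),
    list(kind = "swap", sigma = c(2, 1, 3), prior = params$p_swap / 3,
         swapped = c(TRUE, TRUE, FALSE)),
    list(kind = "swap", sigma = c(3, 2, 1), prior = params$p_swap / 3,
         swapped = c(TRUE, FALSE, TRUE)),
    list(kind = "swap", sigma = c(1, 3, 2), prior = params$p_swap / 3,
         swapped = c(FALSE, TRUE, TRUE)),
    list(kind = "cyclic", sigma = c(2, 3, 1), prior = params$p_cyclic_swap / 2,
         swapped = c(FALSE, FALSE, FALSE)),
    list(kind = "cyclic", sigma = c(3, 1, 2), prior = params$p_cyclic_swap / 2,
         swapped = c(FALSE, FALSE, FALSE))
  )
  rates <- function(kind, swapped) {
    if (kind == "none") c(params$g_feature, params$g_object)
    else if (kind == "cyclic") c(params$g_feat_cyclic, params$g_obj_cyclic)
    else if (swapped) c(params$g_feat_swap_swp, params$g_obj_swap_swp)
    else c(params$g_feat_swap_non, params$g_obj_swap_non)
  }

  perms <- if (cued) {
    matrix(as.integer(trial[paste0("cue_sel_", 1:3)]), 1)
  } else {
    all_perms3()
  }
  lik <- 0
  for (ip in seq_len(nrow(perms))) {
    perm <- perms[ip, ]
    wp <- if (cued) 1 else {
      # match the permutation against lexicographic order weights
      lex <- all_perms3()[order(all_perms3()[, 1], all_perms3()[, 2]), ]
      params$order_weights[which(apply(lex, 1, function(r) all(r == perm)))]
    }
    for (er in errors) {
      if (er$prior == 0) next
      if (!cued) {
        # guess states per object: obj guess, or independent feature flags
        for (s1 in 1:5) for (s2 in 1:5) for (s3 in 1:5) {
          stt <- c(s1, s2, s3)
          pr <- er$prior * wp
          dens <- 1
          for (o in 1:3) {
            gg <- rates(er$kind, er$swapped[o])
            gf <- gg[1]; go <- gg[2]
            st <- stt[o]
            og <- st == 1
            fc <- st %in% c(1, 2, 3)  # colour flag set in states 1,2,3
            fl <- st %in% c(1, 2, 4)  # location flag set in states 1,2,4
            pr <- pr * if (og) go else
              (1 - go) * (if (fc) gf else 1 - gf) * (if (fl) gf else 1 - gf)
            s <- which(perm == o)  # slot reporting object o
            dens <- dens * (if (fc) u else dvm(rc[s], sc[er$sigma[o]], params$kappa_colour))
            dens <- dens * (if (fl) u else dvm(rl[s], sl[o], params$kappa_location))
          }
          lik <- lik + pr * dens
        }
      } else {
        for (s1 in 1:3) for (s2 in 1:3) for (s3 in 1:3) {
          stt <- c(s1, s2, s3)
          pr <- er$prior
          dens <- 1
          for (s in 1:3) {
            o <- perm[s]
            gg <- rates(er$kind, er$swapped[o])
            gf <- gg[1]; go <- gg[2]
            st <- stt[o]
            pr <- pr * c(go, (1 - go) * gf, (1 - go) * (1 - gf))[st]
            guessed <- st < 3
            dens <- dens * if (guessed) u else if (cond == "cued_by_location") {
              dvm(rc[s], sc[er$sigma[o]], params$kappa_colour)
            } else {
              dvm(rl[s], sl[er$sigma[o]], params$kappa_location)
            }
          }
          lik <- lik + pr * dens
        }
      }
    }
  }
  log(lik)
}
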