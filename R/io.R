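# Tabular trial format, run configuration, and fit serialization.
#
# Trial tables travel as plain CSV with a versioned header comment that
# embeds the package version, the generating seed and a config hash, so
# any artifact can be regenerated exactly.

TRIAL_FORMAT_VERSION <- 1L

ANGLE_COLS <- c(paste0("stim_col_", 1:3), paste0("stim_loc_", 1:3),
                paste0("resp_col_", 1:3), paste0("resp_loc_", 1:3))

fmt_num <- function(x, digits = 6) {
  out <- ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
  out
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

#' Write a trial table
#'
#' Writes the canonical CSV representation: a versioned header comment
#' carrying package version, seed and config hash, then one row per trial.
#' Angles are written with six decimals so that write/read/write round
#' trips are byte-identical.
#'
#' @param data Trial table.
#' @param path Output file.
#' @param seed Seed recorded in the header (defaults to the table's
#'   `seed` attribute, if any).
#' @param config Optional configuration list; its hash is recorded.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path, seed = attr(data, "seed"),
                         config = attr(data, "config")) {
  data <- tibble::as_tibble(data)
  for (cl in intersect(ANGLE_COLS, names(data))) {
    data[[cl]] <- fmt_num(data[[cl]])
  }
  header <- c(
    sprintf("# wholereport trial table v%d", TRIAL_FORMAT_VERSION),
    sprintf("# package_version=%s seed=%s config_hash=%s",
            as.character(utils::packageVersion("wholereport")),
            if (is.null(seed)) "NA" else as.character(seed),
            if (is.null(config)) "NA" else config_hash(config))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(data, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trial table
#'
#' Reads and validates the CSV trial format: angles must lie in
#' `[0, 360)`, conditions must come from the closed vocabulary, and cued
#' rows must carry a valid cue-selection permutation.  Schema violations
#' report the offending row and column.
#'
#' @param path CSV file written by [write_trials()] (or matching its
#'   schema).
#' @return A tibble of trials, with header metadata in the `meta`
#'   attribute.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("read_trials(): no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 2L)
  data <- suppressWarnings(readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(condition = "c", presentation = "c",
                            pres_order = "c", .default = readr::col_guess())
  ))
  if (!nrow(data)) {
    warning("read_trials(): empty trial table: ", path, call. = FALSE)
    return(data)
  }
  check_condition(data$condition)
  for (cl in intersect(c(paste0("cue_sel_", 1:3), "subject", "trial",
                         "truth_perm", "truth_cyclic_dir"), names(data))) {
    if (is.numeric(data[[cl]])) data[[cl]] <- as.integer(data[[cl]])
  }
  for (cl in intersect(ANGLE_COLS, names(data))) {
    bad <- which(!is.na(data[[cl]]) &
                   (data[[cl]] < 0 | data[[cl]] >= 360 | !is.finite(data[[cl]])))
    if (length(bad)) {
      stop(sprintf("read_trials(): angle out of [0, 360) at row %d, column %s",
                   bad[1], cl), call. = FALSE)
    }
  }
  cued_rows <- which(is_cued(data$condition))
  if (length(cued_rows)) {
    cue <- as.matrix(data[cued_rows, paste0("cue_sel_", 1:3)])
    bad <- cued_rows[apply(cue, 1L, function(r) any(is.na(r)) || any(sort(r) != 1:3))]
    if (length(bad)) {
      stop(sprintf("read_trials(): invalid cue_selection at row %d, columns cue_sel_1..3",
                   bad[1]), call. = FALSE)
    }
  }
  attr(data, "meta") <- grep("^#", first, value = TRUE)
  data
}

# -- run configuration ------------------------------------------------------

CONFIG_KEYS <- c("geometry", "design", "params", "priors", "mcmc",
                 "variant", "seed", "out")

#' Default run configuration
#'
#' The configuration block consumed by the command-line interface and
#' [run_recovery()]: task geometry, design counts, true generating
#' parameters (for simulation), hyperpriors, MCMC settings and variant.
#'
#' @return A named list; see the fields of [task_geometry()],
#'   [make_design()], [model_params()], [population_prior()] and
#'   [mcmc_config()].
#' @export
default_config <- function() {
  list(
    geometry = list(circle_radius_dva = 6.5, dot_radius_dva = 0.7,
                    min_dot_distance_dva = 1.4, min_hue_sep_deg = 5),
    design = list(n_subjects = 12, trials_per_condition = 120,
                  conditions = "uncued_CL", presentation = "simultaneous"),
    params = list(kappa_colour = 10, kappa_location = 15, p_swap = 0.06,
                  p_cyclic_swap = 0.01, g_feature = 0.12, g_object = 0.05,
                  g_feat_swap_non = 0.1, g_feat_swap_swp = 0.2,
                  g_obj_swap_non = 0.05, g_obj_swap_swp = 0.15,
                  g_feat_cyclic = 0.1, g_obj_cyclic = 0.05),
    priors = list(mean_loc = 0, mean_scale = 1.5, sd_scale = 1, kappa_init = 5),
    mcmc = list(n_adapt = 5000, n_iter = 10000, n_chains = 4, thin = 1),
    variant = "full",
    seed = 1
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown top-level keys are rejected; known blocks are merged over
#' [default_config()].
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown)) {
    stop("read_config(): unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- default_config()
  for (k in names(cfg)) {
    if (is.list(base[[k]]) && is.list(cfg[[k]])) {
      unknown <- setdiff(names(cfg[[k]]), names(base[[k]]))
      if (length(unknown)) {
        stop("read_config(): unknown key(s) in ", k, ": ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      base[[k]][names(cfg[[k]])] <- cfg[[k]]
    } else {
      base[[k]] <- cfg[[k]]
    }
  }
  base
}

config_params <- function(cfg) do.call(model_params, cfg$params)

# -- fit serialization ------------------------------------------------------

#' Serialize a fit to a directory
#'
#' Writes `draws_subject.csv` (long: chain, draw, group, subject,
#' parameter, value — natural scale, including order weights),
#' `draws_population.csv` (transformed-scale population mean and SD) and
#' `meta.json`.
#'
#' @param fit A [fit_hierarchical()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nk <- length(fit$chain)
  subj_long <- purrr::map_dfr(fit$egroups, function(g) {
    arr <- fit$draws$subj[[g]]
    ord <- fit$draws$order[[g]]
    purrr::map_dfr(seq_along(fit$subjects), function(s) {
      tibble::tibble(
        chain = rep(fit$chain, 18L),
        draw = rep(seq_len(nk), 18L),
        group = g,
        subject = fit$subjects[s],
        parameter = rep(c(PARAM_NAMES, paste0("order_w", 1:6)), each = nk),
        value = c(arr[, s, ], ord[, s, ])
      )
    })
  })
  readr::write_csv(subj_long, file.path(dir, "draws_subject.csv"))
  pop_long <- purrr::map_dfr(fit$egroups, function(g) {
    tibble::tibble(
      chain = rep(fit$chain, 12L),
      draw = rep(seq_len(nk), 12L),
      group = g,
      parameter = rep(PARAM_NAMES, each = nk),
      pop_mean = c(fit$draws$pop_mean[[g]]),
      pop_sd = c(fit$draws$pop_sd[[g]])
    )
  })
  readr::write_csv(pop_long, file.path(dir, "draws_population.csv"))
  meta <- list(
    package_version = as.character(utils::packageVersion("wholereport")),
    variant = fit$spec$variant,
    group_map = as.list(fit$spec$group_map),
    frozen = fit$spec$frozen,
    subjects = fit$subjects,
    egroups = fit$egroups,
    free_idx = fit$free_idx,
    mcmc = unclass(fit$mcmc),
    prior = unclass(fit$prior),
    acc_rate = unname(fit$acc_rate),
    n_trials = fit$n_trials,
    runtime_s = fit$runtime_s
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a serialized fit
#'
#' @param dir Directory written by [write_fit()].
#' @return A `wr_fit` object.
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  subj_long <- readr::read_csv(file.path(dir, "draws_subject.csv"),
                               show_col_types = FALSE, progress = FALSE)
  pop_long <- readr::read_csv(file.path(dir, "draws_population.csv"),
                              show_col_types = FALSE, progress = FALSE)
  subjects <- meta$subjects
  egroups <- meta$egroups
  nk <- max(subj_long$draw)
  draws <- list(
    subj = lapply(setNames(egroups, egroups), function(g)
      array(NA_real_, c(nk, length(subjects), 12))),
    order = lapply(setNames(egroups, egroups), function(g)
      array(NA_real_, c(nk, length(subjects), 6))),
    pop_mean = lapply(setNames(egroups, egroups), function(g)
      matrix(NA_real_, nk, 12)),
    pop_sd = lapply(setNames(egroups, egroups), function(g)
      matrix(NA_real_, nk, 12))
  )
  for (g in egroups) {
    gl <- subj_long[subj_long$group == g, ]
    for (s in seq_along(subjects)) {
      sl <- gl[gl$subject == subjects[s], ]
      for (p in seq_len(12)) {
        draws$subj[[g]][, s, p] <- sl$value[sl$parameter == PARAM_NAMES[p]]
      }
      for (p in seq_len(6)) {
        draws$order[[g]][, s, p] <-
          sl$value[sl$parameter == paste0("order_w", p)]
      }
    }
    pl <- pop_long[pop_long$group == g, ]
    for (p in seq_len(12)) {
      draws$pop_mean[[g]][, p] <- pl$pop_mean[pl$parameter == PARAM_NAMES[p]]
      draws$pop_sd[[g]][, p] <- pl$pop_sd[pl$parameter == PARAM_NAMES[p]]
    }
  }
  spec <- structure(list(variant = meta$variant,
                         group_map = unlist(meta$group_map),
                         frozen = meta$frozen %||% character(0)),
                    class = "wr_model_spec")
  chain <- subj_long$chain[subj_long$group == egroups[1] &
                             subj_long$subject == subjects[1] &
                             subj_long$parameter == PARAM_NAMES[1]]
  structure(list(
    draws = draws, chain = chain, subjects = subjects, egroups = egroups,
    free_idx = meta$free_idx, spec = spec,
    prior = do.call(population_prior, meta$prior[c("mean_loc", "mean_scale",
                                                   "sd_scale", "kappa_init")]),
    mcmc = do.call(mcmc_config, meta$mcmc[c("n_adapt", "n_iter", "n_chains",
                                            "thin", "seed")]),
    acc_rate = meta$acc_rate, n_trials = meta$n_trials,
    runtime_s = meta$runtime_s
  ), class = "wr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
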