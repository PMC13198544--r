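# Stimulus arrays and experiment designs.
#
# Three coloured dots sit on an imaginary circle of radius 6.5 degrees of
# visual angle (dva) around fixation; dot centres may not come closer than
# 1.4 dva, and the three hues must be at least 5 degrees apart on the colour
# wheel.  Both colours and dot positions are otherwise uniform on [0, 360).

#' Task geometry
#'
#' Container for the display geometry and the separation constraints used
#' when sampling stimulus arrays.
#'
#' @param circle_radius_dva Radius of the imaginary stimulus circle, in
#'   degrees of visual angle (default 6.5).
#' @param dot_radius_dva Radius of each dot, dva (default 0.7).
#' @param min_dot_distance_dva Minimum distance between dot centres, dva
#'   (default 1.4).
#' @param min_hue_sep_deg Minimum angular separation between any two hues on
#'   the colour wheel, degrees (default 5).
#' @return An object of class `wr_geometry`.
#' @export
task_geometry <- function(circle_radius_dva = 6.5,
                          dot_radius_dva = 0.7,
                          min_dot_distance_dva = 1.4,
                          min_hue_sep_deg = 5) {
  g <- list(circle_radius_dva = circle_radius_dva,
            dot_radius_dva = dot_radius_dva,
            min_dot_distance_dva = min_dot_distance_dva,
            min_hue_sep_deg = min_hue_sep_deg)
  if (any(vapply(g, function(x) !is.numeric(x) || length(x) != 1L || x < 0, TRUE))) {
    stop("task_geometry(): all fields must be non-negative scalars", call. = FALSE)
  }
  if (min_dot_distance_dva > 2 * circle_radius_dva) {
    stop("task_geometry(): min_dot_distance_dva exceeds the circle diameter",
         call. = FALSE)
  }
  structure(g, class = "wr_geometry")
}

#' Minimum location separation as a central angle
#'
#' Converts the minimum dot-centre distance (a chord length in visual-angle
#' units) into the corresponding central angle on the stimulus circle:
#' `2 * asin(d / (2 r))`, in degrees.
#'
#' @param geometry A [task_geometry()] object.
#' @return Central angle in degrees.
#' @export
min_location_sep_central_angle <- function(geometry = task_geometry()) {
  ratio <- geometry$min_dot_distance_dva / (2 * geometry$circle_radius_dva)
  if (ratio > 1) stop("impossible geometry: chord longer than diameter", call. = FALSE)
  rad2deg(2 * asin(ratio))
}

#' Sample one stimulus array
#'
#' Draws three colour hues and three dot locations uniformly on `[0, 360)`
#' by rejection until the pairwise hue separation and dot-centre distance
#' constraints are satisfied.
#'
#' @param geometry A [task_geometry()] object.
#' @param presentation `"simultaneous"` or `"sequential"`.
#' @param max_attempts Rejection cap before the constraints are declared
#'   infeasible.
#' @return A one-row tibble with columns `stim_col_1..3`, `stim_loc_1..3`,
#'   `presentation` and, for sequential presentation, `pres_order` (the
#'   object presentation order as a string such as `"213"`).
#' @export
sample_stimulus_array <- function(geometry = task_geometry(),
                                  presentation = c("simultaneous", "sequential"),
                                  max_attempts = 10000L) {
  presentation <- match.arg(presentation)
  cols <- sample_separated_angles(geometry$min_hue_sep_deg, max_attempts, "colour")
  loc_sep <- min_location_sep_central_angle(geometry)
  locs <- sample_separated_angles(loc_sep, max_attempts, "location")
  ord <- if (presentation == "sequential") {
    paste(sample.int(3L), collapse = "")
  } else NA_character_
  tibble::tibble(
    stim_col_1 = cols[1L], stim_col_2 = cols[2L], stim_col_3 = cols[3L],
    stim_loc_1 = locs[1L], stim_loc_2 = locs[2L], stim_loc_3 = locs[3L],
    presentation = presentation, pres_order = ord
  )
}

# uniform triples on the circle with a minimum pairwise circular separation
sample_separated_angles <- function(min_sep_deg, max_attempts, what) {
  if (3 * min_sep_deg > 360) {
    stop("infeasible ", what, " constraint: three angles cannot all be ",
         min_sep_deg, " degrees apart", call. = FALSE)
  }
  for (i in seq_len(max_attempts)) {
    a <- stats::runif(3, 0, 360)
    d <- abs(circ_dist(rep(a, each = 3), rep(a, times = 3)))
    if (min(d[-c(1, 5, 9)]) >= min_sep_deg) return(a)
  }
  stop("infeasible ", what, " constraint: no valid triple in ",
       max_attempts, " attempts", call. = FALSE)
}

#' Build an experiment design
#'
#' Expands a design specification into one trial shell per row: subject,
#' condition, and a freshly sampled stimulus array.  Fully reproducible
#' given `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_condition Trials per subject in each condition.
#' @param conditions Which probe conditions to include (default all four).
#' @param presentation `"simultaneous"` or `"sequential"`.
#' @param geometry A [task_geometry()] object.
#' @param seed Integer seed.
#' @return A tibble of trial shells with columns `subject`, `trial`,
#'   `condition`, the stimulus columns of [sample_stimulus_array()].
#' @export
make_design <- function(n_subjects,
                        trials_per_condition,
                        conditions = CONDITIONS,
                        presentation = c("simultaneous", "sequential"),
                        geometry = task_geometry(),
                        seed = 1L) {
  presentation <- match.arg(presentation)
  check_condition(conditions)
  if (n_subjects < 1 || trials_per_condition < 1) {
    stop("make_design(): counts must be positive", call. = FALSE)
  }
  set.seed(seed)
  shells <- tidyr::expand_grid(
    subject = seq_len(n_subjects),
    condition = conditions,
    rep = seq_len(trials_per_condition)
  )
  arrays <- purrr::map(seq_len(nrow(shells)),
                       ~sample_stimulus_array(geometry, presentation))
  dplyr::bind_cols(
    dplyr::select(shells, -"rep"),
    dplyr::bind_rows(arrays)
  ) |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(trial = dplyr::row_number(), .after = "subject") |>
    dplyr::ungroup()
}
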