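# The 13 free parameters of the generative model, per parameter group.
#
# Two von Mises concentrations (colour, location), the swap / cyclic-swap
# mixture weights, six guessing probabilities conditioned on the error kind
# and on whether the object took part in the swap, and a categorical
# distribution over the six report orders (counted as one parameter).

# fixed order of the 12 scalar parameters; order_weights is parameter 13
PARAM_NAMES <- c(
  "kappa_colour", "kappa_location",
  "p_swap", "p_cyclic_swap",
  "g_feature", "g_object",
  "g_feat_swap_non", "g_feat_swap_swp",
  "g_obj_swap_non", "g_obj_swap_swp",
  "g_feat_cyclic", "g_obj_cyclic"
)

#' Model parameters for one parameter group
#'
#' Bundles the 13 free parameters of the generative model: the two von
#' Mises concentrations, the swap/cyclic mixture probabilities, the six
#' guessing probabilities, and the categorical distribution over the six
#' report orders (`order_weights`, one parameter on the 6-simplex).
#'
#' @param kappa_colour,kappa_location von Mises concentrations (> 0) for
#'   colour and location reports.
#' @param p_swap Probability of a symmetric pairwise swap on a trial.
#' @param p_cyclic_swap Probability of a three-way cyclic swap.
#'   `p_swap + p_cyclic_swap` must not exceed 1.
#' @param g_feature,g_object Baseline feature / whole-object guessing
#'   probabilities on trials without a swap.
#' @param g_feat_swap_non,g_obj_swap_non Feature / object guessing for the
#'   object *not* taking part in a swap, on swap trials.
#' @param g_feat_swap_swp,g_obj_swap_swp Feature / object guessing for the
#'   two objects taking part in the swap.  These two parameters generate
#'   asymmetric misattribution.
#' @param g_feat_cyclic,g_obj_cyclic Guessing probabilities on cyclic-swap
#'   trials.
#' @param order_weights Probability of each of the six report orders (rows
#'   of [permutations3()]); normalised to sum to 1.
#' @return An object of class `wr_params` (a named list).
#' @export
model_params <- function(kappa_colour = 10, kappa_location = 15,
                         p_swap = 0, p_cyclic_swap = 0,
                         g_feature = 0, g_object = 0,
                         g_feat_swap_non = 0, g_feat_swap_swp = 0,
                         g_obj_swap_non = 0, g_obj_swap_swp = 0,
                         g_feat_cyclic = 0, g_obj_cyclic = 0,
                         order_weights = rep(1 / 6, 6)) {
  p <- list(kappa_colour = kappa_colour, kappa_location = kappa_location,
            p_swap = p_swap, p_cyclic_swap = p_cyclic_swap,
            g_feature = g_feature, g_object = g_object,
            g_feat_swap_non = g_feat_swap_non, g_feat_swap_swp = g_feat_swap_swp,
            g_obj_swap_non = g_obj_swap_non, g_obj_swap_swp = g_obj_swap_swp,
            g_feat_cyclic = g_feat_cyclic, g_obj_cyclic = g_obj_cyclic,
            order_weights = order_weights)
  validate_params(p)
  p$order_weights <- order_weights / sum(order_weights)
  structure(p, class = "wr_params")
}

validate_params <- function(p) {
  if (p$kappa_colour <= 0 || p$kappa_location <= 0) {
    stop("model_params(): concentrations must be positive", call. = FALSE)
  }
  probs <- unlist(p[PARAM_NAMES[3:12]])
  if (any(probs < 0 | probs > 1)) {
    stop("model_params(): probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$p_swap + p$p_cyclic_swap > 1 + 1e-12) {
    stop("model_params(): p_swap + p_cyclic_swap must not exceed 1", call. = FALSE)
  }
  if (length(p$order_weights) != 6L || any(p$order_weights < 0) ||
      sum(p$order_weights) <= 0) {
    stop("model_params(): order_weights must be 6 non-negative weights",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.wr_params <- function(x, ...) {
  cat("<wr_params>\n")
  for (nm in PARAM_NAMES) cat(sprintf("  %-16s %.4g\n", nm, x[[nm]]))
  cat("  order_weights    ", paste(sprintf("%.3f", x$order_weights), collapse = " "), "\n")
  invisible(x)
}

# as a plain numeric vector (12 scalars), used by the C++ likelihood
params_vector <- function(p) {
  vapply(PARAM_NAMES, function(nm) p[[nm]], numeric(1))
}

# guessing rates applying to object `o` given the error configuration
guess_rates <- function(p, error_kind, in_swap) {
  if (error_kind == "none") {
    c(gf = p$g_feature, go = p$g_object)
  } else if (error_kind == "cyclic") {
    c(gf = p$g_feat_cyclic, go = p$g_obj_cyclic)
  } else if (in_swap) {
    c(gf = p$g_feat_swap_swp, go = p$g_obj_swap_swp)
  } else {
    c(gf = p$g_feat_swap_non, go = p$g_obj_swap_non)
  }
}

# Subject parameter sets: named list subject -> named list group -> wr_params.
# A single wr_params (or group -> params list) is recycled to all subjects.
resolve_subject_params <- function(subject_params, subjects, groups) {
  if (inherits(subject_params, "wr_params")) {
    subject_params <- stats::setNames(
      rep(list(subject_params), length(groups)), groups)
  }
  if (!is.null(names(subject_params)) &&
      all(names(subject_params) %in% PARAM_GROUPS)) {
    subject_params <- stats::setNames(
      rep(list(subject_params), length(subjects)), as.character(subjects))
  }
  out <- lapply(as.character(subjects), function(s) {
    sp <- subject_params[[s]]
    if (is.null(sp)) stop("no parameters for subject ", s, call. = FALSE)
    if (inherits(sp, "wr_params")) {
      sp <- stats::setNames(rep(list(sp), length(groups)), groups)
    }
    missing <- setdiff(groups, names(sp))
    if (length(missing)) {
      stop("subject ", s, ": no parameters for group(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    sp
  })
  stats::setNames(out, as.character(subjects))
}
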