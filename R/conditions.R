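# Shared enumerations: probe conditions, parameter groups, and the six
# report-order permutations of three objects.

#' Probe conditions
#'
#' The four ways a trial can be probed: cued by colour, cued by location, or
#' uncued whole report with colour reproduced first (`uncued_CL`) or location
#' first (`uncued_LC`).
#'
#' @format Character vector of the four condition labels.
#' @export
CONDITIONS <- c("cued_by_colour", "cued_by_location", "uncued_CL", "uncued_LC")

#' Map a probe condition to its parameter group
#'
#' Model parameters are allowed to vary between cued trials and the two
#' uncued conditions; both cued probes share one parameter group.
#'
#' @param condition Character vector of condition labels.
#' @return Character vector of `"cued"`, `"uncued_CL"` or `"uncued_LC"`.
#' @export
param_group <- function(condition) {
  check_condition(condition)
  ifelse(condition %in% c("cued_by_colour", "cued_by_location"), "cued", condition)
}

#' @rdname param_group
#' @export
PARAM_GROUPS <- c("cued", "uncued_CL", "uncued_LC")

check_condition <- function(condition) {
  bad <- setdiff(unique(condition), CONDITIONS)
  if (length(bad)) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(CONDITIONS, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(condition)
}

is_cued <- function(condition) {
  check_condition(condition)
  condition %in% c("cued_by_colour", "cued_by_location")
}

# dimension the participant has to recall from memory on cued trials
report_dimension <- function(condition) {
  check_condition(condition)
  dplyr::case_when(
    condition == "cued_by_colour"   ~ "location",
    condition == "cued_by_location" ~ "colour",
    TRUE                            ~ "both"
  )
}

# The six permutations of three objects, lexicographic; row p gives the
# object reported in slots 1..3 under permutation id p.
PERMS <- rbind(
  c(1L, 2L, 3L),
  c(1L, 3L, 2L),
  c(2L, 1L, 3L),
  c(2L, 3L, 1L),
  c(3L, 1L, 2L),
  c(3L, 2L, 1L)
)

#' Permutations of the three report slots
#'
#' Returns the six possible assignments of memorised objects to report
#' slots, in lexicographic order.  Row `p` is the object reported in slots
#' 1 to 3 under permutation id `p`; the order-weight vector of the model is
#' indexed the same way.
#'
#' @return A 6 x 3 integer matrix.
#' @export
permutations3 <- function() PERMS

perm_id <- function(mapping) {
  stopifnot(length(mapping) == 3L)
  id <- which(apply(PERMS, 1L, function(r) all(r == mapping)))
  if (!length(id)) stop("not a permutation of 1:3", call. = FALSE)
  id
}

perm_inverse <- function(mapping) order(mapping)

# unordered swap pairs and cyclic rotations, fixed enumeration order
SWAP_PAIRS <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
CYCLES <- rbind(c(2L, 3L, 1L), c(3L, 1L, 2L))  # sigma[o] = colour source of object o

# mapping sigma on the swapped dimension for an error configuration
error_sigma <- function(error_kind, swap_pair = NULL, cyclic_dir = NULL) {
  sigma <- 1:3
  if (error_kind == "swap") {
    sigma[swap_pair[1L]] <- swap_pair[2L]
    sigma[swap_pair[2L]] <- swap_pair[1L]
  } else if (error_kind == "cyclic") {
    sigma <- CYCLES[cyclic_dir, ]
  }
  sigma
}
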