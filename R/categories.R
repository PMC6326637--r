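#' The facility workload-category ladder
#'
#' Healthcare facilities are classified into an ordered ladder of eleven
#' workload categories, from community-based health planning and services
#' compounds (CHPS) at the bottom to established teaching hospitals (EsTH) at
#' the top:
#' CHPS < HCA < HCB < PolyC < PHA < PHB < PHC < PHD < RH < EmTH < EsTH.
#' A facility whose workload grows sufficiently moves one rung up the ladder;
#' downward moves and rung-skipping do not occur in the model, and EsTH is
#' absorbing.
#'
#' @return Character vector of the 11 category codes in ladder (rank) order.
#' @export
#' @examples
#' facility_categories()
facility_categories <- function() {
  c("CHPS", "HCA", "HCB", "PolyC", "PHA", "PHB", "PHC", "PHD",
    "RH", "EmTH", "EsTH")
}

#' Rank of a facility category on the workload ladder
#'
#' @param category Character vector of category codes.
#' @return Integer rank, 0 (CHPS) through 10 (EsTH).
#' @export
#' @examples
#' category_rank(c("CHPS", "EsTH"))
category_rank <- function(category) {
  r <- match(category, facility_categories()) - 1L
  if (anyNA(r)) {
    bad <- unique(category[is.na(r)])
    abort(paste0("Unknown facility category: ", paste(bad, collapse = ", "),
                 ". Valid codes: ", paste(facility_categories(), collapse = ", ")))
  }
  r
}

#' Coerce to an ordered factor over the facility ladder
#'
#' @param x Character vector of category codes.
#' @return Ordered factor with levels in ladder order.
#' @export
as_category <- function(x) {
  category_rank(x) # validates
  factor(x, levels = facility_categories(), ordered = TRUE)
}

#' The ten adjacent upward category pairs
#'
#' The only permitted transitions are one rung up the ladder, so exactly ten
#' ordered pairs exist (EsTH has no outgoing pair).
#'
#' @return A tibble with columns `from_category` and `to_category`.
#' @export
#' @examples
#' adjacent_pairs()
adjacent_pairs <- function() {
  cats <- facility_categories()
  tibble(from_category = cats[-11], to_category = cats[-1])
}

#' Round half away from zero
#'
#' Report tables print integers (facility censuses, staff headcounts) and one
#' decimal (annual flows) using conventional half-up rounding, not the
#' round-half-even rule of [base::round()]. Internal state is never rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.5)      # 3, where round(2.5) gives 2
#' round_half_up(16.032, 1)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # strip float dust (e.g. 183.37499999999997) before applying the half-up rule
  sign(x) * floor(round(abs(x) * m, 9) + 0.5) / m
}
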