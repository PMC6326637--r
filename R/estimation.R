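#' Estimate adjacent-upward transition probabilities from a facility panel
#'
#' Pools all observed year-to-year intervals across facilities, years and
#' regions and fits, for each adjacent category pair, the binomial maximum
#' likelihood estimate: `p_hat = n_events / n_at_risk`, where a facility-year
#' is at risk for the pair r -> r+1 if the facility is observed in category r
#' with an observation the following calendar year, and an event is an
#' observation in category r+1 that year. The standard error is the binomial
#' `sqrt(p_hat (1 - p_hat) / n_at_risk)`. Facilities missing a year are
#' censored for the affected intervals; no interpolation is attempted.
#'
#' Downward category moves violate the model's upward-only assumption and are
#' rejected by default (`downward = "error"`); `downward = "drop"` discards
#' the offending intervals instead. Jumps of more than one rung are likewise
#' rejected by default; `jumps = "adjacent"` counts them as a single event for
#' the origin category's adjacent pair.
#'
#' @param panel Facility-category panel: tibble with columns `facility_id`,
#'   `year`, `category`, one record per facility-year, spanning at least two
#'   calendar years.
#' @param downward How to treat downward moves: `"error"` (default) or
#'   `"drop"`.
#' @param jumps How to treat upward jumps of more than one rung: `"error"`
#'   (default) or `"adjacent"`.
#' @return A `hwf_transitions` tibble with columns `from_category`,
#'   `to_category`, `probability`, `standard_error`, `n_at_risk`, `n_events`.
#'   Pairs with no at-risk facility-years get probability 0, standard error 0
#'   and raise a warning. The result is directly usable wherever a transition
#'   table is expected.
#' @export
#' @examples
#' fix <- make_ghana_fixture()
#' panel <- simulate_panel(fix$transitions, n_per_category = 200, years = 5,
#'                         seed = 1)
#' estimate_transitions(panel)
estimate_transitions <- function(panel, downward = c("error", "drop"),
                                 jumps = c("error", "adjacent")) {
  downward <- match.arg(downward)
  jumps <- match.arg(jumps)
  validate_panel(panel)
  if (length(unique(panel$year)) < 2) {
    abort("Panel must span at least 2 calendar years")
  }

  ## vectorised interval extraction: after sorting by (facility, year), an
  ## at-risk interval is any row whose successor is the same facility one
  ## calendar year later; gaps (missing years) censor the interval
  fcode <- match(panel$facility_id, unique(panel$facility_id))
  ord <- order(fcode, panel$year, method = "radix")
  fid <- fcode[ord]
  yr <- panel$year[ord]
  rk <- category_rank(as.character(panel$category))[ord]
  nr <- length(fid)
  adjacent <- which(fid[-nr] == fid[-1] & yr[-1] == yr[-nr] + 1)
  intervals <- tibble(facility_id = panel$facility_id[ord][adjacent],
                      year = yr[adjacent],
                      next_year = yr[adjacent + 1],
                      rank = rk[adjacent],
                      jump = rk[adjacent + 1] - rk[adjacent])

  down <- intervals$jump < 0
  if (any(down)) {
    if (downward == "error") {
      ex <- intervals[which(down)[1], ]
      abort(paste0("Downward category move for facility '", ex$facility_id,
                   "' between ", ex$year, " and ", ex$next_year,
                   "; the model assumes upward-only transitions ",
                   "(use downward = \"drop\" to discard such intervals)"))
    }
    intervals <- intervals[!down, , drop = FALSE]
  }
  big <- intervals$jump > 1
  if (any(big)) {
    if (jumps == "error") {
      ex <- intervals[which(big)[1], ]
      abort(paste0("Facility '", ex$facility_id, "' jumps ", ex$jump,
                   " rungs between ", ex$year, " and ", ex$next_year,
                   "; only adjacent moves are modelled ",
                   "(use jumps = \"adjacent\" to count them as one event)"))
    }
    intervals$jump[big] <- 1L
  }

  by_rank <- intervals |>
    filter(.data$rank < 10) |>  # top category is absorbing; never at risk
    group_by(.data$rank) |>
    summarise(n_at_risk = dplyr::n(),
              n_events = sum(.data$jump == 1L), .groups = "drop")

  res <- adjacent_pairs() |>
    mutate(rank = category_rank(.data$from_category)) |>
    left_join(by_rank, by = "rank") |>
    mutate(n_at_risk = dplyr::coalesce(.data$n_at_risk, 0L),
           n_events = dplyr::coalesce(.data$n_events, 0L),
           probability = ifelse(.data$n_at_risk > 0,
                                .data$n_events / .data$n_at_risk, 0),
           standard_error = ifelse(
             .data$n_at_risk > 0,
             sqrt(.data$probability * (1 - .data$probability) / .data$n_at_risk),
             0)) |>
    select("from_category", "to_category", "probability", "standard_error",
           "n_at_risk", "n_events")

  empty <- res$from_category[res$n_at_risk == 0]
  if (length(empty) > 0) {
    warn(paste0("No at-risk facility-years for pair(s) starting at: ",
                paste(empty, collapse = ", "),
                "; their probability is reported as 0"))
  }
  structure(res, class = c("hwf_transitions", class(res)))
}
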