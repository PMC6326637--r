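#' Population-driven CHPS demarcation
#'
#' Community-based health planning and services (CHPS) zones are demarcated by
#' population: national policy stipulates one CHPS zone per 1,500 population,
#' so the expected number of CHPS compounds in a region-year is the population
#' divided by 1,500. The quotient is returned un-rounded; rounding happens only
#' in report tables.
#'
#' @param population A population series: tibble with columns `region`, `year`,
#'   `population` (strictly positive).
#' @param region Region identifier to look up.
#' @param year Calendar year to look up.
#' @param divisor Population per CHPS zone (default 1500, the policy value).
#' @return Non-negative real number of CHPS zones.
#' @export
#' @examples
#' pop <- tibble::tibble(region = "Ghana", year = 2016, population = 1500000)
#' demarcate_chps(pop, "Ghana", 2016)
demarcate_chps <- function(population, region, year, divisor = 1500) {
  validate_population(population)
  if (!is.finite(divisor) || divisor <= 0) {
    abort("`divisor` must be a positive number")
  }
  hit <- population$population[population$region == region &
                                 population$year == year]
  if (length(hit) == 0) {
    abort(paste0("Population missing for region '", region,
                 "', year ", year))
  }
  hit[[1]] / divisor
}

## Internal one-cycle update on a named count vector (ladder order).
## p is the length-10 vector of adjacent upward probabilities indexed by the
## *from* category rank; cons a length-11 vector of newly built facilities.
## chps_next, when supplied, replaces the CHPS stock (population demarcation
## mode); otherwise CHPS evolves as outflow-only Markov plus construction.
step_counts <- function(counts, p, cons, chps_next = NULL) {
  out <- counts - counts * c(p, 0) +      # outflow; EsTH absorbing (no outflow)
    c(0, counts[-11] * p) +               # inflow from the rung below
    cons                                  # newly commissioned facilities
  if (!is.null(chps_next)) out[1] <- chps_next
  unname(out)
}

#' Advance a facility census by one annual Markov cycle
#'
#' Applies the one-year cohort update to a single region's census: each
#' category loses the fraction moving one rung up the ladder, gains the inflow
#' from the rung below, and gains any newly constructed facilities. The top
#' category (EsTH) is absorbing and has no outflow. The CHPS stock is replaced
#' by `chps_next` when supplied (population-demarcation mode); otherwise it
#' follows the same outflow-plus-construction arithmetic (it has no rung
#' below).
#'
#' @param census One year's census for one region: tibble with columns
#'   `category` and `count` covering all 11 categories, or a named numeric
#'   vector over the categories.
#' @param transitions Transition table: tibble with columns `from_category`,
#'   `to_category`, `probability`, `standard_error` covering all 10 adjacent
#'   pairs.
#' @param construction Optional counts of newly commissioned facilities this
#'   cycle, same shape as `census`; missing categories count as zero.
#' @param chps_next Optional exogenous CHPS count for the next year (from
#'   [demarcate_chps()]).
#' @return Tibble with columns `category`, `count` for the next year.
#' @export
#' @examples
#' fix <- make_ghana_fixture()
#' step_census(dplyr::select(fix$census, category, count), fix$transitions)
step_census <- function(census, transitions, construction = NULL,
                        chps_next = NULL) {
  counts <- as_count_vector(census, "census")
  cons <- if (is.null(construction)) {
    rep(0, 11)
  } else {
    as_count_vector(construction, "construction", partial = TRUE)
  }
  validate_transitions(transitions)
  p <- transition_vector(transitions)
  if (!is.null(chps_next) && (!is.finite(chps_next) || chps_next < 0)) {
    abort("`chps_next` must be a non-negative number")
  }
  tibble(category = as_category(facility_categories()),
         count = step_counts(counts, p, cons, chps_next))
}

## coerce tibble(category, count) or named vector to ladder-ordered vector
as_count_vector <- function(x, what, partial = FALSE) {
  cats <- facility_categories()
  if (is.numeric(x)) {
    v <- x[cats]
    names(v) <- cats
    if (partial) v[is.na(v)] <- 0
  } else {
    require_columns(x, c("category", "count"), what)
    category_rank(as.character(x$category))
    v <- setNames(rep(NA_real_, 11), cats)
    v[as.character(x$category)] <- x$count
    if (partial) v[is.na(v)] <- 0
  }
  if (anyNA(v)) {
    abort(paste0(what, " must cover all 11 categories; missing: ",
                 paste(cats[is.na(v)], collapse = ", ")))
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    abort(paste0(what, " counts must be finite and non-negative"))
  }
  v
}

## length-10 probability vector in from-rank order
transition_vector <- function(transitions) {
  tp <- transitions
  tp$rank <- category_rank(as.character(tp$from_category))
  tp$probability[order(tp$rank)]
}

#' Project a facility census over a forecast horizon
#'
#' Deterministic discrete-time Markov cohort projection: starting from a
#' baseline census, the one-year update of [step_census()] is applied per
#' region for `horizon` annual cycles. Facility counts are real-valued
#' throughout (fractional facilities carry expected-value semantics); rounding
#' is deferred to the report renderers.
#'
#' Two CHPS regimes are supported. When a `population` series is supplied, the
#' CHPS stock is exogenous: each projected year it is set to population /
#' `chps_divisor` (replenishing demarcation). Otherwise CHPS evolves
#' endogenously as an outflow-only Markov stock plus construction.
#'
#' @param baseline Baseline census: tibble with columns `region`, `category`,
#'   `count`. Categories absent for a region are taken as zero.
#' @param transitions Transition table (10 adjacent pairs).
#' @param construction Optional construction schedule: tibble `region`,
#'   `category`, `year`, `count`; facilities commissioned in year `y` appear in
#'   the year-`y` census and first transition the following cycle.
#' @param population Optional population series (`region`, `year`,
#'   `population`) switching CHPS to demarcation mode; must cover every region
#'   and projected year.
#' @param horizon Number of annual cycles to project (default 10).
#' @param baseline_year Calendar year of the baseline census (default 2016).
#' @param chps_divisor Population per CHPS zone (default 1500).
#' @return A `hwf_projection` tibble: columns `region`, `category`, `year`,
#'   `count` covering the baseline year and all projected years.
#' @export
#' @examples
#' fix <- make_ghana_fixture()
#' proj <- project(fix$census, fix$transitions, horizon = 10)
#' census_wide(proj)
project <- function(baseline, transitions, construction = NULL,
                    population = NULL, horizon = 10, baseline_year = 2016,
                    chps_divisor = 1500) {
  validate_census(baseline)
  validate_transitions(transitions)
  if (!is.numeric(horizon) || length(horizon) != 1 || !is.finite(horizon) ||
      horizon < 1 || horizon != floor(horizon)) {
    abort("`horizon` must be an integer >= 1")
  }
  if (!is.null(construction)) {
    validate_construction(construction)
    orphan <- setdiff(unique(construction$region), unique(baseline$region))
    if (length(orphan) > 0) {
      abort(paste0("Construction schedule names region(s) absent from the ",
                   "baseline: ", paste(orphan, collapse = ", ")))
    }
  }
  if (!is.null(population)) validate_population(population)

  regions <- unique(baseline$region)
  p <- transition_vector(transitions)
  cats <- facility_categories()
  years <- baseline_year + 0:horizon

  per_region <- purrr::map(regions, function(rg) {
    v <- as_count_vector(baseline[baseline$region == rg, , drop = FALSE],
                         paste0("baseline census for region '", rg, "'"),
                         partial = TRUE)
    out <- matrix(0, nrow = 11, ncol = horizon + 1,
                  dimnames = list(cats, years))
    out[, 1] <- v
    for (t in seq_len(horizon)) {
      yr <- baseline_year + t
      cons <- construction_vector(construction, rg, yr)
      chps_next <- if (is.null(population)) NULL else {
        demarcate_chps(population, rg, yr, chps_divisor)
      }
      v <- step_counts(v, p, cons, chps_next)
      out[, t + 1] <- v
    }
    tibble(region = rg,
           category = as_category(rep(cats, horizon + 1)),
           year = rep(years, each = 11),
           count = as.vector(out))
  })

  res <- dplyr::bind_rows(per_region)
  structure(res,
            class = c("hwf_projection", class(res)),
            baseline_year = baseline_year,
            horizon = horizon,
            chps_mode = if (is.null(population)) "markov" else "population",
            transitions = transitions)
}

construction_vector <- function(construction, region, year) {
  if (is.null(construction)) return(rep(0, 11))
  sel <- construction[construction$region == region &
                        construction$year == year, , drop = FALSE]
  if (nrow(sel) == 0) return(rep(0, 11))
  v <- setNames(rep(0, 11), facility_categories())
  agg <- tapply(sel$count, as.character(sel$category), sum)
  v[names(agg)] <- agg
  unname(v)
}

#' Modelled annual flows between adjacent categories
#'
#' For each projected year and adjacent pair, the expected number of
#' facilities moving one rung up the ladder is the national count in the
#' origin category times the pair's transition probability. Per-pair totals
#' over the whole horizon are available via [flow_totals()].
#'
#' @param projection A `hwf_projection` (or any census tibble with `region`,
#'   `category`, `year`, `count`).
#' @param transitions Transition table; defaults to the one stored on the
#'   projection.
#' @return Tibble with columns `year`, `from_category`, `to_category`, `flow`
#'   (summed over regions), classed `hwf_flows`.
#' @export
#' @examples
#' fix <- make_ghana_fixture()
#' proj <- project(fix$census, fix$transitions, horizon = 1)
#' transition_flows(proj)
transition_flows <- function(projection, transitions = NULL) {
  if (is.null(transitions)) transitions <- attr(projection, "transitions")
  if (is.null(transitions)) {
    abort("Supply `transitions`: the census carries no transition table")
  }
  validate_transitions(transitions)
  census <- projection
  require_columns(census, c("region", "category", "year", "count"),
                  "projected census")
  tp <- transitions |>
    mutate(from_category = as.character(.data$from_category),
           to_category = as.character(.data$to_category))
  national <- census |>
    as_tibble() |>
    mutate(category = as.character(.data$category)) |>
    group_by(.data$year, .data$category) |>
    summarise(count = sum(.data$count), .groups = "drop")
  res <- national |>
    inner_join(tp, by = c(category = "from_category")) |>
    transmute(year = .data$year,
              from_category = as_category(.data$category),
              to_category = as_category(.data$to_category),
              flow = .data$count * .data$probability) |>
    arrange(.data$year, .data$from_category)
  structure(res, class = c("hwf_flows", class(res)))
}

#' Total flows per category pair over the horizon
#'
#' @param flows Output of [transition_flows()].
#' @return Tibble `from_category`, `to_category`, `total` (summed over years).
#' @export
flow_totals <- function(flows) {
  require_columns(flows, c("from_category", "to_category", "flow"), "flows")
  flows |>
    as_tibble() |>
    group_by(.data$from_category, .data$to_category) |>
    summarise(total = sum(.data$flow), .groups = "drop") |>
    arrange(.data$from_category)
}
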