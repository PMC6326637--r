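#' Confidence-limit variants of a transition table
#'
#' Builds the two limit scenarios used for predictive intervals: every
#' adjacent pair's probability is shifted simultaneously to its lower
#' (`p - z * se`) or upper (`p + z * se`) normal confidence limit, clamped to
#' [0, 1].
#'
#' @param transitions Transition table.
#' @param z Normal quantile (default 1.96 for 95% limits); must be positive.
#' @return Named list with elements `lower` and `upper`, each a transition
#'   table with shifted probabilities (standard errors carried through).
#' @export
#' @examples
#' ci_limits(make_ghana_fixture()$transitions)
ci_limits <- function(transitions, z = 1.96) {
  validate_transitions(transitions)
  if (!is.numeric(z) || length(z) != 1 || !is.finite(z) || z <= 0) {
    abort("`z` must be a positive number")
  }
  shift <- function(sgn) {
    transitions |>
      as_tibble() |>
      mutate(probability = pmin(1, pmax(0, .data$probability +
                                          sgn * z * .data$standard_error)))
  }
  list(lower = shift(-1), upper = shift(1))
}

#' Predictive interval for workforce requirements
#'
#' Propagates transition-probability uncertainty through the whole pipeline.
#' The default `"limits"` method runs the projection-plus-staffing pipeline
#' under three scenarios — the base probabilities and the all-lower / all-upper
#' confidence-limit variants of [ci_limits()] — and reports, per staff type,
#' region and year, the base-scenario requirement with `lower`/`upper` bounds
#' taken as the per-cell minimum and maximum over the three runs. The min/max
#' rule is used because shifting every probability upward does not move every
#' requirement in the same direction (faster upgrading fills high categories
#' but drains low ones); taking per-cell extremes guarantees the bounds
#' bracket the base case.
#'
#' The `"montecarlo"` method is an optional simulation-based extension:
#' probabilities are drawn per pair from a normal distribution truncated to
#' [0, 1] (mean = base probability, sd = standard error), the pipeline is run
#' per draw, and the bounds are the 2.5% / 97.5% quantiles across draws.
#'
#' @inheritParams project
#' @param norms Staffing norms table.
#' @param workload Optional workload-change table (see
#'   [staff_requirements()]).
#' @param z Normal quantile for the limit scenarios (default 1.96).
#' @param method `"limits"` (scenario limits, default) or `"montecarlo"`.
#' @param n_draws Number of Monte-Carlo draws (`"montecarlo"` only).
#' @param seed Seed for the Monte-Carlo draws; required for reproducibility.
#' @return A `hwf_requirements` tibble with columns `staff_type`, `region`,
#'   `year`, `required`, `lower`, `upper`; `lower <= required <= upper` holds
#'   for every cell by construction under `"limits"`.
#' @export
#' @examples
#' fix <- make_ghana_fixture()
#' norms <- synth_norms(seed = 1)
#' pi <- predictive_interval(fix$census, fix$transitions, norms, horizon = 3)
#' national_requirements(pi)
predictive_interval <- function(baseline, transitions, norms,
                                construction = NULL, population = NULL,
                                workload = NULL, horizon = 10,
                                baseline_year = 2016, chps_divisor = 1500,
                                z = 1.96,
                                method = c("limits", "montecarlo"),
                                n_draws = 500, seed = NULL) {
  method <- match.arg(method)
  run <- function(tp) {
    proj <- project(baseline, tp, construction = construction,
                    population = population, horizon = horizon,
                    baseline_year = baseline_year,
                    chps_divisor = chps_divisor)
    staff_requirements(proj, norms, workload = workload) |>
      select("staff_type", "region", "year", "required")
  }
  base_run <- run(transitions)

  if (method == "limits") {
    lim <- ci_limits(transitions, z = z)
    runs <- list(base_run, run(lim$lower), run(lim$upper))
    stacked <- dplyr::bind_rows(runs)
  } else {
    if (!is.numeric(n_draws) || n_draws < 2) {
      abort("`n_draws` must be at least 2")
    }
    if (is.null(seed)) abort("`seed` is required for method = \"montecarlo\"")
    draws <- withr::with_seed(
      seed,
      purrr::map(seq_len(n_draws), function(i) {
        tp <- transitions
        tp$probability <- rnorm_truncated(tp$probability, tp$standard_error)
        run(tp)
      }))
    stacked <- dplyr::bind_rows(draws)
  }

  probs <- if (method == "limits") c(0, 1) else c(0.025, 0.975)
  bounds <- stacked |>
    group_by(.data$staff_type, .data$region, .data$year) |>
    summarise(lower = quantile(.data$required, probs[1], names = FALSE,
                               type = 1),
              upper = quantile(.data$required, probs[2], names = FALSE,
                               type = 1),
              .groups = "drop")
  res <- base_run |>
    inner_join(bounds, by = c("staff_type", "region", "year")) |>
    mutate(lower = pmin(.data$lower, .data$required),
           upper = pmax(.data$upper, .data$required))
  structure(res, class = c("hwf_requirements", class(res)))
}

## one draw from Normal(mean, sd) truncated to [0,1], via inverse CDF;
## sd = 0 collapses to the mean
rnorm_truncated <- function(mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  u <- runif(length(mean), lo, hi)
  out <- stats::qnorm(u, mean, sd)
  out[sd == 0] <- mean[sd == 0]
  pmin(1, pmax(0, out))
}

#' Predictive interval for the facility census itself
#'
#' Same scenario-limit construction as [predictive_interval()], applied to the
#' projected facility counts rather than staffing requirements.
#'
#' @inheritParams project
#' @param z Normal quantile for the limit scenarios.
#' @return Tibble `region`, `category`, `year`, `count`, `lower`, `upper`.
#' @export
project_interval <- function(baseline, transitions, construction = NULL,
                             population = NULL, horizon = 10,
                             baseline_year = 2016, chps_divisor = 1500,
                             z = 1.96) {
  run <- function(tp) {
    project(baseline, tp, construction = construction,
            population = population, horizon = horizon,
            baseline_year = baseline_year, chps_divisor = chps_divisor) |>
      as_tibble() |>
      select("region", "category", "year", "count")
  }
  base_run <- run(transitions)
  lim <- ci_limits(transitions, z = z)
  stacked <- dplyr::bind_rows(base_run, run(lim$lower), run(lim$upper))
  bounds <- stacked |>
    group_by(.data$region, .data$category, .data$year) |>
    summarise(lower = min(.data$count), upper = max(.data$count),
              .groups = "drop")
  base_run |>
    inner_join(bounds, by = c("region", "category", "year"))
}
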