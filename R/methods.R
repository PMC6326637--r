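#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a facility projection
#'
#' @param x A `hwf_projection`.
#' @param ... Unused.
#' @return Plain long tibble `region`, `category`, `year`, `count`.
#' @method tidy hwf_projection
#' @export
tidy.hwf_projection <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of a facility projection
#'
#' @param x A `hwf_projection`.
#' @param ... Unused.
#' @return Tibble with baseline year, horizon, CHPS mode, number of regions,
#'   baseline and final national totals and the overall growth fraction.
#' @method glance hwf_projection
#' @export
glance.hwf_projection <- function(x, ...) {
  df <- as_tibble(unclass_result(x))
  by <- attr(x, "baseline_year")
  fy <- by + attr(x, "horizon")
  tot <- function(y) sum(df$count[df$year == y])
  tibble(baseline_year = by,
         horizon = attr(x, "horizon"),
         chps_mode = attr(x, "chps_mode"),
         n_regions = length(unique(df$region)),
         baseline_total = tot(by),
         final_total = tot(fy),
         growth = tot(fy) / tot(by) - 1)
}

#' Tidy a transition-estimate table
#'
#' @param x A `hwf_transitions` table.
#' @param conf.level Confidence level for the normal-approximation interval
#'   columns (default 0.95).
#' @param ... Unused.
#' @return Tibble with `conf.low`/`conf.high` columns added, clamped to
#'   [0, 1].
#' @method tidy hwf_transitions
#' @export
tidy.hwf_transitions <- function(x, conf.level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  as_tibble(unclass_result(x)) |>
    mutate(conf.low = pmax(0, .data$probability - z * .data$standard_error),
           conf.high = pmin(1, .data$probability + z * .data$standard_error))
}

#' One-row summary of a transition-estimate table
#'
#' @param x A `hwf_transitions` table.
#' @param ... Unused.
#' @return Tibble with the pair count and, when estimation detail is present,
#'   total at-risk facility-years and events.
#' @method glance hwf_transitions
#' @export
glance.hwf_transitions <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_at_risk = if ("n_at_risk" %in% names(x)) sum(x$n_at_risk) else NA_integer_,
         n_events = if ("n_events" %in% names(x)) sum(x$n_events) else NA_integer_)
}

#' Plot a facility projection
#'
#' National facility counts per category over the forecast years, one line
#' per category on a log scale (the ladder spans four orders of magnitude).
#'
#' @param object A `hwf_projection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hwf_projection
#' @export
autoplot.hwf_projection <- function(object, ...) {
  nat <- as_tibble(unclass_result(object)) |>
    group_by(.data$category, .data$year) |>
    summarise(count = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(nat, ggplot2::aes(x = .data$year, y = .data$count,
                                    colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Year", y = "Facilities (log scale)",
                  colour = "Category",
                  title = "Projected facility census by workload category") +
    ggplot2::theme_minimal()
}

#' Plot transition probability estimates with confidence intervals
#'
#' @param object A `hwf_transitions` table.
#' @param conf.level Confidence level for the whiskers (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hwf_transitions
#' @export
autoplot.hwf_transitions <- function(object, conf.level = 0.95, ...) {
  td <- tidy(object, conf.level = conf.level) |>
    mutate(pair = paste(.data$from_category, "→", .data$to_category),
           pair = factor(.data$pair, levels = unique(.data$pair)))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$pair, y = .data$probability)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = NULL, y = "Annual transition probability",
                  title = "Adjacent-upward transition probabilities") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot national workforce requirements over time
#'
#' Draws the national requirement trajectory per staff type; when
#' `lower`/`upper` bound columns are present (from [predictive_interval()]),
#' a ribbon shows the predictive interval.
#'
#' @param requirements A `hwf_requirements` tibble.
#' @param staff_types Optional subset of staff types to draw.
#' @return A ggplot object.
#' @export
plot_requirements <- function(requirements, staff_types = NULL) {
  nat <- national_requirements(requirements)
  if (!is.null(staff_types)) {
    nat <- nat[nat$staff_type %in% staff_types, , drop = FALSE]
  }
  gg <- ggplot2::ggplot(nat, ggplot2::aes(x = .data$year,
                                          y = .data$required)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~staff_type, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Required headcount",
                  title = "Projected workforce requirements") +
    ggplot2::theme_minimal()
  if (all(c("lower", "upper") %in% names(nat))) {
    gg <- gg + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                                 ymax = .data$upper),
                                    alpha = 0.25)
  }
  gg
}

## strip the result class so dplyr verbs inside methods see a plain tibble
unclass_result <- function(x) {
  class(x) <- setdiff(class(x),
                      c("hwf_projection", "hwf_transitions", "hwf_flows",
                        "hwf_requirements"))
  x
}

#' @export
print.hwf_projection <- function(x, ...) {
  cat("<facility projection> baseline ", attr(x, "baseline_year"),
      ", horizon ", attr(x, "horizon"), " years, CHPS mode '",
      attr(x, "chps_mode"), "'\n", sep = "")
  NextMethod()
}
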