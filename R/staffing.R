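#' Workload-change staffing adjustment factor
#'
#' The Ghana Ministry of Health staffing norms prescribe a piecewise staffing
#' adjustment when a facility's workload changes without triggering a category
#' transition: a change of 15% or more in workload adjusts the staff
#' requirement by 23.5%; above 10% but below 15% by 14.3%; from 5% up to 10%
#' (inclusive at both ends) by 6.3%; below 5% no adjustment. The sign of the
#' returned adjustment follows the sign of the workload change, so shrinking
#' workloads reduce requirements symmetrically. Changes beyond 15% additionally
#' call for a facility-status review; see the `needs_review` flag in
#' [staff_requirements()].
#'
#' The printed rules leave a workload change of exactly 10% ambiguous between
#' the 6.3% and 14.3% bands; this implementation reads "5% up to 10%" as
#' inclusive, so 0.10 maps to 0.063.
#'
#' @param delta Fractional workload change (e.g. 0.12 for +12%); vectorised.
#' @return Signed fractional staffing adjustment (0, ±0.063, ±0.143, ±0.235).
#' @export
#' @examples
#' adjustment_factor(c(0.04, 0.07, 0.12, 0.16, -0.12))
adjustment_factor <- function(delta) {
  if (any(!is.finite(delta))) {
    abort("`delta` must be finite (fractional workload change)")
  }
  a <- abs(delta)
  magnitude <- ifelse(a >= 0.15, 0.235,
                      ifelse(a > 0.10, 0.143,
                             ifelse(a >= 0.05, 0.063, 0)))
  sign(delta) * magnitude
}

#' Apply the workload adjustment to a base requirement
#'
#' @param base Non-negative base staffing requirement.
#' @param delta Fractional workload change; passed to [adjustment_factor()].
#' @return `base * (1 + adjustment_factor(delta))`.
#' @export
#' @examples
#' adjusted_requirement(100, 0.12)  # 114.3
adjusted_requirement <- function(base, delta) {
  if (any(!is.finite(base)) || any(base < 0)) {
    abort("`base` must be a non-negative number")
  }
  base * (1 + adjustment_factor(delta))
}

#' Workforce requirements from a projected census and staffing norms
#'
#' For each staff type, region and year, the base requirement is the dot
#' product of the census vector over the 11 facility categories with the staff
#' type's per-facility staffing standard. When a workload-change table is
#' supplied, each (region, category) census cell is adjusted by
#' `1 + adjustment_factor(delta)` before summation; cells with |delta| > 15%
#' are flagged for facility-status review.
#'
#' @param census Census tibble with columns `region`, `category`, `count` and
#'   (optionally) `year`; a [project()] result works directly. Without a
#'   `year` column a single year 0 is assumed.
#' @param norms Staffing norms: tibble `staff_type`, `category`, `headcount`,
#'   every staff type covering all 11 categories.
#' @param workload Optional workload-change table: tibble `region`,
#'   `category`, `delta` (fractional change); missing cells mean no change.
#' @return A `hwf_requirements` tibble: `staff_type`, `region`, `year`,
#'   `required` (plus `needs_review` when `workload` is supplied). National
#'   totals via [national_requirements()].
#' @export
#' @examples
#' fix <- make_ghana_fixture()
#' proj <- project(fix$census, fix$transitions, horizon = 2)
#' norms <- synth_norms(seed = 1)
#' staff_requirements(proj, norms)
staff_requirements <- function(census, norms, workload = NULL) {
  require_columns(census, c("region", "category", "count"), "census")
  validate_norms(norms)
  cen <- as_tibble(census) |>
    mutate(category = as.character(.data$category))
  if (!"year" %in% names(cen)) cen$year <- 0L
  if (!is.null(workload)) {
    require_columns(workload, c("region", "category", "delta"),
                    "workload-change table")
    if (any(!is.finite(workload$delta))) {
      abort("workload-change table: `delta` must be finite")
    }
    wl <- as_tibble(workload) |>
      mutate(category = as.character(.data$category))
    cen <- cen |>
      left_join(wl, by = c("region", "category")) |>
      mutate(delta = dplyr::coalesce(.data$delta, 0),
             count = .data$count * (1 + adjustment_factor(.data$delta)),
             needs_review = abs(.data$delta) > 0.15)
  }
  nr <- as_tibble(norms) |>
    mutate(category = as.character(.data$category))
  res <- cen |>
    inner_join(nr, by = "category", relationship = "many-to-many") |>
    group_by(.data$staff_type, .data$region, .data$year) |>
    summarise(required = sum(.data$count * .data$headcount),
              needs_review = if ("needs_review" %in% names(cen)) {
                any(.data$needs_review)
              } else FALSE,
              .groups = "drop") |>
    arrange(.data$staff_type, .data$region, .data$year)
  if (is.null(workload)) res$needs_review <- NULL
  structure(res, class = c("hwf_requirements", class(res)))
}

#' Base requirement for one staff type, region and year
#'
#' Scalar convenience wrapper around the dot product of a region-year census
#' vector with a staff type's norms vector (no workload adjustment).
#'
#' @inheritParams staff_requirements
#' @param staff_type Staff type to evaluate; must exist in `norms`.
#' @param region Region identifier.
#' @param year Year; ignored when the census has no `year` column.
#' @return Non-negative real headcount.
#' @export
base_requirement <- function(census, norms, staff_type, region, year = NULL) {
  validate_norms(norms)
  if (!staff_type %in% norms$staff_type) {
    abort(paste0("Staff type '", staff_type, "' is absent from the norms"))
  }
  cen <- as_tibble(census)
  cen <- cen[cen$region == region, , drop = FALSE]
  if ("year" %in% names(cen) && !is.null(year)) {
    cen <- cen[cen$year == year, , drop = FALSE]
  }
  if (nrow(cen) == 0) {
    abort(paste0("No census rows for region '", region, "'",
                 if (!is.null(year)) paste0(", year ", year)))
  }
  v <- as_count_vector(cen, "census", partial = TRUE)
  nm <- norms[norms$staff_type == staff_type, , drop = FALSE]
  w <- setNames(nm$headcount, as.character(nm$category))[facility_categories()]
  sum(v * w)
}

#' National requirements per staff type and year
#'
#' @param requirements Output of [staff_requirements()].
#' @return Tibble `staff_type`, `year`, `required` (and `lower`/`upper` when
#'   present), summed exactly over regions.
#' @export
national_requirements <- function(requirements) {
  require_columns(requirements, c("staff_type", "year", "required"),
                  "requirements")
  bounds <- intersect(c("lower", "upper"), names(requirements))
  requirements |>
    as_tibble() |>
    group_by(.data$staff_type, .data$year) |>
    summarise(required = sum(.data$required),
              dplyr::across(dplyr::all_of(bounds), sum),
              .groups = "drop")
}

#' Staff-availability ratio (SAR) and shortfall
#'
#' The staff-availability ratio compares the current employed headcount of
#' each staff type with the modelled national requirement for a given year:
#' SAR = employed / required. The shortfall fraction is `1 - SAR`, floored at
#' zero (a surplus is not a negative shortage).
#'
#' @param requirements A `hwf_requirements` tibble (regional; summed
#'   internally) or an already-national table with `staff_type`, `year`,
#'   `required`.
#' @param roster Employment roster: tibble `staff_type`, `employed`.
#' @param year Year at which to evaluate the requirement.
#' @return Tibble `staff_type`, `employed`, `required`, `sar`, `shortfall`.
#' @export
#' @examples
#' req <- tibble::tibble(staff_type = "Midwife", region = "Ghana",
#'                       year = 2016, required = 100)
#' roster <- tibble::tibble(staff_type = "Midwife", employed = 68)
#' staff_availability_ratio(req, roster, 2016)
staff_availability_ratio <- function(requirements, roster, year) {
  validate_roster(roster)
  nat <- national_requirements(requirements)
  nat <- nat[nat$year == year, , drop = FALSE]
  if (nrow(nat) == 0) abort(paste0("No requirements for year ", year))
  res <- as_tibble(roster) |>
    inner_join(nat, by = "staff_type")
  if (any(res$required <= 0)) {
    bad <- res$staff_type[res$required <= 0]
    abort(paste0("SAR is undefined at zero requirement for: ",
                 paste(bad, collapse = ", ")))
  }
  res |>
    transmute(staff_type = .data$staff_type,
              employed = .data$employed,
              required = .data$required,
              sar = .data$employed / .data$required,
              shortfall = pmax(0, 1 - .data$sar))
}
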