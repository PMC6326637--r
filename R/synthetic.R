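#' Printed national baseline census (2016) and transition parameters
#'
#' The canonical single-region fixture: the national 2016 facility census over
#' the 11 workload categories (5,749 facilities in total, of which 188 primary
#' hospitals) together with the 10 adjacent-pair transition probabilities and
#' their standard errors estimated from the 2011-2015 facility utilisation
#' panel.
#'
#' @return List with elements `census` (tibble `region`, `category`, `count`,
#'   single region `"Ghana"`) and `transitions` (tibble `from_category`,
#'   `to_category`, `probability`, `standard_error`).
#' @export
#' @examples
#' fix <- make_ghana_fixture()
#' sum(fix$census$count)  # 5749
make_ghana_fixture <- function() {
  census <- tibble(
    region = "Ghana",
    category = as_category(facility_categories()),
    count = c(4449, 903, 158, 40, 96, 49, 29, 14, 7, 2, 2))
  transitions <- adjacent_pairs() |>
    mutate(probability = c(0.010, 0.033, 0.028, 0.042, 0.167,
                           0.129, 0.084, 0.021, 0.091, 0.001),
           standard_error = c(0.001, 0.002, 0.002, 0.002, 0.005,
                              0.004, 0.003, 0.002, 0.003, 0.000))
  list(census = census,
       transitions = structure(transitions,
                               class = c("hwf_transitions",
                                         class(transitions))))
}

#' Simulate a facility-category panel (microsimulation)
#'
#' Generates the longitudinal facility panel the transition estimator
#' consumes: each facility starts in its assigned category and, each year,
#' independently moves one rung up the ladder with the pair's transition
#' probability, else stays; the top category is absorbing and downward moves
#' never occur. This is also the microsimulation counterpart of the
#' deterministic cohort projection — at large facility numbers the empirical
#' category counts converge to [project()]'s expected counts.
#'
#' @param transitions Transition table supplying the true probabilities.
#' @param n_per_category Facilities starting in each category: a single number
#'   or a named vector over category codes (zeros allowed).
#' @param years Number of calendar years observed (>= 2).
#' @param start_year First calendar year (default 2011).
#' @param region Region label attached to facility ids (cosmetic).
#' @param missing_rate Fraction of facility-years (never the first year)
#'   dropped at random, emulating incomplete routine reporting. Default 0.
#' @param seed Optional seed; the panel is reproducible given the seed.
#' @return Facility panel tibble `facility_id`, `year`, `category`.
#' @export
#' @examples
#' fix <- make_ghana_fixture()
#' simulate_panel(fix$transitions, n_per_category = 50, years = 3, seed = 7)
simulate_panel <- function(transitions, n_per_category = 1000, years = 5,
                           start_year = 2011, region = "R1",
                           missing_rate = 0, seed = NULL) {
  validate_transitions(transitions)
  if (years < 2) abort("`years` must be at least 2")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1)")
  }
  cats <- facility_categories()
  n <- if (is.null(names(n_per_category))) {
    if (length(n_per_category) == 1) {
      setNames(rep(n_per_category, 11), cats)
    } else {
      setNames(n_per_category, cats)
    }
  } else {
    v <- setNames(rep(0, 11), cats)
    v[names(n_per_category)] <- n_per_category
    v
  }
  p <- transition_vector(transitions)

  sim <- function() {
    rank0 <- rep(0:10, times = n)
    nfac <- length(rank0)
    ranks <- matrix(0L, nrow = nfac, ncol = years)
    ranks[, 1] <- rank0
    for (t in 2:years) {
      cur <- ranks[, t - 1]
      move <- cur < 10 & runif(nfac) < c(p, 0)[cur + 1]
      ranks[, t] <- cur + as.integer(move)
    }
    out <- tibble(
      facility_id = rep(sprintf("%s-F%05d", region, seq_len(nfac)), years),
      year = rep(start_year + 0:(years - 1), each = nfac),
      category = cats[as.vector(ranks) + 1])
    if (missing_rate > 0) {
      later <- which(out$year > start_year)
      drop <- later[runif(length(later)) < missing_rate]
      if (length(drop) > 0) out <- out[-drop, , drop = FALSE]
    }
    out
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' The staff types of the Ghana-shaped workforce
#'
#' The 23 public-sector staff cadres the national workforce forecast covers,
#' from community health nurses to subspecialist physicians.
#'
#' @return Character vector of 23 staff-type names.
#' @export
ghana_staff_types <- function() {
  c("Biomedical scientist", "Community health nurse", "Critical care nurse",
    "Dental surgeon", "Emergency nurse", "Enrolled nurse",
    "Family medicine physician", "General surgeon",
    "Medical officer (general practitioner)", "Mental health nurse",
    "Midwife", "Obstetrician & gynaecologist", "Ophthalmic nurse",
    "Ophthalmologist", "Paediatrician", "Pharmacist", "Pharmacy technician",
    "Physician assistant (anaesthesia)", "Physician assistant (medical)",
    "Public health nurse", "Radiographer/x-ray technician",
    "Registered general nurse", "Technical officer (laboratory)")
}

#' Synthetic staffing-norms matrix
#'
#' The actual Ministry of Health staffing standards are an external policy
#' input not shipped here; this generator produces a fictional but
#' Ghana-shaped stand-in: 23 staff types by 11 facility categories, with
#' per-facility headcounts that are non-negative and monotone non-decreasing
#' in facility rank for every cadre (a teaching hospital never needs fewer of
#' a staff type than a CHPS compound), nursing cadres present from the bottom
#' of the ladder and specialist physicians appearing only at hospital level.
#' Magnitudes are order-of-magnitude plausible (fractions of a specialist per
#' small facility, tens of nurses per teaching hospital) and explicitly
#' fictional — outputs computed from them are not policy numbers.
#'
#' @param staff_types Character vector of staff-type names (default the
#'   23-cadre Ghana shape).
#' @param scale Positive multiplier on every headcount (default 1); doubling
#'   it exactly doubles every downstream requirement.
#' @param seed Optional seed for the per-cadre intensity draws.
#' @return Norms tibble `staff_type`, `category`, `headcount`.
#' @export
#' @examples
#' synth_norms(seed = 1)
synth_norms <- function(staff_types = ghana_staff_types(), scale = 1,
                        seed = NULL) {
  if (!is.finite(scale) || scale <= 0) abort("`scale` must be positive")
  cats <- facility_categories()
  # ladder profile: staffing intensity grows with facility rank
  ladder <- c(0.25, 0.6, 1, 1.8, 3, 4.5, 6, 8, 14, 28, 40)
  # specialist cadres staff only hospitals (rank >= PHA)
  specialist <- grepl(
    "surgeon|physician|Ophthalmologist|Paediatrician|Obstetrician|officer \\(general",
    staff_types, ignore.case = TRUE)
  gen <- function() {
    purrr::map2(staff_types, specialist, function(st, sp) {
      base <- rgamma(1, shape = 2, rate = if (sp) 8 else 2)
      prof <- base * ladder
      if (sp) prof[1:4] <- 0
      # round before scaling so `scale` stays an exact multiplier
      tibble(staff_type = st, category = as_category(cats),
             headcount = scale * round(prof, 2))
    }) |>
      purrr::list_rbind()
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out
}

#' Synthetic regional population series
#'
#' Geometric population growth per region from a jittered regional base,
#' driving the CHPS demarcation rule (population / 1500).
#'
#' @param regions Character vector of region ids (default 10 regions).
#' @param years Calendar years to cover (default 2016:2026).
#' @param base_population Mean regional population in the first year (default
#'   2.8 million, i.e. a 28 million national total over 10 regions).
#' @param growth_rate Annual fractional growth (default 0.022).
#' @param seed Optional seed for the regional base jitter.
#' @return Population tibble `region`, `year`, `population`.
#' @export
synth_population <- function(regions = paste0("R", 1:10),
                             years = 2016:2026, base_population = 2.8e6,
                             growth_rate = 0.022, seed = NULL) {
  gen <- function() {
    base <- base_population * exp(rnorm(length(regions), 0, 0.25))
    tidyr::expand_grid(region = regions, year = years) |>
      mutate(population = base[match(.data$region, regions)] *
               (1 + growth_rate)^(.data$year - min(years)))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Synthetic construction schedule
#'
#' Poisson counts of newly commissioned facilities per region, category and
#' year, concentrated in the lower rungs of the ladder where public building
#' programmes operate.
#'
#' @param regions Character vector of region ids.
#' @param years Years the schedule covers.
#' @param mean_per_year Expected national new builds per year per targeted
#'   category (default 4).
#' @param categories Categories receiving new construction (default CHPS,
#'   HCA, PolyC).
#' @param seed Optional seed.
#' @return Construction tibble `region`, `category`, `year`, `count`.
#' @export
synth_construction <- function(regions = paste0("R", 1:10),
                               years = 2017:2026, mean_per_year = 4,
                               categories = c("CHPS", "HCA", "PolyC"),
                               seed = NULL) {
  category_rank(categories)
  gen <- function() {
    tidyr::expand_grid(region = regions, category = categories,
                       year = years) |>
      mutate(count = rpois(dplyr::n(),
                           mean_per_year / length(regions)),
             category = as_category(.data$category)) |>
      filter(.data$count > 0)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Synthetic employment roster targeting an aggregate SAR
#'
#' Draws a current-employment roster whose aggregate staff-availability ratio
#' against a given requirements table is close to a target (each cadre's SAR
#' is jittered around it, emulating the wide spread observed across staff
#' types).
#'
#' @param requirements Requirements table (regional or national).
#' @param year Year whose national requirement anchors the roster.
#' @param sar_target Target aggregate SAR (default 0.68).
#' @param spread Half-width of the per-cadre uniform jitter around the target
#'   (default 0.15).
#' @param seed Optional seed.
#' @return Roster tibble `staff_type`, `employed`.
#' @export
synth_roster <- function(requirements, year, sar_target = 0.68,
                         spread = 0.15, seed = NULL) {
  nat <- national_requirements(requirements)
  nat <- nat[nat$year == year, , drop = FALSE]
  if (nrow(nat) == 0) abort(paste0("No requirements for year ", year))
  gen <- function() {
    sar <- pmax(0, sar_target + runif(nrow(nat), -spread, spread))
    tibble(staff_type = nat$staff_type,
           employed = round(nat$required * sar))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a complete, coherent set of synthetic pipeline inputs
#'
#' One call producing every table the forecasting pipeline consumes — panel,
#' baseline census, transition table (the panel's generating truth),
#' construction schedule, population series, staffing norms and employment
#' roster — all driven by one seed so the whole set is reproducible.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_regions Number of regions (default 10).
#' @param n_per_category Facilities per category per region in the panel.
#' @param years Panel span in years (default 5, emulating 2011-2015).
#' @param sar_target Aggregate SAR the roster is drawn around.
#' @return Named list: `panel`, `census`, `transitions`, `construction`,
#'   `population`, `norms`, `roster`.
#' @export
#' @examples
#' inputs <- simulate_inputs(seed = 42, n_regions = 2, n_per_category = 50)
#' names(inputs)
simulate_inputs <- function(seed, n_regions = 10, n_per_category = 100,
                            years = 5, sar_target = 0.68) {
  tp <- make_ghana_fixture()$transitions
  regions <- paste0("R", seq_len(n_regions))
  withr::with_seed(seed, {
    panel <- purrr::map(regions, function(rg) {
      simulate_panel(tp, n_per_category = n_per_category, years = years,
                     start_year = 2011, region = rg)
    }) |> purrr::list_rbind()
    # baseline census: the panel's final observed year
    census <- panel |>
      filter(.data$year == max(.data$year)) |>
      mutate(region = sub("-F.*", "", .data$facility_id)) |>
      count(.data$region, .data$category, name = "count") |>
      mutate(category = as_category(as.character(.data$category))) |>
      tidyr::complete(region = regions,
                      category = as_category(facility_categories()),
                      fill = list(count = 0))
    population <- synth_population(regions)
    construction <- synth_construction(regions)
    norms <- synth_norms()
    proj <- project(census, tp, horizon = 1)
    req <- staff_requirements(proj, norms)
    roster <- synth_roster(req, year = 2016, sar_target = sar_target)
    list(panel = panel, census = census, transitions = tp,
         construction = construction, population = population,
         norms = norms, roster = roster)
  })
}
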