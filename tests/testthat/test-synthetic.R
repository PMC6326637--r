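fix <- make_ghana_fixture()

test_that("the national fixture reproduces the printed baseline and parameters", {
  expect_equal(sum(fix$census$count), 5749)
  ph <- c("PHA", "PHB", "PHC", "PHD")
  expect_equal(sum(fix$census$count[as.character(fix$census$category) %in% ph]),
               188)
  rh <- fix$transitions[fix$transitions$from_category == "RH", ]
  expect_equal(rh$probability, 0.091)
  expect_equal(rh$standard_error, 0.003)
  expect_equal(fix$census$count[1], 4449)  # CHPS
  expect_silent(validate_transitions(fix$transitions))
})

test_that("panel simulation honours degenerate probabilities", {
  frozen <- simulate_panel(tp_from_p(rep(0, 10)), n_per_category = 20,
                           years = 4, seed = 1)
  per_fac <- tapply(frozen$category, frozen$facility_id,
                    function(x) length(unique(x)))
  expect_true(all(per_fac == 1))
  certain <- simulate_panel(tp_from_p(c(1, rep(0, 9))),
                            n_per_category = c(CHPS = 25), years = 2,
                            seed = 1)
  y2 <- certain[certain$year == 2012, ]
  expect_true(all(y2$category == "HCA"))
})

test_that("panels are reproducible under a seed and distinct across seeds", {
  a <- simulate_panel(fix$transitions, n_per_category = 100, years = 4,
                      seed = 5)
  b <- simulate_panel(fix$transitions, n_per_category = 100, years = 4,
                      seed = 5)
  c <- simulate_panel(fix$transitions, n_per_category = 100, years = 4,
                      seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("generated panels satisfy the panel invariants", {
  panel <- simulate_panel(fix$transitions, n_per_category = 200, years = 5,
                          seed = 8, missing_rate = 0.1)
  expect_silent(validate_panel(panel))
  ranks <- panel |>
    dplyr::mutate(rank = category_rank(as.character(category))) |>
    dplyr::arrange(facility_id, year) |>
    dplyr::group_by(facility_id) |>
    dplyr::summarise(ok = all(diff(rank) >= 0), .groups = "drop")
  expect_true(all(ranks$ok))
  # censoring never removes the first year
  expect_equal(sum(panel$year == 2011), 11 * 200)
  expect_lt(sum(panel$year > 2011), 11 * 200 * 4)
})

test_that("one-step empirical transition fractions match the generating probabilities", {
  n <- 10000
  panel <- simulate_panel(fix$transitions, n_per_category = n, years = 2,
                          seed = 12)
  p <- fix$transitions$probability
  wide <- tidyr::pivot_wider(panel, names_from = year,
                             values_from = category)
  r1 <- category_rank(wide$`2011`)
  r2 <- category_rank(wide$`2012`)
  for (r in 0:9) {
    frac <- mean(r2[r1 == r] == r + 1)
    bound <- 3 * sqrt(p[r + 1] * (1 - p[r + 1]) / n)
    expect_lt(abs(frac - p[r + 1]), bound + 1e-9)
  }
})

test_that("synthetic norms are non-negative and monotone up the ladder", {
  norms <- synth_norms(seed = 2)
  expect_equal(nrow(norms), 23 * 11)
  expect_true(all(norms$headcount >= 0))
  mono <- norms |>
    dplyr::mutate(rank = category_rank(as.character(category))) |>
    dplyr::arrange(staff_type, rank) |>
    dplyr::group_by(staff_type) |>
    dplyr::summarise(ok = all(diff(headcount) >= 0), .groups = "drop")
  expect_true(all(mono$ok))
  expect_silent(validate_norms(norms))
})

test_that("population generator grows geometrically; zero growth is constant", {
  flat <- synth_population(regions = "R1", years = 2016:2020,
                           growth_rate = 0, seed = 1)
  expect_equal(length(unique(flat$population)), 1)
  grow <- synth_population(regions = "R1", years = 2016:2020,
                           growth_rate = 0.05, seed = 1)
  ratio <- grow$population[-1] / grow$population[-5]
  expect_equal(ratio, rep(1.05, 4), tolerance = 1e-12)
})

test_that("synthetic roster lands near the target aggregate availability ratio", {
  norms <- synth_norms(seed = 4)
  req <- staff_requirements(fix$census, norms)
  req$year <- 2016
  roster <- synth_roster(req, year = 2016, sar_target = 0.68, seed = 4)
  sar <- staff_availability_ratio(req, roster, 2016)
  aggregate <- sum(sar$employed) / sum(sar$required)
  expect_gt(aggregate, 0.63)
  expect_lt(aggregate, 0.73)
})

test_that("simulate_inputs yields a coherent, fully validated input set", {
  inputs <- simulate_inputs(seed = 42, n_regions = 2, n_per_category = 40,
                            years = 3)
  expect_silent(validate_panel(inputs$panel))
  expect_silent(validate_census(inputs$census))
  expect_silent(validate_transitions(inputs$transitions))
  expect_silent(validate_population(inputs$population))
  expect_silent(validate_norms(inputs$norms))
  expect_silent(validate_roster(inputs$roster))
  # same seed, same set
  again <- simulate_inputs(seed = 42, n_regions = 2, n_per_category = 40,
                           years = 3)
  expect_identical(inputs, again)
})

test_that("the estimate -> project loop agrees with projecting the generating truth", {
  panel <- simulate_panel(fix$transitions, n_per_category = 4000, years = 5,
                          seed = 77)
  est <- estimate_transitions(panel)
  norms <- synth_norms(seed = 77)
  req_est <- national_requirements(
    staff_requirements(project(fix$census, est, horizon = 5), norms))
  req_true <- national_requirements(
    staff_requirements(project(fix$census, fix$transitions, horizon = 5),
                       norms))
  # estimation error propagates mildly: within 5% per staff type and year
  rel <- abs(req_est$required - req_true$required) / req_true$required
  expect_lt(max(rel), 0.05)
})
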