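fix <- make_ghana_fixture()

test_that("the workload adjustment ladder reproduces the four printed rules", {
  expect_equal(adjustment_factor(0.12), 0.143)
  expect_equal(adjustment_factor(0.04), 0)
  expect_equal(adjustment_factor(0.07), 0.063)
  expect_equal(adjustment_factor(0.16), 0.235)
  expect_error(adjustment_factor(NA_real_), "finite")
  expect_error(adjustment_factor(Inf), "finite")
})

test_that("adjustment factor is a piecewise-constant odd step function on a dense grid", {
  # independent restatement of the printed bands
  band <- function(a) {
    if (a >= 0.15) 0.235
    else if (a > 0.10 && a < 0.15) 0.143
    else if (a >= 0.05 && a <= 0.10) 0.063
    else 0
  }
  grid <- seq(-0.30, 0.30, by = 0.001)
  expected <- vapply(grid, function(d) sign(d) * band(abs(d)), numeric(1))
  expect_equal(adjustment_factor(grid), expected)
  # documented boundary reading: exactly 10% takes the 6.3% rule
  expect_equal(adjustment_factor(0.10), 0.063)
  expect_equal(adjustment_factor(0.15), 0.235)
  expect_equal(adjustment_factor(0.05), 0.063)
})

test_that("base requirement is the census-by-norms dot product", {
  census <- census_from_counts(c(10, 2, rep(0, 9)))
  norms <- tidyr::expand_grid(staff_type = "Nurse",
                              category = facility_categories()) |>
    dplyr::mutate(headcount = dplyr::case_when(category == "CHPS" ~ 1,
                                               category == "HCA" ~ 5,
                                               TRUE ~ 0))
  expect_equal(base_requirement(census, norms, "Nurse", "Ghana"), 20)
  zero <- dplyr::mutate(norms, headcount = 0)
  expect_equal(base_requirement(census, zero, "Nurse", "Ghana"), 0)
  expect_error(base_requirement(census, norms, "Doctor", "Ghana"),
               "'Doctor' is absent")
})

test_that("fixture-census requirement matches an independent dot-product oracle", {
  norms <- synth_norms(seed = 5)
  st <- "Midwife"
  got <- base_requirement(fix$census, norms, st, "Ghana")
  # brute-force: explicit 11-term sum from the raw tables
  expected <- 0
  for (cat in facility_categories()) {
    cnt <- fix$census$count[as.character(fix$census$category) == cat]
    hc <- norms$headcount[norms$staff_type == st &
                            as.character(norms$category) == cat]
    expected <- expected + cnt * hc
  }
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("workload adjustment scales the base requirement by the ladder factor", {
  expect_equal(adjusted_requirement(100, 0.12), 114.3)
  expect_equal(adjusted_requirement(100, 0), 100)
  expect_equal(adjusted_requirement(80, 0.20), 98.8)
  expect_error(adjusted_requirement(-1, 0.1), "non-negative")
})

test_that("requirements are linear in census and norms and aggregate exactly", {
  norms <- synth_norms(seed = 7)
  proj <- project(fix$census, fix$transitions, horizon = 3)
  req <- staff_requirements(proj, norms)
  doubled_census <- dplyr::mutate(tibble::as_tibble(proj), count = 2 * count)
  req2 <- staff_requirements(doubled_census, norms)
  expect_equal(req2$required, 2 * req$required, tolerance = 1e-12)
  # norms scale linearity
  req3 <- staff_requirements(proj, synth_norms(seed = 7, scale = 2))
  expect_equal(req3$required, 2 * req$required, tolerance = 1e-9)
  # national = exact sum over regions on a multi-region census
  multi <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(proj), region = "North"),
    dplyr::mutate(tibble::as_tibble(proj), region = "South", count = count / 3))
  reqm <- staff_requirements(multi, norms)
  nat <- national_requirements(reqm)
  byhand <- reqm |>
    dplyr::group_by(staff_type, year) |>
    dplyr::summarise(required = sum(required), .groups = "drop")
  expect_equal(nat$required, byhand$required, tolerance = 1e-12)
})

test_that("workload-change input adjusts cells and flags reviews", {
  norms <- synth_norms(seed = 7)
  wl <- tibble::tibble(region = "Ghana", category = c("CHPS", "PHA"),
                       delta = c(0.12, 0.20))
  req <- staff_requirements(fix$census, norms, workload = wl)
  expect_true(all(req$needs_review))  # PHA delta 0.20 > 0.15 flags every type
  base <- staff_requirements(fix$census, norms)
  expect_true(all(req$required >= base$required - 1e-9))
})

test_that("staff-availability ratio and shortfall follow the definition", {
  req <- tibble::tibble(staff_type = c("Midwife", "Nurse"), region = "Ghana",
                        year = 2016, required = c(100, 100))
  roster <- tibble::tibble(staff_type = c("Midwife", "Nurse"),
                           employed = c(68, 120))
  sar <- staff_availability_ratio(req, roster, 2016)
  expect_equal(sar$sar, c(0.68, 1.20))
  expect_equal(sar$shortfall, c(0.32, 0))  # surplus floors at zero
  zero_emp <- dplyr::mutate(roster, employed = 0)
  expect_equal(staff_availability_ratio(req, zero_emp, 2016)$sar, c(0, 0))
  zero_req <- dplyr::mutate(req, required = 0)
  expect_error(staff_availability_ratio(zero_req, roster, 2016),
               "undefined at zero requirement")
  expect_error(staff_availability_ratio(req, roster, 1999), "No requirements")
})

test_that("requirements rise year on year under upward drift into better-staffed categories", {
  norms <- synth_norms(seed = 9)
  proj <- project(fix$census, fix$transitions, horizon = 10)
  nat <- national_requirements(staff_requirements(proj, norms))
  for (st in unique(nat$staff_type)) {
    series <- nat$required[nat$staff_type == st][order(nat$year[nat$staff_type == st])]
    expect_true(all(diff(series) >= -1e-9))
  }
})
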