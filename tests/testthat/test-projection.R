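fix <- make_ghana_fixture()

test_that("CHPS demarcation divides population by the zone size", {
  pop <- tibble::tibble(region = c("A", "A"), year = c(2016, 2017),
                        population = c(1500000, 987654))
  expect_equal(demarcate_chps(pop, "A", 2016), 1000)
  expect_equal(demarcate_chps(pop, "A", 2017), 987654 / 1500)
  expect_error(demarcate_chps(pop, "A", 2020), "Population missing.*2020")
  expect_error(demarcate_chps(pop, "B", 2016), "region 'B'")
  bad <- tibble::tibble(region = "A", year = 2016, population = 0)
  expect_error(demarcate_chps(bad, "A", 2016), "strictly positive")
})

test_that("one-cycle update matches the hand arithmetic of the equations", {
  counts <- fix$census$count
  p <- fix$transitions$probability
  nxt <- step_census(census_from_counts(counts), fix$transitions)
  # brute-force oracle over all 11 categories
  expect_equal(nxt$count, oracle_step(counts, p), tolerance = 1e-12)
  # frozen hand values: HCB = 158 - 158*0.028 + 903*0.033
  expect_equal(nxt$count[3], 183.375)
  # PHB = 49 - 49*0.129 + 96*0.167
  expect_equal(nxt$count[6], 58.711)
  # top category only accumulates: EsTH = 2 + 2*0.001
  expect_equal(nxt$count[11], 2.002)
})

test_that("zero probabilities make the update an identity; construction adds on top", {
  counts <- fix$census$count
  tp0 <- tp_from_p(rep(0, 10))
  expect_equal(step_census(census_from_counts(counts), tp0)$count, counts)
  cons <- census_from_counts(c(5, rep(0, 10)))
  with_cons <- step_census(census_from_counts(counts), tp0,
                           construction = cons)
  expect_equal(with_cons$count[1], counts[1] + 5)
})

test_that("invalid inputs to the update are rejected", {
  counts <- fix$census$count
  counts[2] <- -1
  expect_error(step_census(census_from_counts(counts), fix$transitions),
               "non-negative")
  expect_error(step_census(census_from_counts(fix$census$count),
                           tp_from_p(c(1.2, rep(0, 9)))),
               "\\[0, 1\\]")
  short <- census_from_counts(fix$census$count)[1:5, ]
  expect_error(step_census(short, fix$transitions), "all 11 categories")
})

test_that("project validates horizon and region coverage", {
  expect_error(project(fix$census, fix$transitions, horizon = 0),
               "horizon")
  expect_error(project(fix$census, fix$transitions, horizon = 2.5),
               "horizon")
  cons <- tibble::tibble(region = "Nowhere", category = "CHPS",
                         year = 2017, count = 1)
  expect_error(project(fix$census, fix$transitions, construction = cons),
               "absent from the baseline")
})

test_that("total facilities are conserved without construction or population feed", {
  proj <- project(fix$census, fix$transitions, horizon = 10)
  totals <- tapply(proj$count, proj$year, sum)
  expect_equal(as.numeric(totals), rep(5749, 11), tolerance = 1e-9)
})

test_that("projection is linear: a region partition sums to the whole", {
  half <- fix$census
  half$count <- half$count / 2
  two <- dplyr::bind_rows(dplyr::mutate(half, region = "North"),
                          dplyr::mutate(half, region = "South"))
  p2 <- project(two, fix$transitions, horizon = 5)
  p1 <- project(fix$census, fix$transitions, horizon = 5)
  nat2 <- p2 |>
    dplyr::group_by(category, year) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    dplyr::arrange(year, category)
  nat1 <- tibble::as_tibble(p1) |>
    dplyr::select(category, year, count) |>
    dplyr::arrange(year, category)
  expect_equal(nat2$count, nat1$count, tolerance = 1e-12)
})

test_that("the absorbing top category never decreases and counts stay non-negative", {
  withr::with_seed(11, {
    for (i in 1:20) {
      counts <- runif(11, 0, 500)
      p <- runif(10)
      proj <- project(census_from_counts(counts), tp_from_p(p), horizon = 8)
      expect_true(all(proj$count >= 0))
      esth <- proj$count[as.character(proj$category) == "EsTH"]
      expect_true(all(diff(esth[order(unique(proj$year))]) >= -1e-12))
    }
  })
})

test_that("population mode pins the CHPS stock to population / divisor each year", {
  pop <- tibble::tibble(region = "Ghana", year = 2017:2018,
                        population = c(3000000, 3300000))
  proj <- project(fix$census, fix$transitions, population = pop, horizon = 2)
  expect_equal(counts_of(proj, "CHPS", 2017), 2000)
  expect_equal(counts_of(proj, "CHPS", 2018), 2200)
  # other categories still follow the Markov update off the pinned CHPS stock
  expect_equal(counts_of(proj, "HCA", 2018),
               counts_of(proj, "HCA", 2017) * (1 - 0.033) + 2000 * 0.010,
               tolerance = 1e-12)
  # population mode requires coverage of every projected year
  expect_error(project(fix$census, fix$transitions, population = pop,
                       horizon = 5), "Population missing")
})

test_that("newly built facilities enter the census in their year and transition the next", {
  tp <- tp_from_p(c(0.5, rep(0, 9)))  # CHPS -> HCA at 0.5, rest frozen
  base <- census_from_counts(c(100, rep(0, 10)))
  cons <- tibble::tibble(region = "Ghana", category = "CHPS",
                         year = 2017, count = 10)
  proj <- project(base, tp, construction = cons, horizon = 2)
  expect_equal(counts_of(proj, "CHPS", 2017), 100 * 0.5 + 10)
  # the 10 new CHPS are at risk in the 2017 -> 2018 cycle
  expect_equal(counts_of(proj, "HCA", 2018), 50 + 60 * 0.5)
})

test_that("annual flows are origin counts times probabilities, summed over regions", {
  proj <- project(fix$census, fix$transitions, horizon = 1)
  fl <- transition_flows(proj)
  y0 <- fl[fl$year == 2016, ]
  expect_equal(y0$flow[as.character(y0$from_category) == "PHA"], 96 * 0.167)
  expect_equal(y0$flow[as.character(y0$from_category) == "PHC"], 29 * 0.084)
  # a zero origin count yields a zero flow
  empty <- project(census_from_counts(rep(0, 11)), fix$transitions,
                   horizon = 1)
  expect_true(all(transition_flows(empty)$flow == 0))
  # totals equal the sum over years, pair by pair
  tot <- flow_totals(fl)
  expect_equal(tot$total,
               tapply(fl$flow, as.character(fl$from_category), sum)[
                 as.character(tot$from_category)] |> as.numeric())
})
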