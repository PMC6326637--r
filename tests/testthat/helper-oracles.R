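# Independent oracles used to cross-check the vectorised engine.

# Literal per-category arithmetic following the printed update equations,
# one explicit term at a time (no vector tricks shared with the engine).
oracle_step <- function(counts, p, cons = rep(0, 11), chps_next = NULL) {
  nxt <- numeric(11)
  for (r in seq_len(11)) {
    outflow <- if (r < 11) counts[r] * p[r] else 0 # top category absorbs
    inflow <- if (r > 1) counts[r - 1] * p[r - 1] else 0
    nxt[r] <- counts[r] - outflow + inflow + cons[r]
  }
  if (!is.null(chps_next)) nxt[1] <- chps_next
  nxt
}

# census tibble from a plain count vector in ladder order
census_from_counts <- function(counts, region = "Ghana") {
  tibble::tibble(region = region,
                 category = hwforecast::as_category(hwforecast::facility_categories()),
                 count = counts)
}

# transition table from a plain length-10 probability vector
tp_from_p <- function(p, se = rep(0, 10)) {
  dplyr::mutate(hwforecast::adjacent_pairs(),
                probability = p, standard_error = se)
}

# a small panel built record-by-record: n facilities sit in `from` for one
# interval, the first n_events of them move up one rung
panel_one_pair <- function(from, to, n, n_events, start_year = 2011) {
  tibble::tibble(
    facility_id = rep(sprintf("F%03d", seq_len(n)), each = 2),
    year = rep(c(start_year, start_year + 1), times = n),
    category = as.vector(vapply(seq_len(n), function(i) {
      c(from, if (i <= n_events) to else from)
    }, character(2))))
}

counts_of <- function(census_df, cat, yr) {
  sum(census_df$count[as.character(census_df$category) == cat &
                        census_df$year == yr])
}
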