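## Schema validators. Each checks one of the canonical long-format tables and
## aborts with a message naming the offending column/cell; all pipeline entry
## points call these so malformed CSVs fail early with a usable message.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}

validate_census <- function(census, what = "facility census") {
  require_columns(census, c("region", "category", "count"), what)
  category_rank(as.character(census$category))
  if (any(!is.finite(census$count)) || any(census$count < 0)) {
    abort(paste0(what, ": `count` must be finite and non-negative"))
  }
  invisible(census)
}

validate_transitions <- function(tp, what = "transition table") {
  require_columns(tp, c("from_category", "to_category", "probability",
                        "standard_error"), what)
  pairs <- adjacent_pairs()
  key <- paste(tp$from_category, tp$to_category)
  expected <- paste(pairs$from_category, pairs$to_category)
  if (anyDuplicated(key)) abort(paste0(what, ": duplicated category pair"))
  missing <- setdiff(expected, key)
  if (length(missing) > 0) {
    abort(paste0(what, ": missing adjacent pair(s): ",
                 paste(missing, collapse = "; ")))
  }
  extra <- setdiff(key, expected)
  if (length(extra) > 0) {
    abort(paste0(what, ": non-adjacent pair(s) not allowed: ",
                 paste(extra, collapse = "; ")))
  }
  if (any(!is.finite(tp$probability)) ||
      any(tp$probability < 0) || any(tp$probability > 1)) {
    abort(paste0(what, ": `probability` must lie in [0, 1]"))
  }
  if (any(!is.finite(tp$standard_error)) || any(tp$standard_error < 0)) {
    abort(paste0(what, ": `standard_error` must be non-negative"))
  }
  invisible(tp)
}

validate_construction <- function(cons, what = "construction schedule") {
  require_columns(cons, c("region", "category", "year", "count"), what)
  category_rank(as.character(cons$category))
  if (any(!is.finite(cons$count)) || any(cons$count < 0)) {
    abort(paste0(what, ": `count` must be finite and non-negative"))
  }
  invisible(cons)
}

validate_population <- function(pop, what = "population series") {
  require_columns(pop, c("region", "year", "population"), what)
  if (any(!is.finite(pop$population)) || any(pop$population <= 0)) {
    abort(paste0(what, ": `population` must be finite and strictly positive"))
  }
  if (anyDuplicated(paste(pop$region, pop$year))) {
    abort(paste0(what, ": duplicated (region, year) cell"))
  }
  invisible(pop)
}

validate_norms <- function(norms, what = "staffing norms") {
  require_columns(norms, c("staff_type", "category", "headcount"), what)
  category_rank(as.character(norms$category))
  if (any(!is.finite(norms$headcount)) || any(norms$headcount < 0)) {
    abort(paste0(what, ": `headcount` must be finite and non-negative"))
  }
  # every staff type must define a value for every category
  tab <- table(norms$staff_type)
  if (any(tab != 11)) {
    bad <- names(tab)[tab != 11]
    abort(paste0(what, ": staff type(s) without all 11 categories: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(norms)
}

validate_roster <- function(roster, what = "employment roster") {
  require_columns(roster, c("staff_type", "employed"), what)
  if (any(!is.finite(roster$employed)) || any(roster$employed < 0)) {
    abort(paste0(what, ": `employed` must be non-negative"))
  }
  invisible(roster)
}

validate_panel <- function(panel, what = "facility panel") {
  require_columns(panel, c("facility_id", "year", "category"), what)
  category_rank(as.character(panel$category))
  # integer-coded key: avoids string collation on large panels
  fcode <- match(panel$facility_id, unique(panel$facility_id))
  years <- sort(unique(panel$year))
  key <- (fcode - 1) * length(years) + match(panel$year, years)
  if (anyDuplicated(key)) {
    abort(paste0(what, ": duplicated (facility_id, year) record"))
  }
  invisible(panel)
}
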