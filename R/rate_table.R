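#' Lexis-style mortality rate table
#'
#' A `rate_table` holds death counts and person-years on an age-group by
#' calendar-year grid. Age groups are closed, contiguous, equal-width
#' integer-year intervals (canonically 5-year groups such as 20--24, ...,
#' 80--84); open-ended intervals such as "85+" are rejected because the
#' additive APC decomposition has no cohort diagonal for them.
#'
#' @param deaths integer matrix of death counts, one row per age group,
#'   one column per period; all entries `>= 0`.
#' @param population matrix of person-years, same shape; all entries `> 0`
#'   and no cell may hold fewer person-years than deaths.
#' @param age_start integer vector of lower interval bounds, ascending.
#' @param age_end integer vector of upper bounds; defaults to the
#'   contiguous completion `age_start + width - 1` when `age_start` has
#'   more than one element.
#' @param years integer vector of calendar years, ascending, one per
#'   column of `deaths`.
#' @return An object of class `rate_table`.
#' @examples
#' tab <- rate_table(deaths = matrix(0, 1, 1),
#'                   population = matrix(1000, 1, 1),
#'                   age_start = 20, age_end = 24, years = 2000)
#' compute_rates(tab)
#' @export
rate_table <- function(deaths, population, age_start, age_end = NULL, years) {
  deaths <- as.matrix(deaths)
  population <- as.matrix(population)
  age_start <- as.integer(age_start)
  years <- as.integer(years)

  if (is.null(age_end)) {
    if (length(age_start) < 2L)
      abort_validation("age_end must be given for a single age group")
    w <- diff(age_start)[1]
    age_end <- age_start + w - 1L
  }
  age_end <- as.integer(age_end)

  if (anyNA(age_start) || anyNA(age_end))
    abort_validation(paste(
      "open-ended or incomplete age intervals are not supported:",
      "every age group needs finite start and end years",
      "(the APC model cannot place an open-ended group on a cohort diagonal)"),
      subclass = "apcie_open_ended_error")
  if (length(age_end) != length(age_start))
    abort_validation("age_start and age_end lengths differ")
  if (any(age_end < age_start))
    abort_validation("age_end must be >= age_start for every interval")

  widths <- age_end - age_start + 1L
  if (length(unique(widths)) != 1L)
    abort_validation("age intervals must all have the same width")
  if (length(age_start) > 1L &&
      any(age_start[-1] != age_end[-length(age_end)] + 1L))
    abort_validation("age intervals must be contiguous and ascending")
  if (anyNA(years) || (length(years) > 1L && any(diff(years) <= 0)))
    abort_validation("years must be distinct and ascending")

  A <- length(age_start)
  P <- length(years)
  if (!all(dim(deaths) == c(A, P)) || !all(dim(population) == c(A, P)))
    abort_validation(sprintf(
      "deaths and population must both be %d x %d matrices", A, P))
  if (anyNA(deaths) || anyNA(population))
    abort_validation("deaths and population must not contain missing values")
  if (any(abs(deaths - round(deaths)) > 1e-9) || any(deaths < 0))
    abort_validation("deaths must be nonnegative integers")
  if (any(population <= 0))
    abort_validation("population person-years must be strictly positive")
  if (any(deaths > population))
    abort_validation("deaths may not exceed population in any cell")

  deaths <- round(deaths)
  lab <- paste0(age_start, "-", age_end)
  dimnames(deaths) <- dimnames(population) <- list(lab, years)

  structure(
    list(age_start = age_start, age_end = age_end, years = years,
         deaths = deaths, population = population),
    class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("rate_table: %d age groups (%s) x %d periods (%s-%s)\n",
              n_age(x), paste0(x$age_start[1], "-", x$age_end[n_age(x)]),
              n_period(x), min(x$years), max(x$years)))
  cat(sprintf("  total deaths %s over %s person-years\n",
              format(sum(x$deaths), big.mark = ","),
              format(sum(x$population), big.mark = ",")))
  invisible(x)
}

#' @rdname rate_table
#' @param table a `rate_table`.
#' @export
n_age <- function(table) length(table$age_start)

#' @rdname rate_table
#' @export
n_period <- function(table) length(table$years)

#' @rdname rate_table
#' @export
age_width <- function(table) table$age_end[1] - table$age_start[1] + 1L

age_labels <- function(table) paste0(table$age_start, "-", table$age_end)

#' Read a long-format rate table from CSV
#'
#' Expects columns `age_start`, `age_end`, `year`, `deaths`, `population`,
#' one row per (age group, year) cell. The grid must be complete: a
#' missing (age, year) combination is a structural error naming the gap.
#' A blank or missing `age_end` marks an open-ended group (e.g. 85+) and
#' is rejected.
#'
#' @param file path to a CSV file (or a connection).
#' @return A validated [rate_table()], rows sorted into the canonical
#'   age-ascending, year-ascending grid.
#' @export
read_rate_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("age_start", "age_end", "year", "deaths", "population")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort_validation(paste("missing required columns:",
                           paste(missing_cols, collapse = ", ")),
                     subclass = "apcie_parse_error")

  age_end_num <- suppressWarnings(as.numeric(df$age_end))
  if (anyNA(age_end_num))
    abort_validation(paste(
      "open-ended age group in input (blank or non-numeric age_end,",
      "e.g. an '85+' row); drop open-ended groups before modelling"),
      subclass = "apcie_open_ended_error")
  df$age_end <- age_end_num

  ages <- sort(unique(df$age_start))
  yrs <- sort(unique(df$year))
  key <- paste(df$age_start, df$year, sep = ", ")
  want <- as.vector(outer(ages, yrs, paste, sep = ", "))
  gap <- setdiff(want, key)
  if (length(gap))
    abort_validation(sprintf(
      "incomplete grid: no row for (age_start, year) = (%s)", gap[1]),
      subclass = "apcie_structural_error")
  if (anyDuplicated(key))
    abort_validation(sprintf("duplicate row for (age_start, year) = (%s)",
                             key[anyDuplicated(key)]),
                     subclass = "apcie_structural_error")

  df <- df[order(df$age_start, df$year), , drop = FALSE]
  A <- length(ages); P <- length(yrs)
  ends <- vapply(ages, function(a) df$age_end[match(a, df$age_start)], 0)
  rate_table(
    deaths = matrix(df$deaths, A, P, byrow = TRUE),
    population = matrix(df$population, A, P, byrow = TRUE),
    age_start = ages, age_end = ends, years = yrs)
}

#' Write a rate table as canonical long CSV
#'
#' Inverse of [read_rate_table()]: columns `age_start`, `age_end`, `year`,
#' `deaths`, `population`, age-major row order.
#'
#' @param table a `rate_table`.
#' @param file output path.
#' @export
write_rate_table <- function(table, file) {
  df <- as.data.frame(table)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
as.data.frame.rate_table <- function(x, ...) {
  A <- n_age(x); P <- n_period(x)
  data.frame(
    age_start = rep(x$age_start, each = P),
    age_end = rep(x$age_end, each = P),
    year = rep(x$years, times = A),
    deaths = as.vector(t(x$deaths)),
    population = as.vector(t(x$population)))
}

#' Retain only periods on a regular sampling grid
#'
#' Implements the single-year-data-five-years-apart sampling rule: keep
#' the years `start_year, start_year + step, ...` so that, when `step`
#' equals the age-interval width, each table diagonal is a true
#' single-width birth cohort rather than a double-width moving average.
#'
#' @param table a `rate_table`.
#' @param start_year first year to retain; must be present in `table`.
#' @param step spacing in years between retained periods.
#' @return A `rate_table` restricted to the sampled years.
#' @export
subsample_periods <- function(table, start_year, step) {
  stopifnot(inherits(table, "rate_table"))
  if (!start_year %in% table$years)
    abort_validation(sprintf("start_year %d not present in table", start_year),
                     subclass = "apcie_lookup_error")
  if (step < 1) abort_validation("step must be a positive number of years")
  want <- seq.int(start_year, max(table$years), by = step)
  absent <- setdiff(want, table$years)
  if (length(absent))
    abort_validation(sprintf("sampled year %d not present in table", absent[1]),
                     subclass = "apcie_lookup_error")
  if (length(want) < 2L)
    abort_validation("fewer than 2 periods retained; no trend is estimable")
  keep <- match(want, table$years)
  rate_table(table$deaths[, keep, drop = FALSE],
             table$population[, keep, drop = FALSE],
             age_start = table$age_start, age_end = table$age_end,
             years = want)
}

#' Cohort diagonal layout of an age-period grid
#'
#' Index algebra mapping cells (age i, period j) of an A x P grid to the
#' C = A + P - 1 birth-cohort diagonals, with i = 1 the youngest age
#' group and j = 1 the earliest period: k = (A - i) + j. Birth-year
#' labels are back-dated from the earliest period and the oldest age
#' interval, e.g. year 1990 - age 84 = birth year 1906 and
#' 1990 - 80 = 1910, giving cohort 1 the label 1906--1910.
#'
#' @param n_age number of age groups (A).
#' @param n_period number of modelled periods (P).
#' @param period_step years between modelled periods; equal to the age
#'   width for true single-width cohorts.
#' @param earliest_period first modelled calendar year (for labels).
#' @param oldest_age length-2 vector `c(start, end)` of the oldest age
#'   interval (for labels).
#' @return An object of class `cohort_layout` with `n_cohort` and, when
#'   label inputs are supplied, `cohort_labels` ascending with k.
#' @examples
#' lay <- cohort_layout(13, 6, period_step = 5,
#'                      earliest_period = 1990, oldest_age = c(80, 84))
#' cohort_label(lay, 1)   # 1906 1910
#' cohort_label(lay, 18)  # 1991 1995
#' @export
cohort_layout <- function(n_age, n_period, period_step = 5L,
                          earliest_period = NULL, oldest_age = NULL) {
  if (n_age < 1 || n_period < 1)
    abort_validation("n_age and n_period must be >= 1")
  C <- n_age + n_period - 1L
  labels <- NULL
  if (!is.null(earliest_period) && !is.null(oldest_age)) {
    k <- seq_len(C)
    lo <- earliest_period - oldest_age[2] + period_step * (k - 1)
    hi <- earliest_period - oldest_age[1] + period_step * (k - 1)
    labels <- paste0(lo, "-", hi)
  }
  structure(
    list(n_age = as.integer(n_age), n_period = as.integer(n_period),
         n_cohort = as.integer(C), period_step = as.integer(period_step),
         earliest_period = earliest_period, oldest_age = oldest_age,
         cohort_labels = labels),
    class = "cohort_layout")
}

layout_from_table <- function(table) {
  A <- n_age(table)
  cohort_layout(A, n_period(table),
                period_step = if (n_period(table) > 1)
                  diff(table$years)[1] else age_width(table),
                earliest_period = min(table$years),
                oldest_age = c(table$age_start[A], table$age_end[A]))
}

#' Cohort index of a grid cell
#'
#' @param n_age number of age groups A.
#' @param i age-group index, 1 = youngest.
#' @param j period index, 1 = earliest.
#' @return k = (A - i) + j, in 1..(A + P - 1).
#' @export
cohort_index <- function(n_age, i, j) (n_age - i) + j

#' Birth-year range of a cohort diagonal
#'
#' @param layout a [cohort_layout()] built with `earliest_period` and
#'   `oldest_age`.
#' @param k cohort index in 1..C (1 = oldest cohort).
#' @return Integer vector `c(from, to)` of birth years.
#' @export
cohort_label <- function(layout, k) {
  stopifnot(inherits(layout, "cohort_layout"))
  if (length(k) != 1L || is.na(k) || k < 1 || k > layout$n_cohort)
    abort_validation(sprintf("cohort index k = %s out of range 1..%d",
                             as.character(k), layout$n_cohort),
                     subclass = "apcie_lookup_error")
  if (is.null(layout$earliest_period) || is.null(layout$oldest_age))
    abort_validation("layout carries no label anchors")
  lo <- layout$earliest_period - layout$oldest_age[2] +
    layout$period_step * (k - 1)
  hi <- layout$earliest_period - layout$oldest_age[1] +
    layout$period_step * (k - 1)
  c(from = lo, to = hi)
}

#' Age-specific mortality rates
#'
#' @param table a `rate_table`.
#' @param scale persons at risk the rate refers to; default 100,000.
#' @return Matrix `scale * deaths / population`, same shape as `deaths`.
#' @export
compute_rates <- function(table, scale = 1e5) {
  stopifnot(inherits(table, "rate_table"))
  if (scale <= 0) abort_validation("scale must be positive")
  scale * table$deaths / table$population
}

#' Crude all-age mortality rate for one year
#'
#' @inheritParams compute_rates
#' @param year calendar year present in the table.
#' @return `scale * sum(deaths) / sum(population)` over all age groups.
#' @export
aggregate_rate <- function(table, year, scale = 1e5) {
  stopifnot(inherits(table, "rate_table"))
  j <- match(year, table$years)
  if (is.na(j))
    abort_validation(sprintf("year %s not present in table", year),
                     subclass = "apcie_lookup_error")
  scale * sum(table$deaths[, j]) / sum(table$population[, j])
}

#' Fold change between two rates
#'
#' @param rate_a baseline rate, must be positive.
#' @param rate_b comparison rate.
#' @return `rate_b / rate_a` (e.g. 12.07 / 6.83 = 1.77 to 2 decimals).
#' @export
fold_change <- function(rate_a, rate_b) {
  if (!is.finite(rate_a) || rate_a <= 0)
    abort_validation("fold change is undefined for a non-positive baseline rate")
  rate_b / rate_a
}
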