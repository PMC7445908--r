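test_that("rate_table validates its invariants", {
  # minimal well-formed table
  tab <- rate_table(matrix(0, 1, 1), matrix(1000, 1, 1),
                    age_start = 20, age_end = 24, years = 2000)
  expect_s3_class(tab, "rate_table")
  expect_equal(compute_rates(tab)[1, 1], 0)

  ok_d <- matrix(1:4, 2, 2); ok_n <- matrix(1e5, 2, 2)
  expect_error(rate_table(ok_d, matrix(c(1e5, 0, 1e5, 1e5), 2, 2),
                          age_start = c(20, 25), years = c(1990, 1995)),
               class = "apcie_validation_error")
  expect_error(rate_table(matrix(c(1.5, 1, 1, 1), 2, 2), ok_n,
                          age_start = c(20, 25), years = c(1990, 1995)),
               class = "apcie_validation_error")
  expect_error(rate_table(matrix(2e5, 2, 2), ok_n,
                          age_start = c(20, 25), years = c(1990, 1995)),
               class = "apcie_validation_error")
  # non-contiguous and unequal-width age intervals
  expect_error(rate_table(ok_d, ok_n, age_start = c(20, 30),
                          age_end = c(24, 34), years = c(1990, 1995)),
               class = "apcie_validation_error")
  expect_error(rate_table(ok_d, ok_n, age_start = c(20, 25),
                          age_end = c(24, 34), years = c(1990, 1995)),
               class = "apcie_validation_error")
  # open-ended interval
  expect_error(rate_table(ok_d, ok_n, age_start = c(20, 25),
                          age_end = c(24, NA), years = c(1990, 1995)),
               class = "apcie_open_ended_error")
})

test_that("CSV round trip is the identity on canonical tables", {
  cfg <- sim_config(A = 4, P = 6, first_year = 1990, year_step = 5,
                    populations = 123456.789, seed = 3)
  tab <- simulate_table(make_true_params(cfg), cfg)
  f <- write_temp_csv(tab)
  back <- read_rate_table(f)
  expect_identical(unname(back$deaths), unname(tab$deaths))
  expect_equal(unname(back$population), unname(tab$population),
               tolerance = 1e-9)
  expect_identical(back$age_start, tab$age_start)
  expect_identical(back$years, tab$years)
})

test_that("reader rejects open-ended groups and incomplete grids", {
  tab <- small_table()
  df <- as.data.frame(tab)

  f1 <- tempfile(fileext = ".csv")
  df1 <- rbind(df, data.frame(age_start = 85, age_end = NA, year = 1990,
                              deaths = 1, population = 1000))
  write.csv(df1, f1, row.names = FALSE)
  expect_error(read_rate_table(f1), class = "apcie_open_ended_error")

  f2 <- tempfile(fileext = ".csv")
  write.csv(df[-2, ], f2, row.names = FALSE)
  err <- expect_error(read_rate_table(f2), class = "apcie_structural_error")
  expect_match(conditionMessage(err), "50, 1995")

  f3 <- tempfile(fileext = ".csv")
  df3 <- df; df3$deaths[1] <- 2.5
  write.csv(df3, f3, row.names = FALSE)
  expect_error(read_rate_table(f3), class = "apcie_validation_error")
})

test_that("a 13-age by 26-year CSV reads into the study layout", {
  cfg <- sim_config(emulate_study = TRUE, seed = 5)
  tab <- simulate_table(make_true_params(cfg), cfg)
  f <- write_temp_csv(tab)
  back <- read_rate_table(f)
  expect_equal(n_age(back), 13)
  expect_equal(n_period(back), 26)
  expect_equal(back$age_start[1], 20)
  expect_equal(back$age_end[13], 84)
})

test_that("period subsampling implements the five-years-apart rule", {
  cfg <- sim_config(A = 3, P = 26, first_year = 1990, year_step = 1, seed = 2)
  tab <- simulate_table(make_true_params(cfg), cfg)

  sub5 <- subsample_periods(tab, 1990, 5)
  expect_equal(sub5$years, seq(1990, 2015, 5))
  expect_equal(n_period(sub5), 6)
  expect_equal(sub5$deaths[, "1995"], tab$deaths[, "1995"])

  sub25 <- subsample_periods(tab, 1990, 25)
  expect_equal(sub25$years, c(1990, 2015))

  cfg2 <- sim_config(A = 3, P = 2, first_year = 1990, year_step = 1, seed = 2)
  tab2 <- simulate_table(make_true_params(cfg2), cfg2)
  expect_error(subsample_periods(tab2, 1990, 5),
               class = "apcie_validation_error")
  expect_error(subsample_periods(tab, 1989, 5), class = "apcie_lookup_error")
})

test_that("cohort indexing covers exactly A+P-1 diagonals with shared labels", {
  for (A in 1:20) {
    for (P in 1:20) {
      i <- rep(seq_len(A), each = P)
      j <- rep(seq_len(P), times = A)
      k <- cohort_index(A, i, j)
      expect_identical(sort(unique(k)), seq_len(A + P - 1L))
      # all cells on one diagonal share i + k - j = A
      expect_true(all(i + k - j == A))
    }
  }
  expect_equal(cohort_layout(13, 6)$n_cohort, 18)
})

test_that("cohort labels back-date birth years from the oldest age group", {
  lay <- cohort_layout(13, 6, period_step = 5, earliest_period = 1990,
                       oldest_age = c(80, 84))
  expect_equal(unname(cohort_label(lay, 1)), c(1906, 1910))
  expect_equal(unname(cohort_label(lay, 18)), c(1991, 1995))
  expect_error(cohort_label(lay, 19), class = "apcie_lookup_error")
  expect_error(cohort_label(lay, 0), class = "apcie_lookup_error")

  lay1 <- cohort_layout(1, 1, period_step = 5, earliest_period = 2000,
                        oldest_age = c(20, 24))
  expect_equal(unname(cohort_label(lay1, 1)), c(1976, 1980))
  # labels ascend with k
  labs <- vapply(1:18, function(k) cohort_label(lay, k)[1], 0)
  expect_true(all(diff(labs) == 5))
})

test_that("rates, crude aggregation and fold change follow their definitions", {
  tab <- rate_table(matrix(c(5, 12), 1, 2), matrix(c(1e5, 2e5), 1, 2),
                    age_start = 40, age_end = 44, years = c(1990, 1995))
  expect_equal(unname(compute_rates(tab)[1, ]), c(5, 6))

  tab2 <- rate_table(matrix(c(1, 3), 2, 1), matrix(1e5, 2, 1),
                     age_start = c(40, 45), years = 1990)
  expect_equal(aggregate_rate(tab2, 1990), 2)
  # degenerate single-age aggregation equals the cell rate
  expect_equal(aggregate_rate(tab, 1990), compute_rates(tab)[1, 1])
  expect_error(aggregate_rate(tab, 1991), class = "apcie_lookup_error")

  expect_equal(round(fold_change(6.83, 12.07), 2), 1.77)
  expect_equal(fold_change(3.7, 3.7), 1)
  expect_equal(fold_change(2, 5), 2.5)
  expect_error(fold_change(0, 5), class = "apcie_validation_error")
})
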