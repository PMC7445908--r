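test_that("poisson deviance matches hand arithmetic including the zero branch", {
  expect_equal(poisson_deviance(c(3, 0, 7), c(3, 0.5, 7)), 1)
  expect_equal(poisson_deviance(5, 5), 0)
  expect_equal(poisson_deviance(0, 2), 4)
  expect_equal(poisson_deviance(3, 2), 2 * (3 * log(1.5) - 1))
  expect_error(poisson_deviance(-1, 2), class = "apcie_validation_error")
  expect_error(poisson_deviance(c(1, 2), 2), class = "apcie_dimension_error")
})

test_that("information criteria follow the deviance-minus-df*log(n) convention", {
  ic <- information_criteria(1.246, log_lik = NA, n_obs = 78, model_rank = 34)
  expect_equal(ic$bic, 1.246 - 44 * log(78))
  expect_equal(information_criteria(0, NA, 11, 10)$bic, -log(11))
  expect_equal(information_criteria(2.5, NA, 1, 0)$bic, 2.5)
  # aic_per_obs = (-2 logLik + 2 (rank+1)) / n
  expect_equal(information_criteria(1, -10, 10, 4)$aic_per_obs, 3)
  expect_error(information_criteria(1, -10, 10, 10),
               class = "apcie_dimension_error")
})

test_that("a null-structure table is recovered as a pure intercept model", {
  cfg <- sim_config(A = 5, P = 4, populations = 1e9, intercept = log(1e-4),
                    effect_scale = 0, seed = 11)
  tp <- make_true_params(cfg)
  expect_true(all(unlist(tp[c("age_effects", "period_effects",
                              "cohort_effects")]) == 0))
  fit <- fit_ie(simulate_table(tp, cfg))
  expect_lt(max(abs(all_effects(fit))), 0.01)
  expect_lt(abs(fit$intercept - log(1e-4)), 0.01)
})

test_that("fit refuses tables whose period spacing mismatches the age width", {
  cfg <- sim_config(A = 3, P = 26, first_year = 1990, year_step = 1, seed = 4)
  tab <- simulate_table(make_true_params(cfg), cfg)
  expect_error(fit_ie(tab), class = "apcie_validation_error")
  expect_s3_class(fit_ie(subsample_periods(tab, 1990, 5)), "apc_fit")
})

test_that("IE equals the penalized-likelihood oracle on a small grid", {
  tab <- small_table()
  fit <- fit_ie(tab)
  des <- fit$design
  b0 <- fit$b0_used
  D <- as.vector(t(tab$deaths))
  N <- as.vector(t(tab$population))

  # independent route: maximize the Poisson likelihood with a quadratic
  # penalty on the null-direction component; the likelihood is flat
  # along b0 so any positive penalty weight selects the IE solution
  nll <- function(theta) {
    lam <- exp(des$X %*% theta + log(N))
    sum(lam - D * (des$X %*% theta + log(N))) + 1e4 * sum(theta * b0)^2
  }
  grad <- function(theta) {
    lam <- exp(des$X %*% theta + log(N))
    as.vector(t(des$X) %*% (lam - D)) + 2e4 * sum(theta * b0) * b0
  }
  start <- c(log(sum(D) / sum(N)), rep(0, des$q - 1))
  opt <- optim(start, nll, grad, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(max(abs(opt$par - unname(fit$coefficients))), 1e-5)
})

test_that("fit object satisfies its structural invariants on the study layout", {
  cfg <- sim_config(emulate_study = TRUE, seed = 8)
  tab <- subsample_periods(simulate_table(make_true_params(cfg), cfg), 1990, 5)
  fit <- fit_ie(tab)

  expect_equal(fit$n_obs, 78)
  expect_equal(fit$model_rank, 34)
  expect_true(fit$converged)
  expect_lt(abs(sum(fit$age_effects)), 1e-8)
  expect_lt(abs(sum(fit$period_effects)), 1e-8)
  expect_lt(abs(sum(fit$cohort_effects)), 1e-8)
  expect_lt(abs(sum(fit$coefficients * fit$b0_used)), 1e-8)
  expect_lt(abs(sum(fit$fitted_deaths) - sum(tab$deaths)) / sum(tab$deaths),
            1e-6)

  et <- effects_table(fit)
  expect_equal(nrow(et), 37)
  expect_equal(et$label[et$dimension == "cohort"][1], "1906-1910")
  expect_equal(tail(et$label, 1), "1991-1995")
  # deviance agrees with the GLM-family computation as a cross-check
  expect_equal(fit$deviance,
               sum(poisson()$dev.resids(fit$observed_deaths,
                                        fit$fitted_deaths,
                                        rep(1, fit$n_obs))),
               tolerance = 1e-8)
})
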