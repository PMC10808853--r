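test_that("noise-free data recover the identity curve with zero variance", {
  des <- two_level_design(2)
  comp <- variance_components(c("repeatability", "block", "F1", "F2"),
                              rep(0, 4), rep(0, 4))
  spec <- simulation_spec(des, known_x = c(1, 5, 10), p = 1,
                          curve = mean_curve(0, 1), components = comp)
  d <- simulate_study(spec, seed = 3)
  fit <- suppressWarnings(fit_uncertainty_model(d))
  expect_equal(fit$curve$alpha, 0, tolerance = 1e-4)
  expect_equal(fit$curve$beta, 1, tolerance = 1e-4)
  prof <- precision_profile(fit)
  expect_lt(prof$C + prof$P, 1e-6)
})

test_that("single-level reduction: total variance equals the sample variance", {
  # one concentration, one observation per block: every component is
  # confounded into a single dispersion parameter, whose REML estimate
  # must equal the classical unbiased sample variance
  set.seed(11)
  d <- validation_data(data.frame(block = sprintf("b%02d", 1:12),
                                  known_x = 5,
                                  y = rnorm(12, 5, 0.7)))
  fit <- suppressWarnings(fit_uncertainty_model(d))
  expect_equal(reproducibility_sd(fit, 5)^2, var(d$y), tolerance = 1e-5)
  expect_equal(fit$curve$alpha, mean(d$y), tolerance = 1e-6)
})

test_that("homoscedastic random-intercept case agrees with lme4 REML", {
  des <- data.frame(block = sprintf("%02d", 1:8))
  comp <- variance_components(c("repeatability", "block"),
                              c(0.25, 0.5), c(0, 0))
  spec <- simulation_spec(des, known_x = c(2, 4, 6, 8), p = 2,
                          curve = mean_curve(0.5, 1.1), components = comp)
  d <- simulate_study(spec, seed = 21)
  fit <- fit_uncertainty_model(d, variance_model = "constant")

  lfit <- lme4::lmer(y ~ known_x + (1 | block), data = as.data.frame(d),
                     REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$components$const_var[fit$components$term == "block"],
               vc$vcov[vc$grp == "block"], tolerance = 1e-3)
  expect_equal(fit$components$const_var[fit$components$term == "repeatability"],
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
  expect_equal(unname(fit$curve$alpha), unname(lme4::fixef(lfit)[1]),
               tolerance = 1e-4)
  expect_equal(unname(fit$curve$beta), unname(lme4::fixef(lfit)[2]),
               tolerance = 1e-4)
  expect_equal(unname(fit$loglik), unname(as.numeric(logLik(lfit))),
               tolerance = 1e-6)
})

test_that("rescaling data scales constant components by c^2, leaves proportional ones", {
  d <- toy_validation(n_blocks = 6, x = c(1, 4, 9), seed = 5)
  cfac <- 10
  d2 <- as.data.frame(d)
  d2$known_x <- d2$known_x * cfac
  d2$y <- d2$y * cfac
  d2 <- validation_data(d2, factors = "oper")
  f1 <- suppressWarnings(fit_uncertainty_model(d))
  f2 <- suppressWarnings(fit_uncertainty_model(d2))
  p1 <- precision_profile(f1); p2 <- precision_profile(f2)
  expect_equal(p2$C, cfac^2 * p1$C, tolerance = 1e-3)
  expect_equal(p2$P, p1$P, tolerance = 1e-3)
  expect_equal(f2$curve$alpha, cfac * f1$curve$alpha, tolerance = 1e-3)
  expect_equal(f2$curve$beta, f1$curve$beta, tolerance = 1e-4)
})

test_that("estimates are non-negative and the fit is deterministic", {
  fit <- ex_fit("clopidol_egg")
  expect_true(all(fit$components$const_var >= 0))
  expect_true(all(fit$components$prop_var >= 0))
  expect_true(fit$converged)
  expect_equal(fit$n_obs, 48)
  refit <- fit_uncertainty_model(validation_example("clopidol_egg"))
  expect_identical(refit$loglik, fit$loglik)
  expect_identical(refit$components$const_var, fit$components$const_var)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- data.frame(block = c("a", "a", "b", "b"), oper = "same",
                  known_x = c(1, 2, 1, 2), y = c(1, 2, 1.1, 2.1))
  vd <- validation_data(d, factors = "oper")
  expect_error(fit_uncertainty_model(vd), "single represented level")

  # aliased terms are confounded: warn, never silently misattribute
  d2 <- toy_validation(n_blocks = 4, x = c(1, 10))
  d2$twin <- d2$oper
  vd2 <- validation_data(as.data.frame(d2), factors = c("oper", "twin"))
  expect_warning(fit_uncertainty_model(vd2), "aliased")

  # a decreasing response cannot give an invertible mean curve
  d3 <- data.frame(block = rep(c("a", "b", "c", "d"), each = 2),
                   known_x = rep(c(1, 10), 4),
                   y = rep(c(10, 1), 4) + rnorm(8, 0, 0.01))
  expect_error(suppressWarnings(
    fit_uncertainty_model(validation_data(d3))), "not positive")
})
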