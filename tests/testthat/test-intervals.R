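test_that("standard and expanded uncertainty follow the variance function", {
  p2 <- ex2_profile()
  expect_equal(round(standard_uncertainty(p2, 4), 2), 0.59)
  expect_equal(round(expanded_uncertainty(p2, 4, k = 2), 2), 1.19)
  expect_equal(round(expanded_uncertainty(p2, 5.5, k = 2), 2), 1.62)
  expect_equal(expanded_uncertainty(p2, 3, k = 0), 0)
  zero <- precision_profile(variance_components("repeatability", 0, 0))
  expect_equal(standard_uncertainty(zero, 7), 0)
  x <- c(0.3, 1, 8)
  expect_equal(standard_uncertainty(p2, x)^2 - p2$C, p2$P * x^2,
               tolerance = 1e-12)
})

test_that("symmetric y +/- U intervals match the constant-RSD example", {
  iv <- symmetric_interval(c(10, 3), rsd = 0.35, k = 2)
  expect_equal(iv$lower, c(3, 0.9))
  expect_equal(iv$upper, c(17, 5.1))
  expect_equal(symmetric_interval(4, rsd = 0, k = 2)$lower, 4)
  expect_error(symmetric_interval(4), "exactly one")
  expect_error(symmetric_interval(4, rsd = 0.1, profile = ex2_profile()),
               "exactly one")
})

test_that("y +/- U is one-way inconsistent under constant RSD; inversion is mutual", {
  sym_rule <- function(y) symmetric_interval(y, rsd = 0.35, k = 2)
  cc <- consistency_check(3, 10, sym_rule)
  expect_equal(cc$interval_1, c(0.9, 5.1))
  expect_equal(cc$interval_2, c(3, 17))
  expect_false(cc$in_interval_1)
  expect_true(cc$in_interval_2)
  expect_true(cc$one_way)
  expect_false(cc$mutual)

  # the inverted interval is consistent with the prediction band it came
  # from: a measurand v is attributable from result ym exactly when ym is
  # a plausible measurement at v (f_L(v) <= ym <= f_U(v)), for every pair
  srel <- 0.4; k <- 2
  for (ym in c(0.5, 2, 7)) {
    iv <- closed_form_interval(ym, srel, k)
    for (v in c(0.3, 1, 2, 5, 9)) {
      in_interval <- v >= iv$yL && v <= iv$yU
      plausible <- (v - k * srel * v) <= ym && ym <= (v + k * srel * v)
      expect_identical(in_interval, plausible)
    }
  }
  expect_true(consistency_check(5, 5, sym_rule)$mutual)
})

test_that("a plausible larger measurand stays inside the asymmetric interval", {
  # the motivating failure of y +/- U: a 4 ug/kg result excludes 5.5
  # under the symmetric rule although 5.5 ug/kg samples can plausibly
  # measure as 4; the inverted interval keeps 5.5 inside
  prof <- ex2_profile()
  sym <- symmetric_interval(4, profile = prof, k = 2)
  expect_lt(sym$upper, 5.5)
  low_pred_55 <- 5.5 - expanded_uncertainty(prof, 5.5, 2)
  expect_lt(low_pred_55, 4)        # 5.5 predicts results down to 3.88
  rng <- prediction_range(mean_curve(0, 1), prof, k = 2)
  iv <- uncertainty_interval(4, rng)
  expect_true(5.5 >= iv$yL && 5.5 <= iv$yU)
})

test_that("closed-form constant-RSD interval and its edge cases", {
  iv <- closed_form_interval(100, 0.4, 2)
  expect_equal(iv$yL, 100 / 1.8)
  expect_equal(round(iv$yL), 56)
  expect_equal(iv$yU, 500)
  expect_false(iv$unbounded_high)

  unb <- closed_form_interval(10, 0.5, 2)   # k*sigma_rel = 1
  expect_true(unb$unbounded_high)
  expect_equal(unb$yU, Inf)
  expect_equal(unb$yL, 5)

  tiny <- closed_form_interval(10, 1e-9, 2)
  expect_equal(tiny$yL, 10, tolerance = 1e-7)
  expect_equal(tiny$yU, 10, tolerance = 1e-7)
  z <- closed_form_interval(0, 0.4, 2)
  expect_equal(c(z$yL, z$yU), c(0, 0))
})

test_that("lognormal interval: multiplicative factor and small-sigma limit", {
  iv <- lognormal_interval(1, 0.25, 2)
  expect_equal(iv$yU, exp(0.5))
  expect_equal(iv$yL, 1 / exp(0.5))
  expect_equal(round(iv$yU, 2), 1.65)
  # the normal closed form at the same RSD is [y/1.5, 2y]
  cf <- closed_form_interval(1, 0.25, 2)
  expect_equal(c(cf$yL, cf$yU), c(1 / 1.5, 2))

  expect_equal(unlist(lognormal_interval(3, 0, 2)[c("yL", "yU")]),
               c(yL = 3, yU = 3))
  # first-order agreement with the normal closed form for small sigma
  s <- 0.01
  ln <- lognormal_interval(1, s, 2)
  cf <- closed_form_interval(1, s, 2)
  expect_equal(ln$yU, cf$yU, tolerance = 5e-4)
  expect_equal(ln$yL, cf$yL, tolerance = 5e-4)
  expect_gt(abs(ln$yU - 1), 0.015)   # both really move by ~ k*sigma
})

test_that("best estimate inverts the mean curve and floors at zero", {
  expect_equal(best_estimate(4, mean_curve(0, 1)), 4)
  crv <- mean_curve(2, 0.5)
  expect_equal(best_estimate(c(2, 4, 1), crv), c(0, 4, 0))
  fit1 <- ex_fit("thiamphenicol_milk")
  expect_equal(best_estimate(100, fit1), 98.97, tolerance = 1e-3)
})

test_that("prediction range construction: k vs p_pred, bias modes, ordering", {
  prof <- ex2_profile()
  crv <- mean_curve(0.05, 1.01)
  expect_error(prediction_range(crv, prof, k = 2, p_pred = 0.95),
               "exactly one")
  rng <- prediction_range(crv, prof, p_pred = 0.95)
  expect_equal(rng$k, qnorm(0.975))
  rng2 <- prediction_range(crv, prof, k = 2)
  expect_equal(rng2$p_pred, 2 * pnorm(2) - 1)
  nb <- prediction_range(crv, prof, k = 2, bias = "none")
  expect_equal(c(nb$curve$alpha, nb$curve$beta), c(0, 1))
  pl <- prediction_limits(rng2, seq(0, 10, length.out = 50))
  expect_true(all(pl$lower <= pl$upper))
})

test_that("inversion identities hold to 1e-9 and limits are monotone in ym", {
  rng <- prediction_range(mean_curve(0.05, 1.007),
                          precision_profile(variance_components(
                            c("repeatability", "block"),
                            c(0.008, 0.005), c(0.012, 0.009))), k = 2)
  a <- rng$curve$alpha; b <- rng$curve$beta
  C <- rng$profile$C; P <- rng$profile$P
  f_U <- function(y) a + b * y + 2 * sqrt(C + P * y^2)
  f_L <- function(y) a + b * y - 2 * sqrt(C + P * y^2)
  ym <- c(0.5, 1, 2.5, 7, 20)
  iv <- uncertainty_interval(ym, rng)
  expect_true(all(!iv$truncated_low))
  expect_equal(f_U(iv$yL), ym, tolerance = 1e-9)
  expect_equal(f_L(iv$yU), ym, tolerance = 1e-9)
  expect_true(all(diff(iv$yL) > 0))
  expect_true(all(diff(iv$ycorr) > 0))
  expect_true(all(diff(iv$yU) > 0))
  expect_true(all(iv$yL <= iv$ycorr & iv$ycorr <= iv$yU))
})

test_that("no bias + constant absolute SD collapses to the symmetric interval", {
  sd0 <- 0.7; k <- 2
  rng <- prediction_range(mean_curve(0, 1),
                          precision_profile(variance_components(
                            "repeatability", sd0^2, 0)), k = k)
  ym <- c(3, 8, 15)
  iv <- uncertainty_interval(ym, rng)
  expect_equal(iv$yL, ym - k * sd0, tolerance = 1e-9)
  expect_equal(iv$yU, ym + k * sd0, tolerance = 1e-9)
  expect_equal(iv$ycorr - iv$yL, iv$yU - iv$ycorr, tolerance = 1e-9)
  expect_equal(iv$yU - iv$ycorr, rep(k * sd0, 3), tolerance = 1e-9)
})

test_that("iterative inversion reproduces the closed form when C = 0", {
  for (srel in c(0.1, 0.25, 0.4)) for (k in c(1.5, 2)) {
    if (k * srel >= 1) next
    rng <- prediction_range(mean_curve(0, 1),
                            precision_profile(variance_components(
                              "repeatability", 0, srel^2)), k = k)
    ym <- c(0.4, 1, 10, 100)
    iv <- uncertainty_interval(ym, rng)
    cf <- closed_form_interval(ym, srel, k)
    expect_equal(iv$yL, cf$yL, tolerance = 1e-8)
    expect_equal(iv$yU, cf$yU, tolerance = 1e-8)
  }
})

test_that("truncation and unboundedness flags fire where the geometry says", {
  prof <- precision_profile(variance_components("repeatability", 0.04, 0.01))
  rng <- prediction_range(mean_curve(0.1, 1), prof, k = 2)
  # f_U(0) = 0.1 + 2*0.2 = 0.5 > ym
  low <- uncertainty_interval(0.3, rng)
  expect_true(low$truncated_low)
  expect_equal(low$yL, 0)
  # k*sqrt(P) = 0.2 < beta: bounded above
  expect_false(low$unbounded_high)

  wide <- prediction_range(mean_curve(0, 1),
                           precision_profile(variance_components(
                             "repeatability", 0, 0.36)), k = 2)
  iv <- uncertainty_interval(5, wide)   # k*sqrt(P) = 1.2 > 1
  expect_true(iv$unbounded_high)
  expect_equal(iv$yU, Inf)
  expect_false(iv$truncated_low)
})

test_that("the interval equals the band-membership set (brute force)", {
  rng <- prediction_range(mean_curve(0.06, 1.01), ex2_profile(), k = 2)
  step <- 15 / 20000
  for (ym in c(0.5, 2, 6)) {
    iv <- uncertainty_interval(ym, rng)
    bf <- grid_interval(ym, rng, ymax = 15)
    expect_lt(abs(iv$yL - bf[1]), 2 * step)
    expect_lt(abs(iv$yU - bf[2]), 2 * step)
  }
})

test_that("growing the proportional part skews the interval upward", {
  C <- 0.05
  ratio <- vapply(c(0, 0.005, 0.02, 0.05), function(P) {
    comp <- variance_components("repeatability", C, P)
    rng <- prediction_range(mean_curve(0, 1), precision_profile(comp), k = 2)
    iv <- uncertainty_interval(5, rng)
    (iv$yU - iv$ycorr) / (iv$ycorr - iv$yL)
  }, numeric(1))
  expect_equal(ratio[1], 1, tolerance = 1e-9)
  expect_true(all(diff(ratio) > 0))
})
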