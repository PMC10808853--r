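#' Standard and expanded measurement uncertainty
#'
#' The standard uncertainty at concentration `x` is the in-house
#' reproducibility standard deviation `u(x) = sqrt(C + P x^2)`; the
#' expanded uncertainty multiplies it by the coverage factor `k`.
#'
#' @inheritParams reproducibility_sd
#' @param k coverage factor, `> 0` (`k = 2` is the conventional choice for
#'   approximately 95 % coverage).
#' @return numeric vector of uncertainties in study units.
#' @export
standard_uncertainty <- function(profile, x) reproducibility_sd(profile, x)

#' @rdname standard_uncertainty
#' @export
expanded_uncertainty <- function(profile, x, k = 2) {
  if (k < 0) stop("`k` must be >= 0")
  k * standard_uncertainty(profile, x)
}

#' Classical symmetric y +/- U uncertainty interval
#'
#' Builds the interval `[ym - U(ym), ym + U(ym)]` with the expanded
#' uncertainty evaluated at the measurement result itself.  Supply either a
#' precision profile or a constant relative standard deviation.
#'
#' @param ym measurement result(s), `>= 0`.
#' @param profile a [precision_profile()] (or coercible); mutually
#'   exclusive with `rsd`.
#' @param rsd constant relative standard deviation (e.g. `0.35` for 35 %).
#' @param k coverage factor.
#' @return data.frame with columns `ym`, `lower`, `upper`, `U`.
#' @export
#' @examples
#' symmetric_interval(c(3, 10), rsd = 0.35, k = 2)
symmetric_interval <- function(ym, profile = NULL, rsd = NULL, k = 2) {
  if (any(ym < 0)) stop("`ym` must be >= 0")
  if (is.null(profile) == is.null(rsd))
    stop("supply exactly one of `profile` or `rsd`")
  U <- if (!is.null(profile)) expanded_uncertainty(profile, ym, k)
       else k * rsd * ym
  data.frame(ym = ym, lower = ym - U, upper = ym + U, U = U)
}

#' Mutual-containment check for an interval rule
#'
#' Given two measurement results and a rule mapping a result to an
#' uncertainty interval, reports whether each result lies in the interval
#' of the other.  Under heteroscedasticity the symmetric `y +/- U` rule
#' can fail one way (the larger result contains the smaller, but not vice
#' versa), whereas intervals obtained by inverting a fixed prediction range
#' are mutually consistent by construction.
#'
#' @param ym1,ym2 measurement results, `ym1 <= ym2`.
#' @param interval_fn function of one measurement result returning its
#'   interval, either as a numeric `c(lower, upper)` or as a data.frame
#'   with columns `lower`/`upper` or `yL`/`yU`.
#' @return list with elements `in_interval_1` (is `ym2` inside the
#'   interval of `ym1`?), `in_interval_2` (the converse), `mutual`,
#'   `one_way`.
#' @export
#' @examples
#' rule <- function(y) symmetric_interval(y, rsd = 0.35, k = 2)
#' consistency_check(3, 10, rule)  # one-way only
consistency_check <- function(ym1, ym2, interval_fn) {
  if (ym1 > ym2) stop("`ym1` must be <= `ym2`")
  lims <- function(ym) {
    iv <- interval_fn(ym)
    if (is.data.frame(iv)) {
      lo <- if (!is.null(iv$lower)) iv$lower else iv$yL
      hi <- if (!is.null(iv$upper)) iv$upper else iv$yU
      c(lo[1L], hi[1L])
    } else c(iv[1L], iv[2L])
  }
  i1 <- lims(ym1)
  i2 <- lims(ym2)
  in1 <- ym2 >= i1[1L] && ym2 <= i1[2L]
  in2 <- ym1 >= i2[1L] && ym1 <= i2[2L]
  structure(list(interval_1 = i1, interval_2 = i2,
                 in_interval_1 = in1, in_interval_2 = in2,
                 mutual = in1 && in2, one_way = xor(in1, in2)),
            class = "consistency_check")
}

#' @export
print.consistency_check <- function(x, ...) {
  cat(sprintf("interval(ym1) = [%.4g, %.4g]; interval(ym2) = [%.4g, %.4g]\n",
              x$interval_1[1L], x$interval_1[2L],
              x$interval_2[1L], x$interval_2[2L]))
  cat(sprintf("ym2 in interval(ym1): %s; ym1 in interval(ym2): %s -> %s\n",
              x$in_interval_1, x$in_interval_2,
              if (x$mutual) "mutually consistent"
              else if (x$one_way) "INCONSISTENT (one-way containment)"
              else "disjoint"))
  invisible(x)
}

#' Prediction range of a fitted method
#'
#' Combines a mean curve and a precision profile into the concentration-
#' indexed prediction band
#' \deqn{f_{L}(y) = \alpha + \beta y - k\,\sigma(y), \qquad
#'       f_{U}(y) = \alpha + \beta y + k\,\sigma(y),}
#' which contains a future single measurement at true concentration `y`
#' with the prediction probability implied by `k`.  Specify the band width
#' either through the coverage factor `k` or through a prediction
#' probability `p_pred` (converted via the exact standard-normal quantile);
#' never both.
#'
#' @param object an `uncert_fit`, or a [mean_curve()] when `profile` is
#'   given separately.
#' @param profile a [precision_profile()] (or coercible); taken from the
#'   fit when `object` is an `uncert_fit`.
#' @param k coverage factor (`k = 2` by default).
#' @param p_pred prediction probability in (0, 1); when supplied, `k` is
#'   set to `qnorm((1 + p_pred) / 2)`.
#' @param bias `"corrected"` applies the mean curve inside the band (the
#'   default); `"none"` replaces it by the identity curve, ignoring method
#'   bias.
#' @return a `prediction_range` object with elements `curve`, `profile`,
#'   `k`, `p_pred`, `bias`.
#' @export
#' @examples
#' rng <- prediction_range(mean_curve(0, 1),
#'                         variance_components("repeatability", 0, 0.16),
#'                         k = 2)
#' uncertainty_interval(100, rng)
prediction_range <- function(object, profile = NULL, k = NULL,
                             p_pred = NULL, bias = c("corrected", "none")) {
  bias <- match.arg(bias)
  if (inherits(object, "uncert_fit")) {
    curve <- object$curve
    if (is.null(profile)) profile <- precision_profile(object)
  } else if (inherits(object, "mean_curve")) {
    curve <- object
    if (is.null(profile)) stop("`profile` is required with a mean_curve")
  } else stop("`object` must be an uncert_fit or a mean_curve")
  profile <- as_profile(profile)
  if (!is.null(k) && !is.null(p_pred))
    stop("supply exactly one of `k` or `p_pred`")
  if (!is.null(p_pred)) {
    stopifnot(p_pred > 0, p_pred < 1)
    k <- qnorm((1 + p_pred) / 2)
  } else {
    if (is.null(k)) k <- 2
    p_pred <- 2 * stats::pnorm(k) - 1
  }
  if (k <= 0) stop("`k` must be > 0")
  if (bias == "none") curve <- mean_curve(0, 1)
  structure(list(curve = curve, profile = profile, k = k, p_pred = p_pred,
                 bias = bias),
            class = "prediction_range")
}

#' Evaluate the prediction limits of a range
#'
#' @param range a [prediction_range()].
#' @param y true concentration(s), `>= 0`.
#' @return data.frame with columns `y`, `fit` (mean curve), `lower`
#'   (`f_L(y)`) and `upper` (`f_U(y)`).
#' @export
prediction_limits <- function(range, y) {
  stopifnot(inherits(range, "prediction_range"))
  if (any(y < 0)) stop("`y` must be >= 0")
  mu <- mean_response(range$curve, y)
  half <- range$k * reproducibility_sd(range$profile, y)
  data.frame(y = y, fit = mu, lower = mu - half, upper = mu + half)
}

#' @export
print.prediction_range <- function(x, ...) {
  cat(sprintf(
    "Prediction range (k = %.4f, p_pred = %.4f, bias %s):\n",
    x$k, x$p_pred, x$bias))
  cat(sprintf("  f(y) = %.4f + %.4f*y -/+ %.4f * sqrt(%.5g + %.5g*y^2)\n",
              x$curve$alpha, x$curve$beta, x$k, x$profile$C, x$profile$P))
  invisible(x)
}

#' Best estimate of the measurand
#'
#' Projects a measurement result through the inverse mean curve,
#' `(ym - alpha) / beta`, floored at zero — equivalent to a bias/recovery
#' correction.
#'
#' @param ym measurement result(s).
#' @param curve a [mean_curve()] (or an object holding one: an
#'   `uncert_fit` or `prediction_range`).
#' @return corrected estimate(s) `ycorr`.
#' @export
best_estimate <- function(ym, curve) {
  if (inherits(curve, "uncert_fit") || inherits(curve, "prediction_range"))
    curve <- curve$curve
  stopifnot(inherits(curve, "mean_curve"))
  pmax(0, (ym - curve$alpha) / curve$beta)
}

#' Invert a prediction range into a measurement uncertainty interval
#'
#' For a routine measurement result `ym`, the lower uncertainty limit `yL`
#' solves `f_U(yL) = ym` (measurands below `yL` would rarely produce a
#' result as large as `ym`), and the upper limit `yU` solves
#' `f_L(yU) = ym`.  Together with the bias-corrected best estimate
#' `ycorr = (ym - alpha)/beta` this yields a generally asymmetric interval
#' `[yL, yU]` of values reasonably attributable to the measurand.  When
#' `f_U(0) >= ym` the lower limit is truncated at zero; when the
#' asymptotic slope `beta - k*sqrt(P)` is not positive the upper limit is
#' unbounded.
#'
#' @param ym measurement result(s), `>= 0`.
#' @param range a [prediction_range()].
#' @param tol absolute tolerance on `|f(root) - ym|`, scaled by
#'   `max(1, ym)`.
#' @return an `uncertainty_interval` data.frame with columns `ym`, `yL`,
#'   `yU`, `ycorr`, `truncated_low`, `unbounded_high`, plus attribute `k`.
#' @export
#' @examples
#' rng <- prediction_range(mean_curve(0, 1),
#'                         variance_components("repeatability", 0, 0.16))
#' uncertainty_interval(100, rng)  # matches closed_form_interval(100, 0.4)
uncertainty_interval <- function(ym, range, tol = 1e-9) {
  stopifnot(inherits(range, "prediction_range"))
  if (any(ym < 0)) stop("`ym` must be >= 0")
  a <- range$curve$alpha; b <- range$curve$beta
  C <- range$profile$C; P <- range$profile$P; k <- range$k
  f_U <- function(y) a + b * y + k * sqrt(C + P * y^2)
  f_L <- function(y) a + b * y - k * sqrt(C + P * y^2)
  slope_inf <- b - k * sqrt(P)

  solve_up <- function(f, target, guess) {
    # f strictly increasing on [0, Inf); find root of f(y) = target
    hi <- max(guess, 1)
    it <- 0L
    while (f(hi) < target && it < 200L) { hi <- hi * 2; it <- it + 1L }
    if (f(hi) < target)
      stop("root bracketing failed: f(", format(hi), ") = ",
           format(f(hi)), " < ", format(target))
    r <- uniroot(function(y) f(y) - target, c(0, hi),
                 tol = .Machine$double.eps^0.75)$root
    if (abs(f(r) - target) > tol * max(1, target))
      stop("root not converged to tolerance at ym = ", format(target))
    r
  }

  one <- function(y_m) {
    ycorr <- max(0, (y_m - a) / b)
    if (f_U(0) >= y_m) {
      yL <- 0; trunc_low <- TRUE
    } else {
      yL <- solve_up(f_U, y_m, ycorr); trunc_low <- FALSE
    }
    if (slope_inf <= 0) {
      yU <- Inf; unb <- TRUE
    } else if (f_L(0) >= y_m) {
      yU <- 0; unb <- FALSE   # degenerate: even measurand 0 predicts above ym
    } else {
      yU <- solve_up(f_L, y_m, ycorr); unb <- FALSE
    }
    c(yL = yL, yU = yU, ycorr = ycorr,
      truncated_low = trunc_low, unbounded_high = unb)
  }
  res <- t(vapply(ym, one, c(yL = 0, yU = 0, ycorr = 0,
                             truncated_low = 0, unbounded_high = 0)))
  out <- data.frame(ym = ym, yL = res[, "yL"], yU = res[, "yU"],
                    ycorr = res[, "ycorr"],
                    truncated_low = as.logical(res[, "truncated_low"]),
                    unbounded_high = as.logical(res[, "unbounded_high"]))
  attr(out, "k") <- k
  class(out) <- c("uncertainty_interval", "data.frame")
  out
}

#' Closed-form uncertainty interval for constant relative SD, no bias
#'
#' When the relative standard deviation `sigma_rel` is constant across
#' concentrations and the method is unbiased, inverting the normal
#' prediction range has the explicit solution
#' `[ym / (1 + k*sigma_rel), ym / (1 - k*sigma_rel)]`.  The upper limit is
#' finite only when `k*sigma_rel < 1`; otherwise it is reported as `Inf`
#' with the `unbounded_high` flag set.
#'
#' @param ym measurement result(s), `>= 0`.
#' @param sigma_rel constant relative standard deviation, `> 0`.
#' @param k coverage factor, `> 0`.
#' @return an `uncertainty_interval` data.frame (see
#'   [uncertainty_interval()]).
#' @export
#' @examples
#' closed_form_interval(100, 0.4, 2)  # [approx. 56, 500]
closed_form_interval <- function(ym, sigma_rel, k = 2) {
  stopifnot(sigma_rel > 0, k > 0)
  if (any(ym < 0)) stop("`ym` must be >= 0")
  unbounded <- k * sigma_rel >= 1
  out <- data.frame(ym = ym,
                    yL = ym / (1 + k * sigma_rel),
                    yU = if (unbounded) rep(Inf, length(ym))
                         else ym / (1 - k * sigma_rel),
                    ycorr = ym,
                    truncated_low = ym == 0,
                    unbounded_high = rep(unbounded, length(ym)))
  out$yU[out$ym == 0 & !unbounded] <- 0
  attr(out, "k") <- k
  class(out) <- c("uncertainty_interval", "data.frame")
  out
}

#' Multiplicative uncertainty interval for lognormal data
#'
#' When a log transformation stabilises the variance (constant standard
#' deviation `sigma_log` in the log domain), back-transforming the
#' symmetric log-domain interval gives the asymmetric interval
#' `[ym / exp(k*sigma_log), ym * exp(k*sigma_log)]`.
#'
#' @param ym measurement result(s), `>= 0`.
#' @param sigma_log standard deviation in the log domain, `>= 0`.
#' @param k coverage factor, `> 0`.
#' @return an `uncertainty_interval` data.frame.
#' @export
#' @examples
#' lognormal_interval(1, 0.25, 2)  # multiplicative factor exp(0.5) ~ 1.65
lognormal_interval <- function(ym, sigma_log, k = 2) {
  stopifnot(sigma_log >= 0, k > 0)
  if (any(ym < 0)) stop("`ym` must be >= 0")
  fac <- exp(k * sigma_log)
  out <- data.frame(ym = ym, yL = ym / fac, yU = ym * fac, ycorr = ym,
                    truncated_low = ym == 0,
                    unbounded_high = FALSE)
  attr(out, "k") <- k
  class(out) <- c("uncertainty_interval", "data.frame")
  out
}

#' @export
print.uncertainty_interval <- function(x, digits = 4, ...) {
  cat(sprintf("Measurement uncertainty intervals (k = %.4f):\n",
              attr(x, "k")))
  df <- as.data.frame(x)
  df$yL <- signif(df$yL, digits); df$yU <- signif(df$yU, digits)
  df$ycorr <- signif(df$ycorr, digits)
  flags <- ifelse(df$truncated_low, "truncated at 0",
                  ifelse(df$unbounded_high, "unbounded above", ""))
  print(cbind(df[c("ym", "yL", "yU", "ycorr")], note = flags),
        row.names = FALSE)
  invisible(x)
}

#' Plot a prediction range and its inversion
#'
#' Draws the mean curve and the prediction band against the true
#' concentration; optional measurement results are shown with their
#' projections onto the measurand axis (the asymmetric uncertainty
#' interval).
#'
#' @param x a [prediction_range()].
#' @param ym optional measurement result(s) to project.
#' @param xmax upper plotting limit on the measurand axis; a default is
#'   chosen from `ym` or the profile.
#' @param n grid resolution.
#' @param ... passed to [plot()].
#' @export
plot.prediction_range <- function(x, ym = NULL, xmax = NULL, n = 200, ...) {
  if (is.null(xmax)) {
    xmax <- if (!is.null(ym)) {
      iv <- uncertainty_interval(max(ym), x)
      if (is.finite(iv$yU)) 1.3 * iv$yU else 3 * max(ym)
    } else max(1, 10 * sqrt(x$profile$C + 1e-12))
  }
  g <- seq(0, xmax, length.out = n)
  pl <- prediction_limits(x, g)
  plot(g, pl$fit, type = "n", xlab = "measurand y",
       ylab = "measurement result", ylim = range(pl$lower, pl$upper), ...)
  polygon(c(g, rev(g)), c(pl$lower, rev(pl$upper)),
          col = adjustcolor("steelblue", 0.25), border = NA)
  lines(g, pl$fit, lwd = 2)
  lines(g, pl$lower, lty = 2); lines(g, pl$upper, lty = 2)
  if (!is.null(ym)) {
    iv <- uncertainty_interval(ym, x)
    for (i in seq_len(nrow(iv))) {
      abline(h = iv$ym[i], col = "firebrick", lty = 3)
      segments(iv$yL[i], iv$ym[i], min(iv$yU[i], xmax), iv$ym[i],
               col = "firebrick", lwd = 2)
      points(iv$ycorr[i], iv$ym[i], pch = 19, col = "firebrick")
    }
  }
  invisible(x)
}

#' Plot a precision profile
#'
#' Relative standard deviation (percent) against concentration.
#'
#' @param x a [precision_profile()].
#' @param xlim concentration range (must exclude 0).
#' @param n grid resolution.
#' @param ... passed to [plot()].
#' @export
plot.precision_profile <- function(x, xlim = c(0.1, 10), n = 200, ...) {
  g <- seq(xlim[1L], xlim[2L], length.out = n)
  rsd <- 100 * reproducibility_sd(x, g) / g
  plot(g, rsd, type = "l", lwd = 2, xlab = "concentration",
       ylab = "reproducibility RSD [%]", ...)
  abline(h = 100 * sqrt(x$P), lty = 2)
  invisible(x)
}
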