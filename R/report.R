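#' Precision table at selected concentrations
#'
#' The decomposition of [precision_breakdown()] rounded for reporting:
#' percentages to 1 decimal place, standard deviations to 2 (full
#' precision is kept internally and used by all computations).
#'
#' @inheritParams precision_breakdown
#' @param digits_pct,digits_sd rounding for the percent and SD columns.
#' @return data.frame in reporting layout.
#' @export
precision_table <- function(profile, x, digits_pct = 1, digits_sd = 2) {
  b <- precision_breakdown(profile, x)
  data.frame(concentration = b$x,
             repeatability_pct = round(b$repeatability_rsd, digits_pct),
             block_pct = round(b$block_rsd, digits_pct),
             factors_pct = round(b$factors_rsd, digits_pct),
             reproducibility_pct = round(b$reproducibility_rsd, digits_pct),
             reproducibility_sd = round(b$reproducibility_sd, digits_sd))
}

#' Expanded-uncertainty table at selected concentrations
#'
#' @inheritParams precision_breakdown
#' @param k coverage factor.
#' @param digits_pct,digits_u rounding for the percent and absolute
#'   columns.
#' @return data.frame with `concentration`, `U_pct`, `U`.
#' @export
expanded_uncertainty_table <- function(profile, x, k = 2,
                                       digits_pct = 1, digits_u = 2) {
  profile <- as_profile(profile)
  U <- expanded_uncertainty(profile, x, k)
  data.frame(concentration = x,
             U_pct = round(100 * U / x, digits_pct),
             U = round(U, digits_u))
}

#' Uncertainty-interval table for a set of measurement results
#'
#' One row per measurement result: the asymmetric limits from inverting
#' the prediction range, the best estimate, the two half-widths
#' `ycorr - yL` and `yU - ycorr`, and the symmetric expanded uncertainty
#' `U(ym)` for comparison.
#'
#' @param range a [prediction_range()].
#' @param ym measurement results.
#' @param digits rounding for the limit columns (`ycorr` always gets
#'   `digits + 1` when `digits < 2`, mirroring usual reporting practice).
#' @return data.frame.
#' @export
interval_table <- function(range, ym, digits = 2) {
  iv <- uncertainty_interval(ym, range)
  U <- expanded_uncertainty(range$profile, ym, range$k)
  dc <- max(digits, 2)
  data.frame(ym = ym,
             yL = round(iv$yL, digits),
             yU = round(iv$yU, digits),
             ycorr = round(iv$ycorr, dc),
             diff_low = round(iv$ycorr - iv$yL, dc),
             diff_high = round(iv$yU - iv$ycorr, dc),
             U = round(U, dc),
             truncated_low = iv$truncated_low,
             unbounded_high = iv$unbounded_high)
}

#' Full report bundle for a fitted validation study
#'
#' Collects the reporting tables for one fit: the variance-component
#' table, the precision table, the expanded-uncertainty table, and (when
#' measurement results are supplied) the asymmetric interval table.
#'
#' @param fit an [fit_uncertainty_model()] result (must have converged).
#' @param x concentrations for the precision tables; defaults to `ym`, or
#'   must be given.
#' @param ym optional routine measurement results for the interval table.
#' @param k coverage factor.
#' @param bias passed to [prediction_range()].
#' @param digits rounding for interval limits.
#' @return an `uncertainty_report`: a list of data.frames
#'   (`variance_table`, `precision_table`, `expanded_table`, and
#'   optionally `interval_table`) plus the `prediction_range` used.
#' @export
uncertainty_report <- function(fit, x = NULL, ym = NULL, k = 2,
                               bias = "corrected", digits = 2) {
  stopifnot(inherits(fit, "uncert_fit"))
  if (!fit$converged)
    stop("refusing to report a fit that did not converge")
  if (is.null(x)) {
    if (is.null(ym)) stop("supply `x` and/or `ym`")
    x <- ym
  }
  profile <- precision_profile(fit)
  rng <- prediction_range(fit, k = k, bias = bias)
  out <- list(
    variance_table = data.frame(term = fit$components$term,
                                constant = round(fit$components$const_var, 5),
                                proportional = round(fit$components$prop_var, 5)),
    precision_table = precision_table(profile, x),
    expanded_table = expanded_uncertainty_table(profile, x, k),
    prediction_range = rng)
  if (!is.null(ym))
    out$interval_table <- interval_table(rng, ym, digits = digits)
  structure(out, class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat("== Variance components ==\n")
  print(x$variance_table, row.names = FALSE)
  cat("\n== Precision profile ==\n")
  print(x$precision_table, row.names = FALSE)
  cat("\n== Expanded uncertainty (k =", format(x$prediction_range$k), ") ==\n")
  print(x$expanded_table, row.names = FALSE)
  if (!is.null(x$interval_table)) {
    cat("\n== Asymmetric uncertainty intervals ==\n")
    print(x$interval_table, row.names = FALSE)
  }
  invisible(x)
}

#' Write a report bundle to CSV files (plus diagnostic plots)
#'
#' @param report an [uncertainty_report()].
#' @param dir output directory (created if missing).
#' @param plots also write `prediction_range.pdf` and
#'   `precision_profile.pdf`.
#' @return character vector of files written, invisibly.
#' @export
write_uncertainty_report <- function(report, dir, plots = TRUE) {
  stopifnot(inherits(report, "uncertainty_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in c("variance_table", "precision_table", "expanded_table",
               "interval_table")) {
    if (is.null(report[[nm]])) next
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(report[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  if (plots) {
    rng <- report$prediction_range
    xs <- report$precision_table$concentration
    f1 <- file.path(dir, "prediction_range.pdf")
    grDevices::pdf(f1, width = 6, height = 5)
    plot(rng, ym = report$interval_table$ym, xmax = 1.5 * max(xs))
    grDevices::dev.off()
    f2 <- file.path(dir, "precision_profile.pdf")
    grDevices::pdf(f2, width = 6, height = 5)
    plot(rng$profile, xlim = c(min(xs) / 2, 1.5 * max(xs)))
    grDevices::dev.off()
    files <- c(files, f1, f2)
  }
  invisible(files)
}
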