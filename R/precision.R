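#' Mean curve of a measurement method
#'
#' The expected measured concentration at true concentration `x` is
#' `alpha + beta * x`; `alpha` and `beta - 1` are the absolute and relative
#' components of method bias.
#'
#' @param alpha intercept, in study units.
#' @param beta slope (dimensionless); must be positive.
#' @return a `mean_curve` object.
#' @export
mean_curve <- function(alpha = 0, beta = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (beta <= 0) stop("`beta` must be > 0")
  structure(list(alpha = alpha, beta = beta), class = "mean_curve")
}

#' @export
print.mean_curve <- function(x, digits = 4, ...) {
  cat(sprintf("Mean curve: E[Y] = %.*f + %.*f * x\n",
              digits, x$alpha, digits, x$beta))
  invisible(x)
}

#' Expected measured concentration
#'
#' Evaluates the mean curve `alpha + beta * x`.
#'
#' @param curve a [mean_curve()].
#' @param x true concentration(s).
#' @return numeric vector of expected measured concentrations.
#' @export
mean_response <- function(curve, x) {
  stopifnot(inherits(curve, "mean_curve"))
  curve$alpha + curve$beta * x
}

#' Constant and proportional variance components
#'
#' One entry per random term of the model: the residual/repeatability term,
#' the block term, and one term per design factor.  Each entry has a
#' constant component (units squared) and a proportional component
#' (dimensionless, multiplying `x^2`).  Both must be non-negative; exact
#' zeros mark components estimated on (or pinned to) the boundary.
#'
#' @param term character vector of term names; the names `"repeatability"`
#'   and `"block"` are reserved for the residual and the block term.
#' @param const_var,prop_var non-negative numeric vectors.
#' @return a `variance_components` data.frame.
#' @export
#' @examples
#' vc <- variance_components(c("repeatability", "block", "operator"),
#'                           const_var = c(0.9, 0.9, 1.5),
#'                           prop_var  = c(0, 0, 3e-4))
#' precision_profile(vc)
variance_components <- function(term, const_var, prop_var) {
  term <- as.character(term)
  stopifnot(length(term) == length(const_var),
            length(term) == length(prop_var))
  if (anyDuplicated(term)) stop("duplicate term names")
  if (any(!is.finite(const_var)) || any(!is.finite(prop_var)))
    stop("variance components must be finite")
  if (any(const_var < 0) || any(prop_var < 0))
    stop("variance components must be >= 0")
  structure(data.frame(term = term, const_var = as.numeric(const_var),
                       prop_var = as.numeric(prop_var),
                       stringsAsFactors = FALSE),
            class = c("variance_components", "data.frame"))
}

#' @export
print.variance_components <- function(x, digits = 5, ...) {
  cat("Variance components (constant | proportional):\n")
  out <- data.frame(term = x$term,
                    constant = round(x$const_var, digits),
                    proportional = round(x$prop_var, digits))
  print(out, row.names = FALSE)
  invisible(x)
}

group_of_term <- function(term) {
  ifelse(term == "repeatability", "repeatability",
         ifelse(term == "block", "block", "factors"))
}

#' Precision profile: the variance function of a method
#'
#' Aggregates variance components into the variance function
#' \eqn{\sigma^2(x) = C + P x^2}, with `C` the sum of the constant
#' components and `P` the sum of the proportional components.
#'
#' @param x a [variance_components()] object or a fitted
#'   [fit_uncertainty_model()] result.
#' @param ... unused.
#' @return a `precision_profile` with elements `components`, `C`, `P`.
#' @export
precision_profile <- function(x, ...) UseMethod("precision_profile")

#' @rdname precision_profile
#' @export
precision_profile.variance_components <- function(x, ...) {
  structure(list(components = x, C = sum(x$const_var), P = sum(x$prop_var)),
            class = "precision_profile")
}

#' @rdname precision_profile
#' @export
precision_profile.uncert_fit <- function(x, ...) {
  precision_profile(x$components)
}

#' @export
print.precision_profile <- function(x, ...) {
  cat(sprintf(
    "Precision profile: sigma^2(x) = %.5g + %.5g * x^2  (%d terms)\n",
    x$C, x$P, nrow(x$components)))
  invisible(x)
}

#' In-house reproducibility standard deviation at a concentration
#'
#' Evaluates `sqrt(C + P * x^2)` from the aggregated variance components.
#'
#' @param profile a [precision_profile()] (or an object coercible via
#'   [precision_profile()]).
#' @param x concentration(s), `>= 0`.
#' @return standard deviation(s) in study units.
#' @export
#' @examples
#' vc <- variance_components("repeatability", 4, 9e-4)
#' reproducibility_sd(precision_profile(vc), 100)  # sqrt(4 + 9)
reproducibility_sd <- function(profile, x) {
  profile <- as_profile(profile)
  if (any(x < 0)) stop("concentration must be >= 0")
  sqrt(profile$C + profile$P * x^2)
}

as_profile <- function(profile) {
  if (inherits(profile, "precision_profile")) return(profile)
  if (inherits(profile, "variance_components") ||
      inherits(profile, "uncert_fit")) return(precision_profile(profile))
  stop("expected a precision_profile, variance_components or uncert_fit")
}

#' Decompose the reproducibility RSD into its contributions
#'
#' Splits the variance function at concentration `x` into the repeatability,
#' block, and (pooled) factor groups, reported as relative standard
#' deviations in percent; the squared group RSDs sum to the squared
#' reproducibility RSD.  Per-term RSDs are attached as attribute
#' `"per_term"`.
#'
#' @inheritParams reproducibility_sd
#' @param x concentration(s), strictly positive (an RSD is undefined at 0).
#' @return data.frame with columns `x`, `repeatability_rsd`, `block_rsd`,
#'   `factors_rsd`, `reproducibility_rsd` (percent) and
#'   `reproducibility_sd` (study units).
#' @export
precision_breakdown <- function(profile, x) {
  profile <- as_profile(profile)
  if (any(x <= 0)) stop("RSD undefined: concentration must be > 0")
  comp <- profile$components
  grp <- group_of_term(comp$term)
  grp_rsd <- function(g, xx) {
    sel <- grp == g
    100 * sqrt(sum(comp$const_var[sel]) + xx^2 * sum(comp$prop_var[sel])) / xx
  }
  out <- data.frame(
    x = x,
    repeatability_rsd = vapply(x, function(xx) grp_rsd("repeatability", xx),
                               numeric(1)),
    block_rsd = vapply(x, function(xx) grp_rsd("block", xx), numeric(1)),
    factors_rsd = vapply(x, function(xx) grp_rsd("factors", xx), numeric(1)),
    reproducibility_rsd = 100 * reproducibility_sd(profile, x) / x,
    reproducibility_sd = reproducibility_sd(profile, x))
  per_term <- vapply(seq_len(nrow(comp)), function(i)
    100 * sqrt(comp$const_var[i] + x^2 * comp$prop_var[i]) / x, numeric(length(x)))
  per_term <- matrix(per_term, nrow = length(x),
                     dimnames = list(NULL, comp$term))
  attr(out, "per_term") <- per_term
  out
}
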