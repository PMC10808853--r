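#' Two-level factorial validation design
#'
#' The standard eight-block, two-level design used for in-house validation
#' studies with up to seven factors; for fewer factors the corresponding
#' leading columns are used.  Every factor level appears in four blocks.
#'
#' @param q number of factors (1 to 7).
#' @param factor_names optional character vector of factor names
#'   (defaults to `F1...Fq`).
#' @return data.frame with a `block` column and one level column
#'   (`"1"`/`"2"`) per factor.
#' @export
two_level_design <- function(q, factor_names = NULL) {
  stopifnot(q >= 1, q <= 7)
  tab <- rbind(c(1, 1, 1, 2, 2, 2, 1),
               c(1, 1, 2, 2, 1, 1, 2),
               c(1, 2, 1, 1, 2, 1, 2),
               c(1, 2, 2, 1, 1, 2, 1),
               c(2, 1, 1, 1, 1, 2, 2),
               c(2, 1, 2, 1, 2, 1, 1),
               c(2, 2, 1, 2, 1, 1, 1),
               c(2, 2, 2, 2, 2, 2, 2))
  if (is.null(factor_names)) factor_names <- paste0("F", seq_len(q))
  stopifnot(length(factor_names) == q)
  d <- data.frame(block = sprintf("%02d", 1:8))
  for (i in seq_len(q)) d[[factor_names[i]]] <- as.character(tab[, i])
  d
}

#' Specify a simulated validation study
#'
#' Bundles the generative truth for the validation-study model: a factorial
#' design, known concentrations, replicate count, a mean curve, variance
#' components, and the response distribution.
#'
#' Under `distribution = "normal"` each random term contributes an
#' additive effect `A + B*x` with `A ~ N(0, const_var)` and
#' `B ~ N(0, prop_var)`, drawn once per level of the term (per block for
#' the block term, per observation for repeatability).  Under
#' `distribution = "lognormal"` all constant components must be zero and
#' the proportional components act as variances of additive effects in the
#' log domain: `Y = (alpha + beta*x) * exp(sum of effects)`, giving an
#' approximately constant relative standard deviation.
#'
#' @param design data.frame with a `block` column and one column per
#'   factor (see [two_level_design()]).
#' @param known_x strictly positive concentration levels.
#' @param p replicates per (block, level) cell.
#' @param curve a [mean_curve()]: the true bias.
#' @param components a [variance_components()] with entries
#'   `"repeatability"`, `"block"`, and one per design factor.
#' @param distribution `"normal"` or `"lognormal"`.
#' @param seed default integer seed used by [simulate_study()].
#' @return a `simulation_spec` object.
#' @export
simulation_spec <- function(design, known_x, p = 1, curve, components,
                            distribution = c("normal", "lognormal"),
                            seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(is.data.frame(design), "block" %in% names(design),
            all(known_x > 0), p >= 1,
            inherits(curve, "mean_curve"),
            inherits(components, "variance_components"))
  factors <- setdiff(names(design), "block")
  need <- c("repeatability", "block", factors)
  miss <- setdiff(need, components$term)
  if (length(miss))
    stop("components missing for term(s): ", paste(miss, collapse = ", "))
  if (distribution == "lognormal" && any(components$const_var > 0))
    stop("lognormal simulation requires all constant components to be 0")
  structure(list(design = design, known_x = sort(known_x), p = as.integer(p),
                 curve = curve, components = components,
                 distribution = distribution, factors = factors,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "Simulation spec: %d blocks x %d levels x %d replicates, %s errors\n",
    nrow(x$design), length(x$known_x), x$p, x$distribution))
  invisible(x)
}

comp_var <- function(components, term, kind) {
  i <- match(term, components$term)
  components[[kind]][i]
}

#' Simulate a validation study from its generative model
#'
#' Draws one dataset under the spec's mixed model: each random term's
#' effects are shared across all observations with the same level (block
#' effects within a block, factor effects across blocks sharing the
#' level), and the repeatability term is drawn per observation.
#' Reproducible for a given seed.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a [validation_data()] object.
#' @export
#' @examples
#' spec <- simulation_spec(two_level_design(2), known_x = c(1, 5), p = 2,
#'                         curve = mean_curve(0, 1),
#'                         components = variance_components(
#'                           c("repeatability", "block", "F1", "F2"),
#'                           c(0.01, 0.01, 0, 0), c(0, 0, 1e-3, 0)))
#' simulate_study(spec, seed = 7)
simulate_study <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  des <- spec$design
  nb <- nrow(des)
  d <- expand.grid(block = des$block, known_x = spec$known_x,
                   replicate = seq_len(spec$p), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d <- merge(d, des, by = "block", sort = FALSE)
  d <- d[order(d$block, d$known_x, d$replicate), , drop = FALSE]
  N <- nrow(d)
  x <- d$known_x
  lognorm <- spec$distribution == "lognormal"
  eff <- numeric(N)

  draw_term <- function(term, idx) {
    cv <- comp_var(spec$components, term, "const_var")
    pv <- comp_var(spec$components, term, "prop_var")
    L <- length(unique(idx))
    A <- rnorm(L, 0, sqrt(cv))
    B <- rnorm(L, 0, sqrt(pv))
    if (lognorm) B[idx] else A[idx] + B[idx] * x
  }
  eff <- eff + draw_term("block", as.integer(factor(d$block)))
  for (f in spec$factors)
    eff <- eff + draw_term(f, as.integer(factor(d[[f]])))
  # repeatability: per observation
  cv <- comp_var(spec$components, "repeatability", "const_var")
  pv <- comp_var(spec$components, "repeatability", "prop_var")
  eff <- eff + if (lognorm) rnorm(N, 0, sqrt(pv))
               else rnorm(N, 0, sqrt(cv)) + rnorm(N, 0, sqrt(pv)) * x

  mu <- mean_response(spec$curve, x)
  d$y <- if (lognorm) mu * exp(eff) else mu + eff
  validation_data(d[c("block", spec$factors, "known_x", "replicate", "y")],
                  factors = spec$factors, units = "")
}

replicate_seed <- function(seed, r) {
  (as.numeric(seed) + 69069 * r + 1013904223) %% 2147483647
}

#' Monte Carlo coverage of an interval rule
#'
#' For each concentration in the spec, repeatedly simulates a single
#' routine measurement under the generative truth, computes the
#' uncertainty interval by the chosen rule (with the truth known), and
#' reports the fraction of replicates whose interval contains the true
#' measurand.  With the exact 95 % quantile, no bias, and constant
#' relative SD, the asymmetric rule is exact: coverage is 95 % up to
#' binomial noise.  The symmetric `y +/- U` rule loses this guarantee
#' under heteroscedasticity.
#'
#' @param spec a [simulation_spec()] carrying the truth.
#' @param interval_rule `"asymmetric"` (prediction-range inversion) or
#'   `"y_plus_minus_U"`.
#' @param R number of replicates per concentration, `>= 100`.
#' @param k coverage factor; defaults to the exact 95 % normal quantile.
#' @param seed integer seed.
#' @return data.frame with columns `y_true`, `rule`, `coverage`, `se`
#'   (binomial standard error), `R`.
#' @export
coverage_experiment <- function(spec,
                                interval_rule = c("asymmetric",
                                                  "y_plus_minus_U"),
                                R = 10000, k = qnorm(0.975), seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"), R >= 100)
  interval_rule <- match.arg(interval_rule)
  if (is.null(seed)) seed <- spec$seed
  profile <- precision_profile(spec$components)
  rng <- prediction_range(spec$curve, profile, k = k)
  rows <- lapply(seq_along(spec$known_x), function(i) {
    y <- spec$known_x[i]
    set.seed(replicate_seed(seed, i))
    mu <- mean_response(spec$curve, y)
    sdy <- reproducibility_sd(profile, y)
    ym <- pmax(0, rnorm(R, mu, sdy))
    hit <- if (interval_rule == "asymmetric") {
      iv <- uncertainty_interval(ym, rng)
      y >= iv$yL & y <= iv$yU
    } else {
      U <- expanded_uncertainty(profile, ym, k)
      y >= ym - U & y <= ym + U
    }
    cov <- mean(hit)
    data.frame(y_true = y, rule = interval_rule, coverage = cov,
               se = sqrt(cov * (1 - cov) / R), R = R)
  })
  do.call(rbind, rows)
}

#' Monte Carlo parameter recovery of the REML estimator
#'
#' Simulates `R` validation studies from the spec, refits each with
#' [fit_uncertainty_model()], and tabulates the estimate distribution for
#' every variance component and for the aggregate constant (`C`) and
#' proportional (`P`) parts of the variance function, plus the fixed
#' effects.  Fit failures are counted, never silently dropped.
#'
#' @param spec a [simulation_spec()].
#' @param R number of replicate studies, `>= 2`.
#' @param seed integer seed.
#' @return data.frame with one row per parameter: `parameter`, `truth`,
#'   `median_est`, `mean_est`, `bias`, `rmse`; attributes `estimates`
#'   (matrix of all draws) and `n_failed`.
#' @export
recovery_experiment <- function(spec, R = 200, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"), R >= 2)
  if (is.null(seed)) seed <- spec$seed
  comp <- spec$components
  par_names <- c(paste0(comp$term, ".const"), paste0(comp$term, ".prop"),
                 "C", "P", "alpha", "beta")
  truth <- c(comp$const_var, comp$prop_var,
             sum(comp$const_var), sum(comp$prop_var),
             spec$curve$alpha, spec$curve$beta)
  est <- matrix(NA_real_, nrow = R, ncol = length(par_names),
                dimnames = list(NULL, par_names))
  n_failed <- 0L
  for (r in seq_len(R)) {
    d <- simulate_study(spec, seed = replicate_seed(seed, r))
    fit <- tryCatch(
      suppressWarnings(fit_uncertainty_model(d)),
      error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    fc <- fit$components
    i <- match(comp$term, fc$term)
    prof <- precision_profile(fit)
    est[r, ] <- c(fc$const_var[i], fc$prop_var[i], prof$C, prof$P,
                  fit$curve$alpha, fit$curve$beta)
  }
  ok <- stats::complete.cases(est)
  out <- data.frame(
    parameter = par_names, truth = truth,
    median_est = apply(est[ok, , drop = FALSE], 2, median),
    mean_est = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - truth,
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                          rep(truth, each = sum(ok)))^2)))
  attr(out, "estimates") <- est
  attr(out, "n_failed") <- n_failed
  rownames(out) <- NULL
  out
}
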