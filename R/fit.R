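#' Fit the validation-study mixed model by REML
#'
#' Fits the mean curve \eqn{\alpha + \beta x} together with a constant and a
#' proportional variance component for every random term: one term per
#' design factor (effects indexed by factor level), one block term (effects
#' indexed by block), and the repeatability/residual term.  The marginal
#' covariance of the responses is
#' \deqn{V = \sum_t \sigma^2_{A,t} J_t + \sigma^2_{B,t} (x x' \circ J_t)
#'       + \mathrm{diag}(\sigma^2_a + \sigma^2_b x^2),}
#' where \eqn{J_t} indicates shared levels of term \eqn{t}.  The restricted
#' log-likelihood is maximised numerically over standard-deviation
#' parameters (so all variances are non-negative by construction; boundary
#' solutions are reported as zeros), from several analytically motivated
#' starting points, and the fixed effects are obtained by generalised least
#' squares at the estimated covariance.  The fit is deterministic.
#'
#' @param data a [validation_data()] object with at least two distinct
#'   concentration levels and at least two represented levels per factor.
#' @param variance_model `"constant+proportional"` (default) or
#'   `"constant"`, which drops all proportional components (homoscedastic
#'   special case).
#' @param non_negative constrain variance components to be `>= 0`
#'   (the default; the unconstrained fit is not implemented because the
#'   downstream variance function requires non-negative components).
#' @param max_iter iteration cap passed to the optimiser.
#' @param tol relative convergence tolerance on the restricted
#'   log-likelihood.
#' @return an `uncert_fit` with elements `curve` ([mean_curve()]),
#'   `components` ([variance_components()]), `converged`, `n_obs`,
#'   `loglik` (restricted), `se_alpha`, `se_beta`, `vcov_fixed`.
#' @export
#' @examples
#' fit <- fit_uncertainty_model(validation_example("thiamphenicol_milk"))
#' fit
fit_uncertainty_model <- function(data,
                                  variance_model = c("constant+proportional",
                                                     "constant"),
                                  non_negative = TRUE,
                                  max_iter = 500, tol = 1e-8) {
  stopifnot(inherits(data, "validation_data"))
  variance_model <- match.arg(variance_model)
  if (!isTRUE(non_negative))
    stop("only the non-negative variance parameterisation is implemented")
  factors <- attr(data, "factors")
  x <- data$known_x
  y <- data$y
  N <- length(y)
  m <- length(unique(x))

  for (f in factors)
    if (length(unique(data[[f]])) < 2L)
      stop("factor `", f, "` has a single represented level; ",
           "its variance components are not estimable")

  # random terms: block + factors (residual handled separately)
  term_names <- c("block", factors)
  term_idx <- lapply(term_names, function(tm)
    as.integer(factor(data[[if (tm == "block") "block" else tm]])))
  # warn on aliased terms (identical level partitions): components confounded
  part <- vapply(term_idx, function(ix) paste(ix, collapse = ","), character(1))
  if (anyDuplicated(part)) {
    al <- split(term_names, part)
    al <- al[lengths(al) > 1L]
    warning("aliased random terms (components confounded, split arbitrarily ",
            "between them): ",
            paste(vapply(al, paste, character(1), collapse = " = "),
                  collapse = "; "))
  }

  Js <- lapply(term_idx, function(ix) outer(ix, ix, "=="))
  xx <- outer(x, x)
  Ks <- lapply(Js, function(J) J * xx)
  nt <- length(term_names)
  X <- if (m >= 2L) cbind(`(Intercept)` = 1, x = x)
       else cbind(`(Intercept)` = rep(1, N))
  rx <- ncol(X)

  with_prop <- variance_model == "constant+proportional"
  # theta layout: [sd_A (nt), sd_a] then, if with_prop, [sd_B (nt), sd_b]
  npar_c <- nt + 1L
  npar <- if (with_prop) 2L * npar_c else npar_c

  build_V <- function(v) {
    vc <- v[seq_len(npar_c)]
    vp <- if (with_prop) v[npar_c + seq_len(npar_c)] else numeric(npar_c)
    V <- diag(vc[npar_c] + vp[npar_c] * x^2, N)
    for (i in seq_len(nt)) V <- V + vc[i] * Js[[i]] + vp[i] * Ks[[i]]
    V
  }

  # component design matrices in theta order
  Ms <- c(Js, list(diag(N)))
  if (with_prop) Ms <- c(Ms, Ks, list(diag(x^2, N)))

  # REML deviance/2 and its analytic gradient wrt the sd parameters;
  # both computed from one covariance factorisation, cached between the
  # fn and gr calls that optim makes at the same point
  cache <- new.env(parent = emptyenv())
  neg_reml <- function(th) {
    if (!is.null(cache$th) && identical(th, cache$th)) return(cache$value)
    cache$th <- th
    cache$grad <- NULL
    cache$ok <- FALSE
    V <- build_V(th^2)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(cache$value <- 1e10)
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    XtViX <- crossprod(X, Vi_X)
    bhat <- tryCatch(solve(XtViX, crossprod(X, Vi_y)),
                     error = function(e) NULL)
    if (is.null(bhat)) return(cache$value <- 1e10)
    r <- y - X %*% bhat
    t_vec <- Vi_y - Vi_X %*% bhat              # = V^{-1} r = P y
    ld <- as.numeric(determinant(XtViX)$modulus)
    cache$ch <- ch; cache$Vi_X <- Vi_X; cache$XtViX <- XtViX
    cache$t_vec <- t_vec; cache$ok <- TRUE
    cache$value <- 0.5 * (2 * sum(log(diag(ch))) + ld + sum(r * t_vec))
  }
  neg_reml_gr <- function(th) {
    neg_reml(th)
    if (!is.null(cache$grad)) return(cache$grad)
    if (!cache$ok) return(cache$grad <- rep(0, length(th)))
    # REML projector P = V^{-1} - V^{-1}X (X'V^{-1}X)^{-1} X'V^{-1};
    # d(-2l)/d sigma2_i = tr(P M_i) - y'P M_i P y, chained through
    # sigma2 = theta^2
    Vi <- chol2inv(cache$ch)
    Pm <- Vi - cache$Vi_X %*% solve(cache$XtViX, t(cache$Vi_X))
    t_vec <- cache$t_vec
    cache$grad <- vapply(seq_along(th), function(i)
      th[i] * (sum(Pm * Ms[[i]]) -
               as.numeric(crossprod(t_vec, Ms[[i]] %*% t_vec))),
      numeric(1))
    cache$grad
  }

  # starting points: residual scale split evenly; constant-heavy; prop-heavy
  sd0 <- if (m >= 2L) summary(lm(y ~ x))$sigma else sd(y)
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- max(sd(y), 1e-6)
  xm <- mean(x)
  eq_c <- rep(sd0 / sqrt(npar_c), npar_c)
  eq_p <- rep(sd0 / xm / sqrt(npar_c), npar_c)
  starts <- if (with_prop) list(c(eq_c, eq_p),
                                c(rep(sd0 / 2, npar_c), rep(1e-4 * sd0 / xm, npar_c)),
                                c(rep(1e-4 * sd0, npar_c), rep(sd0 / xm / 2, npar_c)))
            else list(eq_c, eq_c / 4)

  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o1 <- tryCatch(
      optim(s, neg_reml, gr = neg_reml_gr, method = "L-BFGS-B",
            control = list(maxit = max_iter, factr = max(1, tol * 1e12))),
      error = function(e) NULL)
    if (is.null(o1)) next
    # short derivative-free polish guards against L-BFGS-B stalling on
    # the flat sd^2 parameterisation near boundary zeros
    o2 <- optim(o1$par, neg_reml, method = "Nelder-Mead",
                control = list(maxit = 4L * max_iter, reltol = tol * 1e-2))
    o3 <- tryCatch(
      optim(o2$par, neg_reml, gr = neg_reml_gr, method = "L-BFGS-B",
            control = list(maxit = max_iter, factr = max(1, tol * 1e12))),
      error = function(e) o2)
    o <- if (o3$value <= o2$value) o3 else o2
    if (is.null(best) || o$value < best$value) {
      best <- o
      conv <- o$convergence == 0L || abs(o$value - o1$value) < tol * max(1, abs(o$value))
    }
  }
  if (is.null(best))
    stop("REML optimisation failed for every starting point")
  if (!conv)
    warning("REML fit did not meet the convergence tolerance; ",
            "estimates are reported from the best point reached")

  v <- best$par^2
  vc <- v[seq_len(npar_c)]
  vp <- if (with_prop) v[npar_c + seq_len(npar_c)] else numeric(npar_c)
  comps <- variance_components(c(term_names, "repeatability"),
                               const_var = c(vc[seq_len(nt)], vc[npar_c]),
                               prop_var = c(vp[seq_len(nt)], vp[npar_c]))

  # fixed effects by GLS at the estimated covariance
  V <- build_V(v)
  ch <- chol(V)
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, Vi_X)
  bhat <- solve(XtViX, crossprod(X, Vi_y))
  vcov_fixed <- solve(XtViX)
  loglik <- -best$value - 0.5 * (N - rx) * log(2 * pi)

  curve <- if (m >= 2L) {
    if (bhat[2L] <= 0)
      stop("fitted slope beta is not positive; the mean curve is not ",
           "invertible on this dataset")
    mean_curve(alpha = bhat[1L], beta = bhat[2L])
  } else mean_curve(alpha = bhat[1L], beta = 1)

  structure(list(curve = curve, components = comps, converged = conv,
                 n_obs = N, loglik = loglik,
                 se_alpha = sqrt(vcov_fixed[1L, 1L]),
                 se_beta = if (m >= 2L) sqrt(vcov_fixed[2L, 2L]) else NA_real_,
                 vcov_fixed = vcov_fixed,
                 variance_model = variance_model,
                 units = attr(data, "units"),
                 optim = best),
            class = "uncert_fit")
}

#' @export
print.uncert_fit <- function(x, ...) {
  cat("Validation-study mixed model (REML)\n")
  cat(sprintf("  n_obs = %d, restricted logLik = %.4f, converged: %s\n",
              x$n_obs, x$loglik, x$converged))
  cat(sprintf("  mean curve: %.4f + %.4f * x  (SE %.4f, %.4f)\n",
              x$curve$alpha, x$curve$beta, x$se_alpha, x$se_beta))
  print(x$components)
  p <- precision_profile(x)
  cat(sprintf("  aggregate: C = %.5g, P = %.5g\n", p$C, p$P))
  invisible(x)
}

#' @export
logLik.uncert_fit <- function(object, ...) {
  structure(object$loglik, df = NA, class = "logLik")
}
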