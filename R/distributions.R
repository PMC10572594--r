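#' Parametric specification of a measurand distribution
#'
#' A parametric model of a diagnostic measurand is specified by a family and
#' the mean and standard deviation of the measurand itself (not of any
#' transformed scale). Internal family parameters are resolved later by
#' [moment_match()].
#'
#' @param family one of `"normal"`, `"lognormal"`, `"gamma"`.
#' @param mean mean of the measurand, in measurand units (e.g. mg/dL for
#'   fasting plasma glucose, % for HbA1c). Must be positive for the lognormal
#'   and gamma families, whose support is the positive reals.
#' @param sd standard deviation of the measurand, same units; must be
#'   strictly positive (a point mass is rejected, not approximated).
#' @return an object of class `dx_spec`.
#' @examples
#' parametric_spec("lognormal", mean = 141.3, sd = 54.0)
#' @export
parametric_spec <- function(family = c("normal", "lognormal", "gamma"),
                            mean, sd) {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("'mean' must be a single finite number", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("'sd' must be a single strictly positive number", call. = FALSE)
  if (family %in% c("lognormal", "gamma") && mean <= 0)
    stop(sprintf("'mean' must be positive for the %s family", family),
         call. = FALSE)
  structure(list(family = family, mean = mean, sd = sd), class = "dx_spec")
}

#' Resolve a parametric specification by moment matching
#'
#' Solves the family's internal parameters so that the analytic mean and
#' standard deviation of the resolved distribution equal the specified values
#' exactly:
#' \itemize{
#'   \item normal: location = mean, scale = sd;
#'   \item lognormal: `sdlog^2 = log(1 + (sd/mean)^2)`,
#'     `meanlog = log(mean) - sdlog^2/2`;
#'   \item gamma: `shape = (mean/sd)^2`, `scale = sd^2/mean`.
#' }
#' This is moment matching, not maximum likelihood; to fit a family to data
#' by matching the sample moments see [fit_to_data()].
#'
#' @param spec a [parametric_spec()], or a family name (with `mean`, `sd`
#'   supplied) for convenience.
#' @param mean,sd used only when `spec` is a family name.
#' @return a `dx_parametric` model (inherits `dx_model`) supporting [dens()],
#'   [cdf()], [quantile()], [moments()] and [rmodel()].
#' @examples
#' m <- moment_match(parametric_spec("gamma", mean = 1, sd = 1))
#' m$params  # shape 1, scale 1: the unit exponential
#' @export
moment_match <- function(spec, mean = NULL, sd = NULL) {
  if (is.character(spec)) spec <- parametric_spec(spec, mean, sd)
  if (!inherits(spec, "dx_spec")) stop("'spec' must be a parametric_spec")
  mu <- spec$mean; s <- spec$sd
  params <- switch(spec$family,
    normal = list(mean = mu, sd = s),
    lognormal = {
      s2 <- log(1 + (s / mu)^2)
      list(meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
    },
    gamma = list(shape = (mu / s)^2, scale = s^2 / mu)
  )
  structure(list(family = spec$family, mean = mu, sd = s, params = params),
            class = c("dx_parametric", "dx_model"))
}

#' Evaluate a model density
#'
#' @param model a fitted model (`dx_model` or `dx_joint`).
#' @param x numeric vector of evaluation points; for bivariate models supply
#'   `x` and `y` of equal length.
#' @param ... passed to methods.
#' @param log if `TRUE` return the log density.
#' @return numeric vector of (log) density values. Points outside the support
#'   (e.g. `x <= 0` under lognormal or gamma) have density 0 (`-Inf` on the
#'   log scale), not an error.
#' @export
dens <- function(model, x, ..., log = FALSE) UseMethod("dens")

#' Evaluate a model cumulative distribution function
#' @param model a univariate `dx_model`.
#' @param q numeric vector of quantiles.
#' @param ... passed to methods.
#' @return numeric vector of probabilities.
#' @export
cdf <- function(model, q, ...) UseMethod("cdf")

#' Analytic moments of a model
#'
#' @param model a univariate `dx_model`.
#' @param ... passed to methods.
#' @return a named list with `mean`, `median`, `sd`, `skewness` and
#'   `kurtosis`. Kurtosis is reported on the non-excess convention
#'   (normal = 3); most statistics libraries default to excess kurtosis
#'   (normal = 0), so subtract 3 to compare.
#' @export
moments <- function(model, ...) UseMethod("moments")

#' Draw random variates from a model
#' @param model a `dx_model` or `dx_joint`.
#' @param n number of draws.
#' @param ... passed to methods.
#' @return a numeric vector, or a two-column matrix for bivariate models.
#'   Uses the current RNG state; call [set.seed()] for reproducibility.
#' @export
rmodel <- function(model, n, ...) UseMethod("rmodel")

#' @export
dens.dx_parametric <- function(model, x, ..., log = FALSE) {
  p <- model$params
  out <- switch(model$family,
    normal    = stats::dnorm(x, p$mean, p$sd, log = log),
    lognormal = stats::dlnorm(x, p$meanlog, p$sdlog, log = log),
    gamma     = stats::dgamma(x, shape = p$shape, scale = p$scale, log = log)
  )
  # boundary convention: density 0 at x <= 0 on positive-support families
  # (dgamma(0) is finite for shape <= 1, but 0 is not an attainable value)
  if (model$family != "normal") out[x <= 0] <- if (log) -Inf else 0
  out
}

#' @export
cdf.dx_parametric <- function(model, q, ...) {
  p <- model$params
  switch(model$family,
    normal    = stats::pnorm(q, p$mean, p$sd),
    lognormal = stats::plnorm(q, p$meanlog, p$sdlog),
    gamma     = stats::pgamma(q, shape = p$shape, scale = p$scale)
  )
}

#' Quantile function of a fitted model
#' @param x a `dx_parametric` model.
#' @param probs probabilities, each strictly inside (0, 1).
#' @param ... ignored.
#' @export
quantile.dx_parametric <- function(x, probs, ...) {
  check_probs(probs)
  p <- x$params
  switch(x$family,
    normal    = stats::qnorm(probs, p$mean, p$sd),
    lognormal = stats::qlnorm(probs, p$meanlog, p$sdlog),
    gamma     = stats::qgamma(probs, shape = p$shape, scale = p$scale)
  )
}

check_probs <- function(probs) {
  if (any(!is.finite(probs)) || any(probs <= 0) || any(probs >= 1))
    stop("quantile probabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  invisible(probs)
}

#' @export
rmodel.dx_parametric <- function(model, n, ...) {
  p <- model$params
  switch(model$family,
    normal    = stats::rnorm(n, p$mean, p$sd),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    gamma     = stats::rgamma(n, shape = p$shape, scale = p$scale)
  )
}

#' @export
moments.dx_parametric <- function(model, ...) {
  p <- model$params
  out <- switch(model$family,
    normal = list(mean = p$mean, median = p$mean, sd = p$sd,
                  skewness = 0, kurtosis = 3),
    lognormal = {
      w <- exp(p$sdlog^2)  # e^{sigma^2}, >= 1
      list(mean = model$mean, median = exp(p$meanlog), sd = model$sd,
           skewness = (w + 2) * sqrt(w - 1),
           kurtosis = w^4 + 2 * w^3 + 3 * w^2 - 3)
    },
    gamma = {
      k <- p$shape
      list(mean = model$mean,
           median = stats::qgamma(0.5, shape = k, scale = p$scale),
           sd = model$sd, skewness = 2 / sqrt(k), kurtosis = 3 + 6 / k)
    }
  )
  out
}

#' Support of a univariate model
#' @param model a `dx_model`.
#' @return length-2 numeric vector `c(lower, upper)`.
#' @keywords internal
model_support <- function(model) {
  if (inherits(model, "dx_parametric") && model$family != "normal")
    c(0, Inf) else c(-Inf, Inf)
}

#' @export
print.dx_parametric <- function(x, ...) {
  cat(sprintf("<%s model> mean %g, sd %g\n", x$family, x$mean, x$sd))
  cat("  params:", paste(names(x$params), signif(unlist(x$params), 6),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# --- Gaussian copula joint -------------------------------------------------

# Standard-normal scores of the marginal cdfs are clamped to +/- Z_CLAMP so
# the copula density stays finite when posterior surfaces are evaluated far
# into the tails (u numerically 0 or 1 would give z = -/+ Inf).
Z_CLAMP <- 8.2

#' Join two univariate models with a Gaussian copula
#'
#' Builds the bivariate density
#' \deqn{f(x_1, x_2) = c(F_1(x_1), F_2(x_2); \rho)\, f_1(x_1)\, f_2(x_2)}
#' where `c` is the bivariate-normal copula density with correlation `rho`
#' and `F_i`, `f_i` are the marginal cdf/pdf. With two normal marginals this
#' is exactly the bivariate normal distribution. `rho` is the correlation of
#' the normal dependence kernel, not the Pearson correlation of the joint;
#' the two differ for non-normal marginals (see [stats_table()] for the
#' realized Pearson correlation).
#'
#' @param marginal1,marginal2 univariate `dx_model`s (parametric or KDE).
#' @param rho copula correlation, strictly inside (-1, 1).
#' @return a `dx_copula` model (inherits `dx_joint`).
#' @examples
#' m1 <- moment_match("lognormal", mean = 141.3, sd = 54.0)
#' m2 <- moment_match("lognormal", mean = 6.67, sd = 1.57)
#' j <- copula_joint(m1, m2, rho = 0.914)
#' dens(j, 126, 6.5)
#' @export
copula_joint <- function(marginal1, marginal2, rho) {
  if (!inherits(marginal1, "dx_model") || !inherits(marginal2, "dx_model"))
    stop("marginals must be univariate dx_model objects", call. = FALSE)
  check_rho(rho)
  structure(list(marginal1 = marginal1, marginal2 = marginal2, rho = rho),
            class = c("dx_copula", "dx_joint"))
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      abs(rho) >= 1)
    stop("'rho' must lie strictly inside (-1, 1)", call. = FALSE)
  invisible(rho)
}

# log density of the Gaussian copula at normal scores z1, z2; exactly 0 when
# rho = 0 so that independent joints factorize to machine precision.
copula_logdens <- function(z1, z2, rho) {
  if (rho == 0) return(rep(0, length(z1)))
  om <- 1 - rho^2
  -0.5 * log(om) - (rho^2 * (z1^2 + z2^2) - 2 * rho * z1 * z2) / (2 * om)
}

#' @param y second coordinate (same length as `x`) for bivariate models.
#' @rdname dens
#' @export
dens.dx_copula <- function(model, x, y, ..., log = FALSE) {
  lf1 <- dens(model$marginal1, x, log = TRUE)
  lf2 <- dens(model$marginal2, y, log = TRUE)
  z1 <- pmin(pmax(stats::qnorm(cdf(model$marginal1, x)), -Z_CLAMP), Z_CLAMP)
  z2 <- pmin(pmax(stats::qnorm(cdf(model$marginal2, y)), -Z_CLAMP), Z_CLAMP)
  ld <- copula_logdens(z1, z2, model$rho) + lf1 + lf2
  ld[!is.finite(lf1) | !is.finite(lf2)] <- -Inf  # outside a marginal support
  if (log) ld else exp(ld)
}

#' Extract a marginal from a bivariate model
#' @param model a `dx_joint`.
#' @param which 1 or 2.
#' @return the univariate `dx_model` for that coordinate.
#' @export
marginal <- function(model, which) UseMethod("marginal")

#' @export
marginal.dx_copula <- function(model, which) {
  stopifnot(which %in% 1:2)
  if (which == 1L) model$marginal1 else model$marginal2
}

#' @export
rmodel.dx_copula <- function(model, n, ...) {
  z1 <- stats::rnorm(n)
  z2 <- model$rho * z1 + sqrt(1 - model$rho^2) * stats::rnorm(n)
  cbind(quantile(model$marginal1, clamp_unit(stats::pnorm(z1))),
        quantile(model$marginal2, clamp_unit(stats::pnorm(z2))))
}

# keep copula uniforms strictly inside (0,1) for the marginal quantile
clamp_unit <- function(u) pmin(pmax(u, 1e-15), 1 - 1e-15)

#' @export
print.dx_copula <- function(x, ...) {
  cat(sprintf("<Gaussian-copula joint> rho = %g\n", x$rho))
  cat("  marginal 1: "); print(x$marginal1)
  cat("  marginal 2: "); print(x$marginal2)
  invisible(x)
}

#' Fit a parametric family to data by sample-moment matching
#'
#' Convenience wrapper: matches the family to the sample mean and sample
#' standard deviation (n-1) of `x`. This is method-of-moments, not maximum
#' likelihood.
#'
#' @param x numeric data, `length(x) >= 2`.
#' @param family as in [parametric_spec()].
#' @return a `dx_parametric` model.
#' @export
fit_to_data <- function(x, family = c("normal", "lognormal", "gamma")) {
  family <- match.arg(family)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  moment_match(parametric_spec(family, mean(x), stats::sd(x)))
}
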