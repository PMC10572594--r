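#' Silverman's rule-of-thumb bandwidth, in sample-SD units
#'
#' Computes `0.9 * min(1, IQR/(1.34 s)) * n^(-1/5)`, i.e. the classic
#' `0.9 * min(s, IQR/1.34) * n^(-1/5)` reference bandwidth divided by the
#' sample standard deviation `s`, so the result is expressed in SD units and
#' can be passed directly as `h` to [kde_fit()]. The IQR uses
#' linear-interpolation (type-7) quantiles.
#'
#' @param x numeric data, at least 2 distinct values.
#' @param doubled if `TRUE`, multiply by 2 — the setting used for the
#'   smoothed diagnostic densities in this package's examples, where the
#'   reference rule undersmooths heavy-tailed biomarker data.
#' @return a positive scalar bandwidth in SD units.
#' @examples
#' silverman_bandwidth(qnorm(ppoints(1024)))           # 0.9 * 1024^(-1/5)
#' silverman_bandwidth(qnorm(ppoints(1024)), doubled = TRUE)
#' @export
silverman_bandwidth <- function(x, doubled = FALSE) {
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("data are degenerate (zero sample standard deviation)",
         call. = FALSE)
  iqr <- stats::IQR(x, type = 7)
  h <- 0.9 * min(1, iqr / (1.34 * s)) * length(x)^(-1 / 5)
  if (doubled) h <- 2 * h
  h
}

#' Univariate Gaussian kernel density estimate
#'
#' Fits the estimator
#' \deqn{\hat f(x) = \frac{1}{n b}\sum_i \phi\!\left(\frac{x - x_i}{b}\right)}
#' with absolute bandwidth `b = h * sd(x)` (sample sd, n-1). Bandwidths are
#' given in SD units so that one `h` is comparable across measurands with
#' very different scales. The cdf is the corresponding mixture of normal
#' cdfs and the quantile function inverts it by bracketed root-finding.
#'
#' @param x numeric data, `length(x) >= 2`, nondegenerate.
#' @param h bandwidth in sample-SD units; see [silverman_bandwidth()].
#' @return a `dx_kde` model (inherits `dx_model`).
#' @export
kde_fit <- function(x, h) {
  if (length(x) < 2L) stop("KDE needs at least 2 observations", call. = FALSE)
  if (any(!is.finite(x))) stop("KDE data must be finite", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("KDE data are degenerate (zero sample sd)", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be a single positive bandwidth", call. = FALSE)
  structure(list(data = as.numeric(x), h = h, bw = h * s, n = length(x)),
            class = c("dx_kde", "dx_model"))
}

#' @export
dens.dx_kde <- function(model, x, ..., log = FALSE) {
  b <- model$bw
  if (log) {
    # log-sum-exp over kernels: keeps deep-tail log densities finite
    vapply(x, function(xi) {
      l <- stats::dnorm((xi - model$data) / b, log = TRUE)
      m <- max(l)
      m + base::log(sum(exp(l - m))) - base::log(model$n * b)
    }, numeric(1))
  } else {
    vapply(x, function(xi)
      sum(stats::dnorm((xi - model$data) / b)) / (model$n * b), numeric(1))
  }
}

#' @export
cdf.dx_kde <- function(model, q, ...) {
  vapply(q, function(qi)
    mean(stats::pnorm(qi, mean = model$data, sd = model$bw)), numeric(1))
}

#' @rdname quantile.dx_parametric
#' @export
quantile.dx_kde <- function(x, probs, ...) {
  check_probs(probs)
  lo <- min(x$data) - 10 * x$bw
  hi <- max(x$data) + 10 * x$bw
  vapply(probs, function(p) {
    stats::uniroot(function(q) cdf(x, q) - p, lower = lo, upper = hi,
                   extendInt = "upX", tol = 1e-10)$root
  }, numeric(1))
}

#' @export
rmodel.dx_kde <- function(model, n, ...) {
  model$data[sample.int(model$n, n, replace = TRUE)] +
    stats::rnorm(n, sd = model$bw)
}

#' @export
moments.dx_kde <- function(model, ...) {
  # Gaussian-kernel mixture moments in closed form: the KDE mean equals the
  # sample mean; central moments gain the kernel's even moments.
  d <- model$data; b <- model$bw
  mu <- mean(d)
  m2 <- mean((d - mu)^2)            # biased sample variance
  m3 <- mean((d - mu)^3)
  m4 <- mean((d - mu)^4)
  v <- m2 + b^2
  k4 <- m4 + 6 * b^2 * m2 + 3 * b^4
  list(mean = mu, median = quantile(model, 0.5), sd = sqrt(v),
       skewness = m3 / v^1.5, kurtosis = k4 / v^2)
}

#' @export
print.dx_kde <- function(x, ...) {
  cat(sprintf("<Gaussian KDE> n = %d, h = %g SD units (absolute bw %g)\n",
              x$n, x$h, x$bw))
  invisible(x)
}

# --- bivariate KDE ---------------------------------------------------------

#' Bivariate Gaussian kernel density estimate with a correlated kernel
#'
#' Fits \deqn{\hat f(x_1, x_2) = \frac{1}{n}\sum_i
#'   \phi_2\big((x_1, x_2) - (x_{1i}, x_{2i}); H\big)}
#' with kernel covariance
#' `H = [[b1^2, rho b1 b2], [rho b1 b2, b2^2]]`, `b_i = h_i * sd(x_i)`.
#' With `kernel = "diagonal"` the cross term is dropped (`rho` used only by
#' the correlated kernel); with `rho = 0` (or diagonal kernel and `b1 = b2`)
#' the kernel is radial.
#'
#' @param x1,x2 paired numeric data of equal length `>= 2`.
#' @param h1,h2 bandwidths in sample-SD units of each coordinate.
#' @param rho kernel correlation, strictly inside (-1, 1).
#' @param kernel `"correlated"` (default) rotates the kernel by `rho`;
#'   `"diagonal"` ignores `rho` in the kernel (truly radial when `b1 = b2`).
#' @return a `dx_kde2` model (inherits `dx_joint`).
#' @export
kde_fit_bivariate <- function(x1, x2, h1, h2, rho = 0,
                              kernel = c("correlated", "diagonal")) {
  kernel <- match.arg(kernel)
  if (length(x1) != length(x2))
    stop("'x1' and 'x2' must be paired (equal length)", call. = FALSE)
  if (length(x1) < 2L) stop("KDE needs at least 2 pairs", call. = FALSE)
  check_rho(rho)
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  if (s1 == 0 || s2 == 0)
    stop("KDE data are degenerate (zero sample sd)", call. = FALSE)
  for (h in c(h1, h2))
    if (!is.numeric(h) || !is.finite(h) || h <= 0)
      stop("bandwidths must be positive", call. = FALSE)
  structure(list(x1 = as.numeric(x1), x2 = as.numeric(x2),
                 h1 = h1, h2 = h2, b1 = h1 * s1, b2 = h2 * s2,
                 rho = if (kernel == "correlated") rho else 0,
                 kernel = kernel, n = length(x1)),
            class = c("dx_kde2", "dx_joint"))
}

# log bivariate-normal kernel density at standardized offsets u1, u2
kernel2_logdens <- function(u1, u2, rho, b1, b2) {
  om <- 1 - rho^2
  -log(2 * pi * b1 * b2 * sqrt(om)) -
    (u1^2 - 2 * rho * u1 * u2 + u2^2) / (2 * om)
}

#' @export
dens.dx_kde2 <- function(model, x, y, ..., log = FALSE) {
  stopifnot(length(x) == length(y))
  out <- vapply(seq_along(x), function(i) {
    l <- kernel2_logdens((x[i] - model$x1) / model$b1,
                         (y[i] - model$x2) / model$b2,
                         model$rho, model$b1, model$b2)
    m <- max(l)
    m + base::log(sum(exp(l - m))) - base::log(model$n)
  }, numeric(1))
  if (log) out else exp(out)
}

#' @export
marginal.dx_kde2 <- function(model, which) {
  stopifnot(which %in% 1:2)
  # marginal of each bivariate-normal kernel is normal with sd b_i, so the
  # marginal KDE is the univariate KDE at the same absolute bandwidth
  d <- if (which == 1L) model$x1 else model$x2
  b <- if (which == 1L) model$b1 else model$b2
  structure(list(data = d, h = b / stats::sd(d), bw = b, n = model$n),
            class = c("dx_kde", "dx_model"))
}

#' @export
rmodel.dx_kde2 <- function(model, n, ...) {
  i <- sample.int(model$n, n, replace = TRUE)
  e1 <- stats::rnorm(n)
  e2 <- model$rho * e1 + sqrt(1 - model$rho^2) * stats::rnorm(n)
  cbind(model$x1[i] + model$b1 * e1, model$x2[i] + model$b2 * e2)
}

#' @export
print.dx_kde2 <- function(x, ...) {
  cat(sprintf(
    "<bivariate Gaussian KDE> n = %d, h = (%g, %g) SD units, kernel %s, rho = %g\n",
    x$n, x$h1, x$h2, x$kernel, x$rho))
  invisible(x)
}
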