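#' Descriptive statistics of a dataset
#'
#' Sample standard deviation uses n-1; skewness is `m3 / m2^(3/2)` and
#' kurtosis `m4 / m2^2` with central moments computed with divisor n, on the
#' non-excess convention (normal data give kurtosis near 3). Median uses
#' linear-interpolation (type-7) quantiles.
#'
#' @param x numeric data, `length(x) >= 2`, no missing values.
#' @return a one-row data frame with `n`, `mean`, `median`, `sd`,
#'   `skewness`, `kurtosis`.
#' @export
describe <- function(x) {
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x))) stop("data must be finite", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  data.frame(n = n, mean = mu,
             median = unname(stats::quantile(x, 0.5, type = 7)),
             sd = stats::sd(x),
             skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

#' Pearson correlation of paired measurements
#'
#' @param x1,x2 paired numeric vectors, `n >= 3`, each with nonzero variance.
#' @return the product-moment correlation coefficient.
#' @export
correlation <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("unpaired data", call. = FALSE)
  if (length(x1) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0)
    stop("zero variance in a coordinate", call. = FALSE)
  stats::cor(x1, x2)
}

#' Log-likelihood of data under a model
#'
#' `sum(log f(x_i))`. For KDE models fitted on the same data this is the
#' in-sample log-likelihood, which is what the comparative fit table uses;
#' `loo = TRUE` computes the leave-one-out version instead (each point's
#' density excludes its own kernel), which does not reward vanishing
#' bandwidths.
#'
#' @param model a univariate `dx_model`.
#' @param x numeric data (nonempty).
#' @param loo leave-one-out evaluation for KDE models (ignored otherwise).
#' @return the log-likelihood; `-Inf` if any point has zero density, in
#'   which case the attribute `"zero_density_index"` holds the offending
#'   indices.
#' @export
loglikelihood <- function(model, x, loo = FALSE) {
  if (length(x) == 0L) stop("empty data", call. = FALSE)
  if (loo && inherits(model, "dx_kde")) {
    if (model$n < 2L) stop("leave-one-out needs n >= 2", call. = FALSE)
    b <- model$bw
    ll <- vapply(seq_along(x), function(i) {
      d <- model$data[-i]
      l <- stats::dnorm((x[i] - d) / b, log = TRUE)
      m <- max(l)
      m + base::log(sum(exp(l - m))) - base::log(length(d) * b)
    }, numeric(1))
  } else {
    ll <- dens(model, x, log = TRUE)
  }
  bad <- which(!is.finite(ll) & ll < 0)
  out <- if (length(bad)) -Inf else sum(ll)
  if (length(bad)) attr(out, "zero_density_index") <- bad
  out
}

plotting_positions <- function(n, position = c("hazen", "weibull")) {
  position <- match.arg(position)
  i <- seq_len(n)
  switch(position, hazen = (i - 0.5) / n, weibull = i / (n + 1))
}

#' Q-Q point set: model quantiles vs empirical order statistics
#'
#' For the sorted data `x_(i)`, returns the pairs
#' `(quantile(model, p_i), x_(i))` with Hazen plotting positions
#' `p_i = (i - 0.5)/n` (or Weibull `i/(n + 1)`). Points on the identity
#' line indicate a good fit.
#'
#' @param x numeric data, `n >= 2`.
#' @param model a univariate `dx_model` (must have a quantile function;
#'   bivariate models are rejected).
#' @param position plotting-position rule.
#' @return data frame with columns `theoretical` and `empirical`, both
#'   nondecreasing.
#' @export
qq_points <- function(x, model, position = c("hazen", "weibull")) {
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (inherits(model, "dx_joint"))
    stop("Q-Q points require a univariate model", call. = FALSE)
  p <- plotting_positions(length(x), match.arg(position))
  data.frame(theoretical = quantile(model, p), empirical = sort(x))
}

#' P-P point set: model cdf at order statistics vs plotting positions
#'
#' Returns the pairs `(F(x_(i)), p_i)`; identity line indicates fit.
#'
#' @inheritParams qq_points
#' @return data frame with columns `model_cdf` and `empirical`, both
#'   nondecreasing.
#' @export
pp_points <- function(x, model, position = c("hazen", "weibull")) {
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (inherits(model, "dx_joint"))
    stop("P-P points require a univariate model", call. = FALSE)
  p <- plotting_positions(length(x), match.arg(position))
  data.frame(model_cdf = cdf(model, sort(x)), empirical = p)
}

#' Density-normalized histogram table
#'
#' Bin edges follow the selected rule with the exact rule width (no
#' prettying): Freedman-Diaconis `w = 2 IQR n^(-1/3)`, Sturges
#' `ceiling(log2(n)) + 1` equal bins over the range, or a user-fixed width.
#' Heights are density-normalized: `sum(height * width) = 1`.
#'
#' @param x numeric data, `n >= 2`, nondegenerate.
#' @param rule `"fd"`, `"sturges"` or `"fixed"`.
#' @param width bin width when `rule = "fixed"`; also the fallback if the
#'   FD width degenerates (zero IQR).
#' @param origin left edge of the first bin for `rule = "fixed"`; defaults
#'   to `min(x)`.
#' @return data frame with columns `lower`, `upper`, `count`, `density`.
#' @export
histogram_table <- function(x, rule = c("fd", "sturges", "fixed"),
                            width = NULL, origin = NULL) {
  rule <- match.arg(rule)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate data (zero range)", call. = FALSE)
  n <- length(x)
  # left-closed bins of exact rule width; last edge just past max(x)
  width_edges <- function(origin, width) {
    k <- floor((rng[2] - origin) / width) + 1L
    seq(origin, by = width, length.out = k + 1L)
  }
  if (rule == "fd") {
    width <- 2 * stats::IQR(x, type = 7) * n^(-1 / 3)
    if (width <= 0) stop("Freedman-Diaconis width degenerates (zero IQR); use rule = 'fixed'",
                         call. = FALSE)
    edges <- width_edges(rng[1], width)
  } else if (rule == "sturges") {
    k <- ceiling(log2(n)) + 1
    edges <- seq(rng[1], rng[2], length.out = k + 1)
  } else {
    if (is.null(width) || width <= 0)
      stop("rule = 'fixed' needs a positive 'width'", call. = FALSE)
    if (is.null(origin)) origin <- rng[1]
    edges <- width_edges(origin, width)
  }
  h <- graphics::hist(x, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  data.frame(lower = utils::head(h$breaks, -1),
             upper = utils::tail(h$breaks, -1),
             count = h$counts, density = h$density)
}

#' Population statistics table across datasets and model sets
#'
#' One row per (class x measurand x source), where source is the dataset
#' itself or one of the supplied model sets. Model rows carry the model's
#' analytic moments and the in-sample log-likelihood of the class data under
#' that model; dataset rows carry the sample statistics. Each class also
#' gets a correlation row: the sample Pearson correlation for the dataset,
#' and for bivariate models the Pearson correlation realized by the joint,
#' computed by seeded simulation (`cor_draws` draws) because no closed form
#' exists for a Gaussian copula with non-normal marginals.
#'
#' @param cohort a cohort data frame (`test1`, `test2`, `status`).
#' @param panels named list of [diagnostic_panel()]s.
#' @param cor_draws simulation size for model correlations.
#' @param cor_seed RNG seed for that simulation (fixed so the table is
#'   reproducible).
#' @return a data frame with columns `class`, `measurand`, `source`, `n`,
#'   `mean`, `median`, `sd`, `skewness`, `kurtosis`, `loglik`, `correlation`.
#' @export
stats_table <- function(cohort, panels, cor_draws = 1e5, cor_seed = 20231) {
  classes <- c(D = "diseased", ND = "nondiseased")
  rows <- list()
  for (lab in names(classes)) {
    cls <- classes[[lab]]
    sub <- cohort[cohort$status == lab, , drop = FALSE]
    samp_cor <- correlation(sub$test1, sub$test2)
    for (k in 1:2) {
      xs <- sub[[paste0("test", k)]]
      dstat <- describe(xs)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(class = cls, measurand = paste0("test", k),
                   source = "dataset"),
        dstat, data.frame(loglik = NA_real_, correlation = samp_cor))
      for (nm in names(panels)) {
        mdl <- panels[[nm]][[paste0("test", k)]][[cls]]
        mom <- moments(mdl)
        jm <- panels[[nm]]$joint[[cls]]
        set.seed(cor_seed)
        draws <- rmodel(jm, cor_draws)
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls, measurand = paste0("test", k), source = nm,
          n = length(xs), mean = mom$mean, median = mom$median, sd = mom$sd,
          skewness = mom$skewness, kurtosis = mom$kurtosis,
          loglik = as.numeric(loglikelihood(mdl, xs)),
          correlation = stats::cor(draws[, 1], draws[, 2]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
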