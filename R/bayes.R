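#' Estimate the prior probability of disease from counts
#'
#' @param n_diseased number of diseased subjects in the reference sample.
#' @param n_total total sample size; must be positive and at least
#'   `n_diseased`.
#' @return the prevalence `n_diseased / n_total`, a probability in `[0, 1]`.
#' @examples
#' estimate_prior(211, 3854)  # 0.0547..., ~ 0.055
#' @export
estimate_prior <- function(n_diseased, n_total) {
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total <= 0)
    stop("'n_total' must be a positive count", call. = FALSE)
  if (!is.numeric(n_diseased) || length(n_diseased) != 1L || n_diseased < 0)
    stop("'n_diseased' must be a nonnegative count", call. = FALSE)
  if (n_diseased > n_total)
    stop("'n_diseased' cannot exceed 'n_total'", call. = FALSE)
  n_diseased / n_total
}

#' Pair of class-conditional models for one measurand (or the combination)
#'
#' @param diseased,nondiseased two models of the same kind: both univariate
#'   (`dx_model`) or both bivariate (`dx_joint`).
#' @return a `dx_pair`.
#' @export
population_pair <- function(diseased, nondiseased) {
  uni <- inherits(diseased, "dx_model") && inherits(nondiseased, "dx_model")
  biv <- inherits(diseased, "dx_joint") && inherits(nondiseased, "dx_joint")
  if (!uni && !biv)
    stop("diseased and nondiseased models must both be univariate or both bivariate",
         call. = FALSE)
  structure(list(diseased = diseased, nondiseased = nondiseased,
                 bivariate = biv), class = "dx_pair")
}

#' Diagnostic panel: two measurands, their joint, and the prior
#'
#' The object on which posteriors are evaluated. `test1` and `test2` hold
#' univariate class-conditional pairs; `joint` holds the bivariate pair used
#' for the combined posterior (each class carries its own correlation). When
#' the joint models are Gaussian copulas built from parametric marginals,
#' construction asserts that their marginals coincide with the univariate
#' models.
#'
#' @param prior prior probability of disease, in `[0, 1]`.
#' @param test1,test2 univariate [population_pair()]s.
#' @param joint a bivariate [population_pair()].
#' @param measurands,units length-2 character vectors of names and unit
#'   labels (metadata only; no conversion is performed).
#' @return a `dx_panel`.
#' @seealso [panel_parametric()], [panel_kde()] for one-call constructors.
#' @export
diagnostic_panel <- function(prior, test1, test2, joint,
                             measurands = c("test1", "test2"),
                             units = c("", "")) {
  if (!is.numeric(prior) || length(prior) != 1L || prior < 0 || prior > 1)
    stop("'prior' must be a probability in [0, 1]", call. = FALSE)
  for (p in list(test1, test2)) {
    if (!inherits(p, "dx_pair") || p$bivariate)
      stop("'test1'/'test2' must be univariate population_pairs", call. = FALSE)
  }
  if (!inherits(joint, "dx_pair") || !joint$bivariate)
    stop("'joint' must be a bivariate population_pair", call. = FALSE)
  for (cls in c("diseased", "nondiseased")) {
    jm <- joint[[cls]]
    if (inherits(jm, "dx_copula")) {
      for (k in 1:2) {
        uv <- (if (k == 1) test1 else test2)[[cls]]
        mg <- marginal(jm, k)
        if (inherits(uv, "dx_parametric") && inherits(mg, "dx_parametric") &&
            !isTRUE(all.equal(mg$params, uv$params, tolerance = 1e-12)))
          stop(sprintf(
            "joint %s marginal %d does not match the univariate model", cls, k),
            call. = FALSE)
      }
    }
  }
  structure(list(prior = prior, test1 = test1, test2 = test2, joint = joint,
                 measurands = measurands, units = units),
            class = "dx_panel")
}

#' Build a fully parametric diagnostic panel
#'
#' @param prior prior probability of disease.
#' @param diseased,nondiseased lists with elements `test1`, `test2` (each a
#'   [parametric_spec()] or a list `(family, mean, sd)`) and `rho` (the
#'   class's copula correlation).
#' @param measurands,units metadata, see [diagnostic_panel()].
#' @return a `dx_panel` whose joint models are Gaussian copulas over the
#'   moment-matched marginals.
#' @examples
#' panel <- panel_parametric(
#'   prior = estimate_prior(211, 3854),
#'   diseased = list(test1 = list("lognormal", 141.3, 54.0),
#'                   test2 = list("lognormal", 6.67, 1.57), rho = 0.914),
#'   nondiseased = list(test1 = list("lognormal", 99.9, 10.1),
#'                      test2 = list("lognormal", 5.47, 0.38), rho = 0.320),
#'   measurands = c("FPG", "HbA1c"), units = c("mg/dL", "%"))
#' @export
panel_parametric <- function(prior, diseased, nondiseased,
                             measurands = c("test1", "test2"),
                             units = c("", "")) {
  as_spec <- function(s) {
    if (inherits(s, "dx_spec")) s
    else parametric_spec(s[[1]], s[[2]], s[[3]])
  }
  build <- function(cls) {
    m1 <- moment_match(as_spec(cls$test1))
    m2 <- moment_match(as_spec(cls$test2))
    list(m1 = m1, m2 = m2, joint = copula_joint(m1, m2, cls$rho))
  }
  d <- build(diseased); nd <- build(nondiseased)
  diagnostic_panel(prior,
                   population_pair(d$m1, nd$m1),
                   population_pair(d$m2, nd$m2),
                   population_pair(d$joint, nd$joint),
                   measurands = measurands, units = units)
}

#' Build a KDE diagnostic panel from a cohort dataset
#'
#' Fits univariate Gaussian KDEs per class and measurand, and a bivariate
#' KDE per class, from the labelled cohort.
#'
#' @param prior prior probability of disease.
#' @param cohort a cohort data frame with columns `test1`, `test2`, `status`
#'   (`"D"`/`"ND"`), as produced by [generate_cohort()] or [read_cohort()].
#' @param h named list/vector of bandwidths in SD units:
#'   `diseased = c(h1, h2)`, `nondiseased = c(h1, h2)`. `NULL` entries
#'   default to the doubled Silverman rule.
#' @param rho named vector `c(diseased = , nondiseased = )` of kernel
#'   correlations for the bivariate KDEs.
#' @param kernel passed to [kde_fit_bivariate()].
#' @inheritParams diagnostic_panel
#' @return a `dx_panel`.
#' @export
panel_kde <- function(prior, cohort, h = NULL,
                      rho = c(diseased = 0, nondiseased = 0),
                      kernel = "correlated",
                      measurands = c("test1", "test2"), units = c("", "")) {
  build <- function(label, hcls, rhocls) {
    sub <- cohort[cohort$status == label, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop(sprintf("fewer than 2 records with status '%s'", label),
           call. = FALSE)
    if (is.null(hcls))
      hcls <- c(silverman_bandwidth(sub$test1, doubled = TRUE),
                silverman_bandwidth(sub$test2, doubled = TRUE))
    list(m1 = kde_fit(sub$test1, hcls[1]),
         m2 = kde_fit(sub$test2, hcls[2]),
         joint = kde_fit_bivariate(sub$test1, sub$test2, hcls[1], hcls[2],
                                   rho = rhocls, kernel = kernel))
  }
  d <- build("D", h$diseased, unname(rho["diseased"]))
  nd <- build("ND", h$nondiseased, unname(rho["nondiseased"]))
  diagnostic_panel(prior,
                   population_pair(d$m1, nd$m1),
                   population_pair(d$m2, nd$m2),
                   population_pair(d$joint, nd$joint),
                   measurands = measurands, units = units)
}

# stable logistic posterior from prior log-odds and class log-likelihoods;
# returns list(value, log_odds, defined)
posterior_from_loglik <- function(prior, ll_d, ll_nd) {
  if (prior == 0) {
    val <- ifelse(is.finite(ll_nd), 0, NA_real_)
    return(list(value = val, log_odds = rep(-Inf, length(ll_d)),
                defined = is.finite(ll_nd)))
  }
  if (prior == 1) {
    val <- ifelse(is.finite(ll_d), 1, NA_real_)
    return(list(value = val, log_odds = rep(Inf, length(ll_d)),
                defined = is.finite(ll_d)))
  }
  eta0 <- stats::qlogis(prior)
  lr <- ll_d - ll_nd
  eta <- eta0 + lr
  val <- stats::plogis(eta)
  # one class density zero: the limit posterior is exactly 0 or 1
  val[is.infinite(ll_nd) & ll_nd < 0 & is.finite(ll_d)] <- 1
  val[is.infinite(ll_d) & ll_d < 0 & is.finite(ll_nd)] <- 0
  undef <- (is.infinite(ll_d) & ll_d < 0) & (is.infinite(ll_nd) & ll_nd < 0)
  val[undef] <- NA_real_
  list(value = val, log_odds = eta, defined = !undef)
}

pair_loglik <- function(pair, x) {
  if (pair$bivariate) {
    list(d = dens(pair$diseased, x[[1]], x[[2]], log = TRUE),
         nd = dens(pair$nondiseased, x[[1]], x[[2]], log = TRUE))
  } else {
    list(d = dens(pair$diseased, x, log = TRUE),
         nd = dens(pair$nondiseased, x, log = TRUE))
  }
}

#' Posterior probability of disease at a measurement point
#'
#' Evaluates Bayes' theorem
#' \deqn{P(D \mid x) = \frac{v f_D(x)}{v f_D(x) + (1 - v) f_{ND}(x)}}
#' in log space via the logistic form
#' `plogis(qlogis(v) + log f_D(x) - log f_ND(x))`, which is stable deep in
#' the tails where the densities underflow. If exactly one class density is
#' zero the posterior is the well-defined limit 0 or 1; if both are zero the
#' result is flagged undefined (`defined = FALSE`, value `NA`).
#'
#' @param panel a [diagnostic_panel()].
#' @param which `"test1"`, `"test2"` or `"combined"`.
#' @param x the measurement: a single value for a univariate test, a
#'   length-2 vector (or list) `c(x1, x2)` for `"combined"`.
#' @return a `dx_posterior`: list with `value`, `log_lik_diseased`,
#'   `log_lik_nondiseased`, `log_odds`, `defined`, `which` and `x`.
#' @export
posterior <- function(panel, which = c("test1", "test2", "combined"), x) {
  which <- match.arg(which)
  stopifnot(inherits(panel, "dx_panel"))
  if (which == "combined") {
    if (length(x) != 2L) stop("combined posterior needs a pair (x1, x2)",
                              call. = FALSE)
    ll <- pair_loglik(panel$joint, list(x[[1]], x[[2]]))
  } else {
    if (length(x) != 1L) stop("univariate posterior takes a single value",
                              call. = FALSE)
    ll <- pair_loglik(panel[[which]], x)
  }
  p <- posterior_from_loglik(panel$prior, ll$d, ll$nd)
  structure(list(value = p$value, log_lik_diseased = ll$d,
                 log_lik_nondiseased = ll$nd, log_odds = p$log_odds,
                 defined = p$defined, which = which, x = x),
            class = "dx_posterior")
}

#' @export
print.dx_posterior <- function(x, ...) {
  if (!x$defined)
    cat(sprintf("posterior(%s) at %s: undefined (zero density in both classes)\n",
                x$which, paste(signif(unlist(x$x), 6), collapse = ", ")))
  else
    cat(sprintf("posterior(%s) at %s: %.6f\n", x$which,
                paste(signif(unlist(x$x), 6), collapse = ", "), x$value))
  invisible(x)
}

#' Posterior probability curve over a grid
#'
#' @param panel a [diagnostic_panel()].
#' @param which `"test1"` or `"test2"`.
#' @param grid numeric grid of measurement values (nonempty).
#' @return data frame with columns `x` and `posterior`; grid points where
#'   both class densities vanish are dropped and reported in the
#'   `"dropped"` attribute. The returned curve is NaN-free.
#' @export
posterior_curve <- function(panel, which = c("test1", "test2"), grid) {
  which <- match.arg(which)
  if (length(grid) == 0L) stop("empty grid", call. = FALSE)
  ll <- pair_loglik(panel[[which]], grid)
  p <- posterior_from_loglik(panel$prior, ll$d, ll$nd)
  keep <- p$defined & !is.na(p$value)
  out <- data.frame(x = grid[keep], posterior = p$value[keep])
  attr(out, "dropped") <- grid[!keep]
  out
}

#' Posterior probability surface over a grid of measurement pairs
#'
#' @param panel a [diagnostic_panel()].
#' @param grid1,grid2 numeric grids for the two measurands.
#' @return a `length(grid1) x length(grid2)` matrix of posterior values
#'   (`NA` where both class densities vanish), with the grids as dimnames.
#' @export
posterior_surface <- function(panel, grid1, grid2) {
  if (length(grid1) == 0L || length(grid2) == 0L)
    stop("empty grid", call. = FALSE)
  g <- expand.grid(x1 = grid1, x2 = grid2, KEEP.OUT.ATTRS = FALSE)
  ll <- pair_loglik(panel$joint, list(g$x1, g$x2))
  p <- posterior_from_loglik(panel$prior, ll$d, ll$nd)
  matrix(p$value, nrow = length(grid1), ncol = length(grid2),
         dimnames = list(format(grid1, trim = TRUE),
                         format(grid2, trim = TRUE)))
}

#' Sequential (chained) two-test Bayes update
#'
#' Applies the test1 update to the prior, then uses the resulting posterior
#' as the prior for test2, treating the two tests as conditionally
#' independent given disease status. Chaining is done on the log-odds scale:
#' `eta = qlogis(v) + LR1 + LR2` where `LRk` is the log-likelihood ratio of
#' test k, which is identical to passing the intermediate posterior onward
#' but does not saturate at double precision in deep tails. When both class
#' copulas have `rho = 0`, this equals the combined joint posterior.
#'
#' @param panel a [diagnostic_panel()].
#' @param x1,x2 measurement values (vectorized, equal length).
#' @return numeric vector of posterior probabilities.
#' @export
posterior_sequential <- function(panel, x1, x2) {
  ll1 <- pair_loglik(panel$test1, x1)
  ll2 <- pair_loglik(panel$test2, x2)
  eta <- stats::qlogis(panel$prior) + (ll1$d - ll1$nd) + (ll2$d - ll2$nd)
  stats::plogis(eta)
}

#' Posterior table at a query point, across model sets
#'
#' Produces the summary table of prior and posterior probabilities of
#' disease at one pair of measurement values: one row per model kind, with
#' columns for the prior and the posteriors given test 1 alone, test 2
#' alone, and both combined.
#'
#' @param panels named list of [diagnostic_panel()]s (e.g.
#'   `list(parametric = ..., kde = ...)`).
#' @param x1,x2 the query measurement values.
#' @return a data frame with columns `model`, `prior`, `posterior_test1`,
#'   `posterior_test2`, `posterior_combined`.
#' @export
posterior_table <- function(panels, x1, x2) {
  stopifnot(is.list(panels), length(panels) >= 1L)
  rows <- lapply(names(panels), function(nm) {
    p <- panels[[nm]]
    data.frame(model = nm, prior = p$prior,
               posterior_test1 = posterior(p, "test1", x1)$value,
               posterior_test2 = posterior(p, "test2", x2)$value,
               posterior_combined = posterior(p, "combined", c(x1, x2))$value)
  })
  do.call(rbind, rows)
}
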