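test_that("prior estimation is the simple prevalence with guarded inputs", {
  expect_equal(estimate_prior(211, 3854), 211 / 3854)
  expect_equal(round(estimate_prior(211, 3854), 3), 0.055)
  expect_equal(estimate_prior(0, 100), 0)
  expect_equal(estimate_prior(100, 100), 1)
  expect_error(estimate_prior(5, 0), "n_total")
  expect_error(estimate_prior(11, 10), "exceed")
  expect_error(estimate_prior(-1, 10), "nonnegative")
})

test_that("equal class likelihoods return the prior; degenerate priors are fixed points", {
  m <- moment_match(parametric_spec("lognormal", 99.9, 10.1))
  j <- copula_joint(m, m, 0.3)
  pan <- diagnostic_panel(0.055, population_pair(m, m), population_pair(m, m),
                          population_pair(j, j))
  for (x in c(80, 99.9, 130))
    expect_equal(posterior(pan, "test1", x)$value, 0.055, tolerance = 1e-12)
  cur <- posterior_curve(pan, "test1", seq(70, 140, length.out = 51))
  expect_equal(cur$posterior, rep(0.055, 51), tolerance = 1e-12)

  pan0 <- diagnostic_panel(0, population_pair(m, m), population_pair(m, m),
                           population_pair(j, j))
  expect_equal(posterior(pan0, "test1", 100)$value, 0)
  pan1 <- diagnostic_panel(1, population_pair(m, m), population_pair(m, m),
                           population_pair(j, j))
  expect_equal(posterior(pan1, "test1", 100)$value, 1)
})

test_that("posterior agrees with a cohort-simulation Monte-Carlo oracle at 126 mg/dL", {
  pan <- ref_panel()
  v <- ref_prior()
  set.seed(17)
  n <- 2e6
  lab <- rbinom(n, 1, v) == 1
  x <- numeric(n)
  x[lab] <- rmodel(pan$test1$diseased, sum(lab))
  x[!lab] <- rmodel(pan$test1$nondiseased, sum(!lab))
  win <- abs(x - 126) <= 0.5
  emp <- mean(lab[win])
  model <- mean(posterior_curve(pan, "test1", x[win])$posterior)
  se <- sqrt(model * (1 - model) / sum(win))
  expect_lt(abs(emp - model), 3 * se)
})

test_that("posterior is monotone nondecreasing in the prior at fixed x", {
  d <- moment_match(parametric_spec("lognormal", 141.3, 54.0))
  nd <- moment_match(parametric_spec("lognormal", 99.9, 10.1))
  for (x in c(60, 100, 126, 200)) {
    lls <- list(d = dens(d, x, log = TRUE), nd = dens(nd, x, log = TRUE))
    vals <- vapply(seq(0, 1, by = 0.05), function(v)
      bayesdx:::posterior_from_loglik(v, lls$d, lls$nd)$value, numeric(1))
    expect_true(all(diff(vals) >= -1e-15))
  }
})

test_that("law of total probability: posterior integrates back to the prior", {
  pan <- ref_panel()
  v <- ref_prior()
  fd <- function(x) dens(pan$test1$diseased, x)
  fnd <- function(x) dens(pan$test1$nondiseased, x)
  mix <- function(x) v * fd(x) + (1 - v) * fnd(x)
  post_mix <- function(x) {
    p <- posterior_curve(pan, "test1", x)$posterior
    p * mix(x)
  }
  got <- stats::integrate(post_mix, 1e-6, 3000, rel.tol = 1e-10,
                          subdivisions = 1000L)$value
  expect_equal(got, v, tolerance = 1e-6)
})

test_that("log-space evaluation is finite and sensible deep in the tails", {
  pan <- ref_panel()
  far <- quantile(pan$test1$nondiseased, 1 - 1e-12)
  p_far <- posterior(pan, "test1", far)
  p_mode <- posterior(pan, "test1", moments(pan$test1$nondiseased)$median)
  expect_true(is.finite(p_far$value))
  expect_true(p_far$defined)
  expect_gte(p_far$value, p_mode$value)
  # even further out: still defined, no NaN
  p_ext <- posterior(pan, "test1", 5000)
  expect_false(is.nan(p_ext$value))
})

test_that("zero-density points: one-sided limits and typed undefined results", {
  d <- moment_match(parametric_spec("lognormal", 141.3, 54.0))
  nd_norm <- moment_match(parametric_spec("normal", 99.9, 10.1))
  jd <- copula_joint(d, d, 0)
  # support mismatch: at x < 0 only the normal class has density
  pan <- diagnostic_panel(0.055, population_pair(d, nd_norm),
                          population_pair(d, nd_norm),
                          population_pair(jd, copula_joint(nd_norm, nd_norm, 0)))
  p <- posterior(pan, "test1", -5)
  expect_identical(p$value, 0)
  expect_true(p$defined)
  # both supports violated: typed undefined, not a number
  nd_ln <- moment_match(parametric_spec("lognormal", 99.9, 10.1))
  pan2 <- diagnostic_panel(0.055, population_pair(d, nd_ln),
                           population_pair(d, nd_ln),
                           population_pair(jd, copula_joint(nd_ln, nd_ln, 0)))
  p2 <- posterior(pan2, "test1", -5)
  expect_false(p2$defined)
  expect_true(is.na(p2$value))
  # undefined grid points are dropped from curves, reported as an attribute
  cur <- posterior_curve(pan2, "test1", c(-5, 100, 126))
  expect_equal(nrow(cur), 2L)
  expect_equal(attr(cur, "dropped"), -5)
})

test_that("combined posterior at rho = 0 equals the chained sequential update", {
  pan <- ref_panel(rho_d = 0, rho_nd = 0)
  g1 <- seq(quantile(pan$test1$nondiseased, 0.001),
            quantile(pan$test1$diseased, 0.999), length.out = 50)
  g2 <- seq(quantile(pan$test2$nondiseased, 0.001),
            quantile(pan$test2$diseased, 0.999), length.out = 50)
  surf <- posterior_surface(pan, g1, g2)
  g <- expand.grid(x1 = g1, x2 = g2)
  seqp <- posterior_sequential(pan, g$x1, g$x2)
  expect_lt(max(abs(as.vector(surf) - seqp)), 1e-12)
})

test_that("posterior surfaces are probabilities everywhere", {
  pan <- ref_panel()
  g1 <- seq(40, 450, length.out = 50)
  g2 <- seq(3, 14, length.out = 50)
  surf <- posterior_surface(pan, g1, g2)
  expect_true(all(surf >= 0 & surf <= 1))
  expect_false(anyNA(surf))
})

test_that("the class correlation changes the combined posterior at discordant points", {
  pan_cor <- ref_panel()                    # diseased rho = 0.914
  pan_ind <- ref_panel(rho_d = 0)           # diseased rho = 0
  x <- c(140, 5.0)                          # raised FPG, low HbA1c: discordant
  p_cor <- posterior(pan_cor, "combined", x)$value
  p_ind <- posterior(pan_ind, "combined", x)$value
  expect_gt(abs(p_cor - p_ind), 1e-3)
  # direction oracle: Monte-Carlo density of the diseased joint near x under
  # each rho; strong positive correlation makes the discordant point rarer
  set.seed(31)
  in_box <- function(m) {
    d <- rmodel(m, 4e5)
    mean(abs(d[, 1] - x[1]) < 10 & abs(d[, 2] - x[2]) < 0.3)
  }
  dens_cor <- in_box(pan_cor$joint$diseased)
  dens_ind <- in_box(pan_ind$joint$diseased)
  expect_lt(dens_cor, dens_ind)
  expect_lt(p_cor, p_ind)
})

test_that("parametric posterior curves are double sigmoidal over the reference panel", {
  pan <- ref_panel()
  grid <- seq(20, 400, length.out = 401)
  cur <- posterior_curve(pan, "test1", grid)
  p <- cur$posterior
  i_min <- which.min(p)
  expect_gt(i_min, 1)                  # interior minimum ...
  expect_lt(i_min, length(p))
  expect_gt(p[1], p[i_min])            # ... with both tails rising
  expect_gt(p[length(p)], p[i_min])
  expect_gt(p[1], ref_prior())         # heavier diseased left tail near 0
  expect_gt(p[length(p)], 0.9)         # and posterior -> 1 for large values
})

test_that("KDE posterior curves propagate multimodality of the diseased class", {
  x_d <- generate_multimodal_fixture(means = c(80, 140, 220),
                                     sds = c(6, 8, 12),
                                     weights = c(1, 1, 1) / 3,
                                     n = 1500, seed = 91)
  set.seed(92)
  x_nd <- rmodel(moment_match(parametric_spec("lognormal", 120, 45)), 3000)
  kd <- kde_fit(x_d, 0.15)
  knd <- kde_fit(x_nd, 0.3)
  j <- kde_fit_bivariate(x_d, x_d, 0.15, 0.15, 0)
  pan <- diagnostic_panel(0.055, population_pair(kd, knd),
                          population_pair(kd, knd), population_pair(j, j))
  cur <- posterior_curve(pan, "test1", seq(60, 260, length.out = 301))
  expect_gte(local_maxima(cur$posterior), 2)
})

test_that("panel construction enforces kind and marginal-consistency invariants", {
  m <- moment_match(parametric_spec("lognormal", 99.9, 10.1))
  d <- moment_match(parametric_spec("lognormal", 141.3, 54.0))
  j <- copula_joint(d, d, 0.5)
  expect_error(population_pair(m, j), "univariate or both bivariate")
  # joint whose marginals do not match the univariate models
  expect_error(
    diagnostic_panel(0.1, population_pair(d, m), population_pair(d, m),
                     population_pair(copula_joint(m, m, 0.2),
                                     copula_joint(m, m, 0.2))),
    "marginal")
  expect_error(
    diagnostic_panel(1.5, population_pair(d, m), population_pair(d, m),
                     population_pair(j, j)),
    "prior")
  pan <- ref_panel()
  expect_error(posterior(pan, "combined", 126), "pair")
  expect_error(posterior(pan, "test1", c(1, 2)), "single value")
  expect_error(posterior_curve(pan, "test1", numeric(0)), "empty grid")
})

test_that("posterior_table reports one row per model set with shared prior", {
  pans <- list(parametric = ref_panel(), independent = ref_panel(0, 0))
  tab <- posterior_table(pans, 126, 6.5)
  expect_equal(tab$model, c("parametric", "independent"))
  expect_equal(tab$prior, rep(ref_prior(), 2))
  expect_true(all(tab$posterior_test1 >= 0 & tab$posterior_test1 <= 1))
  expect_equal(tab$posterior_test1[1], tab$posterior_test1[2])  # same marginals
})
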