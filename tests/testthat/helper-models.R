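# Shared fixtures: the glycemia reference panel (lognormal FPG/HbA1c in two
# classes, Gaussian copulas, prevalence 211/3854) and small oracle helpers.

ref_prior <- function() estimate_prior(211, 3854)

ref_diseased <- function() list(
  test1 = list("lognormal", 141.3, 54.0),
  test2 = list("lognormal", 6.67, 1.57), rho = 0.914)

ref_nondiseased <- function() list(
  test1 = list("lognormal", 99.9, 10.1),
  test2 = list("lognormal", 5.47, 0.38), rho = 0.320)

ref_panel <- function(rho_d = 0.914, rho_nd = 0.320) {
  d <- ref_diseased(); d$rho <- rho_d
  nd <- ref_nondiseased(); nd$rho <- rho_nd
  panel_parametric(ref_prior(), d, nd,
                   measurands = c("FPG", "HbA1c"), units = c("mg/dL", "%"))
}

# lognormal model with meanlog 0, sdlog 1 (standard lognormal)
std_lognormal <- function() {
  m <- exp(0.5)
  s <- sqrt((exp(1) - 1) * exp(1))
  moment_match(parametric_spec("lognormal", m, s))
}

# closed-form bivariate normal density (independent oracle for the copula)
bvn_dens <- function(x1, x2, mu1, mu2, s1, s2, rho) {
  z1 <- (x1 - mu1) / s1
  z2 <- (x2 - mu2) / s2
  q <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
  exp(-q / 2) / (2 * pi * s1 * s2 * sqrt(1 - rho^2))
}

# batch-based Monte-Carlo estimate of a statistic with its standard error
mc_batches <- function(draw, stat, n_batch = 20L, n_per = 5e4) {
  vals <- vapply(seq_len(n_batch), function(i) stat(draw(n_per)), numeric(1))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(n_batch))
}

# count strict local maxima of a numeric sequence (interior only unless
# boundary = TRUE, which treats the ends as candidate modes)
local_maxima <- function(y, boundary = FALSE) {
  if (boundary) y <- c(-Inf, y, -Inf)
  n <- length(y)
  sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n])
}

# nested adaptive quadrature of a bivariate density over a rectangle
quad2 <- function(f, xlo, xhi, ylo, yhi, tol = 1e-9) {
  inner <- function(x) {
    stats::integrate(function(y) f(rep(x, length(y)), y), ylo, yhi,
                     rel.tol = tol, subdivisions = 500L)$value
  }
  stats::integrate(Vectorize(inner), xlo, xhi, rel.tol = tol,
                   subdivisions = 500L)$value
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample skewness / non-excess kurtosis (independent arithmetic)
sample_skew <- function(x) {
  m <- mean(x); m2 <- mean((x - m)^2); mean((x - m)^3) / m2^1.5
}
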