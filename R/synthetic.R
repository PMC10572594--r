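#' Recipe for a synthetic diagnostic cohort
#'
#' Describes the generating process: a Bernoulli disease label with success
#' probability `prior`, and per-class Gaussian-copula joints over parametric
#' marginals for the two measurands.
#'
#' @param prior prior probability of disease, strictly inside (0, 1) (use
#'   boundary values only for degenerate test fixtures).
#' @param diseased,nondiseased lists with `test1`, `test2` (each a
#'   [parametric_spec()] or a list `(family, mean, sd)`) and `rho`.
#' @param n cohort size, `>= 1`.
#' @param seed integer RNG seed; recorded in the generated cohort's
#'   metadata.
#' @param measurands,units metadata labels.
#' @return a `dx_recipe`.
#' @export
cohort_recipe <- function(prior, diseased, nondiseased, n, seed = 1L,
                          measurands = c("test1", "test2"),
                          units = c("", "")) {
  if (!is.numeric(prior) || prior < 0 || prior > 1)
    stop("'prior' must be a probability", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  as_spec <- function(s) if (inherits(s, "dx_spec")) s else
    parametric_spec(s[[1]], s[[2]], s[[3]])
  build <- function(cls) {
    copula_joint(moment_match(as_spec(cls$test1)),
                 moment_match(as_spec(cls$test2)), cls$rho)
  }
  structure(list(prior = prior, diseased = build(diseased),
                 nondiseased = build(nondiseased), n = as.integer(n),
                 seed = as.integer(seed), measurands = measurands,
                 units = units),
            class = "dx_recipe")
}

#' Reference cohort recipe: skewed, correlated glycemia panel
#'
#' The packaged example: two right-skewed, positively correlated measurands
#' (fasting plasma glucose in mg/dL and HbA1c in %) in a mostly nondiseased
#' population. Diseased class: lognormal FPG (141.3, 54.0) and HbA1c
#' (6.67, 1.57) with copula correlation 0.914; nondiseased class: lognormal
#' FPG (99.9, 10.1) and HbA1c (5.47, 0.38) with correlation 0.320; disease
#' prevalence 211/3854 = 0.0547.
#'
#' @param n cohort size (default 3854, the reference sample size).
#' @param seed RNG seed.
#' @return a `dx_recipe`.
#' @export
example_recipe <- function(n = 3854, seed = 1L) {
  cohort_recipe(
    prior = estimate_prior(211, 3854),
    diseased = list(test1 = list("lognormal", 141.3, 54.0),
                    test2 = list("lognormal", 6.67, 1.57), rho = 0.914),
    nondiseased = list(test1 = list("lognormal", 99.9, 10.1),
                       test2 = list("lognormal", 5.47, 0.38), rho = 0.320),
    n = n, seed = seed,
    measurands = c("FPG", "HbA1c"), units = c("mg/dL", "%"))
}

#' Generate a labelled synthetic cohort
#'
#' Labels are Bernoulli(`prior`); conditional on the label, measurement
#' pairs are drawn exactly from the class's Gaussian-copula joint by the
#' inverse-marginal transform of correlated standard-normal draws.
#' Deterministic under the recipe's seed.
#'
#' @param recipe a [cohort_recipe()].
#' @return a data frame of class `dx_cohort` with columns `test1`, `test2`,
#'   `status` (`"D"`/`"ND"`) and attributes `measurands`, `units`, `seed`.
#' @export
generate_cohort <- function(recipe) {
  stopifnot(inherits(recipe, "dx_recipe"))
  set.seed(recipe$seed)
  n <- recipe$n
  lab <- stats::rbinom(n, 1L, recipe$prior) == 1L
  x <- matrix(NA_real_, n, 2)
  if (any(lab))  x[lab, ]  <- rmodel(recipe$diseased, sum(lab))
  if (any(!lab)) x[!lab, ] <- rmodel(recipe$nondiseased, sum(!lab))
  out <- data.frame(test1 = x[, 1], test2 = x[, 2],
                    status = ifelse(lab, "D", "ND"))
  attr(out, "measurands") <- recipe$measurands
  attr(out, "units") <- recipe$units
  attr(out, "seed") <- recipe$seed
  class(out) <- c("dx_cohort", class(out))
  out
}

#' Generate a multimodal lognormal-mixture fixture
#'
#' Samples from a mixture of lognormal components, each moment-matched to a
#' given (mean, sd); used to exercise the multimodal behaviour of
#' nonparametric posterior curves and the fit-comparison direction of the
#' statistics table.
#'
#' @param means,sds numeric vectors of component means and sds (equal
#'   length).
#' @param weights mixture weights; must sum to 1.
#' @param n sample size.
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
generate_multimodal_fixture <- function(means, sds, weights, n, seed = 1L) {
  k <- length(means)
  if (length(sds) != k || length(weights) != k)
    stop("'means', 'sds', 'weights' must have equal length", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12 || any(weights < 0))
    stop("'weights' must be nonnegative and sum to 1", call. = FALSE)
  comps <- lapply(seq_len(k), function(i)
    moment_match(parametric_spec("lognormal", means[i], sds[i])))
  set.seed(seed)
  z <- sample.int(k, n, replace = TRUE, prob = weights)
  x <- numeric(n)
  for (i in seq_len(k)) {
    idx <- z == i
    if (any(idx)) x[idx] <- rmodel(comps[[i]], sum(idx))
  }
  x
}

#' Write a cohort to delimited text
#'
#' The shared dataset format: a headered CSV with columns
#' `test1,test2,status`, `status` in `{D, ND}`, plus `#`-prefixed metadata
#' lines (measurands, units, seed) that [read_cohort()] restores. Identical
#' recipes produce byte-identical files.
#'
#' @param cohort a `dx_cohort` (or compatible data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  meta <- c(
    sprintf("# measurands: %s", paste(attr_default(cohort, "measurands"),
                                      collapse = ",")),
    sprintf("# units: %s", paste(attr_default(cohort, "units"),
                                 collapse = ",")),
    sprintf("# seed: %s", attr_default(cohort, "seed", "NA")))
  con <- file(path, open = "wb")  # binary mode: fixed LF line endings
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("test1,test2,status", con)
  writeLines(sprintf("%.15g,%.15g,%s", cohort$test1, cohort$test2,
                     cohort$status), con)
  invisible(path)
}

attr_default <- function(x, name, default = c("test1", "test2")) {
  a <- attr(x, name)
  if (is.null(a)) default else a
}

#' Read a cohort from delimited text
#'
#' @param path a file written by [write_cohort()] or any headered delimited
#'   file with columns `test1`, `test2`, `status` in `{D, ND}`.
#' @return a `dx_cohort` data frame; rows with missing values are rejected.
#' @export
read_cohort <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  need <- c("test1", "test2", "status")
  if (!all(need %in% names(df)))
    stop("cohort file must have columns test1, test2, status", call. = FALSE)
  if (anyNA(df[need]))
    stop("cohort contains missing values", call. = FALSE)
  if (!all(df$status %in% c("D", "ND")))
    stop("status must be 'D' or 'ND'", call. = FALSE)
  get_meta <- function(key) {
    m <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (!length(m)) return(NULL)
    strsplit(trimws(sub(sprintf("^# %s:", key), "", m[1])), ",")[[1]]
  }
  attr(df, "measurands") <- get_meta("measurands") %||% c("test1", "test2")
  attr(df, "units") <- get_meta("units") %||% c("", "")
  sd <- get_meta("seed")
  attr(df, "seed") <- if (is.null(sd)) NA_integer_ else
    suppressWarnings(as.integer(sd))
  class(df) <- c("dx_cohort", class(df))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
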