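---
title: "Bayesian diagnosis from quantitative tests: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian diagnosis from quantitative tests: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesdx)
```

## The model

A subject has disease status $D$ with prior probability $v$ and a pair of
test measurements $(x_1, x_2)$. Within each class the measurements follow a
class-conditional density — $f_D$ for the diseased and $f_{ND}$ for the
nondiseased population. The posterior probability of disease is Bayes'
theorem:

$$P(D \mid x) = \frac{v\, f_D(x)}{v\, f_D(x) + (1 - v)\, f_{ND}(x)}.$$

Everything in the package is a way of specifying, fitting, checking or
evaluating the four densities (two classes × {single test, both tests}) and
the prior.

The key assumption is that the class-conditional distributions and the
prior describe the population the patient comes from. The prior is the
prevalence in the relevant stratum — restricting the stratum (for example an
age band) makes a single number more defensible. Nothing in the machinery
corrects for a mis-specified prior or non-representative class models; the
goodness-of-fit tools exist so the user can see mis-specification rather
than be protected from it.

## Parametric class models

Each univariate model is one of three families — normal, lognormal, gamma —
specified by the measurand's mean $\mu$ and standard deviation $\sigma$ in
measurand units. The package resolves internal parameters by **moment
matching**:

* normal: location $\mu$, scale $\sigma$;
* lognormal: $\sigma_{\log}^2 = \ln(1 + (\sigma/\mu)^2)$,
  $\mu_{\log} = \ln\mu - \sigma_{\log}^2/2$;
* gamma: shape $(\mu/\sigma)^2$, scale $\sigma^2/\mu$.

Moment matching (rather than maximum likelihood) is the deliberate primary
interface: the inputs a practitioner typically has from the literature are a
published mean and SD, not raw data. When data are available,
`fit_to_data()` matches the sample moments; full ML fitting is intentionally
out of scope.

The lognormal and gamma families have positive support. The package's
convention is density zero for $x \le 0$ — including the gamma with shape
$\le 1$, whose textbook density is finite at 0 — because a measured
concentration of exactly zero is treated as outside the model rather than a
boundary atom. Degenerate $\sigma = 0$ is rejected, not approximated by a
point mass: a point-mass "density" cannot enter a likelihood ratio
meaningfully.

### The bivariate joint

The two measurands within one class are joined by a **Gaussian copula**:

$$f(x_1, x_2) = c\big(F_1(x_1), F_2(x_2); \rho\big)\, f_1(x_1)\, f_2(x_2),$$

with $c$ the bivariate-normal copula density. With two normal marginals this
is exactly the bivariate normal; with skewed marginals it is the minimal
dependence structure that preserves the specified marginals. Two points of
interpretation matter:

* $\rho$ is the correlation of the **normal dependence kernel**, not the
  Pearson correlation of the joint. For non-normal marginals the realized
  Pearson correlation is (slightly) attenuated; the statistics table reports
  it by seeded simulation, since no closed form exists.
* Each class carries its **own** $\rho$. The combined-test posterior always
  uses the full bivariate joints; it never silently assumes conditional
  independence. Only when both classes have $\rho = 0$ does the combined
  posterior reduce to chaining the two single-test updates
  (`posterior_sequential()`), and the test suite asserts that equivalence to
  $10^{-12}$.

## Nonparametric class models

The univariate KDE is the standard Gaussian-kernel estimator
$\hat f(x) = (nb)^{-1} \sum_i \phi((x - x_i)/b)$. Bandwidths are expressed
in **sample-SD units**: the absolute bandwidth is $b = h \cdot s$ with $s$
the sample SD of the data being smoothed. This makes one $h$ comparable
across measurands whose raw scales differ by an order of magnitude (mg/dL
vs %), which is why the same $h \approx 0.32\text{–}0.35$ can be sensible
for both.

`silverman_bandwidth()` implements the robust rule of thumb
$0.9\,\min(1, \mathrm{IQR}/(1.34 s))\, n^{-1/5}$ (already in SD units), with
a `doubled` flag because the reference rule visibly undersmooths
heavy-tailed biomarker data; doubling is the package's recommended starting
point for diagnostic work, where a smooth likelihood ratio matters more than
minimal integrated squared error.

The bivariate KDE uses a full bivariate-normal kernel with covariance
$H = \begin{pmatrix} b_1^2 & \rho b_1 b_2 \\ \rho b_1 b_2 & b_2^2
\end{pmatrix}$. A correlated kernel is the default because the interface
requires the user's $\rho$ to enter the bivariate estimate somewhere, and a
kernel-covariance rotation is the smallest mechanism that does it; a
diagonal (truly radial when $b_1 = b_2$) kernel is selectable via
`kernel = "diagonal"` for users who want $\rho$ ignored. This is an
interpretive choice, flagged as such.

Useful exact identities (all asserted in the tests): the Gaussian-kernel KDE
mean equals the sample mean; its variance is the biased sample variance plus
$b^2$; its skewness/kurtosis follow from the kernel's even moments. The KDE
cdf is the mixture of normal cdfs and the quantile function inverts it by
bracketed root-finding (`uniroot`, tolerance $10^{-10}$), which Q–Q and P–P
constructions for KDE models rely on.

## Numerical choices in the posterior

All density ratios are computed on the log scale and the posterior through
the logistic form
$P(D \mid x) = \operatorname{plogis}\big(\operatorname{qlogis}(v) +
\log f_D(x) - \log f_{ND}(x)\big)$. Posterior curves and surfaces are
routinely evaluated far into the tails, where the densities themselves
underflow double precision; log-likelihood differences stay finite long
after the ratio $f_D/f_{ND}$ does not.

Related choices:

* The copula's normal scores $z_i = \Phi^{-1}(F_i(x_i))$ are clamped to
  $\pm 8.2$ so that marginal cdfs that round to 0 or 1 do not produce
  infinite scores.
* Points where exactly one class density is zero get the limit posterior
  (exactly 0 or 1); where both are zero the result is a **typed undefined**
  (`defined = FALSE`, value `NA`), never a silent `NaN`. Curves drop such
  points and report them in a `dropped` attribute.
* `posterior_sequential()` chains the two tests on the log-odds scale.
  Chaining in probability space is mathematically identical but saturates at
  double precision (probabilities round to 1 beyond log-odds ≈ 37), so the
  package never round-trips through probabilities mid-chain.

## Goodness of fit

* `describe()` uses the sample SD ($n-1$), skewness $m_3/m_2^{3/2}$ and
  **non-excess kurtosis** $m_4/m_2^2$ (normal = 3). The non-excess
  convention is stated prominently because most statistics libraries default
  to excess kurtosis; all kurtosis values in this package are comparable to
  a normal benchmark of 3.
* Q–Q points pair model quantiles at **Hazen plotting positions**
  $(i - 0.5)/n$ with the order statistics; Hazen is symmetric and standard,
  and the Weibull rule $i/(n+1)$ is available. P–P points pair the model cdf
  at order statistics with the same positions.
* `loglikelihood()` of a KDE on its own training data is **in-sample** by
  default — that is what a comparative fit table across model kinds uses —
  with a leave-one-out option, since in-sample likelihood rewards small
  bandwidths.
* Histograms use exact rule widths (Freedman–Diaconis $2\,\mathrm{IQR}\,
  n^{-1/3}$, Sturges, or fixed), with left-closed bins starting at the data
  minimum and no "pretty" rounding of edges, so the documented width
  identities hold exactly. Heights are density-normalized.
* Medians and IQRs everywhere use linear-interpolation (type-7) quantiles.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a two-test screening extract:
a Bernoulli($v$) disease label and, conditional on the label, a pair drawn
exactly from the class's Gaussian-copula joint by inverse-marginal transform
of correlated standard-normal draws (exact, no rejection). The packaged
`example_recipe()` fixes the reference conditions: prevalence
$211/3854 \approx 0.055$, lognormal FPG (141.3, 54.0 mg/dL diseased; 99.9,
10.1 nondiseased), lognormal HbA1c (6.67, 1.57% diseased; 5.47, 0.38%
nondiseased), copula correlations 0.914 and 0.320.

What it emulates: right skew, strong positive dependence in the diseased
class, weak in the nondiseased, rare-disease class imbalance. What it does
**not** emulate: the heavier-than-lognormal tails of real glycemia data
(real skewness/kurtosis exceed the lognormal's at matched moments), survey
design and weighting, measurement rounding, or reference-standard
misclassification. Consequently, passing tests demonstrate internal
correctness — Bayes consistency on data generated by the stated models —
not that lognormal marginals fit any particular real population; the Q–Q,
P–P and log-likelihood tools are what address that question on real data.

## Problem sizes and tolerances in the test suite

The suite checks Bayes consistency on a $10^6$-subject synthetic cohort
(binned empirical disease rates vs computed posteriors within 3 binomial
SEs, for both tests and the combined pair), moment-matching round trips to
$10^{-9}$ relative on a $10 \times 10$ (mean, CV) grid per family, copula
marginalization by adaptive quadrature to $10^{-4}$ at
$\rho \in \{-0.5, 0, 0.5, 0.914\}$, KDE normalization to $10^{-6}$
(univariate) and $10^{-4}$ (bivariate, nested quadrature), and byte-level
determinism of every command-line output under a fixed seed. Monte-Carlo
oracles use batch means with $\pm 3$ batch SEs. These sizes are chosen so
the statistical assertions have negligible false-alarm probability while the
whole suite runs in a few minutes on one core.

## Known limitations

* Exactly two tests; no $k$-test generalization.
* Three parametric families; no ML fitting; no boundary-corrected or
  adaptive KDEs.
* The Gaussian copula cannot represent tail dependence beyond what its
  single $\rho$ implies.
* Priors are point values — no uncertainty propagation to the posterior.
* Thresholds (e.g. FPG 126 mg/dL) are annotation markers only; the package
  deliberately contains no decision rules, costs or ROC machinery.
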