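# Example panel: Bayesian diagnosis of diabetes from fasting plasma glucose
# (FPG) and HbA1c. Parametric settings are lognormal marginals moment-matched
# to the class means/SDs, joined by Gaussian copulas; KDE settings give the
# smoothing bandwidths in sample-SD units (about double Silverman's rule for
# these data) and the same per-class kernel correlations.
prior:
  counts: {diseased: 211, total: 3854}
measurands:
  - {name: FPG, units: mg/dL}
  - {name: HbA1c, units: "%"}
models:
  parametric:
    diseased:
      test1: {family: lognormal, mean: 141.3, sd: 54.0}
      test2: {family: lognormal, mean: 6.67, sd: 1.57}
      rho: 0.914
    nondiseased:
      test1: {family: lognormal, mean: 99.9, sd: 10.1}
      test2: {family: lognormal, mean: 5.47, sd: 0.38}
      rho: 0.320
  kde:
    diseased:
      test1: {bandwidth: 0.32}
      test2: {bandwidth: 0.34}
      rho: 0.914
    nondiseased:
      test1: {bandwidth: 0.34}
      test2: {bandwidth: 0.35}
      rho: 0.320
query: {test1: 126.0, test2: 6.5}
thresholds: {test1: 126.0, test2: 6.5}
simulate: {size: 3854}
seed: 1
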