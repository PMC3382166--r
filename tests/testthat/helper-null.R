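# Deterministic, symmetric log-normal-shaped null sample: the empirical
# type-7 quantiles of these ratios are exactly computable, which the
# interval/confidence consistency checks rely on.
deterministic_null <- function(n = 201, sd = 0.1) {
  exp(stats::qnorm(stats::ppoints(n), mean = 0, sd = sd))
}

tiny_study <- function(...) {
  generate_study(study_config(n_features = 60, spectra_per_feature = 4,
                              seed = 42, ...))
}
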