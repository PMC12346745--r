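# Shared fixtures: small synthetic corpora and reduced model configurations
# used across test files.  All sizes are chosen so the default suite runs
# on a single CPU in minutes.

# A small two-class corpus with classes planted on disjoint leads
# (NORM -> lead I, IMI -> lead II).
tiny_binary_corpus <- function(n = 150, seed = 3, noise_sd = 0.05) {
  generate_corpus(disjoint_leads_config(codes = c("NORM", "IMI"),
                                        n_records = n, noise_sd = noise_sd,
                                        seed = seed))
}

# Reduced-width custom CNN for tests that exercise training or Shapley
# machinery but do not audit the reference architecture.
tiny_model_config <- function(num_classes = 2, use_demographics = TRUE) {
  model_config("custom_cnn", num_classes = num_classes,
               conv_filters = c(8, 16), ecg_dense = c(16, 8),
               use_demographics = use_demographics)
}

# Analytic toy models over a 12-lead signal, used as Shapley oracles.
toy_additive_model <- function(coefs) {
  force(coefs)
  function(signal) sum(colMeans(signal) * coefs)
}
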