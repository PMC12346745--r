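# Shapley lead attribution: exact enumeration axioms, sampled estimator
# convergence, and Eq.-style aggregation.

test_that("exact enumeration satisfies the additivity axiom on linear models", {
  coefs <- (1:12) / 10
  model <- toy_additive_model(coefs)
  sig <- matrix(1, 200, 12)  # colMeans = 1, so phi_l = coefs[l]
  phi <- exact_lead_shapley(model, sig)
  expect_equal(unname(phi), coefs, tolerance = 1e-10)
})

test_that("exact enumeration satisfies dummy, null and efficiency axioms", {
  # model depends only on lead II's mean
  model <- function(signal) 3 * mean(signal[, 2])
  set.seed(3)
  sig <- matrix(rnorm(120 * 12), 120, 12)
  phi <- exact_lead_shapley(model, sig)
  expect_equal(unname(phi[-2]), rep(0, 11), tolerance = 1e-12)
  v_all <- model(sig)
  v_none <- model(matrix(0, 120, 12))
  expect_equal(unname(phi[2]), v_all - v_none, tolerance = 1e-10)
  # efficiency on a nonlinear model
  nl <- function(signal) tanh(sum(colMeans(signal)^2))
  phin <- exact_lead_shapley(nl, sig)
  expect_lt(abs(sum(phin) - (nl(sig) - nl(matrix(0, 120, 12)))), 1e-6)
  # constant model: all-zero attribution
  phi0 <- exact_lead_shapley(function(signal) 0.5, sig)
  expect_equal(unname(phi0), rep(0, 12))
  expect_error(exact_lead_shapley(nl, sig[, 1:3]), "12-lead")
})

test_that("the mean baseline masks leads with the reference signal", {
  model <- function(signal) mean(signal[, 1])
  sig <- matrix(2, 50, 12)
  ref <- matrix(1, 50, 12)
  phi <- exact_lead_shapley(model, sig,
                            scheme = masking_scheme("mean", ref))
  # v(all) - v(none) = 2 - 1 under the reference baseline
  expect_equal(unname(phi[1]), 1, tolerance = 1e-10)
  expect_error(masking_scheme("mean"), "baseline_signal")
})

test_that("the permutation estimator converges to the exact oracle", {
  nl <- function(signal) {
    m <- colMeans(signal)
    tanh(m[1] + 2 * m[2] * m[3] - m[4]^2)
  }
  set.seed(5)
  sig <- matrix(rnorm(100 * 12, sd = 0.8), 100, 12)
  ex <- exact_lead_shapley(nl, sig)
  maes <- vapply(c(10, 60, 400), function(np) {
    est <- sampled_lead_shapley(nl, sig, n_permutations = np, seed = 7)
    mean(abs(est - ex))
  }, numeric(1))
  expect_lt(maes[3], 0.01)
  expect_lt(maes[3], maes[1])
  # seeded reproducibility
  a <- sampled_lead_shapley(nl, sig, n_permutations = 20, seed = 11)
  b <- sampled_lead_shapley(nl, sig, n_permutations = 20, seed = 11)
  expect_identical(a, b)
  expect_error(sampled_lead_shapley(nl, sig, n_permutations = 0), ">= 1")
})

test_that("lead importance is the mean of absolute per-sample attributions", {
  phi1 <- c(1, rep(0, 11))
  li <- lead_importance(matrix(phi1, 1, 12))
  expect_equal(unname(li$importance), phi1)
  # sign symmetry: phi and -phi average to the same importance
  two <- rbind(phi1, -phi1)
  expect_equal(lead_importance(two)$importance, li$importance)
  # brute-force recomputation on a random matrix
  set.seed(13)
  A <- matrix(rnorm(100 * 12), 100, 12)
  expect_equal(unname(lead_importance(A)$importance),
               apply(abs(A), 2, mean))
  # signed option and normalization
  expect_equal(unname(lead_importance(A, signed = TRUE)$importance),
               colMeans(A))
  s1 <- lead_importance(A, normalization = "sum_to_one")
  expect_equal(sum(s1$importance), 1, tolerance = 1e-9)
  expect_true(all(s1$importance >= 0))
  expect_error(lead_importance(matrix(numeric(0), 0, 12)), "at least one")
})

test_that("per-class importance groups records and flags empty classes", {
  corp <- tiny_binary_corpus(n = 40, seed = 51)
  ds <- materialize(binary_superclass("MI"), corp, "train")
  # oracle classifier built from the generative model: prob(MI) rises
  # with lead II energy; treat it as the model for class MI
  oracle <- function(signal) plogis(20 * (mean(signal[, 2]^2) - 0.05))
  keep <- which(ds$y == 1)[1:3]
  phis <- t(vapply(keep, function(i) {
    exact_lead_shapley(oracle, ds$signals[[i]])
  }, numeric(12)))
  li <- lead_importance(phis, class_label = "MI")
  expect_identical(names(which.max(li$importance)), "II")

  one <- ds
  sel <- which(ds$y == 1)[1:2]
  one$signals <- ds$signals[sel]; one$y <- ds$y[sel]
  one$age <- ds$age[sel]; one$sex <- ds$sex[sel]
  m <- build_model(tiny_model_config(), seed = 3)
  m$demo_scaler <- list(age_mean = 60, age_sd = 12, age_impute = 60)
  expect_warning(out <- per_class_importance(m, one, estimator = "sampled",
                                             n_permutations = 4, seed = 1),
                 "no records")
  expect_named(out, "MI")
  expect_equal(out$MI$n_samples, 2)
})
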