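# Model construction, structural audit, training mechanics and prediction.

test_that("config validation rejects impossible geometries", {
  expect_error(model_config("vgg_style", num_classes = 2, input_length = 100),
               "too short")
  expect_error(model_config("custom_cnn", num_classes = 1), "at least 2")
  expect_silent(model_config("custom_cnn", num_classes = 2,
                             input_length = 1000))
})

test_that("realized layer sequences match the reference architectures", {
  m <- build_model(model_config("custom_cnn", num_classes = 5), seed = 1)
  lay <- model_layers(m)
  conv <- lay[lay$type == "conv1d", ]
  expect_equal(conv$units, c(32, 64, 128, 256, 512))
  expect_true(all(conv$kernel == 3))
  expect_true(all(lay$pool[lay$type == "max_pool"] == 2))
  # batch norm after every pooling stage
  expect_equal(sum(lay$type == "batch_norm"), 5)
  expect_equal(lay$units[lay$type == "dense" & lay$branch == "ecg"], c(100, 32))
  expect_equal(lay$rate[lay$type == "dropout" & lay$branch == "ecg"], 0.4)
  expect_equal(lay$units[lay$branch == "demographic" & lay$type == "dense"],
               c(100, 64, 32, 16))
  expect_equal(lay$rate[lay$branch == "demographic" & lay$type == "dropout"], 0.4)
  expect_equal(lay$units[lay$branch == "head" & grepl("dense", lay$type)],
               c(10, 10, 5))
  expect_equal(unique(lay$rate[lay$branch == "head" & lay$type == "dropout"]), 0.2)

  v <- build_model(model_config("vgg_style", num_classes = 2), seed = 1)
  lv <- model_layers(v)
  expect_equal(lv$units[lv$type == "conv1d"],
               c(64, 64, 128, 128, 256, 256, 512, 512))
  expect_equal(sum(lv$type == "batch_norm"), 0)
  expect_equal(lv$units[lv$type == "dense" & lv$branch == "ecg"], c(512, 512))
  expect_equal(lv$rate[lv$type == "dropout" & lv$branch == "ecg"], 0.5)
})

test_that("the demographic branch has exactly 9372 trainable weights", {
  m <- build_model(model_config("custom_cnn", num_classes = 5), seed = 1)
  expect_equal(count_params(m, "demographic"),
               (2 * 100 + 100) + (100 * 64 + 64) + (64 * 32 + 32) +
                 (32 * 16 + 16))
  expect_identical(count_params(m, "demographic"), 9372L)
})

test_that("probability outputs are normalized, pure and shape-safe", {
  corp <- tiny_binary_corpus(n = 20, seed = 41)
  ds <- materialize(binary_superclass("MI"), corp, "train")
  m <- build_model(tiny_model_config(), seed = 2)
  m$demo_scaler <- list(age_mean = 60, age_sd = 12, age_impute = 60)
  p <- predict_proba(m, ds)
  expect_equal(dim(p), c(length(ds$y), 2))
  expect_true(all(abs(rowSums(p) - 1) < 1e-5))
  # duplicated inputs give identical rows
  dup <- list(signals = ds$signals[c(1, 1)], age = ds$age[c(1, 1)],
              sex = ds$sex[c(1, 1)])
  pd <- predict_proba(m, dup)
  expect_identical(pd[1, ], pd[2, ])
  # empty batch
  p0 <- predict_proba(m, list(signals = list(), age = numeric(0),
                              sex = character(0)))
  expect_equal(dim(p0), c(0, 2))
  # length mismatch
  bad <- list(signals = list(matrix(0, 500, 12)), age = 50, sex = "male")
  expect_error(predict_proba(m, bad), "input_length")
})

test_that("training is seeded-deterministic and checkpoints the best epoch", {
  corp <- tiny_binary_corpus(n = 80, seed = 43)
  sc <- binary_superclass("MI")
  sets <- materialize_splits(sc, corp)
  cfg <- train_config(max_epochs = 4, seed = 5)
  f1 <- train(build_model(tiny_model_config(), seed = 5), sets$train,
              sets$validation, cfg)
  f2 <- train(build_model(tiny_model_config(), seed = 5), sets$train,
              sets$validation, cfg)
  expect_identical(tail(f1$history$val_loss, 1), tail(f2$history$val_loss, 1))
  expect_identical(f1$best_val_loss, f2$best_val_loss)
  # checkpoint property: returned weights come from the minimum
  # validation loss over all recorded epochs
  expect_equal(f1$best_val_loss, min(f1$history$val_loss))
  expect_lte(f1$best_val_loss, min(f1$history$val_loss))
  # history records every epoch actually run
  expect_lte(nrow(f1$history), 4)
  expect_identical(f1$history$epoch, seq_len(nrow(f1$history)))
})

test_that("degenerate training inputs are rejected", {
  corp <- tiny_binary_corpus(n = 30, seed = 47)
  sc <- binary_superclass("MI")
  sets <- materialize_splits(sc, corp)
  m <- build_model(tiny_model_config(), seed = 1)
  empty <- sets$train
  empty$signals <- list(); empty$y <- integer(0)
  empty$age <- numeric(0); empty$sex <- character(0)
  expect_error(train(m, empty, sets$validation), "empty training set")
  expect_error(train_config(max_epochs = 0), "at least 1")
  # class absent from the training set warns but does not error
  only0 <- sets$train
  keep <- which(only0$y == 0)[1:5]
  only0$signals <- only0$signals[keep]; only0$y <- only0$y[keep]
  only0$age <- only0$age[keep]; only0$sex <- only0$sex[keep]
  expect_warning(
    train(m, only0, sets$validation, train_config(max_epochs = 1, seed = 1)),
    "absent")
})

test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("ecgfusion")
  set.seed(11)
  for (arch in c("custom_cnn", "vgg_style")) {
    cfg <- model_config(arch, num_classes = 3, input_length = 32,
                        conv_filters = c(4, 6), ecg_dense = c(5, 4),
                        demo_dense = c(4, 3), head_dense = c(4, 3),
                        ecg_dropout = 0, demo_dropout = 0, head_dropout = 0)
    m <- build_model(cfg, seed = 13)
    # jitter biases off zero so no pre-activation sits exactly on the
    # ReLU kink (where subgradients and finite differences disagree)
    for (nm in grep("\\.(b|beta)$", names(m$params), value = TRUE)) {
      m$params[[nm]] <- m$params[[nm]] + rnorm(length(m$params[[nm]]), 0, 0.05)
    }
    n <- 4
    X <- array(rnorm(32 * 12 * n), c(32, 12, n))
    D <- matrix(rnorm(n * 2), n, 2)
    Y <- ns$one_hot(sample(0:2, n, TRUE), 3)
    fw <- ns$nn_forward(m, X, D, training = TRUE)
    g <- ns$nn_backward(m, fw$cache, (fw$probs - Y) / n)
    loss_at <- function(m) {
      f <- ns$nn_forward(m, X, D, training = TRUE, keep_cache = FALSE)
      ns$cross_entropy(f$probs, Y)
    }
    eps <- 1e-5
    for (nm in names(m$params)) {
      i <- sample(length(m$params[[nm]]), 1)
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      ana <- g[[nm]][i]
      # skip exact ReLU kinks (subgradient 0, finite difference crosses 0)
      # and parameters too small to compare relatively
      if (abs(num) + abs(ana) < 1e-6) next
      if (ana == 0 && abs(num) > 1e-8) next
      expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
    }
  }
})
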