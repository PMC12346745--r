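## Dual-branch architectures.  The ECG branch stacks conv(3x1) -> ReLU ->
## max-pool(2x1) blocks (batch-normalized after each pool in the custom
## CNN), then a dense stack; the demographic branch is dense
## [100, 64, 32, 16]; branch outputs are concatenated and passed through
## dense [10, 10, K] with dropout, ending in a K-way softmax.

#' Architectural configuration of a dual-branch ECG classifier
#'
#' Defaults reproduce the two reference architectures: `custom_cnn` uses
#' conv filters \[32, 64, 128, 256, 512\] with batch normalization after
#' every pooling stage and an ECG dense stack \[100, 32\] with dropout 0.4;
#' `vgg_style` uses conv filters \[64, 64, 128, 128, 256, 256, 512, 512\],
#' global average pooling and a dense stack \[512, 512\] with dropout 0.5.
#' Both share the demographic branch \[100, 64, 32, 16\] (dropout 0.4) and
#' the head \[10, 10, K\] (dropout 0.2).  Kernels are 3x1 with "same"
#' padding; pools are 2x1.
#'
#' @param architecture `"custom_cnn"` or `"vgg_style"`.
#' @param num_classes number of output classes K.
#' @param input_length samples per lead (1000 at 100 Hz, 5000 at 500 Hz);
#'   must be at least `2^length(conv_filters)` so pooling never empties the
#'   time axis.
#' @param use_demographics include the demographic branch and fusion.
#' @param conv_filters,ecg_dense,ecg_dropout override the ECG branch
#'   (defaults per architecture).
#' @param demo_dense,demo_dropout demographic branch stack and dropout.
#' @param head_dense,head_dropout fusion head hidden widths and dropout.
#' @param n_leads number of input leads (12).
#' @return object of class `ecg_model_config`.
#' @export
model_config <- function(architecture = c("custom_cnn", "vgg_style"),
                         num_classes, input_length = 1000,
                         use_demographics = TRUE,
                         conv_filters = NULL, ecg_dense = NULL,
                         ecg_dropout = NULL,
                         demo_dense = c(100, 64, 32, 16), demo_dropout = 0.4,
                         head_dense = c(10, 10), head_dropout = 0.2,
                         n_leads = 12) {
  architecture <- match.arg(architecture)
  if (is.null(conv_filters)) {
    conv_filters <- if (architecture == "custom_cnn") c(32, 64, 128, 256, 512)
                    else c(64, 64, 128, 128, 256, 256, 512, 512)
  }
  if (is.null(ecg_dense)) {
    ecg_dense <- if (architecture == "custom_cnn") c(100, 32) else c(512, 512)
  }
  if (is.null(ecg_dropout)) {
    ecg_dropout <- if (architecture == "custom_cnn") 0.4 else 0.5
  }
  if (num_classes < 2) stop("num_classes must be at least 2", call. = FALSE)
  n_pool <- length(conv_filters)
  if (input_length < 2^n_pool) {
    stop("input_length ", input_length, " too short for ", n_pool,
         " pooling stages (needs >= ", 2^n_pool, ")", call. = FALSE)
  }
  structure(list(
    architecture = architecture, num_classes = as.integer(num_classes),
    input_length = as.integer(input_length), n_leads = as.integer(n_leads),
    use_demographics = isTRUE(use_demographics),
    conv_filters = as.integer(conv_filters), kernel = 3L, pool = 2L,
    batch_norm = architecture == "custom_cnn",
    ecg_pool_to_dense = if (architecture == "custom_cnn") "flatten" else "gap",
    ecg_dense = as.integer(ecg_dense), ecg_dropout = ecg_dropout,
    demo_dense = as.integer(demo_dense), demo_dropout = demo_dropout,
    head_dense = as.integer(head_dense), head_dropout = head_dropout
  ), class = "ecg_model_config")
}

# time-axis length after the pooling stack
conv_out_length <- function(config) {
  len <- config$input_length
  for (i in seq_along(config$conv_filters)) len <- len %/% 2L
  len
}

#' Build (initialize) a dual-branch model
#'
#' @param config an [model_config()].
#' @param seed optional RNG seed for the weight initialization
#'   (He-scaled Gaussians).
#' @return object of class `ecg_model` with untrained weights.
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ecg_model_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- list()
  run <- list()
  c_in <- config$n_leads
  for (i in seq_along(config$conv_filters)) {
    f <- config$conv_filters[i]
    p[[paste0("conv", i, ".W")]] <- he_init(c(config$kernel * c_in, f),
                                            config$kernel * c_in)
    p[[paste0("conv", i, ".b")]] <- numeric(f)
    if (config$batch_norm) {
      p[[paste0("bn", i, ".gamma")]] <- rep(1, f)
      p[[paste0("bn", i, ".beta")]] <- numeric(f)
      run[[paste0("bn", i)]] <- list(mean = numeric(f), var = rep(1, f))
    }
    c_in <- f
  }
  d_in <- if (config$ecg_pool_to_dense == "flatten") {
    conv_out_length(config) * c_in
  } else {
    c_in
  }
  for (j in seq_along(config$ecg_dense)) {
    u <- config$ecg_dense[j]
    p[[paste0("ecg_dense", j, ".W")]] <- he_init(c(d_in, u), d_in)
    p[[paste0("ecg_dense", j, ".b")]] <- numeric(u)
    d_in <- u
  }
  fused <- d_in
  if (config$use_demographics) {
    d_in <- 2L
    for (j in seq_along(config$demo_dense)) {
      u <- config$demo_dense[j]
      p[[paste0("demo_dense", j, ".W")]] <- he_init(c(d_in, u), d_in)
      p[[paste0("demo_dense", j, ".b")]] <- numeric(u)
      d_in <- u
    }
    fused <- fused + d_in
  }
  widths <- c(config$head_dense, config$num_classes)
  d_in <- fused
  for (j in seq_along(widths)) {
    u <- widths[j]
    p[[paste0("head", j, ".W")]] <- he_init(c(d_in, u), d_in)
    p[[paste0("head", j, ".b")]] <- numeric(u)
    d_in <- u
  }
  structure(list(config = config, params = p, bn_run = run,
                 demo_scaler = NULL, fitted = FALSE),
            class = "ecg_model")
}

#' @export
print.ecg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ecg_model %s: K=%d, input %d x %d, demographics %s, %s>\n",
              cfg$architecture, cfg$num_classes, cfg$input_length, cfg$n_leads,
              ifelse(cfg$use_demographics, "on", "off"),
              ifelse(x$fitted, "fitted", "untrained")))
  invisible(x)
}

## ---- forward / backward ----------------------------------------------

# X: array (time, leads, batch); D: matrix (batch, 2) scaled demographics
# or NULL.  Returns probs, cache (when requested) and updated bn state.
nn_forward <- function(model, X, D, training = FALSE, keep_cache = training) {
  cfg <- model$config
  p <- model$params
  run <- model$bn_run
  cache <- list(conv_in = list(), pool = list(), bn = list(),
                relu_out = list())
  A <- X
  for (i in seq_along(cfg$conv_filters)) {
    if (keep_cache) cache$conv_in[[i]] <- A
    Z <- conv1d_forward(A, p[[paste0("conv", i, ".W")]],
                        p[[paste0("conv", i, ".b")]], cfg$kernel)
    Z <- relu(Z)
    if (keep_cache) cache$relu_out[[i]] <- Z
    pl <- maxpool_fw(Z)
    A <- pl$Y
    if (keep_cache) cache$pool[[i]] <- pl[c("mask", "t_in")]
    if (cfg$batch_norm) {
      bn <- bn_fw(A, p[[paste0("bn", i, ".gamma")]],
                  p[[paste0("bn", i, ".beta")]],
                  run[[paste0("bn", i)]], training = training)
      A <- bn$Y
      run[[paste0("bn", i)]] <- bn$run
      if (keep_cache) cache$bn[[i]] <- bn[c("xhat", "inv_std", "dims")]
    }
  }
  d <- dim(A)
  if (cfg$ecg_pool_to_dense == "flatten") {
    E <- t(matrix(A, d[1] * d[2], d[3]))
  } else {
    E <- t(colMeans(A, dims = 1L))
  }
  cache$conv_out_dim <- d
  cache$ecg_dense_in <- list()
  cache$ecg_dense_out <- list()
  for (j in seq_along(cfg$ecg_dense)) {
    if (keep_cache) cache$ecg_dense_in[[j]] <- E
    E <- relu(dense_fw(E, p[[paste0("ecg_dense", j, ".W")]],
                       p[[paste0("ecg_dense", j, ".b")]]))
    if (keep_cache) cache$ecg_dense_out[[j]] <- E
  }
  if (training && cfg$ecg_dropout > 0) {
    cache$ecg_drop <- dropout_mask(dim(E), cfg$ecg_dropout)
    E <- E * cache$ecg_drop
  }

  if (cfg$use_demographics) {
    Dm <- D
    cache$demo_dense_in <- list()
    cache$demo_dense_out <- list()
    for (j in seq_along(cfg$demo_dense)) {
      if (keep_cache) cache$demo_dense_in[[j]] <- Dm
      Dm <- relu(dense_fw(Dm, p[[paste0("demo_dense", j, ".W")]],
                          p[[paste0("demo_dense", j, ".b")]]))
      if (keep_cache) cache$demo_dense_out[[j]] <- Dm
    }
    if (training && cfg$demo_dropout > 0) {
      cache$demo_drop <- dropout_mask(dim(Dm), cfg$demo_dropout)
      Dm <- Dm * cache$demo_drop
    }
    H <- cbind(E, Dm)
    cache$ecg_width <- ncol(E)
  } else {
    H <- E
  }

  n_head <- length(cfg$head_dense) + 1L
  cache$head_in <- list()
  cache$head_drop <- list()
  for (j in seq_len(n_head)) {
    if (keep_cache) cache$head_in[[j]] <- H
    H <- dense_fw(H, p[[paste0("head", j, ".W")]], p[[paste0("head", j, ".b")]])
    if (j < n_head) {
      H <- relu(H)
      if (keep_cache) cache$head_relu[[j]] <- H
      if (training && cfg$head_dropout > 0) {
        msk <- dropout_mask(dim(H), cfg$head_dropout)
        cache$head_drop[[j]] <- msk
        H <- H * msk
      }
    }
  }
  probs <- softmax_rows(H)
  list(probs = probs, cache = if (keep_cache) cache else NULL, bn_run = run)
}

# dLogits: (batch, K) gradient of the loss wrt the pre-softmax logits.
nn_backward <- function(model, cache, dLogits) {
  cfg <- model$config
  p <- model$params
  g <- list()
  n_head <- length(cfg$head_dense) + 1L
  dH <- dLogits
  for (j in rev(seq_len(n_head))) {
    if (j < n_head) {
      if (length(cache$head_drop) >= j && !is.null(cache$head_drop[[j]])) {
        dH <- dH * cache$head_drop[[j]]
      }
      dH <- dH * (cache$head_relu[[j]] > 0)
    }
    bw <- dense_bw(cache$head_in[[j]], p[[paste0("head", j, ".W")]], dH)
    g[[paste0("head", j, ".W")]] <- bw$dW
    g[[paste0("head", j, ".b")]] <- bw$db
    dH <- bw$dX
  }

  if (cfg$use_demographics) {
    dE <- dH[, seq_len(cache$ecg_width), drop = FALSE]
    dDm <- dH[, -seq_len(cache$ecg_width), drop = FALSE]
    if (!is.null(cache$demo_drop)) dDm <- dDm * cache$demo_drop
    for (j in rev(seq_along(cfg$demo_dense))) {
      dDm <- dDm * (cache$demo_dense_out[[j]] > 0)
      bw <- dense_bw(cache$demo_dense_in[[j]],
                     p[[paste0("demo_dense", j, ".W")]], dDm)
      g[[paste0("demo_dense", j, ".W")]] <- bw$dW
      g[[paste0("demo_dense", j, ".b")]] <- bw$db
      dDm <- bw$dX
    }
  } else {
    dE <- dH
  }

  if (!is.null(cache$ecg_drop)) dE <- dE * cache$ecg_drop
  for (j in rev(seq_along(cfg$ecg_dense))) {
    dE <- dE * (cache$ecg_dense_out[[j]] > 0)
    bw <- dense_bw(cache$ecg_dense_in[[j]],
                   p[[paste0("ecg_dense", j, ".W")]], dE)
    g[[paste0("ecg_dense", j, ".W")]] <- bw$dW
    g[[paste0("ecg_dense", j, ".b")]] <- bw$db
    dE <- bw$dX
  }

  d <- cache$conv_out_dim
  if (cfg$ecg_pool_to_dense == "flatten") {
    dA <- array(t(dE), dim = d)
  } else {
    dA <- array(rep(as.vector(t(dE)) / d[1], each = d[1]), dim = d)
  }
  for (i in rev(seq_along(cfg$conv_filters))) {
    if (cfg$batch_norm) {
      bnb <- bn_bw(cache$bn[[i]], p[[paste0("bn", i, ".gamma")]], dA)
      g[[paste0("bn", i, ".gamma")]] <- bnb$dgamma
      g[[paste0("bn", i, ".beta")]] <- bnb$dbeta
      dA <- bnb$dX
    }
    dZ <- maxpool_bw(cache$pool[[i]], dA)
    dZ <- dZ * (cache$relu_out[[i]] > 0)
    bw <- conv1d_backward(cache$conv_in[[i]], p[[paste0("conv", i, ".W")]],
                          dZ, cfg$kernel)
    g[[paste0("conv", i, ".W")]] <- bw$dW
    g[[paste0("conv", i, ".b")]] <- as.numeric(bw$db)
    dA <- bw$dX
  }
  g
}

## ---- training ---------------------------------------------------------

#' Optimization configuration
#'
#' Categorical cross-entropy, Adam (learning rate 0.001), batch size 16,
#' at most 60 epochs, with early stopping on validation loss, learning-rate
#' reduction on plateau, and restoration of the weights from the epoch of
#' minimum validation loss.
#'
#' @param learning_rate initial Adam learning rate.
#' @param max_epochs maximum number of epochs.
#' @param batch_size mini-batch size.
#' @param patience early-stopping patience (epochs without a new minimum
#'   validation loss).
#' @param lr_factor,lr_patience,min_lr learning-rate reduction on plateau:
#'   multiply by `lr_factor` after `lr_patience` stale epochs, never below
#'   `min_lr`.
#' @param seed RNG seed covering shuffling and dropout.
#' @param verbose print one line per epoch.
#' @return object of class `ecg_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 60,
                         batch_size = 16, patience = 10,
                         lr_factor = 0.5, lr_patience = 5, min_lr = 1e-5,
                         seed = NULL, verbose = FALSE) {
  if (max_epochs < 1) stop("max_epochs must be at least 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), min_lr = min_lr,
                 seed = seed, verbose = isTRUE(verbose)),
            class = "ecg_train_config")
}

# Stack an ecg_dataset's signals into (time, leads, batch); crop or fail on
# length mismatch with the model input.
dataset_tensor <- function(dataset, input_length) {
  n <- length(dataset$signals)
  if (n == 0L) return(array(0, c(input_length, 12L, 0L)))
  lens <- vapply(dataset$signals, nrow, 1L)
  if (any(lens != input_length)) {
    stop("record length ", lens[which(lens != input_length)[1]],
         " does not match model input_length ", input_length, call. = FALSE)
  }
  array(unlist(dataset$signals, use.names = FALSE),
        dim = c(input_length, 12L, n))
}

# Age is z-scored with training-set mean/sd; sex is encoded male = 0,
# female = 1.  Missing values impute to the training median age / 0.5.
fit_demo_scaler <- function(age, sex) {
  mu <- mean(age, na.rm = TRUE)
  s <- stats::sd(age, na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- 1
  list(age_mean = mu, age_sd = s,
       age_impute = stats::median(age, na.rm = TRUE))
}

encode_demographics <- function(age, sex, scaler) {
  age[is.na(age)] <- scaler$age_impute
  sx <- ifelse(is.na(sex), 0.5, ifelse(sex == "female", 1, 0))
  cbind(age_z = (age - scaler$age_mean) / scaler$age_sd, sex = sx)
}

one_hot <- function(y, k) {
  Y <- matrix(0, length(y), k)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

model_loss_acc <- function(model, X, D, Y1hot, chunk = 64L) {
  n <- dim(X)[3]
  loss <- 0; correct <- 0L
  for (s in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    fw <- nn_forward(model, X[, , s, drop = FALSE],
                     if (is.null(D)) NULL else D[s, , drop = FALSE],
                     training = FALSE, keep_cache = FALSE)
    loss <- loss + cross_entropy(fw$probs, Y1hot[s, , drop = FALSE]) * length(s)
    correct <- correct + sum(max.col(fw$probs) == max.col(Y1hot[s, , drop = FALSE]))
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train a dual-branch model
#'
#' Mini-batch Adam on categorical cross-entropy with per-epoch validation.
#' The returned model carries the weights of the epoch with minimum
#' validation loss (checkpointing); training stops early after
#' `config$patience` epochs without improvement, and the learning rate is
#' halved after `config$lr_patience` stale epochs.
#'
#' @param model an untrained or pre-trained [build_model()] result.
#' @param train_set,val_set `ecg_dataset`s sharing one scenario.
#' @param config an [train_config()].
#' @return list of class `ecg_fit` with `model` (best weights) and
#'   `history` (one row per epoch actually run: loss, accuracy,
#'   validation loss/accuracy, learning rate).
#' @export
train <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "ecg_model"), inherits(config, "ecg_train_config"))
  if (length(train_set$y) == 0L) stop("empty training set", call. = FALSE)
  if (!identical(train_set$scenario$name, val_set$scenario$name)) {
    stop("train and validation sets must share one scenario", call. = FALSE)
  }
  cfg <- model$config
  k <- cfg$num_classes
  if (any(train_set$y >= k)) stop("class index exceeds num_classes", call. = FALSE)
  absent <- setdiff(seq_len(k) - 1L, unique(train_set$y))
  if (length(absent)) {
    warning("class(es) absent from the training set: ",
            paste(train_set$scenario$class_names[absent + 1L], collapse = ", "),
            call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  X <- dataset_tensor(train_set, cfg$input_length)
  Xv <- dataset_tensor(val_set, cfg$input_length)
  Y <- one_hot(train_set$y, k)
  Yv <- one_hot(val_set$y, k)
  D <- Dv <- NULL
  if (cfg$use_demographics) {
    model$demo_scaler <- fit_demo_scaler(train_set$age, train_set$sex)
    D <- encode_demographics(train_set$age, train_set$sex, model$demo_scaler)
    Dv <- encode_demographics(val_set$age, val_set$sex, model$demo_scaler)
  }

  n <- dim(X)[3]
  opt <- adam_init(model$params)
  lr <- config$learning_rate
  best <- list(val_loss = Inf, params = model$params, bn_run = model$bn_run,
               epoch = 0L)
  wait_es <- 0L; wait_lr <- 0L
  hist <- NULL
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (s in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      Xb <- X[, , s, drop = FALSE]
      Db <- if (is.null(D)) NULL else D[s, , drop = FALSE]
      Yb <- Y[s, , drop = FALSE]
      fw <- nn_forward(model, Xb, Db, training = TRUE)
      model$bn_run <- fw$bn_run
      ep_loss <- ep_loss + cross_entropy(fw$probs, Yb) * length(s)
      ep_correct <- ep_correct + sum(max.col(fw$probs) == max.col(Yb))
      dLogits <- (fw$probs - Yb) / length(s)
      grads <- nn_backward(model, fw$cache, dLogits)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$state
    }
    val <- model_loss_acc(model, Xv, Dv, Yv)
    hist <- rbind(hist, data.frame(
      epoch = epoch, loss = ep_loss / n, acc = ep_correct / n,
      val_loss = val[["loss"]], val_acc = val[["acc"]], lr = lr))
    if (config$verbose) {
      message(sprintf("epoch %2d  loss %.4f acc %.3f  val_loss %.4f val_acc %.3f  lr %g",
                      epoch, ep_loss / n, ep_correct / n,
                      val[["loss"]], val[["acc"]], lr))
    }
    if (val[["loss"]] < best$val_loss) {
      best <- list(val_loss = val[["loss"]], params = model$params,
                   bn_run = model$bn_run, epoch = epoch)
      wait_es <- 0L; wait_lr <- 0L
    } else {
      wait_es <- wait_es + 1L; wait_lr <- wait_lr + 1L
      if (wait_lr >= config$lr_patience && lr > config$min_lr) {
        lr <- max(lr * config$lr_factor, config$min_lr)
        wait_lr <- 0L
      }
      if (wait_es >= config$patience) break
    }
  }
  model$params <- best$params
  model$bn_run <- best$bn_run
  model$fitted <- TRUE
  structure(list(model = model, history = hist, best_epoch = best$epoch,
                 best_val_loss = best$val_loss),
            class = "ecg_fit")
}

#' @export
print.ecg_fit <- function(x, ...) {
  cat(sprintf("<ecg_fit: %d epoch(s), best val_loss %.4f at epoch %d>\n",
              nrow(x$history), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' Class-probability predictions
#'
#' @param model a fitted `ecg_model` (or an `ecg_fit`, whose model is
#'   used).
#' @param newdata an `ecg_dataset`, or a list with `signals` (list of
#'   samples x 12 matrices), `age` and `sex`.
#' @param chunk internal batch size.
#' @return n x K matrix of class probabilities; each row sums to 1.
#' @export
predict_proba <- function(model, newdata, chunk = 64L) {
  if (inherits(model, "ecg_fit")) model <- model$model
  stopifnot(inherits(model, "ecg_model"))
  cfg <- model$config
  X <- dataset_tensor(newdata, cfg$input_length)
  n <- dim(X)[3]
  if (n == 0L) return(matrix(numeric(0), 0L, cfg$num_classes))
  D <- NULL
  if (cfg$use_demographics) {
    if (is.null(model$demo_scaler)) {
      stop("model uses demographics but has no fitted scaler; train first",
           call. = FALSE)
    }
    D <- encode_demographics(newdata$age, newdata$sex, model$demo_scaler)
  }
  out <- matrix(0, n, cfg$num_classes)
  for (s in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    fw <- nn_forward(model, X[, , s, drop = FALSE],
                     if (is.null(D)) NULL else D[s, , drop = FALSE],
                     training = FALSE, keep_cache = FALSE)
    out[s, ] <- fw$probs
  }
  out
}

#' Predicted class indices (0-based)
#' @inheritParams predict_proba
#' @export
predict_class <- function(model, newdata, chunk = 64L) {
  max.col(predict_proba(model, newdata, chunk)) - 1L
}

## ---- structural introspection ----------------------------------------

#' Layer-by-layer audit of a model's realized architecture
#'
#' @param model an `ecg_model` (trained or not).
#' @return data.frame with one row per layer: `branch`, `type`, `units`
#'   (filters or neurons), `kernel`, `pool`, `rate` (dropout).
#' @export
model_layers <- function(model) {
  cfg <- model$config
  rows <- list()
  add <- function(branch, type, units = NA, kernel = NA, pool = NA, rate = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      branch = branch, type = type, units = units, kernel = kernel,
      pool = pool, rate = rate, stringsAsFactors = FALSE)
  }
  for (f in cfg$conv_filters) {
    add("ecg", "conv1d", f, kernel = cfg$kernel)
    add("ecg", "max_pool", pool = cfg$pool)
    if (cfg$batch_norm) add("ecg", "batch_norm", f)
  }
  add("ecg", if (cfg$ecg_pool_to_dense == "flatten") "flatten"
      else "global_avg_pool")
  for (u in cfg$ecg_dense) add("ecg", "dense", u)
  add("ecg", "dropout", rate = cfg$ecg_dropout)
  if (cfg$use_demographics) {
    for (u in cfg$demo_dense) add("demographic", "dense", u)
    add("demographic", "dropout", rate = cfg$demo_dropout)
    add("head", "concatenate")
  }
  for (u in cfg$head_dense) {
    add("head", "dense", u)
    add("head", "dropout", rate = cfg$head_dropout)
  }
  add("head", "dense_softmax", cfg$num_classes)
  do.call(rbind, rows)
}

#' Count trainable weights, optionally per branch
#'
#' @param model an `ecg_model`.
#' @param branch `"all"`, `"ecg"`, `"demographic"` or `"head"`.
#' @return integer weight count.
#' @export
count_params <- function(model, branch = c("all", "ecg", "demographic", "head")) {
  branch <- match.arg(branch)
  pat <- switch(branch, all = ".", ecg = "^(conv|bn|ecg_dense)",
                demographic = "^demo_dense", head = "^head")
  nm <- grep(pat, names(model$params), value = TRUE)
  sum(vapply(model$params[nm], length, 1L))
}
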