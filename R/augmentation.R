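## Training-set augmentation: additive Gaussian noise and multiplicative
## gain (amplification/attenuation), applied to the ECG branch only.
## Demographics and labels are never altered, and only the training
## partition may be expanded.

#' Augmentation configuration
#'
#' @param noise_sd standard deviation of the additive Gaussian noise in
#'   millivolts (default 0.01; the mean is fixed at 0).
#' @param gain_x_min,gain_x_max range of the gain offset `x`; the gain is
#'   `1 + x` for amplification and `1 - x` for attenuation, with `x` drawn
#'   uniformly from \[`gain_x_min`, `gain_x_max`\] (defaults 0.001-0.01).
#' @param policy `"triple"` adds one noisy, one amplified and one
#'   attenuated copy per record; `"balance"` augments minority classes up
#'   to the majority class count, cycling through the three operators.
#' @param seed RNG seed for the augmentation draws.
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(noise_sd = 0.01, gain_x_min = 0.001,
                                gain_x_max = 0.01,
                                policy = c("triple", "balance"), seed = 1L) {
  policy <- match.arg(policy)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (gain_x_min > gain_x_max) stop("gain_x_min must be <= gain_x_max", call. = FALSE)
  structure(list(noise_mean = 0, noise_sd = noise_sd,
                 gain_x_min = gain_x_min, gain_x_max = gain_x_max,
                 policy = policy, seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Add zero-mean Gaussian noise to a signal
#'
#' @param signal numeric matrix or vector (millivolts).
#' @param noise_sd noise standard deviation (default 0.01).
#' @param seed optional seed for a reproducible draw.
#' @return signal plus i.i.d. Gaussian(0, noise_sd^2) per sample.
#' @export
add_gaussian_noise <- function(signal, noise_sd = 0.01, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd == 0) return(signal)
  signal + stats::rnorm(length(signal), 0, noise_sd)
}

check_gain_x <- function(x, range) {
  if (x < range[1] || x > range[2]) {
    stop("gain offset x = ", x, " outside configured range [",
         range[1], ", ", range[2], "]", call. = FALSE)
  }
}

#' Amplify a signal by gain k = 1 + x
#'
#' @param signal numeric matrix or vector.
#' @param x gain offset; must lie in `range`.
#' @param range admissible range for `x` (default `c(0.001, 0.01)`).
#' @return `(1 + x) * signal`.
#' @export
amplify <- function(signal, x, range = c(0.001, 0.01)) {
  check_gain_x(x, range)
  (1 + x) * signal
}

#' Attenuate a signal by gain k = 1 - x
#'
#' @inheritParams amplify
#' @return `(1 - x) * signal`.
#' @export
attenuate <- function(signal, x, range = c(0.001, 0.01)) {
  check_gain_x(x, range)
  (1 - x) * signal
}

#' Expand a training set with augmented copies
#'
#' Under policy `"triple"` every record gains one noisy, one amplified and
#' one attenuated copy (gain offsets drawn uniformly from the configured
#' range), so each class count exactly quadruples.  Under `"balance"`,
#' minority classes are augmented up to the majority class count.  Age,
#' sex and class labels are copied unmodified; augmented record ids carry
#' an operator suffix and the per-copy provenance (operator, x) is attached
#' as `attr(, "provenance")`.
#'
#' @param dataset an `ecg_dataset` with `partition == "train"`; validation
#'   and test sets are never augmented.
#' @param config an [augmentation_config()].
#' @return the expanded `ecg_dataset` (originals retained).
#' @export
expand_training_set <- function(dataset, config = augmentation_config()) {
  stopifnot(inherits(dataset, "ecg_dataset"),
            inherits(config, "augmentation_config"))
  if (!identical(dataset$partition, "train")) {
    stop("augmentation is applied to the training partition only, got '",
         dataset$partition, "'", call. = FALSE)
  }
  set.seed(config$seed)
  n <- length(dataset$y)
  ops_for <- function() {
    if (config$policy == "triple") {
      replicate(n, c("noise", "amplify", "attenuate"), simplify = FALSE)
    } else {
      # balance: bring every class up to the majority count
      tab <- table(dataset$y)
      target <- max(tab)
      ops <- vector("list", n)
      cycle <- c("noise", "amplify", "attenuate")
      for (cl in as.integer(names(tab))) {
        idx <- which(dataset$y == cl)
        need <- target - length(idx)
        if (need <= 0) next
        give <- rep(seq_along(idx), length.out = need)
        for (j in seq_len(need)) {
          i <- idx[give[j]]
          ops[[i]] <- c(ops[[i]], cycle[(j - 1L) %% 3L + 1L])
        }
      }
      ops
    }
  }
  ops <- ops_for()

  sigs <- dataset$signals; age <- dataset$age; sex <- dataset$sex
  y <- dataset$y; ids <- dataset$record_id
  prov <- data.frame(record_id = character(0), operator = character(0),
                     x = numeric(0), stringsAsFactors = FALSE)
  suffix <- c(noise = "_n", amplify = "_a", attenuate = "_t")
  wide <- c(config$gain_x_min, config$gain_x_max)
  for (i in seq_len(n)) {
    for (op in ops[[i]]) {
      new_sig <- switch(op,
        noise = add_gaussian_noise(dataset$signals[[i]], config$noise_sd),
        amplify = {
          x <- stats::runif(1, wide[1], wide[2])
          amplify(dataset$signals[[i]], x, wide)
        },
        attenuate = {
          x <- stats::runif(1, wide[1], wide[2])
          attenuate(dataset$signals[[i]], x, wide)
        })
      x_used <- if (op == "noise") NA_real_ else x
      new_id <- paste0(dataset$record_id[i], suffix[[op]],
                       sum(prov$record_id == dataset$record_id[i]) + 1L)
      sigs <- c(sigs, list(new_sig))
      age <- c(age, dataset$age[i]); sex <- c(sex, dataset$sex[i])
      y <- c(y, dataset$y[i]); ids <- c(ids, new_id)
      prov <- rbind(prov, data.frame(record_id = dataset$record_id[i],
                                     operator = op, x = x_used,
                                     stringsAsFactors = FALSE))
    }
  }
  out <- dataset
  out$signals <- sigs; out$age <- age; out$sex <- sex
  out$y <- as.integer(y); out$record_id <- ids
  attr(out, "provenance") <- prov
  out
}
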