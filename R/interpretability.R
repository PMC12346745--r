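## Lead-level Shapley attribution.  The 12 leads are the players; masking
## a lead replaces its whole time series with a baseline lead.  With only
## 12 players the 2^12-coalition game is exactly enumerable, which serves
## as the oracle for the permutation-sampling estimator.

#' Masking scheme for lead-coalition evaluation
#'
#' @param baseline `"zeros"` (masked leads set to 0 mV) or `"mean"`
#'   (masked leads replaced by a reference lead, typically the
#'   training-set mean signal).
#' @param baseline_signal samples x 12 matrix, required for
#'   `baseline = "mean"`.
#' @return object of class `masking_scheme`.
#' @export
masking_scheme <- function(baseline = c("zeros", "mean"),
                           baseline_signal = NULL) {
  baseline <- match.arg(baseline)
  if (baseline == "mean" && is.null(baseline_signal)) {
    stop("baseline = \"mean\" requires baseline_signal", call. = FALSE)
  }
  structure(list(baseline = baseline, baseline_signal = baseline_signal),
            class = "masking_scheme")
}

mask_signal <- function(signal, present, scheme) {
  out <- signal
  off <- which(!present)
  if (length(off)) {
    out[, off] <- if (scheme$baseline == "zeros") 0 else
      scheme$baseline_signal[, off]
  }
  out
}

# Evaluate the value function on a set of coalitions (rows of a logical
# matrix).  `model` is either an ecg_model/ecg_fit (value = predicted
# probability of `class_index`, demographics never masked) or a plain
# function(signal) -> scalar for analytic toy models.
coalition_values <- function(model, signal, demographics, scheme, masks,
                             class_index = 1L) {
  if (is.function(model)) {
    return(vapply(seq_len(nrow(masks)), function(i) {
      model(mask_signal(signal, masks[i, ], scheme))
    }, numeric(1)))
  }
  if (inherits(model, "ecg_fit")) model <- model$model
  stopifnot(inherits(model, "ecg_model"))
  sigs <- lapply(seq_len(nrow(masks)), function(i) {
    mask_signal(signal, masks[i, ], scheme)
  })
  nd <- list(signals = sigs,
             age = rep(demographics$age %||% NA_real_, length(sigs)),
             sex = rep(demographics$sex %||% NA_character_, length(sigs)))
  predict_proba(model, nd)[, class_index + 1L]
}

all_coalitions <- function() {
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 12L)))
  dimnames(m) <- NULL
  m  # row r encodes the subset with bit pattern r - 1 (lead 1 = bit 0)
}

#' Exact per-lead Shapley attribution by coalition enumeration
#'
#' Enumerates all 2^12 lead coalitions and computes each lead's Shapley
#' value phi_l, the coalition-weighted average of its marginal
#' contribution to the value function.  Satisfies efficiency:
#' `sum(phi) = v(all leads) - v(no leads)`.
#'
#' @param model a fitted `ecg_model`/`ecg_fit` (value = probability of
#'   `class_index`) or a function(signal) -> scalar.
#' @param signal samples x 12 matrix (one record).
#' @param demographics list with `age` and `sex` for the record (ignored
#'   for function models); demographic inputs are never masked.
#' @param scheme a [masking_scheme()].
#' @param class_index 0-based class whose probability is attributed.
#' @return named numeric vector of 12 Shapley values.
#' @export
exact_lead_shapley <- function(model, signal, demographics = NULL,
                               scheme = masking_scheme(), class_index = 1L) {
  if (ncol(signal) != 12L) {
    stop("lead attribution requires a 12-lead signal", call. = FALSE)
  }
  masks <- all_coalitions()
  v <- coalition_values(model, signal, demographics, scheme, masks, class_index)
  sizes <- rowSums(masks)
  w <- exp(lfactorial(0:11) + lfactorial(11 - (0:11)) - lfactorial(12))
  phi <- numeric(12L)
  code <- seq_len(nrow(masks)) - 1L
  for (l in seq_len(12L)) {
    without <- which(!masks[, l])
    with_l <- code[without] + bitwShiftL(1L, l - 1L) + 1L
    s <- sizes[without]
    phi[l] <- sum(w[s + 1L] * (v[with_l] - v[without]))
  }
  stats::setNames(phi, ECG_LEADS)
}

#' Sampled per-lead Shapley attribution (permutation estimator)
#'
#' Averages each lead's marginal contribution over random permutations of
#' the 12 leads; unbiased for the exact Shapley value, reproducible from
#' the seed.  Value evaluations are cached per coalition, so estimates for
#' repeated coalitions cost nothing extra.
#'
#' @inheritParams exact_lead_shapley
#' @param n_permutations number of sampled permutations (>= 1).
#' @param seed RNG seed.
#' @return named numeric vector of 12 Shapley estimates.
#' @export
sampled_lead_shapley <- function(model, signal, demographics = NULL,
                                 scheme = masking_scheme(), class_index = 1L,
                                 n_permutations = 64, seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (ncol(signal) != 12L) {
    stop("lead attribution requires a 12-lead signal", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cache <- new.env(parent = emptyenv())
  value_of <- function(mask_rows) {
    keys <- vapply(seq_len(nrow(mask_rows)), function(i) {
      sum(bitwShiftL(1L, which(mask_rows[i, ]) - 1L))
    }, numeric(1))
    need <- !vapply(as.character(keys), exists, logical(1), envir = cache)
    if (any(need)) {
      vals <- coalition_values(model, signal, demographics, scheme,
                               mask_rows[need, , drop = FALSE], class_index)
      for (j in seq_along(vals)) {
        assign(as.character(keys[need][j]), vals[j], envir = cache)
      }
    }
    vapply(as.character(keys), get, numeric(1), envir = cache)
  }
  phi <- numeric(12L)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(12L)
    masks <- matrix(FALSE, 13L, 12L)
    for (j in seq_len(12L)) masks[j + 1L, ord[seq_len(j)]] <- TRUE
    v <- value_of(masks)
    phi[ord] <- phi[ord] + (v[-1L] - v[-13L])
  }
  stats::setNames(phi / n_permutations, ECG_LEADS)
}

#' Aggregate per-sample attributions into a lead-importance vector
#'
#' The relative importance of lead l is the mean over samples of the
#' absolute per-sample Shapley value of that lead (the signed mean is
#' available via `signed = TRUE`); optionally rescaled to sum to one for
#' cross-class comparison.
#'
#' @param attributions N x 12 matrix of per-sample Shapley values.
#' @param normalization `"raw"` or `"sum_to_one"`.
#' @param signed average the signed values instead of absolute values.
#' @param class_label optional class name carried in the result.
#' @return object of class `lead_importance` with fields `importance`
#'   (named 12-vector), `n_samples`, `normalization`, `class_label`.
#' @export
lead_importance <- function(attributions, normalization = c("raw", "sum_to_one"),
                            signed = FALSE, class_label = NA_character_) {
  normalization <- match.arg(normalization)
  attributions <- matrix(attributions, ncol = 12L)
  if (nrow(attributions) == 0L) {
    stop("attribution matrix must have at least one sample", call. = FALSE)
  }
  vals <- if (signed) attributions else abs(attributions)
  imp <- colMeans(vals)
  if (normalization == "sum_to_one" && sum(abs(imp)) > 0) {
    imp <- imp / sum(imp)
  }
  structure(list(class_label = class_label,
                 importance = stats::setNames(imp, ECG_LEADS),
                 n_samples = nrow(attributions),
                 normalization = normalization),
            class = "lead_importance")
}

#' @export
print.lead_importance <- function(x, ...) {
  cat(sprintf("<lead_importance %s (N=%d, %s)>\n", x$class_label,
              x$n_samples, x$normalization))
  print(round(x$importance, 4))
  invisible(x)
}

#' Per-class lead importance over a dataset
#'
#' Groups records by actual class, attributes each record's probability of
#' its own class to the 12 leads, and aggregates with [lead_importance()].
#' Classes without records are omitted with a warning.
#'
#' @param model a fitted `ecg_model` or `ecg_fit`.
#' @param dataset an `ecg_dataset` (typically the test partition).
#' @param scheme a [masking_scheme()].
#' @param estimator `"exact"` (full enumeration) or `"sampled"`.
#' @param n_permutations permutations per record for the sampled
#'   estimator.
#' @param seed RNG seed for the sampled estimator.
#' @param normalization passed to [lead_importance()].
#' @param max_records cap on records attributed per class (records beyond
#'   the cap are ignored; keeps exact enumeration affordable).
#' @return named list of `lead_importance`, one per represented class.
#' @export
per_class_importance <- function(model, dataset, scheme = masking_scheme(),
                                 estimator = c("exact", "sampled"),
                                 n_permutations = 64, seed = NULL,
                                 normalization = "raw", max_records = Inf) {
  estimator <- match.arg(estimator)
  if (!is.null(seed)) set.seed(seed)
  cls <- dataset$scenario$class_names
  out <- list()
  for (ci in seq_along(cls) - 1L) {
    idx <- which(dataset$y == ci)
    if (!length(idx)) {
      warning("class ", cls[ci + 1L], " has no records; omitted", call. = FALSE)
      next
    }
    if (length(idx) > max_records) idx <- idx[seq_len(max_records)]
    phis <- t(vapply(idx, function(i) {
      demo <- list(age = dataset$age[i], sex = dataset$sex[i])
      if (estimator == "exact") {
        exact_lead_shapley(model, dataset$signals[[i]], demo, scheme, ci)
      } else {
        sampled_lead_shapley(model, dataset$signals[[i]], demo, scheme, ci,
                             n_permutations = n_permutations)
      }
    }, numeric(12L)))
    out[[cls[ci + 1L]]] <- lead_importance(phis, normalization,
                                           class_label = cls[ci + 1L])
  }
  out
}
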