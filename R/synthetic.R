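## Synthetic PTB-XL-shaped corpora.  Waveforms are class-specific pulse
## trains (a lead-signature amplitude vector times a periodic Gaussian-bump
## pulse at the class's dominant frequency) plus i.i.d. Gaussian noise;
## demographics optionally carry class signal through an age shift and a
## sex log-odds per class.  Controllable, not morphologically realistic.

#' Build the class specification table for a synthetic corpus
#'
#' @param codes SCP statement codes, one per class (must exist in
#'   [ptbxl_taxonomy()]).
#' @param prevalence class prevalences, summing to 1 (default uniform).
#' @param signatures 12-column matrix of per-lead amplitudes in millivolts,
#'   one row per class, or a single row recycled.
#' @param freq dominant pulse frequency per class in Hz (default spreads
#'   classes over 1-2.5 Hz, i.e. heart-rate-like repetition).
#' @return data.frame with list-column `signature`.
#' @export
synth_class_spec <- function(codes, prevalence = NULL, signatures = NULL,
                             freq = NULL) {
  k <- length(codes)
  tax <- ptbxl_taxonomy()
  if (!all(codes %in% tax$code)) {
    stop("unknown SCP code(s): ", paste(setdiff(codes, tax$code), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(prevalence)) prevalence <- rep(1 / k, k)
  if (is.null(signatures)) {
    # default: class j plants its energy on lead j (wrapping past 12)
    signatures <- matrix(0, k, 12)
    signatures[cbind(seq_len(k), (seq_len(k) - 1L) %% 12L + 1L)] <- 1
  }
  signatures <- matrix(signatures, nrow = k, ncol = 12,
                       byrow = is.vector(signatures))
  if (is.null(freq)) freq <- seq(1, 2.5, length.out = k)
  data.frame(code = codes, prevalence = prevalence, freq = freq,
             signature = I(lapply(seq_len(k), function(i) signatures[i, ])),
             stringsAsFactors = FALSE)
}

#' Configuration of a synthetic ECG corpus
#'
#' @param n_records number of records.
#' @param class_spec table from [synth_class_spec()].
#' @param fs sampling rate in Hz (default 100).
#' @param noise_sd additive Gaussian noise, millivolts (default 0.05).
#' @param demographic_effect optional list with `age_shift` (years added to
#'   the base age per class) and `sex_logodds` (log-odds of female per
#'   class); both vectors of length `nrow(class_spec)`.
#' @param seed RNG seed; the corpus is a pure function of this
#'   configuration.
#' @return object of class `synthesis_config`.
#' @export
synthesis_config <- function(n_records, class_spec, fs = 100, noise_sd = 0.05,
                             demographic_effect = NULL, seed = 1L) {
  if (abs(sum(class_spec$prevalence) - 1) > 1e-8 || any(class_spec$prevalence < 0)) {
    stop("class prevalences must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(unlist(class_spec$signature) < 0)) {
    stop("lead-signature amplitudes must be non-negative", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!fs %in% c(100, 500)) stop("fs must be 100 or 500 Hz", call. = FALSE)
  if (!is.null(demographic_effect)) {
    stopifnot(length(demographic_effect$age_shift) == nrow(class_spec),
              length(demographic_effect$sex_logodds) == nrow(class_spec))
  }
  structure(list(n_records = as.integer(n_records), class_spec = class_spec,
                 fs = fs, noise_sd = noise_sd,
                 demographic_effect = demographic_effect, seed = as.integer(seed)),
            class = "synthesis_config")
}

# Periodic unit-amplitude pulse train: Gaussian bumps of width 25 ms every
# 1/freq seconds, with a random phase offset per record.
pulse_train <- function(n, fs, freq, phase) {
  t <- seq_len(n) / fs
  period <- 1 / freq
  centers <- seq(phase, max(t) + period, by = period)
  sigma <- 0.025
  s <- numeric(n)
  for (c0 in centers) s <- s + exp(-(t - c0)^2 / (2 * sigma^2))
  s
}

#' Generate a synthetic PTB-XL-shaped corpus
#'
#' Each record's 12-lead signal is its class's lead signature times a pulse
#' train at the class's dominant frequency, plus Gaussian noise.  Age is
#' drawn from a Normal(60, 12) base (clamped to 18-95) shifted by the
#' class's age effect; sex is Bernoulli with the class's log-odds of
#' female; folds are uniform on 1-10.  Byte-identical output for identical
#' configurations.
#'
#' @param config a [synthesis_config()].
#' @return `ecg_corpus` object (as from [load_corpus()]) with the metadata
#'   tables attached as `$metadata` and `$scp_statements`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  spec <- config$class_spec
  tax <- ptbxl_taxonomy()
  n <- config$n_records
  fs <- config$fs
  len <- 10L * fs
  cls <- sample.int(nrow(spec), n, replace = TRUE, prob = spec$prevalence)

  age_shift <- if (is.null(config$demographic_effect)) rep(0, nrow(spec)) else
    config$demographic_effect$age_shift
  sex_lo <- if (is.null(config$demographic_effect)) rep(0, nrow(spec)) else
    config$demographic_effect$sex_logodds

  records <- vector("list", n)
  meta <- data.frame(
    ecg_id = seq_len(n),
    age = NA_real_, sex = NA_integer_, scp_codes = NA_character_,
    strat_fold = NA_integer_, filename_lr = NA_character_,
    filename_hr = NA_character_, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    k <- cls[i]
    phase <- stats::runif(1, 0, 1 / spec$freq[k])
    base <- pulse_train(len, fs, spec$freq[k], phase)
    sig <- outer(base, spec$signature[[k]])
    if (config$noise_sd > 0) {
      sig <- sig + matrix(stats::rnorm(len * 12L, 0, config$noise_sd), len, 12L)
    }
    colnames(sig) <- ECG_LEADS
    age <- round(min(95, max(18, stats::rnorm(1, 60, 12) + age_shift[k])))
    sex_i <- stats::rbinom(1, 1, stats::plogis(sex_lo[k]))
    fold <- sample.int(10L, 1L)
    id <- as.character(meta$ecg_id[i])
    records[[i]] <- ecg_record(id, sig, fs, age = age,
                               sex = c("male", "female")[sex_i + 1L],
                               scp_codes = stats::setNames(100, spec$code[k]),
                               fold = fold)
    meta$age[i] <- age
    meta$sex[i] <- sex_i
    meta$scp_codes[i] <- sprintf("{'%s': 100.0}", spec$code[k])
    meta$strat_fold[i] <- fold
    meta$filename_lr[i] <- paste0("records100/", id, "_lr")
    meta$filename_hr[i] <- paste0("records500/", id, "_hr")
  }

  ti <- match(spec$code, tax$code)
  labels <- data.frame(
    record_id = as.character(meta$ecg_id),
    superclass = tax$superclass[ti][cls],
    subclass = tax$subclass[ti][cls],
    age = meta$age, sex = c("male", "female")[meta$sex + 1L],
    fold = meta$strat_fold, stringsAsFactors = FALSE
  )
  labels$partition <- assign_split(labels$fold)

  scp_statements <- data.frame(
    code = tax$code, description = tax$description, diagnostic = 1L,
    diagnostic_class = tax$superclass, diagnostic_subclass = tax$subclass,
    stringsAsFactors = FALSE
  )
  structure(list(records = records, labels = labels, fs = fs,
                 metadata = meta, scp_statements = scp_statements,
                 config = config),
            class = "ecg_corpus")
}

#' Write a synthetic corpus as a PTB-XL-style file tree
#'
#' Writes one WFDB header/signal pair per record plus `ptbxl_database.csv`
#' and `scp_statements.csv` in the column dialect [load_corpus()] reads, so
#' the round trip reproduces signals to the WFDB amplitude resolution and
#' metadata exactly.
#'
#' @param corpus corpus from [generate_corpus()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_wfdb_fixture <- function(corpus, out_dir) {
  stopifnot(inherits(corpus, "ecg_corpus"), !is.null(corpus$metadata))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  sub <- if (corpus$fs == 100) "records100" else "records500"
  suffix <- if (corpus$fs == 100) "_lr" else "_hr"
  rec_dir <- file.path(out_dir, sub)
  for (r in corpus$records) {
    write_wfdb_record(r$signal, paste0(r$record_id, suffix), rec_dir, fs = r$fs)
  }
  utils::write.csv(corpus$metadata, file.path(out_dir, "ptbxl_database.csv"),
                   row.names = FALSE)
  utils::write.csv(corpus$scp_statements, file.path(out_dir, "scp_statements.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Canned study conditions: corpus where only demographics separate classes
#'
#' Two classes share an identical lead signature (all leads, equal
#' amplitude) so the waveforms are exchangeable; the classes differ only
#' through a strong age shift and sex log-odds.  Used to test that the
#' demographic branch adds information.
#'
#' @param n_records corpus size.
#' @param seed RNG seed.
#' @return a [synthesis_config()].
#' @export
demographic_signal_config <- function(n_records = 200, seed = 1L) {
  spec <- synth_class_spec(
    codes = c("NORM", "IMI"),
    signatures = matrix(rep(0.5, 24), nrow = 2, byrow = TRUE),
    freq = c(1.5, 1.5)
  )
  synthesis_config(n_records, spec, noise_sd = 0.05,
                   demographic_effect = list(age_shift = c(-18, 18),
                                             sex_logodds = c(-2, 2)),
                   seed = seed)
}

#' Canned study conditions: classes planted on disjoint leads
#'
#' Class `j` carries all its signal energy on lead `j` at a class-specific
#' pulse frequency, so classes are separable from per-lead energy alone and
#' lead-level Shapley attribution has a known ground truth.
#'
#' @param codes SCP codes, one per class (default a NORM + 4 disease mix).
#' @param n_records corpus size.
#' @param amplitude planted amplitude in millivolts.
#' @param noise_sd additive noise in millivolts.
#' @param seed RNG seed.
#' @return a [synthesis_config()].
#' @export
disjoint_leads_config <- function(codes = c("NORM", "IMI", "CLBBB", "STTC", "LVH"),
                                  n_records = 400, amplitude = 1,
                                  noise_sd = 0.05, seed = 1L) {
  k <- length(codes)
  sig <- matrix(0, k, 12)
  sig[cbind(seq_len(k), seq_len(k))] <- amplitude
  spec <- synth_class_spec(codes, signatures = sig)
  synthesis_config(n_records, spec, noise_sd = noise_sd, seed = seed)
}
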