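## Reading PTB-XL-style corpora: WFDB waveforms, the per-record metadata
## table (ptbxl_database.csv dialect) and the SCP statement table
## (scp_statements.csv dialect), plus label mapping and fold-based splits.

#' Construct a single ECG record
#'
#' @param record_id record identifier.
#' @param signal samples x 12 numeric matrix, millivolts, leads in the
#'   standard order I, II, III, aVR, aVL, aVF, V1-V6.
#' @param fs sampling rate in Hz (100 or 500); records are 10 s long, so
#'   the signal must have `10 * fs` rows.
#' @param age age in years (may be `NA`).
#' @param sex `"male"`, `"female"` or `NA`.
#' @param scp_codes named numeric vector of SCP statement likelihoods in
#'   \[0, 100\].
#' @param fold stratification fold, integer 1-10.
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, signal, fs, age = NA_real_, sex = NA_character_,
                       scp_codes = numeric(0), fold = NA_integer_) {
  signal <- as.matrix(signal)
  if (ncol(signal) != 12L) {
    stop("ECG records must have exactly 12 leads, got ", ncol(signal), call. = FALSE)
  }
  if (!fs %in% c(100, 500)) stop("fs must be 100 or 500 Hz", call. = FALSE)
  if (nrow(signal) != 10L * fs) {
    stop("record length must be 10 s: expected ", 10L * fs,
         " samples at ", fs, " Hz, got ", nrow(signal), call. = FALSE)
  }
  if (!is.na(fold) && !(fold %in% 1:10)) stop("fold must be in 1..10", call. = FALSE)
  structure(list(record_id = as.character(record_id), signal = signal,
                 fs = fs, age = as.numeric(age), sex = sex,
                 scp_codes = scp_codes, fold = as.integer(fold)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d x 12 @ %g Hz, age %s, sex %s, fold %s>\n",
              x$record_id, nrow(x$signal), x$fs,
              ifelse(is.na(x$age), "?", x$age), ifelse(is.na(x$sex), "?", x$sex),
              ifelse(is.na(x$fold), "?", x$fold)))
  invisible(x)
}

#' Read one ECG waveform record from a WFDB file pair
#'
#' @param path WFDB record path (with or without `.hea`).
#' @param fs expected sampling rate in Hz (100 or 500).
#' @return an [ecg_record()] carrying the waveform only; age, sex,
#'   SCP codes and fold are merged from the metadata table separately.
#' @export
read_record <- function(path, fs = 100) {
  w <- read_wfdb_record(path)
  if (w$fs != fs) {
    stop("sampling rate mismatch: header says ", w$fs, " Hz, expected ", fs,
         call. = FALSE)
  }
  ecg_record(record_id = w$record_name, signal = w$signal, fs = fs)
}

# Parse one serialized scp_codes map, e.g. "{'NORM': 100.0, 'SR': 0.0}".
# Returns a named numeric vector, or NULL when the string is malformed.
parse_scp_codes <- function(x) {
  if (is.na(x)) return(NULL)
  x <- trimws(x)
  if (!grepl("^\\{.*\\}$", x)) return(NULL)
  inner <- trimws(substr(x, 2L, nchar(x) - 1L))
  if (!nzchar(inner)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(inner, ",")[[1]]
  m <- regmatches(parts, regexec("^\\s*['\"]([^'\"]+)['\"]\\s*:\\s*([-0-9.eE]+)\\s*$", parts))
  if (any(vapply(m, length, 1L) != 3L)) return(NULL)
  vals <- suppressWarnings(as.numeric(vapply(m, `[[`, "", 3L)))
  if (anyNA(vals)) return(NULL)
  stats::setNames(vals, vapply(m, `[[`, "", 2L))
}

#' Load and join the two PTB-XL-style metadata tables
#'
#' Reads the per-record table (`ptbxl_database.csv` dialect: record id,
#' `age`, `sex`, serialized `scp_codes`, `strat_fold`, waveform paths) and
#' the SCP statement table (`scp_statements.csv` dialect: statement code,
#' `diagnostic_class`, optional `diagnostic_subclass`).  Rows whose
#' `scp_codes` field does not parse are dropped and counted in a message.
#'
#' @param records_csv path to the per-record metadata CSV.
#' @param scp_csv path to the SCP statement CSV.
#' @return data.frame of per-record metadata with a parsed `scp_codes`
#'   list-column; the code-to-class taxonomy is attached as
#'   `attr(, "taxonomy")` and the number of dropped rows as
#'   `attr(, "n_dropped")`.
#' @export
load_metadata <- function(records_csv, scp_csv) {
  meta <- utils::read.csv(records_csv, stringsAsFactors = FALSE)
  need <- c("ecg_id", "age", "sex", "scp_codes", "strat_fold")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("metadata table lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  scp <- utils::read.csv(scp_csv, stringsAsFactors = FALSE)
  code_col <- if ("code" %in% names(scp)) "code" else names(scp)[1L]
  if (!"diagnostic_class" %in% names(scp)) {
    stop("SCP statement table lacks required column: diagnostic_class", call. = FALSE)
  }
  sub_col <- intersect("diagnostic_subclass", names(scp))
  tax <- data.frame(
    code = as.character(scp[[code_col]]),
    superclass = as.character(scp$diagnostic_class),
    subclass = if (length(sub_col)) as.character(scp[[sub_col]]) else
      as.character(scp[[code_col]]),
    stringsAsFactors = FALSE
  )
  tax <- tax[!is.na(tax$superclass) & nzchar(tax$superclass), , drop = FALSE]
  empty_sub <- is.na(tax$subclass) | !nzchar(tax$subclass)
  tax$subclass[empty_sub] <- tax$code[empty_sub]

  parsed <- lapply(meta$scp_codes, parse_scp_codes)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    message(sum(bad), " record(s) dropped: unparseable scp_codes")
  }
  meta <- meta[!bad, , drop = FALSE]
  meta$scp_codes <- parsed[!bad]
  meta$sex <- decode_sex(meta$sex)
  attr(meta, "taxonomy") <- tax
  attr(meta, "n_dropped") <- sum(bad)
  meta
}

# PTB-XL encodes sex as 0 = male, 1 = female; also accept strings.
decode_sex <- function(x) {
  if (is.numeric(x) || all(grepl("^[01]$", x[!is.na(x)]))) {
    c("male", "female")[as.integer(x) + 1L]
  } else {
    out <- tolower(as.character(x))
    out[!out %in% c("male", "female")] <- NA_character_
    out
  }
}

#' Map a record's SCP codes to a single diagnostic label
#'
#' Codes at or above `min_likelihood` are looked up in the taxonomy
#' (non-diagnostic statements are ignored).  A record whose retained codes
#' fall in exactly one superclass yields that label; zero diagnostic codes
#' give status `"unlabeled"` and more than one distinct superclass gives
#' `"ambiguous"` — single-label scenarios exclude both.
#'
#' @param scp_codes named numeric vector of statement likelihoods.
#' @param taxonomy code-to-class table as from [ptbxl_taxonomy()].
#' @param min_likelihood retention threshold in \[0, 100\]; the default 100
#'   keeps only fully confident statements.
#' @return list with `status` (`"ok"`, `"unlabeled"` or `"ambiguous"`),
#'   `superclass` and `subclass` (the subclass is `NA` when the retained
#'   codes disagree at subclass granularity).
#' @export
map_scp_to_label <- function(scp_codes, taxonomy = ptbxl_taxonomy(),
                             min_likelihood = 100) {
  keep <- names(scp_codes)[scp_codes >= min_likelihood]
  hit <- taxonomy[match(keep, taxonomy$code), , drop = FALSE]
  hit <- hit[!is.na(hit$superclass), , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(list(status = "unlabeled", superclass = NA_character_,
                subclass = NA_character_))
  }
  sup <- unique(hit$superclass)
  if (length(sup) > 1L) {
    return(list(status = "ambiguous", superclass = NA_character_,
                subclass = NA_character_))
  }
  sub <- unique(hit$subclass)
  list(status = "ok", superclass = sup,
       subclass = if (length(sub) == 1L) sub else NA_character_)
}

#' Map stratification folds to train/validation/test partitions
#'
#' Folds 1-8 train, fold 9 validation, fold 10 test.
#'
#' @param fold integer vector of folds in 1..10.
#' @return factor with levels `train`, `validation`, `test`.
#' @export
assign_split <- function(fold) {
  fold <- as.integer(fold)
  if (anyNA(fold) || any(fold < 1L | fold > 10L)) {
    stop("fold must be an integer in 1..10", call. = FALSE)
  }
  out <- ifelse(fold <= 8L, "train", ifelse(fold == 9L, "validation", "test"))
  factor(out, levels = c("train", "validation", "test"))
}

#' Load a PTB-XL-style corpus directory
#'
#' Expects `ptbxl_database.csv`, `scp_statements.csv` and a WFDB record
#' tree under `dir` (waveform paths taken from the `filename_lr` /
#' `filename_hr` column for 100 / 500 Hz).  Every record is labeled
#' through [map_scp_to_label()]; ambiguous and unlabeled records are
#' excluded with a message giving the counts.
#'
#' @param dir corpus root directory.
#' @param fs sampling rate to load (100 or 500 Hz).
#' @param min_likelihood SCP likelihood threshold passed to
#'   [map_scp_to_label()].
#' @return object of class `ecg_corpus`: a list with `records` (list of
#'   [ecg_record()]) and `labels` (data.frame with `record_id`,
#'   `superclass`, `subclass`, `age`, `sex`, `fold`, `partition`).
#' @export
load_corpus <- function(dir, fs = 100, min_likelihood = 100) {
  meta <- load_metadata(file.path(dir, "ptbxl_database.csv"),
                        file.path(dir, "scp_statements.csv"))
  tax <- attr(meta, "taxonomy")
  labs <- lapply(meta$scp_codes, map_scp_to_label, taxonomy = tax,
                 min_likelihood = min_likelihood)
  status <- vapply(labs, `[[`, "", "status")
  n_amb <- sum(status == "ambiguous"); n_unl <- sum(status == "unlabeled")
  if (n_amb + n_unl > 0L) {
    message("excluded ", n_amb, " ambiguous and ", n_unl,
            " unlabeled record(s) (single-label rule)")
  }
  keep <- status == "ok"
  meta <- meta[keep, , drop = FALSE]
  labs <- labs[keep]

  path_col <- if (fs == 100) "filename_lr" else "filename_hr"
  if (!path_col %in% names(meta)) {
    stop("metadata table lacks waveform path column ", path_col, call. = FALSE)
  }
  records <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    r <- read_record(file.path(dir, meta[[path_col]][i]), fs = fs)
    records[[i]] <- ecg_record(meta$ecg_id[i], r$signal, fs,
                               age = meta$age[i], sex = meta$sex[i],
                               scp_codes = meta$scp_codes[[i]],
                               fold = meta$strat_fold[i])
  }
  labels <- data.frame(
    record_id = as.character(meta$ecg_id),
    superclass = vapply(labs, `[[`, "", "superclass"),
    subclass = vapply(labs, `[[`, "", "subclass"),
    age = meta$age, sex = meta$sex, fold = as.integer(meta$strat_fold),
    stringsAsFactors = FALSE
  )
  labels$partition <- assign_split(labels$fold)
  structure(list(records = records, labels = labels, fs = fs),
            class = "ecg_corpus")
}

#' @export
print.ecg_corpus <- function(x, ...) {
  cat(sprintf("<ecg_corpus: %d records @ %g Hz>\n", length(x$records), x$fs))
  print(table(x$labels$superclass, x$labels$partition))
  invisible(x)
}
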