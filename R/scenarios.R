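## Classification scenarios: binary cases (normal vs one superclass,
## normal vs one subclass, normal vs abnormal) and the 5/10/15-class
## settings.  A scenario is a declarative task definition; materializing it
## against a corpus yields labeled datasets with 0-based class indices.

new_scenario <- function(name, class_names, granularity) {
  stopifnot(!anyDuplicated(class_names))
  structure(list(name = name, class_names = class_names,
                 granularity = granularity, k = length(class_names)),
            class = "ecg_scenario")
}

#' @export
print.ecg_scenario <- function(x, ...) {
  cat(sprintf("<ecg_scenario %s: %d classes [%s], %s granularity>\n",
              x$name, x$k, paste(x$class_names, collapse = ", "),
              x$granularity))
  invisible(x)
}

#' Binary scenario: normal vs one diagnostic superclass
#'
#' @param disease one of `CD`, `HYP`, `MI`, `STTC`.
#' @return an `ecg_scenario` with classes `c("NORM", disease)`; records of
#'   other superclasses are excluded.
#' @export
binary_superclass <- function(disease) {
  if (!is.character(disease) || length(disease) != 1L ||
      !disease %in% setdiff(ECG_SUPERCLASSES, "NORM")) {
    stop("disease must be one of CD, HYP, MI, STTC", call. = FALSE)
  }
  new_scenario(paste0("NORM_vs_", disease), c("NORM", disease), "superclass")
}

#' Binary scenario: normal vs one diagnostic subclass
#'
#' @param disease one of the nine subclass settings: `STTC`, `AMI`, `IMI`,
#'   `LAFB/LPFB`, `LVH`, `IRBBB`, `CLBBB`, `ISCA`, `CRBBB`.
#' @return an `ecg_scenario` at subclass granularity.
#' @export
binary_subclass <- function(disease) {
  allowed <- c("STTC", "AMI", "IMI", "LAFB/LPFB", "LVH", "IRBBB", "CLBBB",
               "ISCA", "CRBBB")
  if (!is.character(disease) || length(disease) != 1L || !disease %in% allowed) {
    stop("disease must be one of: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  new_scenario(paste0("NORM_vs_", gsub("/", "-", disease)),
               c("NORM", disease), "subclass")
}

#' Binary scenario: normal vs abnormal
#'
#' Every single-disease (non-NORM) record maps to class `ABNORMAL`
#' (index 1), normal records to index 0.
#' @return an `ecg_scenario`.
#' @export
binary_normal_abnormal <- function() {
  new_scenario("NORM_vs_ABNORMAL", c("NORM", "ABNORMAL"), "normal_abnormal")
}

#' Multiclass scenarios: 5 superclasses, or 10/15 subclasses
#'
#' `k = 5` uses the five superclasses in canonical order.  For
#' `k` in 10/15 the classes are NORM plus the `k - 1` most frequent
#' non-NORM subclasses in `class_counts`; ties at the cutoff are broken by
#' taxonomy order (with a message).  Counts should come from the training
#' folds only, so the test set cannot influence class selection (see
#' [subclass_counts()]).
#'
#' @param k number of classes: 5, 10 or 15.
#' @param class_counts named vector of per-subclass training-record counts;
#'   required for `k` in 10/15.
#' @return an `ecg_scenario`.
#' @export
multiclass <- function(k, class_counts = NULL) {
  if (!k %in% c(5, 10, 15)) stop("k must be 5, 10 or 15", call. = FALSE)
  if (k == 5) {
    return(new_scenario("superclass_5", ECG_SUPERCLASSES, "superclass"))
  }
  if (is.null(class_counts)) {
    stop("class_counts is required for subclass scenarios (k = 10, 15)",
         call. = FALSE)
  }
  cand <- setdiff(names(class_counts), "NORM")
  counts <- as.numeric(class_counts[cand])
  ord <- order(-counts, .taxonomy_rank(cand))
  n_take <- k - 1L
  if (length(cand) < n_take) {
    stop("need at least ", n_take, " non-NORM subclasses in class_counts",
         call. = FALSE)
  }
  if (length(cand) > n_take &&
      counts[ord[n_take]] == counts[ord[n_take + 1L]]) {
    message("tie at the top-", n_take, " cutoff broken by taxonomy order")
  }
  sel <- cand[ord[seq_len(n_take)]]
  # report classes in the canonical (printed) subclass order
  sel <- sel[order(match(sel, .SUBCLASS_ORDER))]
  new_scenario(paste0("subclass_", k), c("NORM", sel), "subclass")
}

#' Training-fold subclass counts of a corpus
#'
#' @param corpus an `ecg_corpus`.
#' @param partition which partition to count over (default `"train"`).
#' @return named vector of record counts per subclass.
#' @export
subclass_counts <- function(corpus, partition = "train") {
  lab <- corpus$labels
  lab <- lab[lab$partition %in% partition & !is.na(lab$subclass), , drop = FALSE]
  tab <- table(lab$subclass)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Map one diagnostic label to a scenario's class index
#'
#' @param scenario an `ecg_scenario`.
#' @param superclass,subclass the record's diagnostic label.
#' @return 0-based class index, or `NA` when the record is excluded from
#'   the scenario.
#' @export
scenario_index <- function(scenario, superclass, subclass) {
  cls <- switch(scenario$granularity,
    superclass = superclass,
    subclass = subclass,
    normal_abnormal = ifelse(superclass == "NORM", "NORM", "ABNORMAL"),
    stop("unknown granularity", call. = FALSE)
  )
  match(cls, scenario$class_names) - 1L
}

#' Materialize a scenario against a corpus
#'
#' Keeps the records of one partition that satisfy the scenario's inclusion
#' rule and attaches 0-based class indices.
#'
#' @param scenario an `ecg_scenario`.
#' @param corpus an `ecg_corpus`.
#' @param partition `"train"`, `"validation"` or `"test"`.
#' @return object of class `ecg_dataset`: list with `signals` (list of
#'   samples x 12 matrices), `age`, `sex`, `y` (0-based integer class
#'   indices), `record_id`, `partition`, `scenario`.
#' @export
materialize <- function(scenario, corpus, partition = c("train", "validation", "test")) {
  partition <- match.arg(partition)
  lab <- corpus$labels
  idx0 <- scenario_index(scenario, lab$superclass, lab$subclass)
  keep <- which(!is.na(idx0) & lab$partition == partition)
  structure(list(
    signals = lapply(corpus$records[keep], `[[`, "signal"),
    age = lab$age[keep], sex = lab$sex[keep],
    y = as.integer(idx0[keep]), record_id = lab$record_id[keep],
    partition = partition, scenario = scenario, fs = corpus$fs
  ), class = "ecg_dataset")
}

#' Materialize all three partitions of a scenario
#'
#' @inheritParams materialize
#' @return list with elements `train`, `validation`, `test`.
#' @export
materialize_splits <- function(scenario, corpus) {
  stats::setNames(
    lapply(c("train", "validation", "test"), materialize,
           scenario = scenario, corpus = corpus),
    c("train", "validation", "test")
  )
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset %s/%s: %d records, %d classes>\n",
              x$scenario$name, x$partition, length(x$y), x$scenario$k))
  print(table(factor(x$scenario$class_names[x$y + 1L],
                     levels = x$scenario$class_names)))
  invisible(x)
}

#' Number of records in a dataset
#' @param dataset an `ecg_dataset`.
#' @export
n_records <- function(dataset) length(dataset$y)

#' Serialize a scenario to a YAML manifest
#'
#' @param scenario an `ecg_scenario`.
#' @param path output file.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(list(name = scenario$name,
                        classes = as.list(scenario$class_names),
                        granularity = scenario$granularity), path)
  invisible(path)
}

#' Read a scenario from a YAML manifest
#' @param path manifest file written by [write_scenario()].
#' @return an `ecg_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  new_scenario(y$name, unlist(y$classes), y$granularity)
}
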