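## Diagnostic taxonomy: five superclasses refined into 23 subclasses.
## SCP statement codes map onto (superclass, subclass); LAFB and LPFB are
## distinct statements pooled into the single subclass "LAFB/LPFB".

#' The five diagnostic superclasses, in canonical reporting order
#' @export
ECG_SUPERCLASSES <- c("NORM", "MI", "CD", "STTC", "HYP")

# Canonical subclass ordering used for multiclass class lists: the
# fifteen-class reporting order first, then the remaining taxonomy rows.
.SUBCLASS_ORDER <- c(
  "NORM", "STTC", "AMI", "IMI", "LAFB/LPFB", "LVH", "IRBBB", "CLBBB",
  "NST_", "ISCA", "CRBBB", "IVCD", "ISC_", "_AVB", "ISCI",
  "ILBBB", "WPW", "RVH", "LAO/LAE", "RAO/RAE", "SEHYP", "LMI", "PMI"
)

#' SCP statement taxonomy for the diagnostic axis
#'
#' Returns the mapping from SCP diagnostic statement codes to the
#' five-superclass / 23-subclass taxonomy.  This is the package's built-in
#' default; [load_metadata()] derives an equivalent table from a corpus's
#' own `scp_statements.csv` when one is supplied.
#'
#' @return data.frame with columns `code`, `superclass`, `subclass`,
#'   `description`.  Statement codes `LAFB` and `LPFB` share the subclass
#'   `LAFB/LPFB`, so 24 codes cover 23 subclasses.
#' @export
ptbxl_taxonomy <- function() {
  tab <- rbind(
    c("NORM",      "NORM", "NORM",      "Normal ECG"),
    c("LAFB",      "CD",   "LAFB/LPFB", "Left anterior fascicular block"),
    c("LPFB",      "CD",   "LAFB/LPFB", "Left posterior fascicular block"),
    c("IRBBB",     "CD",   "IRBBB",     "Incomplete right bundle branch block"),
    c("ILBBB",     "CD",   "ILBBB",     "Incomplete left bundle branch block"),
    c("CLBBB",     "CD",   "CLBBB",     "Complete left bundle branch block"),
    c("CRBBB",     "CD",   "CRBBB",     "Complete right bundle branch block"),
    c("_AVB",      "CD",   "_AVB",      "AV block"),
    c("IVCD",      "CD",   "IVCD",      "Non-specific intraventricular conduction disturbance"),
    c("WPW",       "CD",   "WPW",       "Wolff-Parkinson-White syndrome"),
    c("LVH",       "HYP",  "LVH",       "Left ventricular hypertrophy"),
    c("RVH",       "HYP",  "RVH",       "Right ventricular hypertrophy"),
    c("LAO/LAE",   "HYP",  "LAO/LAE",   "Left atrial overload/enlargement"),
    c("RAO/RAE",   "HYP",  "RAO/RAE",   "Right atrial overload/enlargement"),
    c("SEHYP",     "HYP",  "SEHYP",     "Septal hypertrophy"),
    c("AMI",       "MI",   "AMI",       "Anterior myocardial infarction"),
    c("IMI",       "MI",   "IMI",       "Inferior myocardial infarction"),
    c("LMI",       "MI",   "LMI",       "Lateral myocardial infarction"),
    c("PMI",       "MI",   "PMI",       "Posterior myocardial infarction"),
    c("ISCA",      "STTC", "ISCA",      "Ischemic in anterior leads"),
    c("ISCI",      "STTC", "ISCI",      "Ischemic in inferior leads"),
    c("ISC_",      "STTC", "ISC_",      "Non-specific ischemic"),
    c("STTC",      "STTC", "STTC",      "ST-T changes"),
    c("NST_",      "STTC", "NST_",      "Non-specific ST changes")
  )
  data.frame(code = tab[, 1], superclass = tab[, 2], subclass = tab[, 3],
             description = tab[, 4], stringsAsFactors = FALSE)
}

# Table-order rank of a subclass, used to break count ties deterministically.
.taxonomy_rank <- function(subclass) {
  tax <- unique(ptbxl_taxonomy()$subclass)
  match(subclass, tax)
}
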