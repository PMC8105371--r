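#' Multifocal survival cohort
#'
#' A `cohort` bundles the three tables every pipeline stage consumes:
#'
#' * `tumors` — one row per tumor: `patient_id`, `tumor_id`,
#'   `volume_cc` (> 0), plus one numeric column per radiomic feature;
#' * `outcomes` — one row per patient: `patient_id`, `time_months` (> 0),
#'   `event` (1 = death observed, 0 = right-censored), plus any optional
#'   categorical patient attributes;
#' * `schema` — a [feature_schema()] covering every feature column.
#'
#' @param tumors data frame of per-tumor rows (see above).
#' @param outcomes data frame of per-patient outcomes.
#' @param schema a [feature_schema()].
#' @param provenance optional record of where the cohort came from (a
#'   [generator_config()] or file paths).
#' @return A validated `cohort` object.
#' @export
cohort <- function(tumors, outcomes, schema, provenance = NULL) {
  obj <- structure(list(tumors = tumors, outcomes = outcomes,
                        schema = schema, provenance = provenance),
                   class = "cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort's invariants
#'
#' Checks referential integrity (tumor patients and outcome patients are the
#' same set, each patient appearing once in `outcomes`), positivity of
#' volumes and times, binary events, absence of duplicate
#' (patient, tumor) ids, and schema coverage of all feature columns.
#'
#' @param x a `cohort`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  tu <- x$tumors
  oc <- x$outcomes
  need_t <- c("patient_id", "tumor_id", "volume_cc")
  if (!all(need_t %in% names(tu))) {
    stop("tumor table must contain columns: ", paste(need_t, collapse = ", "))
  }
  need_o <- c("patient_id", "time_months", "event")
  if (!all(need_o %in% names(oc))) {
    stop("outcome table must contain columns: ", paste(need_o, collapse = ", "))
  }
  if (anyDuplicated(oc$patient_id)) {
    stop("duplicate patient_id in outcomes: ",
         paste(unique(oc$patient_id[duplicated(oc$patient_id)]), collapse = ", "))
  }
  key <- paste(tu$patient_id, tu$tumor_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, tumor_id) pair in tumor table")
  }
  orphan <- setdiff(unique(tu$patient_id), oc$patient_id)
  if (length(orphan)) {
    stop("tumor rows reference patient(s) absent from outcomes: ",
         paste(orphan, collapse = ", "))
  }
  childless <- setdiff(oc$patient_id, tu$patient_id)
  if (length(childless)) {
    stop("outcome rows for patient(s) with no tumors: ",
         paste(childless, collapse = ", "))
  }
  if (!is.numeric(tu$volume_cc) || anyNA(tu$volume_cc) || any(tu$volume_cc <= 0)) {
    stop("all tumor volumes must be numeric and > 0")
  }
  if (!is.numeric(oc$time_months) || anyNA(oc$time_months) ||
      any(oc$time_months <= 0)) {
    stop("all survival times must be numeric and > 0")
  }
  if (!all(oc$event %in% c(0, 1))) stop("event indicator must be 0/1")
  feats <- cohort_features(x)
  check_schema_coverage(x$schema, feats)
  bad <- feats[!vapply(tu[feats], is.numeric, TRUE)]
  if (length(bad)) {
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(tu[feats])) stop("missing values in tumor feature columns")
  invisible(x)
}

# feature column names of a cohort, in table order
cohort_features <- function(x) {
  setdiff(names(x$tumors), c("patient_id", "tumor_id", "volume_cc"))
}

n_patients <- function(x) nrow(x$outcomes)
n_tumors <- function(x) nrow(x$tumors)

# per-patient tumor counts, in outcomes order
tumor_counts <- function(x) {
  tab <- table(x$tumors$patient_id)
  as.integer(tab[as.character(x$outcomes$patient_id)])
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cnt <- tumor_counts(x)
  cat(sprintf("Multifocal cohort: %d patients, %d tumors (%d features)\n",
              n_patients(x), n_tumors(x), length(cohort_features(x))))
  cat(sprintf("  tumors per patient: median %s, range %d-%d\n",
              format(stats::median(cnt)), min(cnt), max(cnt)))
  cat(sprintf("  events: %d observed, %d censored (%.1f%%)\n",
              sum(x$outcomes$event == 1), sum(x$outcomes$event == 0),
              100 * mean(x$outcomes$event == 0)))
  invisible(x)
}

#' Subset a cohort by patient ids
#'
#' Keeps the given patients (tumor rows and outcome rows); used by the
#' sub-group analyses.
#'
#' @param x a `cohort`.
#' @param patient_ids ids to keep; must all be present.
#' @return A `cohort` restricted to those patients.
#' @export
subset_cohort <- function(x, patient_ids) {
  stopifnot(inherits(x, "cohort"))
  missing <- setdiff(patient_ids, x$outcomes$patient_id)
  if (length(missing)) {
    stop("unknown patient id(s): ", paste(missing, collapse = ", "))
  }
  if (length(patient_ids) == 0L) stop("cannot subset cohort to zero patients")
  cohort(x$tumors[x$tumors$patient_id %in% patient_ids, , drop = FALSE],
         x$outcomes[x$outcomes$patient_id %in% patient_ids, , drop = FALSE],
         x$schema, provenance = x$provenance)
}
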