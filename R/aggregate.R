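#' Patient-level aggregation of per-tumor radiomic features
#'
#' Collapses each patient's set of per-tumor feature vectors into a single
#' patient-level vector. Six methods are supported; all obey the schema
#' rule that *additive* (size/shape) features are **summed** over the
#' included tumors while *intensive* features are **averaged**:
#'
#' * `"unweighted_average"` — additive features summed, intensive features
#'   arithmetically averaged over all tumors.
#' * `"weighted_average"` — intensive features averaged with weights
#'   proportional to each tumor's share of the patient's total volume;
#'   additive features summed.
#' * `"weighted_top_k"` — as `"weighted_average"` but restricted to the
#'   `k` largest tumors by volume (all tumors when a patient has fewer
#'   than `k`); weights renormalize over the included set.
#' * `"largest_plus_count"` — the largest tumor's feature vector plus an
#'   extra `n_metastases` column holding the patient's tumor count.
#' * `"largest_only"` / `"smallest_only"` — the single largest / smallest
#'   tumor's feature vector.
#'
#' "Largest" and "smallest" are defined by volume in cc; volume ties are
#' broken by lexicographic tumor id so results are deterministic. Shuffling
#' tumor rows never changes any output.
#'
#' @param coh a [cohort()].
#' @param method one of the six method names above.
#' @param k tumor-subset size for `"weighted_top_k"` (default 3).
#' @param append_count logical; add the `n_metastases` column. Implied by
#'   `"largest_plus_count"`.
#' @return A `patient_features` object: list with `x` (patients x features
#'   numeric matrix, rownames = patient ids in outcomes order), `method`,
#'   `k`, and `count_col` (name of the count column, or `NULL`).
#' @examples
#' coh <- simulate_cohort(generator_config(n_patients = 20, seed = 1))
#' pf <- aggregate_cohort(coh, "weighted_top_k", k = 3)
#' dim(pf$x)
#' @export
aggregate_cohort <- function(coh,
                             method = c("unweighted_average", "weighted_average",
                                        "weighted_top_k", "largest_plus_count",
                                        "largest_only", "smallest_only"),
                             k = 3L, append_count = NULL) {
  method <- match.arg(method)
  validate_cohort(coh)
  if (is.null(append_count)) append_count <- method == "largest_plus_count"
  switch(method,
    unweighted_average = agg_weighted(coh, method, top_k = NULL,
                                      weighted = FALSE, append_count),
    weighted_average = agg_weighted(coh, method, top_k = NULL,
                                    weighted = TRUE, append_count),
    weighted_top_k = {
      k <- as.integer(k)
      if (is.na(k) || k < 1L) stop("k must be a positive integer")
      agg_weighted(coh, method, top_k = k, weighted = TRUE, append_count)
    },
    largest_plus_count = agg_extreme(coh, method, decreasing = TRUE,
                                     append_count = TRUE),
    largest_only = agg_extreme(coh, method, decreasing = TRUE, append_count),
    smallest_only = agg_extreme(coh, method, decreasing = FALSE, append_count)
  )
}

# order of a patient's tumor rows: by volume, ties by tumor id
tumor_order <- function(vol, tid, decreasing = TRUE) {
  if (decreasing) order(-vol, tid) else order(vol, tid)
}

# shared worker for the averaging-family methods
agg_weighted <- function(coh, method, top_k, weighted, append_count) {
  feats <- cohort_features(coh)
  addv <- coh$schema$class[match(feats, coh$schema$feature)] == "additive"
  pid <- as.character(coh$outcomes$patient_id)
  rows <- split(seq_len(nrow(coh$tumors)),
                as.character(coh$tumors$patient_id))[pid]
  xm <- as.matrix(coh$tumors[feats])
  vol <- coh$tumors$volume_cc
  tid <- as.character(coh$tumors$tumor_id)
  out <- matrix(NA_real_, length(pid), length(feats),
                dimnames = list(pid, feats))
  for (j in seq_along(rows)) {
    idx <- rows[[j]]
    if (!is.null(top_k) && length(idx) > top_k) {
      idx <- idx[tumor_order(vol[idx], tid[idx])[seq_len(top_k)]]
    }
    xs <- xm[idx, , drop = FALSE]
    w <- if (weighted) {
      tv <- sum(vol[idx])
      if (tv <= 0) stop("zero total volume for patient ", pid[j])
      vol[idx] / tv
    } else {
      rep(1 / length(idx), length(idx))
    }
    row <- colSums(xs * w)
    row[addv] <- colSums(xs[, addv, drop = FALSE])
    out[j, ] <- row
  }
  finalize_pfm(out, coh, method, k = top_k, append_count = append_count)
}

agg_extreme <- function(coh, method, decreasing, append_count) {
  feats <- cohort_features(coh)
  pid <- as.character(coh$outcomes$patient_id)
  rows <- split(seq_len(nrow(coh$tumors)),
                as.character(coh$tumors$patient_id))[pid]
  vol <- coh$tumors$volume_cc
  tid <- as.character(coh$tumors$tumor_id)
  pick <- vapply(rows, function(idx) {
    idx[tumor_order(vol[idx], tid[idx], decreasing)[1L]]
  }, integer(1))
  out <- as.matrix(coh$tumors[pick, feats, drop = FALSE])
  dimnames(out) <- list(pid, feats)
  finalize_pfm(out, coh, method, k = NULL, append_count = append_count)
}

finalize_pfm <- function(x, coh, method, k, append_count) {
  count_col <- NULL
  if (isTRUE(append_count)) {
    x <- cbind(x, n_metastases = as.numeric(tumor_counts(coh)))
    count_col <- "n_metastases"
  }
  structure(list(x = x, method = method, k = k, count_col = count_col),
            class = "patient_features")
}

#' @exportS3Method base::print
print.patient_features <- function(x, ...) {
  cat(sprintf("Patient-level feature matrix: %d patients x %d features\n",
              nrow(x$x), ncol(x$x)))
  cat("  method:", x$method,
      if (!is.null(x$k)) sprintf("(k = %d)", x$k) else "", "\n")
  if (!is.null(x$count_col)) cat("  includes metastasis-count column\n")
  invisible(x)
}

# radiomic (non-count) columns of a patient_features matrix
radiomic_cols <- function(pfm) setdiff(colnames(pfm$x), pfm$count_col)
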