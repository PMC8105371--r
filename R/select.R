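# align an outcomes table to the rows of a patient_features matrix
align_outcomes <- function(pfm, outcomes) {
  pid <- rownames(pfm$x)
  m <- match(pid, as.character(outcomes$patient_id))
  if (anyNA(m)) {
    stop("outcomes missing for patient(s): ",
         paste(pid[is.na(m)], collapse = ", "))
  }
  outcomes[m, , drop = FALSE]
}

#' Minimum-redundancy-maximum-relevance feature selection for censored
#' outcomes
#'
#' Greedy forward selection over the radiomic columns of a patient-level
#' feature matrix. The *relevance* of a feature is its censoring-aware
#' discriminative strength, `|C(f) - 0.5|`, where `C(f)` is
#' [concordance_index()] with the feature itself as the risk score; the
#' *redundancy* of a candidate against the selected set is the mean
#' absolute Pearson correlation with its members. Each step adds the
#' candidate maximizing relevance minus redundancy (the difference
#' criterion); the first pick maximizes relevance alone. Deterministic:
#' score ties are broken by column order.
#'
#' Zero-variance columns are excluded with a warning. A metastasis-count
#' column (`pfm$count_col`) never enters the ranking: it is always kept
#' and appended after the selected features.
#'
#' @param pfm a `patient_features` object (see [aggregate_cohort()]).
#' @param outcomes per-patient outcomes (`patient_id`, `time_months`,
#'   `event`).
#' @param n_select number of features to rank; capped at the number
#'   available (with a warning).
#' @return A `feature_selection` object with `method = "mrmr"`, the ranked
#'   `features`, their greedy `scores`, and the per-feature `relevance`.
#' @export
mrmr_select <- function(pfm, outcomes, n_select = 20L) {
  stopifnot(inherits(pfm, "patient_features"))
  n_select <- as.integer(n_select)
  if (is.na(n_select) || n_select < 1L) stop("n_select must be >= 1")
  oc <- align_outcomes(pfm, outcomes)
  x <- pfm$x[, radiomic_cols(pfm), drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- ncol(x)
  if (p == 0L) stop("no usable feature columns")
  if (n_select > p) {
    warning("n_select exceeds available features; selecting all ", p)
    n_select <- p
  }
  rel <- vapply(seq_len(p), function(j) {
    abs(concordance_index(oc$time_months, oc$event, x[, j]) - 0.5)
  }, numeric(1))
  cmat <- abs(stats::cor(x))
  sel <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(n_select)) {
    cand <- setdiff(seq_len(p), sel)
    sc <- rel[cand]
    if (length(sel)) sc <- sc - rowMeans(cmat[cand, sel, drop = FALSE])
    best <- cand[which.max(sc)]  # ties: first in column order
    sel <- c(sel, best)
    scores <- c(scores, max(sc))
  }
  feats <- colnames(x)[sel]
  structure(list(method = "mrmr", features = feats, scores = scores,
                 relevance = stats::setNames(rel, colnames(x)),
                 count_col = pfm$count_col),
            class = "feature_selection")
}

#' Principal-component reduction of a patient-level feature matrix
#'
#' Standardizes the radiomic columns (column z-scores) and keeps the
#' minimal number of leading principal components whose explained-variance
#' ratios sum to at least `retained_variance`. The returned object
#' projects new (standardized with the *training* statistics) data onto
#' those components; a metastasis-count column passes through untouched.
#'
#' @param pfm a `patient_features` object.
#' @param retained_variance target fraction of variance in (0, 1].
#' @return A `feature_selection` object with `method = "pca"`, the
#'   rotation, centering/scaling statistics, explained-variance `ratios`
#'   and the retained component count `n_components`.
#' @export
pca_reduce <- function(pfm, retained_variance = 0.9) {
  stopifnot(inherits(pfm, "patient_features"))
  if (retained_variance <= 0 || retained_variance > 1) {
    stop("retained_variance must lie in (0, 1]")
  }
  x <- pfm$x[, radiomic_cols(pfm), drop = FALSE]
  if (nrow(x) < 2L) stop("need at least 2 patients")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) == 0L) stop("constant matrix: no variance to decompose")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(ratios) >= retained_variance - 1e-12)[1]
  structure(list(method = "pca", n_components = ncomp, ratios = ratios,
                 rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 center = pc$center, scale = pc$scale,
                 count_col = pfm$count_col),
            class = "feature_selection")
}

#' Apply a fitted selection to a patient-level feature matrix
#'
#' @param sel a `feature_selection` from [mrmr_select()], [pca_reduce()]
#'   or [select_features()].
#' @param pfm a `patient_features` object with the same feature columns
#'   the selection was fitted on.
#' @return A `patient_features` object with the reduced columns (the
#'   count column, when present, is re-appended last).
#' @export
apply_selection <- function(sel, pfm) {
  stopifnot(inherits(sel, "feature_selection"), inherits(pfm, "patient_features"))
  x <- pfm$x[, radiomic_cols(pfm), drop = FALSE]
  out <- switch(sel$method,
    none = x,
    mrmr = {
      missing <- setdiff(sel$features, colnames(x))
      if (length(missing)) {
        stop("matrix lacks selected feature(s): ",
             paste(missing, collapse = ", "))
      }
      x[, sel$features, drop = FALSE]
    },
    pca = {
      missing <- setdiff(names(sel$center), colnames(x))
      if (length(missing)) {
        stop("matrix lacks feature(s) the PCA was fitted on: ",
             paste(missing, collapse = ", "))
      }
      z <- scale(x[, names(sel$center), drop = FALSE],
                 center = sel$center, scale = sel$scale)
      z %*% sel$rotation
    },
    stop("unknown selection method: ", sel$method))
  if (!is.null(pfm$count_col)) {
    out <- cbind(out, pfm$x[, pfm$count_col, drop = FALSE])
  }
  structure(list(x = out, method = pfm$method, k = pfm$k,
                 count_col = pfm$count_col),
            class = "patient_features")
}

#' Fit a selection stage by mode name
#'
#' Dispatcher used by the analysis harness: `"mrmr_top20"` ranks the top
#' `n_select` features by [mrmr_select()], `"pca_90"` retains components
#' by [pca_reduce()], `"all_features"` passes everything through.
#'
#' @param pfm a `patient_features` object.
#' @param outcomes per-patient outcomes (used by mRMR only).
#' @param mode `"mrmr_top20"`, `"pca_90"` or `"all_features"`.
#' @param n_select,retained_variance mode parameters.
#' @return A `feature_selection` object.
#' @export
select_features <- function(pfm, outcomes,
                            mode = c("mrmr_top20", "pca_90", "all_features"),
                            n_select = 20L, retained_variance = 0.9) {
  mode <- match.arg(mode)
  switch(mode,
    mrmr_top20 = mrmr_select(pfm, outcomes, n_select),
    pca_90 = pca_reduce(pfm, retained_variance),
    all_features = structure(list(method = "none", count_col = pfm$count_col),
                             class = "feature_selection"))
}

#' @exportS3Method base::print
print.feature_selection <- function(x, ...) {
  switch(x$method,
    mrmr = {
      cat(sprintf("mRMR selection: %d ranked features\n", length(x$features)))
      print(utils::head(data.frame(feature = x$features,
                                   score = round(x$scores, 4)), 10))
    },
    pca = cat(sprintf("PCA reduction: %d components (%.1f%% variance)\n",
                      x$n_components,
                      100 * sum(x$ratios[seq_len(x$n_components)]))),
    none = cat("pass-through selection (all features)\n"))
  invisible(x)
}
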