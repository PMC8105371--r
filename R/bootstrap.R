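pfm_subset <- function(pfm, idx) {
  structure(list(x = pfm$x[idx, , drop = FALSE], method = pfm$method,
                 k = pfm$k, count_col = pfm$count_col),
            class = "patient_features")
}

#' Bootstrapped concordance evaluation of a model on a feature matrix
#'
#' Repeatedly draws `floor(fraction * N)` patients without replacement as
#' a training set, fits the requested model on them (optionally refitting
#' a feature-selection stage on the training split first), scores the
#' held-out patients, and records the held-out [concordance_index()].
#' Reports the mean of the valid replicate C values and their 2.5th/97.5th
#' percentiles as the 95% interval. Replicates whose fit is degenerate
#' (e.g. a collinear Cox design) are recorded as missing; when *every*
#' replicate is degenerate the result carries a flag and no numeric
#' estimate. Deterministic given `seed`.
#'
#' An alternative `mode = "evaluate_only"` fits the model once on all
#' patients and evaluates the concordance on each drawn subsample instead
#' of refitting.
#'
#' @param pfm a `patient_features` object.
#' @param outcomes per-patient outcomes.
#' @param kind model kind passed to [fit_risk_model()].
#' @param n_replicates number of bootstrap replicates.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed; replicate sub-seeds derive from it.
#' @param mode `"refit"` (default) or `"evaluate_only"`.
#' @param selector optional `function(pfm, outcomes)` returning a
#'   `feature_selection`, refitted inside each training split
#'   (split-wise selection; leave `NULL` when selection was already
#'   applied globally).
#' @param ... further arguments to [fit_risk_model()] (grids, `cv_folds`).
#' @return A `benchmark_result` object.
#' @export
bootstrap_evaluate <- function(pfm, outcomes, kind, n_replicates = 100L,
                               fraction = 0.5, seed = 1L,
                               mode = c("refit", "evaluate_only"),
                               selector = NULL, ...) {
  mode <- match.arg(mode)
  pfm <- as_patient_features(pfm)
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  oc <- align_outcomes(pfm, outcomes)
  n <- nrow(pfm$x)
  n_train <- floor(fraction * n)
  if (n_train < 2 || n - n_train < 2) stop("cohort too small for this fraction")

  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  full_fit <- NULL
  if (mode == "evaluate_only") {
    pfm_all <- pfm
    if (!is.null(selector)) {
      sel <- selector(pfm, oc)
      pfm_all <- apply_selection(sel, pfm)
    }
    full_fit <- fit_risk_model(pfm_all, oc, kind, seed = seed, ...)
    if (full_fit$degenerate) {
      return(new_benchmark_result(pfm, kind, rep(NA_real_, n_replicates),
                                  flag = full_fit$flag))
    }
    full_risk <- predict(full_fit, pfm_all)
  }

  cvals <- rep(NA_real_, n_replicates)
  reasons <- character(0)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    tr <- sort(sample.int(n, n_train))
    te <- setdiff(seq_len(n), tr)
    if (mode == "evaluate_only") {
      cvals[r] <- suppressWarnings(
        concordance_index(oc$time_months[tr], oc$event[tr], full_risk[tr]))
      next
    }
    res <- tryCatch({
      pfm_tr <- pfm_subset(pfm, tr)
      pfm_te <- pfm_subset(pfm, te)
      oc_tr <- oc[tr, , drop = FALSE]
      if (!is.null(selector)) {
        sel <- suppressWarnings(selector(pfm_tr, oc_tr))
        pfm_tr <- apply_selection(sel, pfm_tr)
        pfm_te <- apply_selection(sel, pfm_te)
      }
      fit <- fit_risk_model(pfm_tr, oc_tr, kind, seed = rep_seeds[r], ...)
      if (fit$degenerate) {
        list(c = NA_real_, reason = fit$flag)
      } else {
        risks <- predict(fit, pfm_te)
        list(c = suppressWarnings(
          concordance_index(oc$time_months[te], oc$event[te], risks)),
          reason = NULL)
      }
    }, error = function(e) list(c = NA_real_, reason = conditionMessage(e)))
    cvals[r] <- res$c
    if (!is.null(res$reason)) reasons <- c(reasons, res$reason)
  }
  flag <- NULL
  if (all(is.na(cvals))) {
    flag <- if (any(grepl("collinear", reasons))) "collinear" else "degenerate"
  }
  new_benchmark_result(pfm, kind, cvals, flag = flag)
}

new_benchmark_result <- function(pfm, kind, cvals, flag = NULL) {
  valid <- cvals[!is.na(cvals)]
  structure(list(
    method = pfm$method, k = pfm$k, model = kind, replicates = cvals,
    mean_c = if (length(valid)) mean(valid) else NA_real_,
    ci = if (length(valid) >= 2) {
      unname(stats::quantile(valid, c(0.025, 0.975)))
    } else c(NA_real_, NA_real_),
    n_valid = length(valid), flag = flag),
    class = "benchmark_result")
}

#' @exportS3Method base::print
print.benchmark_result <- function(x, ...) {
  lab <- if (!is.null(x$k)) sprintf("%s (k=%d)", x$method, x$k) else x$method
  if (!is.null(x$flag)) {
    cat(sprintf("%s / %s: flagged '%s' (%d valid replicates)\n",
                lab, x$model, x$flag, x$n_valid))
  } else {
    cat(sprintf("%s / %s: C = %.3f (%.3f-%.3f), %d/%d valid replicates\n",
                lab, x$model, x$mean_c, x$ci[1], x$ci[2], x$n_valid,
                length(x$replicates)))
  }
  invisible(x)
}

# one result row for the harness tables
benchmark_row <- function(b, ...) {
  data.frame(..., aggregation = b$method,
             k = if (is.null(b$k)) NA_integer_ else b$k,
             model = b$model,
             mean_c = b$mean_c, ci_low = b$ci[1], ci_high = b$ci[2],
             n_valid_replicates = b$n_valid,
             flag = if (is.null(b$flag)) "" else b$flag,
             stringsAsFactors = FALSE)
}
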