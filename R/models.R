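#' Default hyperparameter grids
#'
#' `default_lambda_grid()`: 20 log-spaced LASSO penalties on
#' `[1e-3, 10]`. `default_rsf_grid()`: all combinations of forest size
#' (200, 500 trees), minimum terminal node size (5, 15) and features per
#' split (`sqrt(p)`, `p/3`, resolved at fit time).
#'
#' @return A numeric vector (lambda grid) or a data frame of forest
#'   hyperparameter combinations.
#' @export
default_lambda_grid <- function() {
  10^seq(log10(1e-3), log10(10), length.out = 20)
}

#' @rdname default_lambda_grid
#' @export
default_rsf_grid <- function() {
  expand.grid(num_trees = c(200L, 500L), min_node_size = c(5L, 15L),
              mtry_rule = c("sqrt", "third"), stringsAsFactors = FALSE)
}

# z-scoring statistics from a training matrix; count column passes raw
scaling_stats <- function(x, count_col) {
  scaled <- setdiff(colnames(x), count_col)
  center <- stats::setNames(rep(0, ncol(x)), colnames(x))
  scale <- stats::setNames(rep(1, ncol(x)), colnames(x))
  center[scaled] <- colMeans(x[, scaled, drop = FALSE])
  sds <- apply(x[, scaled, drop = FALSE], 2, stats::sd)
  scale[scaled] <- ifelse(sds > 0, sds, 1)
  list(center = center, scale = scale)
}

apply_scaling <- function(x, st) {
  sweep(sweep(x, 2, st$center[colnames(x)]), 2, st$scale[colnames(x)], "/")
}

# cross-validation folds; a fold without events is reshuffled once
make_cv_folds <- function(events, k, seed) {
  n <- length(events)
  for (attempt in 0:1) {
    set.seed(seed + attempt)
    folds <- sample(rep_len(seq_len(k), n))
    if (all(vapply(seq_len(k), function(f) sum(events[folds != f]) >= 2 &&
                     sum(events[folds == f]) >= 1, TRUE))) {
      return(list(folds = folds, flagged = FALSE))
    }
  }
  list(folds = folds, flagged = TRUE)
}

# held-out cumulative-hazard risk score from a ranger survival forest
ranger_risk <- function(fit, df) {
  chf <- stats::predict(fit, data = df)$chf
  rowSums(chf)
}

#' Fit a survival risk model on a patient-level feature matrix
#'
#' One fitting front-end for the three model families benchmarked by the
#' pipeline. Radiomic columns are z-scored with training statistics (a
#' metastasis-count column passes through raw); the fitted object stores
#' those statistics and applies them when scoring new data.
#'
#' * `"cox"` — Cox proportional hazards by partial-likelihood
#'   maximization with the Efron tie correction. A rank-deficient design
#'   (collinear or constant columns) raises the `degenerate` flag instead
#'   of fitting, mirroring how collinear sub-group cells are reported
#'   rather than crashed on.
#' * `"cox_lasso"` — L1-penalized Cox over a penalty grid; the penalty is
#'   chosen by mean cross-validated concordance over `cv_folds` folds.
#' * `"rsf"` — random survival forest; forest size, node size and
#'   features-per-split are chosen from `rsf_grid` the same way. Risk
#'   scores are summed cumulative hazards.
#'
#' All randomness (fold assignment, forest bootstrap) is governed by
#' `seed`.
#'
#' @param pfm a `patient_features` object or plain numeric matrix with
#'   patient-id rownames.
#' @param outcomes per-patient outcomes (`patient_id`, `time_months`,
#'   `event`).
#' @param kind `"cox"`, `"cox_lasso"` or `"rsf"`.
#' @param cv_folds folds for hyperparameter tuning.
#' @param lambda_grid penalty grid for `"cox_lasso"`.
#' @param rsf_grid data frame of forest hyperparameters (see
#'   [default_rsf_grid()]).
#' @param seed integer seed.
#' @return A `risk_model` object; inspect with `print()`/`summary()`,
#'   extract coefficients with `coef()`, score new data with `predict()`.
#' @examples
#' coh <- simulate_cohort(generator_config(n_patients = 120, seed = 3))
#' pf <- aggregate_cohort(coh, "weighted_top_k", k = 3)
#' fit <- fit_risk_model(pf, coh$outcomes, "cox")
#' fit
#' @export
fit_risk_model <- function(pfm, outcomes, kind = c("cox", "cox_lasso", "rsf"),
                           cv_folds = 5L,
                           lambda_grid = default_lambda_grid(),
                           rsf_grid = default_rsf_grid(),
                           seed = 1L) {
  kind <- match.arg(kind)
  pfm <- as_patient_features(pfm)
  oc <- align_outcomes(pfm, outcomes)
  if (sum(oc$event) < 2) stop("need at least 2 observed events to fit")
  x <- pfm$x
  st <- scaling_stats(x, pfm$count_col)
  z <- apply_scaling(x, st)

  obj <- structure(list(kind = kind, features = colnames(x),
                        count_col = pfm$count_col, center = st$center,
                        scale = st$scale, degenerate = FALSE, flag = NULL,
                        seed = seed),
                   class = "risk_model")

  if (kind == "cox") {
    if (qr(z)$rank < ncol(z)) {
      obj$degenerate <- TRUE
      obj$flag <- "collinear"
      return(obj)
    }
    df <- data.frame(z, check.names = FALSE)
    df$.time <- oc$time_months
    df$.event <- oc$event
    obj$fit <- survival::coxph(
      survival::Surv(.time, .event) ~ ., data = df, ties = "efron",
      model = FALSE, x = FALSE, y = FALSE)
    return(obj)
  }

  if (kind == "cox_lasso") {
    if (length(lambda_grid) == 0) stop("empty lambda grid")
    if (ncol(z) < 2L) stop("cox_lasso needs at least 2 feature columns")
    lambda_grid <- sort(lambda_grid, decreasing = TRUE)
    y <- survival::Surv(oc$time_months, oc$event)
    cv <- make_cv_folds(oc$event, cv_folds, seed)
    if (cv$flagged) obj$flag <- "cv_fold_without_events"
    cscore <- matrix(NA_real_, cv_folds, length(lambda_grid))
    for (f in seq_len(cv_folds)) {
      tr <- cv$folds != f
      fit_f <- glmnet::glmnet(z[tr, , drop = FALSE], y[tr], family = "cox",
                              lambda = lambda_grid, standardize = FALSE)
      lp <- stats::predict(fit_f, newx = z[!tr, , drop = FALSE],
                           s = lambda_grid, type = "link")
      cscore[f, ] <- suppressWarnings(apply(lp, 2, function(r) {
        concordance_index(oc$time_months[!tr], oc$event[!tr], r)
      }))
    }
    mean_c <- colMeans(cscore, na.rm = TRUE)
    best <- which.max(mean_c)  # ties: largest penalty (grid is decreasing)
    obj$lambda <- lambda_grid[best]
    obj$cv_concordance <- stats::setNames(mean_c, signif(lambda_grid, 4))
    obj$fit <- glmnet::glmnet(z, y, family = "cox", lambda = lambda_grid,
                              standardize = FALSE)
    return(obj)
  }

  # rsf
  if (nrow(rsf_grid) == 0) stop("empty rsf grid")
  p <- ncol(z)
  mtry_of <- function(rule) {
    max(1L, switch(rule, sqrt = floor(sqrt(p)), third = floor(p / 3),
                   as.integer(rule)))
  }
  df <- data.frame(z, check.names = FALSE)
  df$.time <- oc$time_months
  df$.event <- oc$event
  form <- survival::Surv(.time, .event) ~ .
  if (nrow(rsf_grid) > 1L) {
    cv <- make_cv_folds(oc$event, cv_folds, seed)
    if (cv$flagged) obj$flag <- "cv_fold_without_events"
    mean_c <- vapply(seq_len(nrow(rsf_grid)), function(g) {
      cs <- vapply(seq_len(cv_folds), function(f) {
        tr <- cv$folds != f
        fit_f <- ranger::ranger(form, data = df[tr, , drop = FALSE],
                                num.trees = rsf_grid$num_trees[g],
                                min.node.size = rsf_grid$min_node_size[g],
                                mtry = mtry_of(rsf_grid$mtry_rule[g]),
                                seed = seed + f, num.threads = 1)
        r <- ranger_risk(fit_f, df[!tr, , drop = FALSE])
        suppressWarnings(concordance_index(oc$time_months[!tr],
                                           oc$event[!tr], r))
      }, numeric(1))
      mean(cs)
    }, numeric(1))
    best <- which.max(mean_c)
    obj$cv_concordance <- mean_c
  } else {
    best <- 1L
  }
  obj$rsf_params <- rsf_grid[best, , drop = FALSE]
  obj$fit <- ranger::ranger(form, data = df,
                            num.trees = rsf_grid$num_trees[best],
                            min.node.size = rsf_grid$min_node_size[best],
                            mtry = mtry_of(rsf_grid$mtry_rule[best]),
                            seed = seed, num.threads = 1)
  obj
}

# coerce a bare matrix to patient_features
as_patient_features <- function(x) {
  if (inherits(x, "patient_features")) return(x)
  if (is.matrix(x) && !is.null(rownames(x))) {
    return(structure(list(x = x, method = "matrix", k = NULL,
                          count_col = NULL),
                     class = "patient_features"))
  }
  stop("expected a patient_features object or a matrix with patient rownames")
}

#' Predict risk scores from a fitted model
#'
#' Applies the training z-scoring and returns one finite risk score per
#' patient (higher = higher predicted hazard). Feature names must match
#' the training matrix exactly as a set — missing or extra columns are an
#' error, never silently dropped or reordered by position.
#'
#' @param object a `risk_model`.
#' @param newdata a `patient_features` object or numeric matrix.
#' @param ... unused.
#' @return Named numeric vector of risk scores.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  if (object$degenerate) {
    stop("model is degenerate (", object$flag, "); no risk scores available")
  }
  pfm <- as_patient_features(newdata)
  x <- pfm$x
  missing <- setdiff(object$features, colnames(x))
  extra <- setdiff(colnames(x), object$features)
  if (length(missing) || length(extra)) {
    stop("feature-name mismatch with training matrix",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")))
  }
  x <- x[, object$features, drop = FALSE]
  z <- apply_scaling(x, list(center = object$center, scale = object$scale))
  r <- switch(object$kind,
    cox = drop(as.matrix(data.frame(z, check.names = FALSE)) %*%
                 stats::coef(object$fit)),
    cox_lasso = drop(stats::predict(object$fit, newx = z, s = object$lambda,
                                    type = "link")),
    rsf = ranger_risk(object$fit, data.frame(z, check.names = FALSE)))
  stats::setNames(as.numeric(r), rownames(x))
}

#' @export
coef.risk_model <- function(object, ...) {
  if (object$degenerate) return(NULL)
  switch(object$kind,
    cox = stats::coef(object$fit),
    cox_lasso = {
      b <- stats::coef(object$fit, s = object$lambda)
      stats::setNames(as.numeric(b), rownames(b))
    },
    rsf = NULL)
}

#' @exportS3Method base::print
print.risk_model <- function(x, ...) {
  lab <- c(cox = "Cox proportional hazards",
           cox_lasso = "LASSO-penalized Cox",
           rsf = "random survival forest")[x$kind]
  cat("Risk model:", lab, "\n")
  if (x$degenerate) {
    cat("  DEGENERATE:", x$flag, "- not fitted\n")
    return(invisible(x))
  }
  cat(sprintf("  %d features\n", length(x$features)))
  if (x$kind == "cox_lasso") {
    nz <- sum(coef(x) != 0)
    cat(sprintf("  penalty %.4g (CV concordance), %d nonzero coefficients\n",
                x$lambda, nz))
  }
  if (x$kind == "rsf") {
    cat(sprintf("  %d trees, min node %d, mtry rule '%s'\n",
                x$rsf_params$num_trees, x$rsf_params$min_node_size,
                x$rsf_params$mtry_rule))
  }
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Summarize a fitted risk model
#'
#' For a Cox model, returns the coefficient table (estimate, standard
#' error, z, p and the 95% Wald interval); for LASSO-Cox, the nonzero
#' coefficients at the selected penalty; for a forest, its chosen
#' hyperparameters.
#'
#' @param object a `risk_model`.
#' @param ... unused.
#' @return A data frame (or small list for `"rsf"`).
#' @exportS3Method base::summary
summary.risk_model <- function(object, ...) {
  if (object$degenerate) {
    return(list(degenerate = TRUE, flag = object$flag))
  }
  switch(object$kind,
    cox = {
      s <- summary(object$fit)$coefficients
      data.frame(feature = rownames(s), coef = s[, "coef"],
                 se = s[, "se(coef)"], z = s[, "z"],
                 p = s[, "Pr(>|z|)"],
                 ci_low = s[, "coef"] - 1.96 * s[, "se(coef)"],
                 ci_high = s[, "coef"] + 1.96 * s[, "se(coef)"],
                 row.names = NULL)
    },
    cox_lasso = {
      b <- coef(object)
      data.frame(feature = names(b)[b != 0], coef = b[b != 0],
                 row.names = NULL)
    },
    rsf = list(params = object$rsf_params,
               oob_error = object$fit$prediction.error))
}
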