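#' Analysis plan for the aggregation-method comparison
#'
#' Bundles every knob of the benchmarking harness: which aggregation
#' methods and survival models to cross, the feature-selection mode and
#' scope, the bootstrap settings, the sub-group bin edges, hyperparameter
#' grids and the master seed.
#'
#' @param methods aggregation methods to compare (default: all six).
#' @param k tumor-subset size for `"weighted_top_k"`.
#' @param models model kinds to fit (`"cox"`, `"cox_lasso"`, `"rsf"`).
#' @param selection `"mrmr_top20"`, `"pca_90"` or `"all_features"`.
#' @param n_select,retained_variance selection-mode parameters.
#' @param selection_scope `"global"` (fit the selection once on the full
#'   cohort, the literal reading of selecting before bootstrapping) or
#'   `"per_split"` (refit inside every bootstrap training split, the
#'   leakage-free variant).
#' @param n_replicates,fraction bootstrap settings (see
#'   [bootstrap_evaluate()]).
#' @param eval_mode `"refit"` or `"evaluate_only"`.
#' @param count_bins,volume_bins half-open bin edges for the sub-group
#'   analyses: metastasis count `[1,5), [5,11), [11,Inf)` and largest
#'   tumor volume `[0,0.2), [0.2,0.7), [0.7,Inf)` cc.
#' @param cv_folds,lambda_grid,rsf_grid model-tuning settings.
#' @param seed master seed; sub-group runs offset it by bin index.
#' @return An `analysis_plan` object.
#' @export
analysis_plan <- function(methods = c("unweighted_average", "weighted_average",
                                      "weighted_top_k", "largest_plus_count",
                                      "largest_only", "smallest_only"),
                          k = 3L,
                          models = c("cox", "cox_lasso", "rsf"),
                          selection = "mrmr_top20",
                          n_select = 20L, retained_variance = 0.9,
                          selection_scope = c("global", "per_split"),
                          n_replicates = 100L, fraction = 0.5,
                          eval_mode = "refit",
                          count_bins = c(1, 5, 11, Inf),
                          volume_bins = c(0, 0.2, 0.7, Inf),
                          cv_folds = 5L,
                          lambda_grid = default_lambda_grid(),
                          rsf_grid = default_rsf_grid(),
                          seed = 1L) {
  selection_scope <- match.arg(selection_scope)
  known_m <- c("unweighted_average", "weighted_average", "weighted_top_k",
               "largest_plus_count", "largest_only", "smallest_only")
  bad <- setdiff(methods, known_m)
  if (length(bad)) stop("unknown aggregation method(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(models, c("cox", "cox_lasso", "rsf"))
  if (length(bad)) stop("unknown model kind(s): ", paste(bad, collapse = ", "))
  selection <- match.arg(selection, c("mrmr_top20", "pca_90", "all_features"))
  for (b in list(count_bins, volume_bins)) {
    if (length(b) < 2 || is.unsorted(b, strictly = TRUE)) {
      stop("bin edges must be strictly increasing")
    }
  }
  structure(as.list(environment())[c(
    "methods", "k", "models", "selection", "n_select", "retained_variance",
    "selection_scope", "n_replicates", "fraction", "eval_mode",
    "count_bins", "volume_bins", "cv_folds", "lambda_grid", "rsf_grid",
    "seed")], class = "analysis_plan")
}

# aggregate + (global) selection + bootstrap for one (method, model) cell
run_cell <- function(coh, plan, method, model, seed) {
  pfm <- aggregate_cohort(coh, method, k = plan$k)
  selector <- NULL
  tryCatch({
    if (plan$selection_scope == "global") {
      sel <- suppressWarnings(
        select_features(pfm, coh$outcomes, plan$selection,
                        n_select = plan$n_select,
                        retained_variance = plan$retained_variance))
      pfm <- apply_selection(sel, pfm)
    } else {
      selector <- function(p, o) select_features(p, o, plan$selection,
                                                 n_select = plan$n_select,
                                                 retained_variance = plan$retained_variance)
    }
    list(result = bootstrap_evaluate(
      pfm, coh$outcomes, model, n_replicates = plan$n_replicates,
      fraction = plan$fraction, seed = seed, mode = plan$eval_mode,
      selector = selector, cv_folds = plan$cv_folds,
      lambda_grid = plan$lambda_grid, rsf_grid = plan$rsf_grid),
      selection = if (plan$selection_scope == "global") sel else NULL)
  }, error = function(e) {
    list(result = new_benchmark_result(pfm, model, numeric(0),
                                       flag = conditionMessage(e)),
         selection = NULL)
  })
}

#' Run the full aggregation-method x survival-model comparison
#'
#' For every combination of the plan's aggregation methods and model
#' kinds: aggregate the cohort, fit/apply the feature-selection stage,
#' and run [bootstrap_evaluate()]. Every cell uses the same master seed,
#' so all cells see identical bootstrap partitions (paired comparison).
#' Degeneracy anywhere becomes a flagged row, never an error.
#'
#' @param coh a [cohort()].
#' @param plan an [analysis_plan()].
#' @return A `benchmark_table`: data frame with one row per (method,
#'   model) and columns `aggregation`, `k`, `model`, `mean_c`, `ci_low`,
#'   `ci_high`, `n_valid_replicates`, `flag`; the full
#'   `benchmark_result` objects are in `attr(, "results")` and a run log
#'   in `attr(, "log")`.
#' @export
run_comparison <- function(coh, plan = analysis_plan()) {
  validate_cohort(coh)
  rows <- list(); results <- list(); log <- character(0)
  for (model in plan$models) {
    for (method in plan$methods) {
      cell <- run_cell(coh, plan, method, model, seed = plan$seed)
      b <- cell$result
      rows[[length(rows) + 1L]] <- benchmark_row(b)
      results[[paste(method, model, sep = ".")]] <- b
      log <- c(log, sprintf(
        "%s x %s: %s%s", method, model,
        if (is.null(b$flag)) sprintf("C=%.3f", b$mean_c)
        else paste0("flagged [", b$flag, "]"),
        if (!is.null(cell$selection) && cell$selection$method == "pca")
          sprintf(" (pca components=%d)", cell$selection$n_components)
        else ""))
    }
  }
  tbl <- do.call(rbind, rows)
  structure(tbl, results = results, log = log, plan = plan,
            class = c("benchmark_table", "data.frame"))
}

#' @exportS3Method base::print
print.benchmark_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$`C-index (95% CI)` <- ifelse(
    df$flag != "", paste0("* ", df$flag),
    sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
            df$mean_c, df$ci_low, df$ci_high))
  keep <- intersect(c("analysis", "bin", "aggregation", "k", "model",
                      "C-index (95% CI)"), names(df))
  print(df[keep], row.names = FALSE)
  invisible(x)
}

#' @exportS3Method base::summary
summary.benchmark_table <- function(object, ...) {
  df <- as.data.frame(object)
  ok <- df$flag == "" & !is.na(df$mean_c)
  best <- do.call(rbind, lapply(split(df[ok, ], df$model[ok]), function(d) {
    d[which.max(d$mean_c), c("aggregation", "k", "model", "mean_c",
                             "ci_low", "ci_high")]
  }))
  rownames(best) <- NULL
  best
}

#' Boxplot of replicate concordance distributions
#'
#' @param x a `benchmark_table` with stored replicate results.
#' @param model which model kind to plot.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.benchmark_table <- function(x, model = NULL, ...) {
  res <- attr(x, "results")
  if (is.null(model)) model <- as.data.frame(x)$model[1]
  res <- res[vapply(res, function(b) b$model == model, TRUE)]
  reps <- lapply(res, function(b) b$replicates[!is.na(b$replicates)])
  names(reps) <- vapply(res, function(b) b$method, "")
  reps <- reps[vapply(reps, length, 1L) > 0]
  if (!length(reps)) stop("no valid replicates to plot")
  graphics::boxplot(reps, las = 2, ylab = "held-out concordance index",
                    main = paste("model:", model), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

# per-patient bin assignment; half-open [lo, hi) intervals
assign_bins <- function(coh, axis = c("met_count", "largest_volume"),
                        edges) {
  axis <- match.arg(axis)
  val <- if (axis == "met_count") {
    tumor_counts(coh)
  } else {
    vapply(split(coh$tumors$volume_cc, as.character(coh$tumors$patient_id)),
           max, 0)[as.character(coh$outcomes$patient_id)]
  }
  idx <- findInterval(val, edges, rightmost.closed = FALSE)
  if (any(idx == 0 | idx >= length(edges))) {
    stop("bin edges do not cover the observed ", axis, " range")
  }
  labs <- sprintf("[%s,%s)", edges[-length(edges)], edges[-1])
  factor(labs[idx], levels = labs)
}

#' Sub-group analysis across metastasis-count or largest-volume bins
#'
#' Partitions the cohort's patients into the plan's half-open bins on the
#' chosen axis (every patient lands in exactly one bin), then runs
#' [run_comparison()] within each bin — with the Cox model only by
#' default, and the bin's seed offset from the plan's by the bin index so
#' bins are independent but reproducible. Degenerate bins (e.g. a
#' collinear design inside a narrow stratum) yield flagged rows; empty
#' bins yield a flagged placeholder row.
#'
#' @param coh a [cohort()].
#' @param plan an [analysis_plan()].
#' @param axis `"met_count"` or `"largest_volume"`.
#' @param models model kinds to run within bins.
#' @return A `benchmark_table` with extra columns `bin` and `bin_n`.
#' @export
subgroup_analysis <- function(coh, plan = analysis_plan(),
                              axis = c("met_count", "largest_volume"),
                              models = "cox") {
  axis <- match.arg(axis)
  edges <- if (axis == "met_count") plan$count_bins else plan$volume_bins
  bins <- assign_bins(coh, axis, edges)
  out <- list()
  for (i in seq_along(levels(bins))) {
    lab <- levels(bins)[i]
    ids <- coh$outcomes$patient_id[bins == lab]
    if (length(ids) == 0L) {
      out[[lab]] <- data.frame(bin = lab, bin_n = 0L, aggregation = NA,
                               k = NA_integer_, model = NA, mean_c = NA_real_,
                               ci_low = NA_real_, ci_high = NA_real_,
                               n_valid_replicates = 0L, flag = "empty_bin",
                               stringsAsFactors = FALSE)
      next
    }
    sub_plan <- plan
    sub_plan$models <- models
    sub_plan$seed <- plan$seed + i
    tbl <- run_comparison(subset_cohort(coh, ids), sub_plan)
    out[[lab]] <- cbind(bin = lab, bin_n = length(ids), as.data.frame(tbl))
  }
  tbl <- do.call(rbind, out)
  rownames(tbl) <- NULL
  structure(tbl, axis = axis, class = c("benchmark_table", "data.frame"))
}

#' Sensitivity analyses around the main comparison
#'
#' Three planned perturbations of the main analysis:
#' (a) the volume-weighted top-k aggregation with k = 2 and 4 alongside
#' k = 3, across the plan's models; (b) PCA retaining 90% variance in
#' place of mRMR, Cox model, across all aggregation methods; (c) no
#' feature selection at all (`all_features`) for the penalized Cox and
#' forest models. Retained PCA component counts per method are recorded
#' in the run log (`attr(, "log")`).
#'
#' @param coh a [cohort()].
#' @param plan an [analysis_plan()].
#' @return A `benchmark_table` with an `analysis` label column.
#' @export
sensitivity_analysis <- function(coh, plan = analysis_plan()) {
  parts <- list(); logs <- character(0)
  # (a) top-k sweep
  for (kk in c(2L, 3L, 4L)) {
    pk <- plan; pk$methods <- "weighted_top_k"; pk$k <- kk
    tbl <- run_comparison(coh, pk)
    parts[[length(parts) + 1L]] <- cbind(analysis = "topk_sweep",
                                         as.data.frame(tbl))
    logs <- c(logs, attr(tbl, "log"))
  }
  # (b) PCA-90 in place of mRMR, cox only
  pp <- plan; pp$selection <- "pca_90"; pp$models <- "cox"
  tbl <- run_comparison(coh, pp)
  parts[[length(parts) + 1L]] <- cbind(analysis = "pca_90", as.data.frame(tbl))
  logs <- c(logs, attr(tbl, "log"))
  # (c) all features for the regularized / nonparametric models
  pa <- plan; pa$selection <- "all_features"
  pa$models <- intersect(c("cox_lasso", "rsf"), plan$models)
  if (length(pa$models)) {
    tbl <- run_comparison(coh, pa)
    parts[[length(parts) + 1L]] <- cbind(analysis = "all_features",
                                         as.data.frame(tbl))
    logs <- c(logs, attr(tbl, "log"))
  }
  tbl <- do.call(rbind, parts)
  rownames(tbl) <- NULL
  structure(tbl, log = logs, class = c("benchmark_table", "data.frame"))
}
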