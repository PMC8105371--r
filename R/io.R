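# full-precision numeric formatting for text round-trips
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

#' Write / read a cohort as delimited text
#'
#' A cohort is stored as three UTF-8 tab-separated files with header rows
#' and `"."` decimal separator:
#'
#' * `tumors.tsv` — `patient_id`, `tumor_id`, `volume_cc`, one column per
#'   feature;
#' * `outcomes.tsv` — `patient_id`, `time_months`, `event`, plus any
#'   categorical attributes;
#' * `schema.tsv` — `feature`, `class`, optional `family`.
#'
#' Numbers are written with 17 significant digits, so a write/read
#' round-trip reproduces the cohort exactly. `read_cohort()` validates
#' referential integrity and reports malformed numeric fields with their
#' file line numbers.
#'
#' @param coh a [cohort()].
#' @param dir directory to write into (created if needed).
#' @return `write_cohort()`: the three file paths, invisibly.
#'   `read_cohort()`: a validated [cohort()].
#' @export
write_cohort <- function(coh, dir) {
  validate_cohort(coh)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("tumors.tsv", "outcomes.tsv", "schema.tsv"))
  tu <- coh$tumors
  num <- vapply(tu, is.numeric, TRUE)
  tu[num] <- lapply(tu[num], fmt_num)
  utils::write.table(tu, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  oc <- coh$outcomes
  oc$time_months <- fmt_num(oc$time_months)
  utils::write.table(oc, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(as.data.frame(coh$schema), paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

# parse a character column to numeric, reporting 1-based file lines
# (header is line 1) of malformed entries
parse_numeric_col <- function(v, col, file) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) & !(v %in% c("NA", "")))
  if (length(bad)) {
    stop(sprintf("non-numeric value(s) in column '%s' of %s at line(s): %s",
                 col, file, paste(bad + 1L, collapse = ", ")))
  }
  out
}

#' @rdname write_cohort
#' @param tumor_path,outcome_path,schema_path the three file paths;
#'   alternatively pass `dir` to use the standard file names.
#' @export
read_cohort <- function(dir = NULL, tumor_path = NULL, outcome_path = NULL,
                        schema_path = NULL) {
  if (!is.null(dir)) {
    tumor_path <- file.path(dir, "tumors.tsv")
    outcome_path <- file.path(dir, "outcomes.tsv")
    schema_path <- file.path(dir, "schema.tsv")
  }
  for (p in c(tumor_path, outcome_path, schema_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  tu <- utils::read.delim(tumor_path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  oc <- utils::read.delim(outcome_path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  sc <- utils::read.delim(schema_path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  schema <- feature_schema(sc$feature, sc$class, family = sc$family)
  feat_cols <- setdiff(names(tu), c("patient_id", "tumor_id", "volume_cc"))
  check_schema_coverage(schema, feat_cols)
  for (col in c("volume_cc", feat_cols)) {
    tu[[col]] <- parse_numeric_col(tu[[col]], col, basename(tumor_path))
  }
  oc$time_months <- parse_numeric_col(oc$time_months, "time_months",
                                      basename(outcome_path))
  oc$event <- as.integer(parse_numeric_col(oc$event, "event",
                                           basename(outcome_path)))
  cohort(tu, oc, schema,
         provenance = list(tumor_path = tumor_path,
                           outcome_path = outcome_path,
                           schema_path = schema_path))
}

#' Write a benchmark results table as delimited text
#'
#' Serializes a `benchmark_table` (from [run_comparison()],
#' [subgroup_analysis()] or [sensitivity_analysis()]) to a tab-separated
#' file with full numeric precision; flagged rows keep their flag string
#' and empty numeric cells.
#'
#' @param tbl a `benchmark_table` (or plain data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(tbl, path) {
  df <- as.data.frame(tbl)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a generator configuration as a flat key-value file
#'
#' One `key<TAB>value` line per scalar or vector field (vector entries
#' comma-joined); `read_generator_config()` restores the original types
#' and re-validates.
#'
#' @param cfg a [generator_config()].
#' @param path file path.
#' @return `path` (write) or a `generator_config` (read), invisibly for
#'   the writer.
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  flat <- lapply(cfg, function(v) {
    if (is.list(v)) {
      paste(vapply(v, function(b) paste(b, collapse = ":"), ""),
            collapse = ",")
    } else if (is.numeric(v)) {
      paste(fmt_num(v), collapse = ",")
    } else paste(as.character(v), collapse = ",")
  })
  flat <- flat[!vapply(cfg, is.null, TRUE)]
  writeLines(paste(names(flat), unlist(flat), sep = "\t"), path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  num_split <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  chr_split <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  args <- list(
    n_patients = as.integer(vals$n_patients),
    strata_probs = num_split(vals$strata_probs),
    count_geom_p = num_split(vals$count_geom_p),
    count_bounds = lapply(chr_split(vals$count_bounds), function(s) {
      as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    }),
    volume_meanlog = as.numeric(vals$volume_meanlog),
    volume_sdlog = as.numeric(vals$volume_sdlog),
    n_features = as.integer(vals$n_features),
    n_additive = as.integer(vals$n_additive),
    schema_variant = vals$schema_variant,
    informative = chr_split(vals$informative),
    effects = num_split(vals$effects),
    volume_coupling = as.numeric(vals$volume_coupling),
    block_rho = as.numeric(vals$block_rho),
    noise_sd = as.numeric(vals$noise_sd),
    true_aggregation = vals$true_aggregation,
    true_k = as.integer(vals$true_k),
    weibull_shape = as.numeric(vals$weibull_shape),
    median_survival_months = as.numeric(vals$median_survival_months),
    admin_horizon = as.numeric(vals$admin_horizon),
    dropout_horizon = as.numeric(vals$dropout_horizon),
    target_censoring = as.numeric(vals$target_censoring),
    time_resolution = as.numeric(vals$time_resolution),
    seed = as.integer(vals$seed))
  if (!is.null(vals[["weibull_scale"]])) {
    args$weibull_scale <- as.numeric(vals[["weibull_scale"]])
  }
  if (!is.null(vals[["dropout_rate"]])) {
    args$dropout_rate <- as.numeric(vals[["dropout_rate"]])
  }
  do.call(generator_config, args)
}
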