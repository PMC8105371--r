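#' Feature aggregation schema
#'
#' A schema classifies every radiomic feature as *additive* (size/shape
#' features that scale with tumor bulk and are summed across a patient's
#' tumors) or *intensive* (intensity/texture features describing tumor
#' quality, averaged across tumors). Every aggregation rule consults the
#' schema, so the same pipeline can run under different classification
#' conventions.
#'
#' @param feature character vector of feature names (unique, non-empty).
#' @param class character vector, one of `"additive"` or `"intensive"` per
#'   feature.
#' @param family optional character vector of feature-family tags
#'   (e.g. `"size"`, `"shape"`, `"firstorder"`, `"texture"`).
#' @return A `feature_schema` object (a data frame with columns
#'   `feature`, `class` and optionally `family`).
#' @examples
#' feature_schema(c("volume_cc", "entropy"), c("additive", "intensive"))
#' @export
feature_schema <- function(feature, class, family = NULL) {
  feature <- as.character(feature)
  class <- as.character(class)
  if (length(feature) == 0L) stop("schema must contain at least one feature")
  if (anyDuplicated(feature)) {
    stop("duplicate feature names in schema: ",
         paste(unique(feature[duplicated(feature)]), collapse = ", "))
  }
  if (length(class) != length(feature)) {
    stop("'class' must have one entry per feature")
  }
  bad <- setdiff(unique(class), c("additive", "intensive"))
  if (length(bad)) stop("unknown feature class: ", paste(bad, collapse = ", "))
  if (!any(class == "intensive")) {
    stop("schema must contain at least one intensive feature")
  }
  df <- data.frame(feature = feature, class = class,
                   stringsAsFactors = FALSE)
  if (!is.null(family)) {
    stopifnot(length(family) == length(feature))
    df$family <- as.character(family)
  }
  structure(df, class = c("feature_schema", "data.frame"))
}

#' Default schema for synthetic radiomic feature panels
#'
#' Builds the feature panel used by [simulate_cohort()]: four feature
#' families (`size`, `shape`, `firstorder`, `texture`) with names like
#' `size_01`, `texture_05`. Two classification variants are shipped:
#'
#' * `"strict"` — size **and** shape features are additive (summed), all
#'   others intensive; this is the convention the aggregation rules were
#'   designed around.
#' * `"physical"` — only size-like features are additive; dimensionless
#'   shape descriptors (sphericity-like quantities) are treated as
#'   intensive, which is the physically motivated reading.
#'
#' @param n_features total number of features (>= 4).
#' @param n_additive number of features in the additive (size) block under
#'   the `"physical"` variant; under `"strict"` the shape block is additive
#'   too.
#' @param variant `"strict"` or `"physical"`.
#' @return A [feature_schema()].
#' @export
default_feature_schema <- function(n_features = 32L, n_additive = 8L,
                                   variant = c("strict", "physical")) {
  variant <- match.arg(variant)
  n_features <- as.integer(n_features)
  n_additive <- as.integer(n_additive)
  if (n_features < 4L) stop("n_features must be >= 4")
  if (n_additive < 1L || n_additive >= n_features) {
    stop("n_additive must be in [1, n_features)")
  }
  # split the non-size features into shape / firstorder / texture blocks
  n_rest <- n_features - n_additive
  n_shape <- max(1L, n_rest %/% 4L)
  n_first <- max(1L, (n_rest - n_shape) %/% 2L)
  n_text <- n_rest - n_shape - n_first
  fam <- rep(c("size", "shape", "firstorder", "texture"),
             times = c(n_additive, n_shape, n_first, n_text))
  idx <- unlist(lapply(c(size = n_additive, shape = n_shape,
                         firstorder = n_first, texture = n_text),
                       seq_len), use.names = FALSE)
  nm <- sprintf("%s_%02d", fam, idx)
  cls <- ifelse(fam == "size" | (variant == "strict" & fam == "shape"),
                "additive", "intensive")
  feature_schema(nm, cls, family = fam)
}

additive_features <- function(schema) schema$feature[schema$class == "additive"]
intensive_features <- function(schema) schema$feature[schema$class == "intensive"]

# check a schema covers exactly the features of a cohort/table
check_schema_coverage <- function(schema, feature_names) {
  missing <- setdiff(feature_names, schema$feature)
  if (length(missing)) {
    stop("feature(s) absent from schema: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
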