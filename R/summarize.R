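# round half-up to `digits` decimals (table-style percentage rounding,
# where e.g. 0.25 -> 0.3 rather than banker's rounding)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# percentage of total, one decimal, half-up
pct_of_total <- function(count, total) round_half_up(100 * count / total, 1)

#' Demographic-style summary of a cohort
#'
#' Counts and percentages (of total patients, one decimal place) for the
#' metastasis-count strata (<5, 5-10, 11+) and for every categorical
#' patient attribute carried in the outcome table, plus cohort totals:
#' patient and tumor counts, Kaplan-Meier median survival, and the
#' right-censored fraction.
#'
#' @param coh a [cohort()].
#' @return A `cohort_summary`: data frame with columns `section`,
#'   `level`, `count`, `pct`; totals in attributes `n_patients`,
#'   `n_tumors`, `median_survival_months`, `censored_fraction`.
#' @examples
#' coh <- simulate_cohort(generator_config(n_patients = 100, seed = 2))
#' summarize_cohort(coh)
#' @export
summarize_cohort <- function(coh) {
  validate_cohort(coh)
  total <- n_patients(coh)
  cnt <- tumor_counts(coh)
  strata <- cut(cnt, c(1, 5, 11, Inf), right = FALSE,
                labels = c("< 5", "5-10", "11 +"))
  rows <- data.frame(section = "Number of metastases",
                     level = levels(strata),
                     count = as.integer(table(strata)),
                     stringsAsFactors = FALSE)
  # any categorical patient attributes present in the outcome table
  extra <- setdiff(names(coh$outcomes), c("patient_id", "time_months", "event"))
  for (col in extra) {
    v <- coh$outcomes[[col]]
    if (is.character(v) || is.factor(v)) {
      tab <- table(v)
      rows <- rbind(rows, data.frame(section = col, level = names(tab),
                                     count = as.integer(tab),
                                     stringsAsFactors = FALSE))
    }
  }
  rows$pct <- pct_of_total(rows$count, total)
  km <- survival::survfit(
    survival::Surv(time_months, event) ~ 1, data = coh$outcomes)
  med <- unname(summary(km)$table["median"])
  structure(rows, n_patients = total, n_tumors = n_tumors(coh),
            median_survival_months = med,
            censored_fraction = mean(coh$outcomes$event == 0),
            class = c("cohort_summary", "data.frame"))
}

#' @exportS3Method base::print
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Patients: %d   Tumors: %d\n", attr(x, "n_patients"),
              attr(x, "n_tumors")))
  cat(sprintf("Median survival: %s months   Censored: %.1f%%\n",
              format(attr(x, "median_survival_months")),
              100 * attr(x, "censored_fraction")))
  df <- as.data.frame(x)
  df$display <- sprintf("%d (%.1f%%)", df$count, df$pct)
  for (s in unique(df$section)) {
    cat(s, "\n")
    d <- df[df$section == s, ]
    cat(sprintf("  %-12s %s\n", d$level, d$display), sep = "")
  }
  invisible(x)
}
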