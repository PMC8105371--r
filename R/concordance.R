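#' Harrell's concordance index for right-censored survival
#'
#' The probability-like fraction of *comparable* patient pairs whose
#' predicted risk ordering agrees with their observed survival ordering.
#' A pair (i, j) is comparable when `t_i < t_j` and patient i's event was
#' observed (`event_i = 1`); pairs with exactly tied times are not
#' comparable. A comparable pair scores 1 when `risk_i > risk_j`
#' (the earlier death had the higher predicted risk), 0.5 on a risk tie,
#' 0 otherwise. 0.5 is chance level, 1 perfect discrimination.
#'
#' @param times positive survival/censoring times (months).
#' @param events 0/1 event indicators (1 = death observed).
#' @param risks numeric risk scores, higher = worse predicted prognosis.
#' @return The concordance in `[0, 1]`; 0.5 with a warning when no
#'   comparable pair exists.
#' @examples
#' concordance_index(c(2, 4, 5, 7), c(1, 1, 0, 1), c(4, 3, 2, 1))
#' @export
concordance_index <- function(times, events, risks) {
  n <- length(times)
  if (length(events) != n || length(risks) != n) {
    stop("times, events and risks must have equal length")
  }
  if (n < 2L) stop("need at least 2 observations")
  if (!is.numeric(times) || anyNA(times) || any(times <= 0)) {
    stop("times must be positive and non-missing")
  }
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (!is.numeric(risks) || any(!is.finite(risks))) {
    stop("risks must be finite numbers")
  }
  ev <- which(events == 1)
  if (length(ev) == 0L) {
    warning("no comparable pairs; returning 0.5")
    return(0.5)
  }
  conc <- 0
  npairs <- 0
  # row-chunked pair enumeration: pairs (i, j) with event_i = 1, t_i < t_j
  chunk <- max(1L, 2e6 %/% n)
  for (start in seq(1L, length(ev), by = chunk)) {
    ii <- ev[start:min(start + chunk - 1L, length(ev))]
    cmp <- outer(times[ii], times, "<")
    npairs <- npairs + sum(cmp)
    conc <- conc + sum(outer(risks[ii], risks, ">") & cmp) +
      0.5 * sum(outer(risks[ii], risks, "==") & cmp)
  }
  if (npairs == 0) {
    warning("no comparable pairs; returning 0.5")
    return(0.5)
  }
  conc / npairs
}
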