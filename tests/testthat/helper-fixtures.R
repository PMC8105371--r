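# Shared fixtures and independent oracles. Oracles deliberately use naive
# loop-based formulations so they stay independent of the package's
# vectorized implementations.

# hand-built three-patient cohort with known arithmetic
tiny_cohort <- function() {
  schema <- feature_schema(c("size_01", "tex_01"),
                           c("additive", "intensive"))
  tumors <- data.frame(
    patient_id = c("A", "B", "B", "C", "C", "C"),
    tumor_id = c("t1", "t1", "t2", "t1", "t2", "t3"),
    volume_cc = c(2, 3, 1, 1, 1, 1),
    size_01 = c(5, 1, 2, 1, 2, 3),
    tex_01 = c(7, 2, 6, 2, 4, 6),
    stringsAsFactors = FALSE)
  outcomes <- data.frame(patient_id = c("A", "B", "C"),
                         time_months = c(10, 20, 30),
                         event = c(1, 1, 0),
                         stringsAsFactors = FALSE)
  cohort(tumors, outcomes, schema)
}

# random multifocal cohort with arbitrary (non-generator) structure
random_cohort <- function(n_patients, max_tumors = 6, n_features = 4,
                          n_additive = 1, seed = 1) {
  set.seed(seed)
  pid <- sprintf("p%03d", seq_len(n_patients))
  counts <- sample.int(max_tumors, n_patients, replace = TRUE)
  tumors <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    k <- counts[i]
    cbind(data.frame(patient_id = pid[i],
                     tumor_id = sprintf("t%02d", seq_len(k)),
                     volume_cc = stats::rlnorm(k, -1, 1)),
          as.data.frame(matrix(stats::rnorm(k * n_features), k,
                               dimnames = list(NULL, sprintf("f%02d", seq_len(n_features))))))
  }))
  schema <- feature_schema(sprintf("f%02d", seq_len(n_features)),
                           rep(c("additive", "intensive"),
                               c(n_additive, n_features - n_additive)))
  outcomes <- data.frame(patient_id = pid,
                         time_months = round(stats::rexp(n_patients, 1 / 12), 1) + 0.5,
                         event = stats::rbinom(n_patients, 1, 0.7))
  cohort(tumors, outcomes, schema)
}

# O(n^2) pair-enumeration concordance oracle (plain double loop)
oracle_cindex <- function(times, events, risks) {
  num <- 0; den <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (events[i] == 1 && times[i] < times[j]) {
        den <- den + 1
        if (risks[i] > risks[j]) num <- num + 1
        else if (risks[i] == risks[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) return(0.5)
  num / den
}

# brute-force greedy mRMR oracle: relevance |C - 0.5|, redundancy mean
# |pearson|, difference criterion, ties by column order
oracle_mrmr <- function(x, times, events, n_select) {
  p <- ncol(x)
  rel <- numeric(p)
  for (j in seq_len(p)) {
    rel[j] <- abs(oracle_cindex(times, events, x[, j]) - 0.5)
  }
  sel <- integer(0)
  for (step in seq_len(min(n_select, p))) {
    best <- NA; best_sc <- -Inf
    for (j in seq_len(p)) {
      if (j %in% sel) next
      red <- if (length(sel) == 0) 0 else {
        mean(vapply(sel, function(s) abs(stats::cor(x[, j], x[, s])), 0))
      }
      sc <- rel[j] - red
      if (sc > best_sc + 1e-12) { best_sc <- sc; best <- j }
    }
    sel <- c(sel, best)
  }
  colnames(x)[sel]
}

# brute-force top-k volume-weighted aggregation of one patient's tumors:
# sort, truncate, reweight, independently of the package's path
oracle_topk_row <- function(vol, tid, x, additive, k) {
  ord <- order(-vol, tid)
  keep <- ord[seq_len(min(k, length(vol)))]
  w <- vol[keep] / sum(vol[keep])
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    out[j] <- if (additive[j]) sum(x[keep, j]) else sum(w * x[keep, j])
  }
  names(out) <- colnames(x)
  out
}

# small plans for harness tests: trimmed bootstrap and forest settings
fast_plan <- function(..., n_replicates = 8L) {
  analysis_plan(n_replicates = n_replicates, n_select = 8L,
                rsf_grid = data.frame(num_trees = 50L, min_node_size = 15L,
                                      mtry_rule = "sqrt",
                                      stringsAsFactors = FALSE),
                lambda_grid = 10^seq(-3, 1, length.out = 5), ...)
}

# cohort where every patient's smallest tumor carries an identical feature
# vector, making the smallest-only design rank-deficient
collinear_smallest_cohort <- function(n = 60, seed = 61) {
  set.seed(seed)
  pid <- sprintf("p%03d", seq_len(n))
  tumors <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(2:4, 1)
    vol <- sort(stats::rlnorm(k, -1, 0.8))
    vol[1] <- 0.01  # guaranteed smallest
    x <- matrix(stats::rnorm(k * 3), k,
                dimnames = list(NULL, c("f01", "f02", "f03")))
    x[1, ] <- c(1, 2, 3)  # identical smallest-tumor features for everyone
    cbind(data.frame(patient_id = pid[i],
                     tumor_id = sprintf("t%02d", seq_len(k)),
                     volume_cc = vol), as.data.frame(x))
  }))
  schema <- feature_schema(c("f01", "f02", "f03"),
                           c("additive", "intensive", "intensive"))
  outcomes <- data.frame(patient_id = pid,
                         time_months = sample(seq_len(48), n, TRUE) + 0.5,
                         event = stats::rbinom(n, 1, 0.7))
  cohort(tumors, outcomes, schema)
}

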