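pfm_from_matrix <- function(x, count_col = NULL) {
  structure(list(x = x, method = "unweighted_average", k = NULL,
                 count_col = count_col),
            class = "patient_features")
}

outcomes_for <- function(x, times, events) {
  data.frame(patient_id = rownames(x), time_months = times, event = events)
}

test_that("a feature that perfectly orders survival is ranked first", {
  set.seed(1)
  n <- 40
  times <- sample(seq_len(500), n)
  x <- cbind(best = -times + 0, noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(x) <- sprintf("p%02d", seq_len(n))
  sel <- mrmr_select(pfm_from_matrix(x), outcomes_for(x, times, rep(1, n)), 3)
  expect_equal(sel$features[1], "best")
  expect_equal(unname(sel$relevance["best"]), 0.5)
})

test_that("an exact duplicate of a selected feature takes the maximal redundancy penalty", {
  set.seed(2)
  n <- 50
  a <- rnorm(n)
  x <- cbind(a = a, b = a, c = rnorm(n))
  rownames(x) <- sprintf("p%02d", seq_len(n))
  oc <- outcomes_for(x, sample(seq_len(300), n), rbinom(n, 1, 0.8))
  sel <- mrmr_select(pfm_from_matrix(x), oc, 3)
  # the copy scores relevance - 1 once its twin is in: never picked second
  expect_equal(sel$features[1], "a")  # ties with b broken by column order
  expect_equal(sel$features[2], "c")
  expect_equal(sel$scores[3], unname(sel$relevance["b"]) - mean(c(1, abs(cor(a, x[, "c"])))),
               tolerance = 1e-12)
})

test_that("greedy ranking equals the brute-force oracle on random matrices", {
  set.seed(3)
  for (i in 1:12) {
    n <- sample(30:100, 1); p <- sample(4:10, 1)
    x <- matrix(rnorm(n * p), n, dimnames = list(sprintf("p%03d", 1:n),
                                                 sprintf("v%02d", 1:p)))
    # induce some collinearity so redundancy matters
    x[, 2] <- x[, 1] + 0.3 * x[, 2]
    times <- sample(seq_len(40), n, replace = TRUE)
    events <- rbinom(n, 1, 0.7)
    n_sel <- sample(2:p, 1)
    got <- mrmr_select(pfm_from_matrix(x), outcomes_for(x, times, events),
                       n_sel)
    expect_identical(got$features, oracle_mrmr(x, times, events, n_sel))
  }
})

test_that("mRMR is deterministic and invariant to affine feature rescaling", {
  set.seed(4)
  n <- 60
  x <- matrix(rnorm(n * 5), n, dimnames = list(sprintf("p%03d", 1:n),
                                               sprintf("v%02d", 1:5)))
  oc <- outcomes_for(x, sample(seq_len(200), n), rbinom(n, 1, 0.7))
  s1 <- mrmr_select(pfm_from_matrix(x), oc, 4)
  s2 <- mrmr_select(pfm_from_matrix(x), oc, 4)
  expect_identical(s1$features, s2$features)
  xs <- x
  xs[, 3] <- 100 * xs[, 3] - 7  # positive affine map
  s3 <- mrmr_select(pfm_from_matrix(xs), oc, 4)
  expect_identical(s1$features, s3$features)
  expect_equal(s1$scores, s3$scores, tolerance = 1e-12)
})

test_that("the metastasis-count column bypasses ranking but is always kept", {
  set.seed(5)
  n <- 40
  x <- cbind(matrix(rnorm(n * 4), n,
                    dimnames = list(sprintf("p%02d", 1:n),
                                    sprintf("v%02d", 1:4))),
             n_metastases = sample(1:9, n, TRUE))
  pfm <- pfm_from_matrix(x, count_col = "n_metastases")
  oc <- outcomes_for(x, sample(seq_len(200), n), rbinom(n, 1, 0.7))
  sel <- mrmr_select(pfm, oc, 3)
  expect_false("n_metastases" %in% sel$features)
  red <- apply_selection(sel, pfm)
  expect_equal(colnames(red$x), c(sel$features, "n_metastases"))
  expect_equal(red$x[, "n_metastases"], x[, "n_metastases"])
})

test_that("zero-variance columns are excluded with a warning and n_select is capped", {
  set.seed(6)
  n <- 30
  x <- cbind(const = rep(2, n),
             matrix(rnorm(n * 3), n, dimnames = list(NULL, sprintf("v%02d", 1:3))))
  rownames(x) <- sprintf("p%02d", 1:n)
  oc <- outcomes_for(x, sample(seq_len(100), n), rbinom(n, 1, 0.8))
  expect_warning(mrmr_select(pfm_from_matrix(x), oc, 10), "zero-variance")
  sel <- suppressWarnings(mrmr_select(pfm_from_matrix(x), oc, 10))
  expect_identical(sort(sel$features), sort(c("v01", "v02", "v03")))
})

test_that("PCA reduction retains the minimal component count for the target variance", {
  set.seed(7)
  n <- 50
  # rank-1 structure: one latent direction
  u <- rnorm(n)
  x1 <- cbind(a = 2 * u, b = -u, c = 0.5 * u)
  rownames(x1) <- sprintf("p%02d", 1:n)
  sel1 <- pca_reduce(pfm_from_matrix(x1), 0.9)
  expect_equal(sel1$n_components, 1L)

  # full-rank noise: retaining all variance needs the full rank
  x2 <- matrix(rnorm(n * 4), n, dimnames = list(sprintf("p%02d", 1:n),
                                                sprintf("v%02d", 1:4)))
  sel2 <- pca_reduce(pfm_from_matrix(x2), 1.0)
  expect_equal(sel2$n_components, qr(scale(x2))$rank)

  # explained-variance ratios are non-increasing and reach the threshold
  sel3 <- pca_reduce(pfm_from_matrix(x2), 0.7)
  expect_true(all(diff(sel3$ratios) <= 1e-12))
  expect_gte(sum(sel3$ratios[seq_len(sel3$n_components)]), 0.7 - 1e-9)
})

test_that("PCA component count matches an independent eigen-decomposition", {
  set.seed(8)
  n <- 2000
  # three features with specified correlation structure
  sigma <- matrix(c(1, 0.8, 0.1,
                    0.8, 1, 0.1,
                    0.1, 0.1, 1), 3, 3)
  l <- chol(sigma)
  x <- matrix(rnorm(n * 3), n) %*% l
  colnames(x) <- c("a", "b", "c")
  rownames(x) <- sprintf("p%04d", 1:n)
  ev <- eigen(stats::cor(x), symmetric = TRUE)$values
  oracle_count <- function(th) which(cumsum(ev) / sum(ev) >= th - 1e-12)[1]
  for (th in c(0.5, 0.9, 0.99)) {
    expect_equal(pca_reduce(pfm_from_matrix(x), th)$n_components,
                 oracle_count(th), info = th)
  }
})

test_that("reconstruction error shrinks as the variance threshold rises", {
  set.seed(9)
  n <- 80
  x <- matrix(rnorm(n * 6), n, dimnames = list(sprintf("p%02d", 1:n),
                                               sprintf("v%02d", 1:6)))
  x[, 2] <- x[, 1] + 0.2 * x[, 2]
  x[, 4] <- x[, 3] - 0.5 * x[, 4]
  z <- scale(x)
  recon_err <- vapply(c(0.5, 0.8, 0.95, 1.0), function(th) {
    sel <- pca_reduce(pfm_from_matrix(x), th)
    proj <- z %*% sel$rotation
    sum((z - proj %*% t(sel$rotation))^2)
  }, numeric(1))
  expect_true(all(diff(recon_err) <= 1e-8))
})

test_that("selection dispatcher covers the three modes", {
  coh <- random_cohort(50, seed = 10)
  pfm <- aggregate_cohort(coh, "unweighted_average")
  m <- select_features(pfm, coh$outcomes, "mrmr_top20", n_select = 3)
  expect_equal(length(m$features), 3)
  p <- select_features(pfm, coh$outcomes, "pca_90")
  expect_true(p$n_components >= 1)
  a <- select_features(pfm, coh$outcomes, "all_features")
  expect_identical(apply_selection(a, pfm)$x, pfm$x)
})
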