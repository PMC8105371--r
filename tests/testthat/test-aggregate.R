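test_that("aggregation arithmetic matches hand-computed values", {
  coh <- tiny_cohort()
  un <- aggregate_cohort(coh, "unweighted_average")
  # patient C: additive 1+2+3 = 6, intensive mean(2,4,6) = 4
  expect_equal(un$x["C", "size_01"], 6)
  expect_equal(un$x["C", "tex_01"], 4)
  # patient B, volumes 3 and 1, intensive values 2 and 6: (3*2+1*6)/4 = 3
  wt <- aggregate_cohort(coh, "weighted_average")
  expect_equal(wt$x["B", "tex_01"], 3)
  # additive features are summed regardless of weighting
  expect_equal(wt$x["B", "size_01"], 3)
})

test_that("single-tumor patients reproduce their tumor's feature vector", {
  coh <- tiny_cohort()
  for (m in c("unweighted_average", "weighted_average", "weighted_top_k",
              "largest_only", "smallest_only")) {
    pfm <- aggregate_cohort(coh, m)
    expect_equal(unname(pfm$x["A", c("size_01", "tex_01")]), c(5, 7),
                 info = m)
  }
})

test_that("equal volumes make the weighted average collapse to the unweighted", {
  coh <- tiny_cohort()  # patient C has three equal-volume tumors
  un <- aggregate_cohort(coh, "unweighted_average")
  wt <- aggregate_cohort(coh, "weighted_average")
  expect_equal(wt$x["C", ], un$x["C", ])
})

test_that("top-k aggregation agrees with a brute-force sort-truncate-reweight oracle", {
  coh <- random_cohort(60, max_tumors = 7, n_features = 5, n_additive = 2,
                       seed = 11)
  feats <- c("f01", "f02", "f03", "f04", "f05")
  additive <- coh$schema$class[match(feats, coh$schema$feature)] == "additive"
  for (k in c(1, 3, 4)) {
    pfm <- aggregate_cohort(coh, "weighted_top_k", k = k)
    for (pid in coh$outcomes$patient_id) {
      rows <- coh$tumors[coh$tumors$patient_id == pid, ]
      expected <- oracle_topk_row(rows$volume_cc, rows$tumor_id,
                                  as.matrix(rows[feats]), additive, k)
      expect_equal(pfm$x[pid, ], expected, tolerance = 1e-12)
    }
  }
})

test_that("aggregation is invariant to tumor row order", {
  coh <- random_cohort(40, seed = 12)
  set.seed(99)
  shuf <- coh
  shuf$tumors <- coh$tumors[sample(nrow(coh$tumors)), ]
  for (m in c("unweighted_average", "weighted_average", "weighted_top_k",
              "largest_plus_count", "largest_only", "smallest_only")) {
    expect_identical(aggregate_cohort(coh, m)$x, aggregate_cohort(shuf, m)$x,
                     info = m)
  }
})

test_that("intensive aggregates stay inside the component tumors' range", {
  coh <- random_cohort(50, seed = 13)
  intens <- c("f02", "f03", "f04")  # random_cohort: f01 additive, rest intensive
  for (m in c("unweighted_average", "weighted_average", "weighted_top_k")) {
    pfm <- aggregate_cohort(coh, m, k = 3)
    for (pid in coh$outcomes$patient_id) {
      rows <- coh$tumors[coh$tumors$patient_id == pid, ]
      for (f in intens) {
        expect_gte(pfm$x[pid, f], min(rows[[f]]) - 1e-12)
        expect_lte(pfm$x[pid, f], max(rows[[f]]) + 1e-12)
      }
    }
  }
})

test_that("k at or above the maximum tumor count equals the full weighted average", {
  coh <- random_cohort(40, max_tumors = 5, seed = 14)
  expect_equal(aggregate_cohort(coh, "weighted_top_k", k = 5)$x,
               aggregate_cohort(coh, "weighted_average")$x)
  expect_equal(aggregate_cohort(coh, "weighted_top_k", k = 12)$x,
               aggregate_cohort(coh, "weighted_average")$x)
})

test_that("inflating a tumor's volume pulls the weighted aggregate toward it", {
  coh <- tiny_cohort()
  before <- aggregate_cohort(coh, "weighted_average")$x["B", "tex_01"]
  coh$tumors$volume_cc[coh$tumors$patient_id == "B" &
                         coh$tumors$tumor_id == "t2"] <- 50
  after <- aggregate_cohort(coh, "weighted_average")$x["B", "tex_01"]
  # tumor t2 has tex_01 = 6; moving weight onto it moves the mean toward 6
  expect_gt(after, before)
  expect_lt(abs(after - 6), abs(before - 6))
})

test_that("additive sums ignore volumes entirely", {
  coh <- random_cohort(30, seed = 15)
  a1 <- aggregate_cohort(coh, "weighted_average")$x[, "f01"]
  coh$tumors$volume_cc <- rev(coh$tumors$volume_cc)
  # n.b. reversal permutes volumes across all tumors; f01 is additive
  a2 <- aggregate_cohort(coh, "unweighted_average")$x[, "f01"]
  expect_equal(a1, a2)
})

test_that("extreme-tumor selection honors ties, counts, and degenerate cases", {
  coh <- tiny_cohort()
  lg <- aggregate_cohort(coh, "largest_only")
  sm <- aggregate_cohort(coh, "smallest_only")
  # patient B: largest is t1 (vol 3), smallest t2 (vol 1)
  expect_equal(unname(lg$x["B", ]), c(1, 2))
  expect_equal(unname(sm$x["B", ]), c(2, 6))
  # patient C: all volumes tie at 1; lexicographic tumor id breaks the tie
  expect_equal(unname(lg$x["C", ]), c(1, 2))
  expect_equal(unname(sm$x["C", ]), c(1, 2))
  # count column
  lpc <- aggregate_cohort(coh, "largest_plus_count")
  expect_equal(unname(lpc$x[, "n_metastases"]), c(1, 2, 3))
  # a patient with 7 tumors reports count 7
  coh7 <- random_cohort(10, max_tumors = 1, seed = 16)
  extra <- coh7$tumors[rep(1, 6), ]
  extra$tumor_id <- sprintf("x%d", 1:6)
  coh7$tumors <- rbind(coh7$tumors, extra)
  coh7 <- cohort(coh7$tumors, coh7$outcomes, coh7$schema)
  lpc7 <- aggregate_cohort(coh7, "largest_plus_count")
  expect_equal(unname(lpc7$x[1, "n_metastases"]), 7)
})

test_that("unifocal cohorts collapse all methods to the same matrix", {
  coh <- random_cohort(30, max_tumors = 1, seed = 17)
  ms <- c("unweighted_average", "weighted_average", "weighted_top_k",
          "largest_only", "smallest_only")
  mats <- lapply(ms, function(m) aggregate_cohort(coh, m)$x)
  for (i in 2:length(mats)) expect_equal(mats[[i]], mats[[1]])
  lpc <- aggregate_cohort(coh, "largest_plus_count")
  expect_equal(lpc$x[, colnames(mats[[1]])], mats[[1]])
  expect_true(all(lpc$x[, "n_metastases"] == 1))
})

test_that("schema gaps and invalid inputs fail fast", {
  coh <- tiny_cohort()
  coh$tumors$extra_feat <- 1
  expect_error(aggregate_cohort(coh, "unweighted_average"), "extra_feat")
  expect_error(aggregate_cohort(tiny_cohort(), "weighted_top_k", k = 0),
               "positive")
})
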