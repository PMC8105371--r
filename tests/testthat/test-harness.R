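test_that("the full comparison emits one row per method-model cell", {
  coh <- simulate_cohort(generator_config(n_patients = 120, seed = 62))
  plan <- fast_plan(seed = 3)
  tbl <- run_comparison(coh, plan)
  expect_s3_class(tbl, "benchmark_table")
  expect_equal(nrow(tbl), 6 * 3)
  expect_equal(sort(unique(tbl$model)), c("cox", "cox_lasso", "rsf"))
  expect_true(all(table(tbl$aggregation) == 3))
  ok <- tbl$flag == ""
  expect_true(all(tbl$mean_c[ok] > 0 & tbl$mean_c[ok] < 1))
  # flagged rows never carry numeric C values
  expect_true(all(is.na(tbl$mean_c[!ok])))
})

test_that("unifocal cohorts give identical scores across single-tumor methods", {
  coh <- random_cohort(100, max_tumors = 1, seed = 63)
  plan <- fast_plan(models = "cox", selection = "all_features", seed = 4)
  tbl <- run_comparison(coh, plan)
  eq <- tbl$mean_c[tbl$aggregation != "largest_plus_count"]
  expect_true(all(abs(eq - eq[1]) < 1e-12))
})

test_that("sub-group bins partition the cohort and scale like the strata law", {
  coh <- simulate_cohort(generator_config(seed = 64))  # default 831 patients
  bins <- radagg:::assign_bins(coh, "met_count", c(1, 5, 11, Inf))
  expect_equal(length(bins), 831)
  expect_false(anyNA(bins))           # every patient in exactly one bin
  shares <- as.numeric(table(bins)) / 831
  # cohort-scale binomial noise around 65.3 / 25.8 / 8.9 percent
  expect_true(all(abs(shares - c(0.653, 0.258, 0.089)) < 0.04))
  vb <- radagg:::assign_bins(coh, "largest_volume", c(0, 0.2, 0.7, Inf))
  expect_false(anyNA(vb))
  expect_equal(sum(table(vb)), 831)
  expect_true(all(table(vb) > 100))   # all three volume bins well populated
})

test_that("sub-group analysis runs per bin with offset seeds and flags empty bins", {
  coh <- simulate_cohort(generator_config(n_patients = 150, seed = 65))
  plan <- fast_plan(models = "cox", seed = 10)
  tbl <- subgroup_analysis(coh, plan, axis = "met_count")
  expect_true(all(c("bin", "bin_n") %in% names(tbl)))
  expect_equal(sum(unique(tbl[, c("bin", "bin_n")])$bin_n), 150)
  # a cohort confined to the first stratum leaves the upper bins empty
  coh1 <- simulate_cohort(generator_config(n_patients = 60,
                                           strata_probs = c(1, 0, 0),
                                           seed = 66))
  tbl1 <- subgroup_analysis(coh1, fast_plan(models = "cox", seed = 11),
                            axis = "met_count")
  empty <- tbl1[tbl1$flag == "empty_bin", ]
  expect_equal(nrow(empty), 2)
  expect_true(all(is.na(empty$mean_c)))
})

test_that("rank-deficient smallest-tumor designs are flagged collinear, never scored", {
  coh <- collinear_smallest_cohort()
  plan <- fast_plan(models = "cox", selection = "all_features", seed = 12)
  tbl <- run_comparison(coh, plan)
  row <- tbl[tbl$aggregation == "smallest_only", ]
  expect_equal(row$flag, "collinear")
  expect_true(is.na(row$mean_c))
  expect_true(all(tbl$flag[tbl$aggregation == "largest_only"] == ""))
})

test_that("sensitivity analysis expands k, swaps in PCA, and drops selection", {
  coh <- simulate_cohort(generator_config(n_patients = 120, seed = 67))
  plan <- fast_plan(models = c("cox", "cox_lasso"), seed = 13)
  tbl <- sensitivity_analysis(coh, plan)
  ks <- sort(unique(tbl$k[tbl$analysis == "topk_sweep"]))
  expect_equal(ks, c(2L, 3L, 4L))
  expect_true(all(c("topk_sweep", "pca_90", "all_features") %in% tbl$analysis))
  # PCA runs record their retained component counts in the log
  expect_true(any(grepl("pca components=", attr(tbl, "log"))))
  # the all-features part uses only the regularized models
  expect_equal(sort(unique(tbl$model[tbl$analysis == "all_features"])),
               "cox_lasso")
})

test_that("k above every tumor count collapses the top-k sweep rows", {
  coh <- random_cohort(80, max_tumors = 2, seed = 68)
  plan <- fast_plan(models = "cox", selection = "all_features", seed = 14)
  tbl <- sensitivity_analysis(coh, plan)
  sweep_rows <- tbl[tbl$analysis == "topk_sweep", ]
  expect_equal(length(unique(sweep_rows$mean_c)), 1L)
})

test_that("cohort summary reproduces count-and-percentage bookkeeping", {
  coh <- random_cohort(40, seed = 69)
  coh$outcomes$primary <- rep(c("NSCLC", "Melanoma"), c(25, 15))
  s <- summarize_cohort(coh)
  expect_equal(attr(s, "n_patients"), 40)
  prim <- s[s$section == "primary", ]
  expect_equal(prim$pct[prim$level == "NSCLC"], 62.5)
  # percentages per categorical axis sum to 100 within rounding slack
  for (sec in unique(s$section)) {
    expect_lt(abs(sum(s$pct[s$section == sec]) - 100), 0.2)
  }
  # single-stratum cohort reports 100.0
  coh1 <- random_cohort(25, max_tumors = 1, seed = 70)
  s1 <- summarize_cohort(coh1)
  expect_equal(s1$pct[s1$level == "< 5"], 100.0)
  expect_equal(attr(s1, "censored_fraction"),
               mean(coh1$outcomes$event == 0))
})

test_that("cohorts round-trip through delimited text exactly", {
  coh <- simulate_cohort(generator_config(n_patients = 25, seed = 71))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$tumors, coh$tumors)
  expect_equal(back$outcomes, coh$outcomes)
  expect_equal(as.data.frame(back$schema), as.data.frame(coh$schema))
})

test_that("malformed cohort files are reported with names and line numbers", {
  coh <- random_cohort(10, seed = 72)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  # tumor row referencing an unknown patient
  tu <- readLines(file.path(dir, "tumors.tsv"))
  extra <- sub("^p001", "p999", tu[2])
  writeLines(c(tu, extra), file.path(dir, "tumors.tsv"))
  expect_error(read_cohort(dir), "p999")
  writeLines(tu, file.path(dir, "tumors.tsv"))
  # feature column missing from the schema
  sc <- readLines(file.path(dir, "schema.tsv"))
  writeLines(sc[-2], file.path(dir, "schema.tsv"))
  err <- tryCatch(read_cohort(dir), error = conditionMessage)
  expect_match(err, "f01")
  writeLines(sc, file.path(dir, "schema.tsv"))
  # non-numeric volume with its line number
  tu2 <- tu
  tu2[4] <- sub("^(p[0-9]+\tt[0-9]+\t)[0-9.eE+-]+", "\\1oops", tu2[4])
  writeLines(tu2, file.path(dir, "tumors.tsv"))
  err <- tryCatch(read_cohort(dir), error = conditionMessage)
  expect_match(err, "volume_cc")
  expect_match(err, "line\\(s\\): 4")
})

test_that("generator configs round-trip through the flat key-value format", {
  cfg <- generator_config(n_patients = 77, volume_coupling = 0.2, seed = 99)
  path <- withr::local_tempfile()
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  for (f in c("n_patients", "strata_probs", "volume_meanlog", "effects",
              "informative", "true_aggregation", "seed", "count_bounds")) {
    expect_equal(back[[f]], cfg[[f]], info = f)
  }
  expect_identical(simulate_cohort(back)$outcomes,
                   simulate_cohort(cfg)$outcomes)
})

test_that("results tables serialize with flags preserved", {
  coh <- collinear_smallest_cohort(40, seed = 73)
  plan <- fast_plan(models = "cox", selection = "all_features",
                    n_replicates = 4L, seed = 15)
  tbl <- run_comparison(coh, plan)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(tbl, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(tbl))
  expect_true("collinear" %in% back$flag)
})
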