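# Synthetic cohort generation, cleaning filters, partitioning, splitting.

test_that("ci_to_moments inverts the normal-theory CI of the mean", {
  # forward identity: mean +/- 1.959964 * sd / sqrt(n) recovers the interval
  m <- ci_to_moments(77.6, 80.0, 220)
  expect_equal(m$mean, 78.8)
  half <- 1.959964 * m$sd / sqrt(220)
  expect_equal(c(m$mean - half, m$mean + half), c(77.6, 80.0), tolerance = 1e-12)

  # closed-form case: half-width 1.959964 at n = 100 gives sd exactly 10
  m2 <- ci_to_moments(0, 3.919928, 100)
  expect_equal(m2$mean, 1.959964)
  expect_equal(m2$sd, 10, tolerance = 1e-12)

  # degenerate interval
  m3 <- ci_to_moments(5, 5, 100)
  expect_equal(m3, list(mean = 5, sd = 0))

  expect_error(ci_to_moments(2, 1, 10), "reversed")
})

test_that("default cohort reproduces the published structure", {
  cohort <- generate_cohort(cohort_config(), seed = 11)
  expect_equal(nrow(cohort), 408)
  expect_equal(sum(cohort$label == 0), 220)
  expect_equal(sum(cohort$label == 1), 188)
  expect_equal(sum(cohort$sex == "male"), 345)
  expect_equal(sum(cohort$sex == "female"), 63)
  # exact per-group sex counts, not Bernoulli draws
  expect_equal(sum(cohort$sex == "male" & cohort$label == 0), 188)
  expect_equal(sum(cohort$sex == "male" & cohort$label == 1), 157)
  expect_equal(length(fedcopd:::feature_columns(cohort)), 40)
  expect_false(anyNA(cohort[fedcopd:::feature_columns(cohort)]))
})

test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_mild = 30, n_severe = 20, missing_rate = 0.05)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a, c))
})

test_that("continuous features respect truncation bounds and group moments", {
  cohort <- generate_cohort(cohort_config(n_mild = 5000, n_severe = 5000),
                            seed = 3)
  age <- cohort$f001 # first named continuous spec is age
  expect_true(all(age >= 18 & age <= 110))
  mild_age <- age[cohort$label == 0]
  m <- ci_to_moments(77.6, 80.0, 220)
  expect_equal(mean(mild_age), m$mean, tolerance = 4 * m$sd / sqrt(5000) / m$mean)
})

test_that("feature filter drops > threshold, then incomplete records drop", {
  cohort <- toy_cohort(n = 10)
  # feature f001 missing in 2/10 cells -> dropped, all records kept
  c1 <- cohort
  c1$f001[1:2] <- NA
  out1 <- suppressMessages(preprocess_cohort(c1, 0.10))
  expect_false("f001" %in% names(out1))
  expect_equal(nrow(out1), 10)
  log1 <- attr(out1, "preprocess_log")
  expect_equal(log1$dropped_features, "f001")
  expect_equal(log1$n_records_dropped, 0)

  # exactly 10% missing survives the (strict) feature filter; the record goes
  c2 <- cohort
  c2$f001[1] <- NA
  out2 <- suppressMessages(preprocess_cohort(c2, 0.10))
  expect_true("f001" %in% names(out2))
  expect_equal(nrow(out2), 9)

  # no missingness -> identity, and preprocess is idempotent
  out3 <- suppressMessages(preprocess_cohort(cohort))
  expect_equal(as.data.frame(out3), as.data.frame(cohort), ignore_attr = TRUE)
  twice <- suppressMessages(preprocess_cohort(out2))
  expect_equal(as.data.frame(twice), as.data.frame(out2), ignore_attr = TRUE)
})

test_that("preprocess errors name the stage that emptied the cohort", {
  cohort <- toy_cohort(n = 4, n_features = 2)
  allna <- cohort
  allna$f001 <- NA_real_
  allna$f002 <- NA_real_
  expect_error(suppressMessages(preprocess_cohort(allna, 0.10)), "stage 1")
  rowna <- cohort
  rowna$f001[1:2] <- NA
  rowna$f002[3:4] <- NA
  expect_error(suppressMessages(preprocess_cohort(rowna, 0.6)), "stage 2")
})

test_that("partition draws disjoint shards by simple random sampling", {
  cohort <- generate_cohort(cohort_config(), seed = 2)
  shards <- partition_cohort(cohort, k = 3, samples_per_client = 136, seed = 9)
  expect_length(shards, 3)
  expect_true(all(vapply(shards, nrow, integer(1)) == 136))
  ids <- lapply(shards, `[[`, "record_id")
  # pairwise disjoint, union a subset of the cohort, no duplicates
  for (s in 1:50) {
    sh <- partition_cohort(cohort, 3, 100, seed = s)
    all_ids <- unlist(lapply(sh, `[[`, "record_id"))
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_true(all(all_ids %in% cohort$record_id))
  }
  expect_error(partition_cohort(cohort, 3, 200, seed = 1), "requested")
  # k = 1 is a plain subsample
  one <- partition_cohort(cohort, 1, 50, seed = 4)
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]), 50)
})

test_that("train/test split honors the ratio with floor rounding", {
  cohort <- generate_cohort(cohort_config(), seed = 2)
  shard <- partition_cohort(cohort, 3, 136, seed = 9)[[1]]
  sp <- split_cohort(shard, c(7, 3), seed = 1)
  expect_equal(nrow(sp$train), 95) # floor(0.7 * 136)
  expect_equal(nrow(sp$test), 41)
  expect_length(intersect(sp$train$record_id, sp$test$record_id), 0)
  expect_setequal(c(sp$train$record_id, sp$test$record_id), shard$record_id)

  small <- toy_cohort(n = 10)
  expect_equal(nrow(split_cohort(small, c(5, 5), seed = 1)$train), 5)
  expect_equal(nrow(split_cohort(small, c(9, 1), seed = 1)$train), 9)
  expect_error(split_cohort(small[1, ], c(7, 3), seed = 1), "at least 2")
})

test_that("cohort CSV round-trips with empty fields for missing cells", {
  cfg <- cohort_config(n_mild = 15, n_severe = 10, missing_rate = 0.2)
  cohort <- generate_cohort(cfg, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  line1 <- readLines(path, n = 1)
  expect_match(line1, '^"record_id","label","sex","f001"')
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
})

test_that("empirical CI of the group mean recovers each configured interval", {
  # for every continuous spec and group: 1e4 draws, CI rescaled to the
  # printed group size must match the configured interval within 3 MC SEs
  n_rep <- 10000
  cohort <- generate_cohort(
    cohort_config(n_mild = n_rep, n_severe = n_rep), seed = 21)
  specs <- Filter(function(s) s$kind == "continuous", default_feature_specs())
  ci_n <- c(mild = 220, severe = 188)
  for (i in seq_along(specs)) {
    x <- cohort[[sprintf("f%03d", i)]]
    for (g in c("mild", "severe")) {
      v <- x[cohort$label == (g == "severe")]
      half <- 1.959964 * sd(v) / sqrt(ci_n[[g]])
      got <- c(mean(v) - half, mean(v) + half)
      se <- sd(v) / sqrt(n_rep)
      expect_lt(max(abs(got - specs[[i]][[g]])), 3 * se,
                label = sprintf("CI endpoints for %s/%s", specs[[i]]$name, g))
    }
  }
})
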