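# End-to-end experiment runners: comparison pipeline, sweeps, randomized
# trials. Runs here use reduced cohorts/rounds; the full-scale battery lives
# in the acceptance suite.

small_spec <- function(rounds = 2, k = 3, ...) {
  experiment_spec(
    cohort = cohort_config(n_mild = 60, n_severe = 50, n_features = 10),
    fl = fl_config(k = k, rounds = rounds, hidden = c(8), ...))
}

test_that("comparison report has K client rows and a macro row per arm", {
  rep1 <- run_comparison(small_spec(), seed = 1)
  m <- rep1$metrics
  expect_setequal(unique(m$arm), c("fl", "cml"))
  expect_equal(m$client[m$arm == "fl"], c("1", "2", "3", "macro"))
  expect_equal(nrow(rep1$improvement), 5)
  expect_equal(rep1$improvement$metric,
               c("accuracy", "precision", "recall", "f1", "auc"))
  expect_equal(rep1$improvement$improvement_pts,
               100 * (rep1$improvement$fl - rep1$improvement$cml))
})

test_that("with zero rounds both arms share the init: improvement exactly 0", {
  rep0 <- run_comparison(small_spec(rounds = 0), seed = 3)
  expect_equal(rep0$improvement$improvement_pts, rep(0, 5))
  expect_equal(rep0$improvement$fl, rep0$improvement$cml)
})

test_that("identical spec and seed give byte-identical reports", {
  a <- run_comparison(small_spec(), seed = 7)
  b <- run_comparison(small_spec(), seed = 7)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$improvement, b$improvement)
})

test_that("each client is evaluated on exactly its local test set, once", {
  spec <- small_spec()
  shards <- fedcopd:::build_shards(spec, seed = 5)
  rep1 <- run_comparison(spec, seed = 5)
  per <- rep1$metrics[rep1$metrics$arm == "fl" & rep1$metrics$client != "macro", ]
  for (k in 1:3)
    expect_equal(per$n[k], nrow(shards[[k]]$test))
  # no record scored twice within one arm
  fl_pred <- fedcopd:::predict_clients(shards, list(rep1$federation$params))
  expect_equal(anyDuplicated(fl_pred[c("client", "record_id")]), 0L)
  # federated final-round RES equals scoring with the final global parameters
  final <- rep1$federation$res[rep1$federation$res$round == spec$fl$rounds, ]
  expect_equal(final$prob, fl_pred$prob, tolerance = 1e-12)
})

test_that("sweeps produce one report per axis value in long format", {
  sw <- run_sweep(small_spec(), axis = "rounds", values = c(1, 3), seed = 2)
  expect_length(sw$reports, 2)
  expect_setequal(unique(sw$long$axis_value), c("1", "3"))
  expect_setequal(unique(sw$long$metric),
                  c("accuracy", "precision", "recall", "f1", "auc"))

  sp <- run_sweep(small_spec(), axis = "split",
                  values = list(c(5, 5), c(9, 1)), seed = 2)
  expect_setequal(unique(sp$long$axis_value), c("5:5", "9:1"))
  # 9:1 split on 36-record shards leaves tiny test sets; must still complete
  expect_true(all(is.finite(sp$long$value[sp$long$metric == "accuracy"])))

  # sample-size axis scales the generated cohort up when needed
  ss <- run_sweep(small_spec(), axis = "sample_size", values = c(20, 60),
                  seed = 2)
  per <- ss$reports[[2]]$metrics
  expect_equal(per$n[per$arm == "fl" & per$client == "1"],
               60 - floor(0.7 * 60))
  expect_error(run_sweep(small_spec(), axis = "rounds", values = numeric(0)),
               "empty")
})

test_that("randomized trials are reproducible and summarized with CIs", {
  tr <- run_randomized_trials(small_spec(), m = 3, seed = 4)
  tr2 <- run_randomized_trials(small_spec(), m = 3, seed = 4)
  expect_identical(tr$summary, tr2$summary)
  expect_equal(nrow(tr$summary), 10) # 2 arms x 5 metrics
  expect_true(all(tr$summary$lower <= tr$summary$mean + 1e-12))
  expect_true(all(tr$summary$mean <= tr$summary$upper + 1e-12))
  expect_equal(unique(tr$summary$m), 3)
})

test_that("experiment configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "cohort: {n_mild: 30, n_severe: 20, n_features: 12, missing_rate: 0.05}",
    "fl: {k: 2, rounds: 4, epochs: 3, batch_size: 5, eta: 0.01,",
    "     split: [8, 2], hidden: [6], activation: tanh, weighted: true}",
    "samples_per_client: 20"), path)
  spec <- read_experiment_config(path)
  expect_equal(spec$cohort$n_mild, 30)
  expect_equal(spec$cohort$missing_rate, 0.05)
  expect_equal(spec$fl$k, 2)
  expect_equal(spec$fl$train$epochs, 3)
  expect_equal(spec$fl$split, c(8, 2))
  expect_true(spec$fl$weighted)
  expect_equal(spec$samples_per_client, 20)
  # defaults fill everything that is omitted
  d <- as_experiment_spec(list())
  expect_equal(d$cohort$n_mild, 220)
  expect_equal(d$fl$rounds, 350)
})

test_that("the default pipeline runs with injected missingness", {
  spec <- experiment_spec(
    cohort = cohort_config(n_mild = 60, n_severe = 50, n_features = 10,
                           missing_rate = 0.03),
    fl = fl_config(k = 2, rounds = 1, hidden = c(4)))
  rep1 <- run_comparison(spec, seed = 9)
  expect_equal(nrow(rep1$improvement), 5)
})

test_that("the federated advantage persists across per-client sample sizes", {
  # data-scarcity trend at the default rounds, runtime-scaled: advantage in
  # macro accuracy as per-client samples shrink 300 -> 50 may not decrease
  # more than once across the three sizes
  sizes <- c(50, 150, 300)
  adv <- vapply(sizes, function(sz) {
    mean(vapply(1:3, function(s) {
      spec <- experiment_spec(fl = fl_config(rounds = 350),
                              samples_per_client = sz)
      needed <- sz * spec$fl$k
      have <- spec$cohort$n_mild + spec$cohort$n_severe
      if (needed > have) {
        p_mild <- spec$cohort$n_mild / have
        spec$cohort$n_mild <- ceiling(needed * p_mild)
        spec$cohort$n_severe <- needed - spec$cohort$n_mild +
          ceiling(needed * 0.02)
      }
      r <- run_comparison(spec, seed = s)
      r$improvement$improvement_pts[r$improvement$metric == "accuracy"]
    }, numeric(1)))
  }, numeric(1))
  # walking 300 -> 150 -> 50, the advantage should not decrease; count drops
  inversions <- sum(diff(rev(adv)) < 0)
  expect_lte(inversions, 1)
})
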