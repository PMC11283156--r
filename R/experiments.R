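# Config-driven experiment runners: federated-vs-isolated comparison, sweeps
# over sample size / communication rounds / split ratio, and repeated
# randomized trials with confidence intervals. All runs are deterministic
# given the spec and a master seed.

#' Bundle an experiment's settings
#'
#' @param cohort A [cohort_config()].
#' @param fl An [fl_config()].
#' @param samples_per_client Records sampled per simulated hospital; defaults
#'   to an equal split `floor(n / k)` of the preprocessed cohort.
#' @param missing_threshold Feature missing-fraction cutoff passed to
#'   [preprocess_cohort()].
#' @return An `experiment_spec` object.
#' @export
experiment_spec <- function(cohort = cohort_config(), fl = fl_config(),
                            samples_per_client = NULL,
                            missing_threshold = 0.10) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(fl, "fl_config"))
  structure(list(cohort = cohort, fl = fl,
                 samples_per_client = samples_per_client,
                 missing_threshold = missing_threshold),
            class = "experiment_spec")
}

# Generate -> preprocess -> partition -> split, all from seeds derived off the
# master, returning the client shards both arms share.
build_shards <- function(spec, seed) {
  cohort <- generate_cohort(spec$cohort, derive_seed(seed, "cohort"))
  cohort <- suppressMessages(
    preprocess_cohort(cohort, spec$missing_threshold))
  spc <- spec$samples_per_client %||% (nrow(cohort) %/% spec$fl$k)
  shards <- partition_cohort(cohort, spec$fl$k, spc,
                             derive_seed(seed, "partition"))
  lapply(seq_along(shards), function(k)
    split_cohort(shards[[k]], spec$fl$split, derive_seed(seed, "split", k),
                 id = as.character(k)))
}

# Score every client's local test set with a set of final parameters
# (federated: one global set; baseline: per-client sets).
predict_clients <- function(shards, params_list) {
  do.call(rbind, lapply(seq_along(shards), function(k) {
    mats <- shard_matrices(shards[[k]])
    params <- if (length(params_list) == 1) params_list[[1]] else params_list[[k]]
    data.frame(client = k, record_id = mats$test_ids, label = mats$yte,
               prob = forward(params, mats$Xte), stringsAsFactors = FALSE)
  }))
}

#' Run one federated-vs-isolated comparison
#'
#' Full pipeline: generate the synthetic cohort, apply the cleaning filters,
#' partition into `K` simulated hospitals, split each locally, then train the
#' federated arm and the isolated baseline on identical shards, architecture,
#' initialization and derived seeds, and evaluate both on the local test sets
#' with the final parameters (for the federated arm these equal the final
#' communication round's prediction record).
#'
#' @param spec An [experiment_spec()].
#' @param seed Integer master seed.
#' @return A `comparison_report`: `metrics` (per-client + macro rows for both
#'   arms), `improvement` (per metric: federated value, baseline value, and
#'   the absolute improvement in percentage points), plus the underlying
#'   `federation` and `baseline` results.
#' @export
run_comparison <- function(spec, seed) {
  stopifnot(inherits(spec, "experiment_spec"))
  shards <- build_shards(spec, seed)
  fed <- run_federation(shards, spec$fl, seed)
  base <- run_baseline(shards, spec$fl, seed)
  fl_pred <- predict_clients(shards, list(fed$params))
  cml_pred <- predict_clients(shards, lapply(base$clients, `[[`, "params"))
  m_fl <- cbind(arm = "fl", evaluate_predictions(fl_pred))
  m_cml <- cbind(arm = "cml", evaluate_predictions(cml_pred))
  metrics <- rbind(m_fl, m_cml)
  rownames(metrics) <- NULL
  macro_fl <- m_fl[m_fl$client == "macro", ]
  macro_cml <- m_cml[m_cml$client == "macro", ]
  mnames <- c("accuracy", "precision", "recall", "f1", "auc")
  improvement <- data.frame(
    metric = mnames,
    fl = as.numeric(macro_fl[1, mnames]),
    cml = as.numeric(macro_cml[1, mnames]),
    improvement_pts = 100 * (as.numeric(macro_fl[1, mnames]) -
                               as.numeric(macro_cml[1, mnames])))
  structure(list(metrics = metrics, improvement = improvement,
                 federation = fed, baseline = base, spec = spec, seed = seed),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Federated vs isolated training (K =", x$spec$fl$k, ", r =",
      x$spec$fl$rounds, ")\n")
  print(x$improvement, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Sweep one experimental axis
#'
#' Re-runs the full comparison at each value of one axis, all other settings
#' held at the spec's values:
#' * `"sample_size"`: per-client records (default 50 to 350 by 50); the
#'   generated cohort is scaled up proportionally (preserving the mild:severe
#'   mix) whenever `k * value` exceeds its size.
#' * `"rounds"`: communication rounds.
#' * `"split"`: train:test ratios, a list like `list(c(5,5), c(7,3))`
#'   (default the five published ratios 5:5 ... 9:1).
#'
#' @param spec An [experiment_spec()].
#' @param axis One of `"sample_size"`, `"rounds"`, `"split"`.
#' @param values Axis values; sensible defaults per axis.
#' @param seed Integer master seed (each axis value runs from the same seed so
#'   only the axis varies).
#' @return List with `long` (tidy data frame
#'   `axis, axis_value, arm, client, metric, value`) and `reports` (one
#'   `comparison_report` per axis value).
#' @export
run_sweep <- function(spec, axis = c("sample_size", "rounds", "split"),
                      values = NULL, seed = 1) {
  axis <- match.arg(axis)
  values <- values %||% switch(axis,
    sample_size = seq(50, 350, by = 50),
    rounds = c(1, 50, 150, 250, 350),
    split = list(c(5, 5), c(6, 4), c(7, 3), c(8, 2), c(9, 1)))
  if (!length(values)) stop("empty sweep axis")
  vals <- if (is.list(values)) values else as.list(values)
  reports <- lapply(vals, function(v) {
    s <- spec
    if (axis == "sample_size") {
      s$samples_per_client <- v
      needed <- v * s$fl$k
      have <- s$cohort$n_mild + s$cohort$n_severe
      if (needed > have) {
        p_mild <- s$cohort$n_mild / have
        s$cohort$n_mild <- ceiling(needed * p_mild)
        s$cohort$n_severe <- needed - s$cohort$n_mild + ceiling(needed * 0.02)
      }
    } else if (axis == "rounds") {
      s$fl$rounds <- as.integer(v)
    } else {
      s$fl$split <- v
    }
    run_comparison(s, seed)
  })
  label <- vapply(vals, function(v) paste(v, collapse = ":"), character(1))
  long <- do.call(rbind, lapply(seq_along(reports), function(i) {
    m <- reports[[i]]$metrics
    do.call(rbind, lapply(c("accuracy", "precision", "recall", "f1", "auc"),
      function(met) data.frame(axis = axis, axis_value = label[i],
                               arm = m$arm, client = m$client, metric = met,
                               value = m[[met]], stringsAsFactors = FALSE)))
  }))
  rownames(long) <- NULL
  list(long = long, reports = reports)
}

#' Repeated randomized trials with confidence intervals
#'
#' Runs `m` independent end-to-end comparisons differing only in their derived
#' seeds and summarizes each macro metric per arm with a normal-approximation
#' 95% CI ([repeated_ci()]).
#'
#' @param spec An [experiment_spec()].
#' @param m Number of randomized trials (`>= 2`).
#' @param seed Integer master seed; trial `i` uses
#'   `derive_seed(seed, "trial", i)`.
#' @return List with `summary` (data frame
#'   `arm, metric, m, mean, lower, upper`) and `trials` (per-trial macro
#'   metrics, long format).
#' @export
run_randomized_trials <- function(spec, m = 100, seed = 1) {
  stopifnot(m >= 2)
  mnames <- c("accuracy", "precision", "recall", "f1", "auc")
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    rep_i <- run_comparison(spec, derive_seed(seed, "trial", i))
    mm <- rep_i$metrics[rep_i$metrics$client == "macro", ]
    rows[[i]] <- do.call(rbind, lapply(c("fl", "cml"), function(a)
      data.frame(trial = i, arm = a, metric = mnames,
                 value = as.numeric(mm[mm$arm == a, mnames]),
                 stringsAsFactors = FALSE)))
  }
  trials <- do.call(rbind, rows)
  combos <- unique(trials[c("arm", "metric")])
  summary <- do.call(rbind, lapply(seq_len(nrow(combos)), function(j) {
    sel <- trials$arm == combos$arm[j] & trials$metric == combos$metric[j]
    ci <- repeated_ci(trials$value[sel])
    data.frame(arm = combos$arm[j], metric = combos$metric[j], m = ci$m,
               mean = ci$mean, lower = ci$lower, upper = ci$upper,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(summary = summary, trials = trials)
}
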