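# Synthetic AECOPD cohort generation, preprocessing filters, and partitioning
# into simulated hospitals.
#
# The real study data (408 inpatient records from a single tertiary hospital)
# are private, so the generator reproduces the published group-level summary
# structure instead: group sizes 220 (mild) / 188 (severe), exact per-group sex
# counts, and per-group 95% confidence intervals of the mean for seven vital
# signs, padded with uninformative filler features to a 40-column schema.

#' Invert a normal-theory 95% CI of the mean to population moments
#'
#' Published tables report each vital sign as a 95% confidence interval of the
#' group mean. Assuming the interval is normal-theory
#' (`mean +/- 1.959964 * sd / sqrt(n)`), the population moments are recovered
#' as `mean = midpoint` and `sd = half_width / 1.959964 * sqrt(n)`.
#'
#' @param ci_lower,ci_upper Interval endpoints, `ci_lower <= ci_upper`.
#' @param n Group size the interval was computed from (`n >= 2`).
#' @return A list with elements `mean` and `sd`.
#' @export
#' @examples
#' ci_to_moments(77.6, 80.0, 220) # mean 78.8, sd ~ 9.08
ci_to_moments <- function(ci_lower, ci_upper, n) {
  if (!is.numeric(ci_lower) || !is.numeric(ci_upper) || ci_lower > ci_upper)
    stop("reversed or non-numeric confidence interval: (",
         ci_lower, ", ", ci_upper, ")")
  if (n < 2) stop("n must be >= 2")
  list(
    mean = (ci_lower + ci_upper) / 2,
    sd = ((ci_upper - ci_lower) / 2 / 1.959964) * sqrt(n)
  )
}

#' Declare a cohort feature
#'
#' @param name Feature name. The reserved name `"sex"` maps to the cohort's
#'   demographic `sex` column; all other features become numeric `f`-columns.
#' @param kind `"continuous"` or `"binary"`.
#' @param mild,severe For continuous features, the per-group 95% CI of the
#'   mean, `c(lower, upper)`. For binary features, the per-group count of
#'   positives (values > 1) or proportion (values in `[0, 1]`).
#' @param bounds Optional `c(lower, upper)` truncation bounds for continuous
#'   features; sampling is exact truncated-normal via inverse CDF. Bounds must
#'   bracket both group CI midpoints.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(name, kind = c("continuous", "binary"),
                         mild, severe, bounds = NULL) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    stopifnot(length(mild) == 2, length(severe) == 2)
    if (mild[1] > mild[2] || severe[1] > severe[2])
      stop("feature '", name, "': CI lower must be <= upper")
    if (!is.null(bounds)) {
      stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
      mids <- c(mean(mild), mean(severe))
      if (any(mids < bounds[1] | mids > bounds[2]))
        stop("feature '", name, "': truncation bounds must bracket the CI midpoints")
    }
  } else {
    stopifnot(length(mild) == 1, length(severe) == 1, mild >= 0, severe >= 0)
    if ((mild <= 1 && mild < 0) || (severe <= 1 && severe < 0))
      stop("binary proportions must lie in [0, 1]")
  }
  structure(list(name = name, kind = kind, mild = mild, severe = severe,
                 bounds = bounds),
            class = "feature_spec")
}

#' Published feature specifications for the AECOPD cohort
#'
#' Seven vital-sign features with per-group 95% CIs of the mean (mild n = 220,
#' severe n = 188) plus exact per-group male counts (188/32 mild, 157/31
#' severe male/female). Default truncation bounds are broad physiological
#' ranges chosen to cut negligible probability mass, so the configured CIs are
#' still recovered; the hospitalization count is untruncated because its
#' inverted coefficient of variation exceeds what any left-truncated normal
#' can attain, and truncation at zero would visibly bias the group mean.
#'
#' @return A list of [feature_spec()] objects.
#' @export
default_feature_specs <- function() {
  list(
    feature_spec("sex", "binary", mild = 188, severe = 157),
    feature_spec("age", "continuous",
                 mild = c(77.6, 80.0), severe = c(80.2, 82.8),
                 bounds = c(18, 110)),
    feature_spec("n_hospitalizations", "continuous",
                 mild = c(3.3, 3.9), severe = c(5.5, 7.5)),
    feature_spec("systolic_bp", "continuous",
                 mild = c(130.6, 135.6), severe = c(128.1, 135.1),
                 bounds = c(60, 260)),
    feature_spec("diastolic_bp", "continuous",
                 mild = c(74.2, 77.4), severe = c(72.5, 76.3),
                 bounds = c(30, 150)),
    feature_spec("temperature", "continuous",
                 mild = c(36.7, 36.9), severe = c(36.6, 36.8),
                 bounds = c(30, 45)),
    feature_spec("pulse", "continuous",
                 mild = c(90.5, 94.5), severe = c(96.6, 101.4),
                 bounds = c(20, 220)),
    feature_spec("respiratory_rate", "continuous",
                 mild = c(21.3, 22.1), severe = c(23.8, 25.6),
                 bounds = c(5, 60))
  )
}

#' Cohort generator configuration
#'
#' @param n_mild,n_severe Records to generate per group (defaults 220/188,
#'   the published group sizes).
#' @param specs List of [feature_spec()]; defaults to
#'   [default_feature_specs()].
#' @param n_features Total numeric feature columns including fillers
#'   (default 40, the published modeling width). Named non-sex specs occupy
#'   the first columns; the remainder are standard-normal fillers with
#'   identical distribution in both groups.
#' @param missing_rate Per-cell missingness probability in `[0, 1)` injected
#'   into the feature columns (default 0), to exercise the cleaning filters.
#' @param ci_n Per-group sizes the published CIs were computed from,
#'   `c(mild, severe)`. Kept separate from `n_mild`/`n_severe` so cohorts of
#'   any size draw from the same population implied by the printed intervals.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_mild = 220, n_severe = 188,
                          specs = default_feature_specs(),
                          n_features = 40, missing_rate = 0,
                          ci_n = c(mild = 220, severe = 188)) {
  stopifnot(n_mild > 0, n_severe > 0,
            missing_rate >= 0, missing_rate < 1,
            length(ci_n) == 2, all(ci_n >= 2))
  named <- sum(vapply(specs, function(s) s$name != "sex", logical(1)))
  if (n_features < named)
    stop("n_features (", n_features, ") below number of named specs (", named, ")")
  structure(list(n_mild = n_mild, n_severe = n_severe, specs = specs,
                 n_features = n_features, missing_rate = missing_rate,
                 ci_n = c(mild = ci_n[[1]], severe = ci_n[[2]])),
            class = "cohort_config")
}

# Exact truncated-normal draws via inverse CDF: fixed draw count, so the
# generator consumes a deterministic amount of randomness per feature.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Binary vector with an exact positive count (not Bernoulli), randomly placed.
draw_exact_binary <- function(n, spec_value) {
  npos <- if (spec_value <= 1) round(spec_value * n) else round(spec_value)
  npos <- min(max(npos, 0L), n)
  out <- c(rep(1L, npos), rep(0L, n - npos))
  sample(out)
}

#' Generate a synthetic cohort
#'
#' Draws `n_mild + n_severe` labeled records. Continuous features are sampled
#' per group from the normal (optionally truncated) distribution whose moments
#' are recovered from the configured 95% CI by [ci_to_moments()] at the `ci_n`
#' group size. Sex is assigned by exact per-group counts, scaled
#' proportionally when group sizes differ from the published defaults, so the
#' published totals (345 male / 63 female) reproduce exactly at defaults.
#' Filler columns are standard normal in both groups. Identical `config` and
#' `seed` give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `copd_cohort` data frame with columns `record_id`, `label`
#'   (0 = mild, 1 = severe), `sex` (`"male"`/`"female"`), and `f001...` numeric
#'   features (NA marks a missing cell).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' nrow(cohort)        # 408
#' sum(cohort$sex == "male")  # 345
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- list(mild = config$n_mild, severe = config$n_severe)
  cont <- Filter(function(s) s$kind == "continuous", config$specs)
  sex_spec <- Filter(function(s) s$name == "sex", config$specs)
  sex_spec <- if (length(sex_spec)) sex_spec[[1]] else NULL
  n_named <- length(cont)
  n_fill <- config$n_features - n_named
  fnames <- sprintf("f%03d", seq_len(config$n_features))

  with_seed(seed, {
    parts <- lapply(names(groups), function(g) {
      n <- groups[[g]]
      label <- if (g == "mild") 0L else 1L
      cols <- vector("list", config$n_features)
      for (i in seq_along(cont)) {
        s <- cont[[i]]
        mom <- ci_to_moments(s[[g]][1], s[[g]][2], config$ci_n[[g]])
        b <- s$bounds %||% c(-Inf, Inf)
        cols[[i]] <- rtruncnorm(n, mom$mean, mom$sd, b[1], b[2])
      }
      if (n_fill > 0)
        for (j in seq_len(n_fill)) cols[[n_named + j]] <- stats::rnorm(n)
      sex <- if (!is.null(sex_spec)) {
        # spec values are male counts at the published group sizes; rescale
        prop <- if (sex_spec[[g]] <= 1) sex_spec[[g]]
                else sex_spec[[g]] / config$ci_n[[g]]
        ifelse(draw_exact_binary(n, prop) == 1L, "male", "female")
      } else rep(NA_character_, n)
      df <- data.frame(label = rep(label, n), sex = sex,
                       stringsAsFactors = FALSE)
      names(cols) <- fnames
      cbind(df, as.data.frame(cols))
    })
    cohort <- do.call(rbind, parts)
    cohort <- cohort[sample.int(nrow(cohort)), , drop = FALSE]
    cohort <- cbind(record_id = sprintf("P%04d", seq_len(nrow(cohort))),
                    cohort)
    rownames(cohort) <- NULL
    if (config$missing_rate > 0) {
      fm <- as.matrix(cohort[fnames])
      mask <- matrix(stats::runif(length(fm)) < config$missing_rate,
                     nrow = nrow(fm))
      fm[mask] <- NA_real_
      cohort[fnames] <- fm
    }
    structure(cohort, class = c("copd_cohort", "data.frame"))
  })
}

feature_columns <- function(cohort) grep("^f[0-9]+$", names(cohort), value = TRUE)

#' Apply the missing-data cleaning filters
#'
#' Two-stage filter mirroring the study's preprocessing: first every feature
#' column whose missing fraction strictly exceeds `missing_threshold` is
#' dropped (a feature at exactly the threshold survives), then every record
#' with any remaining missing cell is excluded. Counts dropped at each stage
#' are attached as the `preprocess_log` attribute and reported via `message()`.
#'
#' @param cohort A `copd_cohort` data frame.
#' @param missing_threshold Missing-fraction cutoff in `[0, 1]` (default 0.10).
#' @return The filtered cohort. Idempotent: a second application is the
#'   identity.
#' @export
preprocess_cohort <- function(cohort, missing_threshold = 0.10) {
  stopifnot(missing_threshold >= 0, missing_threshold <= 1)
  fcols <- feature_columns(cohort)
  if (!length(fcols)) stop("cohort has no feature columns")
  miss_frac <- vapply(cohort[fcols], function(x) mean(is.na(x)), numeric(1))
  drop <- fcols[miss_frac > missing_threshold]
  keep <- setdiff(names(cohort), drop)
  out <- cohort[keep]
  if (!length(feature_columns(out)))
    stop("preprocessing stage 1 (feature filter) removed every feature")
  complete <- stats::complete.cases(out[feature_columns(out)])
  n_rec_dropped <- sum(!complete)
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out))
    stop("preprocessing stage 2 (record filter) removed every record")
  message(length(drop), " feature(s) dropped (> ",
          round(100 * missing_threshold, 1), "% missing); ",
          n_rec_dropped, " incomplete record(s) excluded")
  structure(out, class = c("copd_cohort", "data.frame"),
            preprocess_log = list(dropped_features = drop,
                                  n_records_dropped = n_rec_dropped))
}

#' Partition a cohort into simulated hospitals
#'
#' Simple random sampling without replacement into `k` disjoint shards of
#' `samples_per_client` records each, emulating multiple data sources drawn
#' from one site's records.
#'
#' @param cohort A `copd_cohort`.
#' @param k Number of clients (simulated hospitals).
#' @param samples_per_client Records per shard; defaults to
#'   `floor(nrow(cohort) / k)`.
#' @param seed Integer seed.
#' @return A list of `k` cohorts.
#' @export
partition_cohort <- function(cohort, k, samples_per_client = NULL, seed) {
  stopifnot(k >= 1)
  samples_per_client <- samples_per_client %||% (nrow(cohort) %/% k)
  stopifnot(samples_per_client >= 1)
  if (k * samples_per_client > nrow(cohort))
    stop("requested ", k * samples_per_client, " records but cohort has ",
         nrow(cohort))
  with_seed(seed, {
    idx <- sample.int(nrow(cohort), k * samples_per_client)
    lapply(seq_len(k), function(i) {
      rows <- idx[((i - 1) * samples_per_client + 1):(i * samples_per_client)]
      out <- cohort[rows, , drop = FALSE]
      rownames(out) <- NULL
      structure(out, class = c("copd_cohort", "data.frame"))
    })
  })
}

#' Split one shard into local train and test sets
#'
#' @param shard A `copd_cohort` with at least 2 records.
#' @param ratio Train:test shares, e.g. `c(7, 3)`; normalized to sum to 1.
#'   Train size is `floor(share * n)`.
#' @param seed Integer seed.
#' @param id Optional client identifier carried on the result.
#' @return A `client_shard`: list with elements `id`, `train`, `test`
#'   (disjoint, exhaustive).
#' @export
split_cohort <- function(shard, ratio = c(7, 3), seed, id = NULL) {
  stopifnot(length(ratio) == 2, all(ratio > 0))
  n <- nrow(shard)
  if (n < 2) stop("shard must have at least 2 records to split")
  n_train <- floor(ratio[1] / sum(ratio) * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  with_seed(seed, {
    tr <- sample.int(n, n_train)
    structure(list(id = id %||% NA_character_,
                   train = structure(shard[tr, , drop = FALSE],
                                     class = c("copd_cohort", "data.frame")),
                   test = structure(shard[-tr, , drop = FALSE],
                                    class = c("copd_cohort", "data.frame"))),
              class = "client_shard")
  })
}

#' Read/write cohorts as CSV
#'
#' Plain CSV with header `record_id,label,sex,f001...`; missing cells are
#' empty fields.
#'
#' @param cohort A `copd_cohort`.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `copd_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(record_id = "character"))
  df$label <- as.integer(df$label)
  for (fc in grep("^f[0-9]+$", names(df), value = TRUE))
    df[[fc]] <- as.numeric(df[[fc]])
  structure(df, class = c("copd_cohort", "data.frame"))
}
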