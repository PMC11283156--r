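# Shared fixtures: tiny cohorts, shards and nets built in code.

# A minimal complete cohort with a controllable missingness pattern.
toy_cohort <- function(n = 10, n_features = 3, seed = 99) {
  fedcopd:::with_seed(seed, {
    df <- data.frame(
      record_id = sprintf("T%03d", seq_len(n)),
      label = rep(c(0L, 1L), length.out = n),
      sex = rep(c("male", "female"), length.out = n),
      stringsAsFactors = FALSE)
    for (j in seq_len(n_features))
      df[[sprintf("f%03d", j)]] <- rnorm(n)
    structure(df, class = c("copd_cohort", "data.frame"))
  })
}

# A small separable shard: one informative feature, labels follow its sign.
toy_shard <- function(n = 40, n_features = 4, seed = 7, shift = 2) {
  fedcopd:::with_seed(seed, {
    label <- rep(c(0L, 1L), length.out = n)
    df <- data.frame(record_id = sprintf("S%03d", seq_len(n)),
                     label = label,
                     sex = rep("male", n), stringsAsFactors = FALSE)
    df$f001 <- rnorm(n) + shift * label
    for (j in 2:n_features) df[[sprintf("f%03d", j)]] <- rnorm(n)
    cohort <- structure(df, class = c("copd_cohort", "data.frame"))
    split_cohort(cohort, c(7, 3), seed = seed + 1, id = "toy")
  })
}

random_params <- function(input = 3, hidden = c(4), seed = 1,
                          activation = "relu") {
  init_params(network_architecture(input, hidden, activation), seed)
}

# Independent finite-difference gradient (central differences on the
# flattened parameter vector).
fd_gradient <- function(params, X, y, h = 1e-6) {
  theta <- flatten_params(params)
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    lu <- bce_loss(y, forward(unflatten_params(up, params), X))
    ld <- bce_loss(y, forward(unflatten_params(dn, params), X))
    g[i] <- (lu - ld) / (2 * h)
  }
  g
}

# O(n^2) pairwise AUC oracle: P(score_pos > score_neg) + 0.5 * P(tie).
pairwise_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Params with jittered biases plus a batch away from ReLU kinks and the
# probability clipping bounds, so central differences are two-sided
# everywhere the loss is differentiable.
fd_test_case <- function(input, hidden, activation, seed, n) {
  params <- random_params(input = input, hidden = hidden, seed = seed,
                          activation = activation)
  params$layers <- lapply(params$layers, function(l)
    list(W = l$W, b = rnorm(length(l$b), sd = 0.3)))
  for (t in 1:50) {
    X <- matrix(rnorm(n * input), n)
    fp <- fedcopd:::forward_pass(params, X)
    zmin <- min(vapply(fp$Z, function(z) min(abs(z)), numeric(1)))
    if (zmin > 1e-4 && all(fp$p > 1e-6) && all(fp$p < 1 - 1e-6))
      return(list(params = params, X = X, y = rbinom(n, 1, 0.5)))
  }
  stop("no kink-free batch found")
}
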