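# The federated-averaging loop: per-round client updates by minibatch gradient
# descent, unweighted server aggregation of parameters, and collection of
# per-client test-set predictions. The federation is simulated in-process;
# privacy is by data locality (clients exchange parameter copies only, never
# records), exactly the premise of the modeled system.

#' Federation hyperparameters
#'
#' Defaults are the study's published settings: `K = 3` clients, `r = 350`
#' communication rounds, `E = 5` local epochs, `B = 10` minibatch size,
#' `eta = 0.001`, train:test split 7:3.
#'
#' @param k Number of clients, all of which participate in every round.
#' @param rounds Communication rounds `r` (`>= 0`).
#' @param eta,epochs,batch_size Local training settings, see [train_config()].
#' @param split Train:test shares, e.g. `c(7, 3)`.
#' @param hidden,activation Backbone architecture, see
#'   [network_architecture()]; input width is taken from the data.
#' @param weighted If `TRUE`, aggregation weights clients by local training-set
#'   size; default `FALSE`, the plain arithmetic mean
#'   `theta_{r+1} = (1/K) * sum_k theta_k^r`.
#' @return An `fl_config` object.
#' @export
fl_config <- function(k = 3L, rounds = 350L, eta = 0.001, epochs = 5L,
                      batch_size = 10L, split = c(7, 3),
                      hidden = c(32L, 16L), activation = "relu",
                      weighted = FALSE) {
  stopifnot(k >= 1, rounds >= 0)
  structure(list(k = as.integer(k), rounds = as.integer(rounds),
                 train = train_config(eta, epochs, batch_size),
                 split = split, hidden = hidden, activation = activation,
                 weighted = isTRUE(weighted)),
            class = "fl_config")
}

# Standardized design matrices for one client. Each client standardizes with
# its OWN training-set mean/sd (constant columns get sd 1); the test set uses
# the same local transform. No cross-client statistic is ever shared.
shard_matrices <- function(shard) {
  stopifnot(inherits(shard, "client_shard"))
  fcols <- feature_columns(shard$train)
  if (!nrow(shard$train)) stop("client training set is empty")
  Xtr <- as.matrix(shard$train[fcols])
  mu <- colMeans(Xtr)
  sdev <- apply(Xtr, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  scale_mat <- function(X) sweep(sweep(X, 2, mu), 2, sdev, "/")
  list(
    Xtr = scale_mat(Xtr), ytr = shard$train$label,
    Xte = scale_mat(as.matrix(shard$test[fcols])), yte = shard$test$label,
    test_ids = shard$test$record_id, n_train = nrow(Xtr)
  )
}

#' One client's local update
#'
#' Runs `E` epochs of minibatch SGD on the client's training shard, starting
#' from (a copy of) the broadcast parameters, and returns the updated
#' parameters; the input object is never modified. Features are standardized
#' with the client's own training statistics. `E = 0` or `eta = 0` returns the
#' parameters unchanged.
#'
#' @param params Broadcast `fcn_params`.
#' @param shard A `client_shard` from [split_cohort()].
#' @param cfg A [train_config()].
#' @param client_seed Integer seed controlling this client's batch shuffles.
#' @return Updated `fcn_params`.
#' @export
client_update <- function(params, shard, cfg, client_seed) {
  mats <- shard_matrices(shard)
  aug <- augment_params(params)
  act <- params_arch(params)$activation
  out <- with_seed(client_seed,
    train_epochs_aug(aug, mats$Xtr, mats$ytr, cfg$epochs, cfg$batch_size,
                     cfg$eta, act))
  deaugment_params(out$aug, params)
}

#' Server aggregation: average the uploaded parameters
#'
#' Elementwise arithmetic mean of the clients' parameters
#' (`theta_{r+1} = (1/K) * sum_k theta_k^r`), or a weighted mean when
#' `weights` are supplied. If the list is named, summation runs in sorted-name
#' order so the result is exactly invariant to the order clients report in.
#'
#' @param client_params Nonempty list of identically shaped `fcn_params`.
#' @param weights Optional nonnegative weights, one per client; normalized to
#'   sum to 1.
#' @return The aggregated `fcn_params`.
#' @export
server_aggregate <- function(client_params, weights = NULL) {
  if (!length(client_params)) stop("no client parameters to aggregate")
  if (!is.null(names(client_params)) && all(nzchar(names(client_params)))) {
    ord <- order(names(client_params))
    client_params <- client_params[ord]
    if (!is.null(weights)) weights <- weights[ord]
  }
  K <- length(client_params)
  w <- if (is.null(weights)) rep(1 / K, K) else {
    stopifnot(length(weights) == K, all(weights >= 0), sum(weights) > 0)
    weights / sum(weights)
  }
  ref <- client_params[[1]]
  unweighted <- is.null(weights)
  shapes_ok <- vapply(client_params, function(p) {
    length(p$layers) == length(ref$layers) &&
      all(vapply(seq_along(p$layers), function(l)
        all(dim(p$layers[[l]]$W) == dim(ref$layers[[l]]$W)) &&
          length(p$layers[[l]]$b) == length(ref$layers[[l]]$b), logical(1)))
  }, logical(1))
  if (!all(shapes_ok)) stop("client parameter shapes do not match")
  # unweighted: sum then divide, so the result is the plain elementwise mean
  layers <- lapply(seq_along(ref$layers), function(l) {
    if (unweighted) {
      W <- ref$layers[[l]]$W
      b <- ref$layers[[l]]$b
      for (kk in seq_len(K)[-1]) {
        W <- W + client_params[[kk]]$layers[[l]]$W
        b <- b + client_params[[kk]]$layers[[l]]$b
      }
      list(W = W / K, b = b / K)
    } else {
      W <- ref$layers[[l]]$W * w[1]
      b <- ref$layers[[l]]$b * w[1]
      for (kk in seq_len(K)[-1]) {
        W <- W + client_params[[kk]]$layers[[l]]$W * w[kk]
        b <- b + client_params[[kk]]$layers[[l]]$b * w[kk]
      }
      list(W = W, b = b)
    }
  })
  structure(list(layers = layers), arch = params_arch(ref),
            class = "fcn_params")
}

# Per-(client, round) seed; sequential-fold property of derive_seed makes this
# consistent with the per-client bases used by the local baseline.
client_round_seed <- function(master, k, round) {
  derive_seed(master, "client", k, "round", round)
}

#' Run the federated-averaging loop
#'
#' Per communication round: every client runs `E` local epochs from the
#' current global parameters (order-independent, parallel-equivalent), the
#' server averages the updates, and each client then scores its local test set
#' with the new global parameters, appending to the prediction record `RES`.
#' Fully deterministic given `seed`: the shared initialization uses
#' `derive_seed(seed, "init")` and client `k` in round `r` uses
#' `derive_seed(seed, "client", k, "round", r)`.
#'
#' @param shards List of `cfg$k` [split_cohort()] shards.
#' @param cfg An [fl_config()].
#' @param seed Integer master seed.
#' @return A `federation_result`: `params` (final global `fcn_params`),
#'   `loss_trace` (`round, client, loss` data frame of per-round mean training
#'   loss), `res` (`round, client, record_id, label, prob` per-round test
#'   predictions), and the echoed `config`/`seed`.
#' @export
run_federation <- function(shards, cfg, seed) {
  stopifnot(inherits(cfg, "fl_config"))
  if (length(shards) != cfg$k)
    stop("expected ", cfg$k, " shards, got ", length(shards))
  mats <- lapply(shards, shard_matrices)
  widths <- vapply(mats, function(m) ncol(m$Xtr), integer(1))
  if (length(unique(widths)) != 1) stop("clients disagree on feature width")
  arch <- network_architecture(widths[1], cfg$hidden, cfg$activation)
  global <- init_params(arch, derive_seed(seed, "init"))
  aug_global <- augment_params(global)
  act <- arch$activation
  tc <- cfg$train
  agg_w <- if (cfg$weighted) {
    nt <- vapply(mats, `[[`, numeric(1), "n_train")
    nt / sum(nt)
  } else rep(1 / cfg$k, cfg$k)

  loss_trace <- vector("list", cfg$rounds)
  res <- vector("list", cfg$rounds)
  for (r in seq_len(cfg$rounds)) {
    updates <- vector("list", cfg$k)
    losses <- numeric(cfg$k)
    for (k in seq_len(cfg$k)) {
      out <- tryCatch(
        with_seed(client_round_seed(seed, k, r),
          train_epochs_aug(aug_global, mats[[k]]$Xtr, mats[[k]]$ytr,
                           tc$epochs, tc$batch_size, tc$eta, act)),
        error = function(e)
          stop("client ", k, " failed in round ", r, ": ",
               conditionMessage(e)))
      updates[[k]] <- out$aug
      losses[k] <- if (length(out$losses)) mean(out$losses) else NA_real_
    }
    # aggregate in fixed client order 1..K (arithmetic mean by default)
    agg <- lapply(seq_along(aug_global), function(l) {
      if (cfg$weighted) {
        M <- updates[[1]][[l]] * agg_w[1]
        for (kk in seq_len(cfg$k)[-1]) M <- M + updates[[kk]][[l]] * agg_w[kk]
        M
      } else {
        M <- updates[[1]][[l]]
        for (kk in seq_len(cfg$k)[-1]) M <- M + updates[[kk]][[l]]
        M / cfg$k
      }
    })
    aug_global <- agg
    loss_trace[[r]] <- data.frame(round = r, client = seq_len(cfg$k),
                                  loss = losses)
    res[[r]] <- do.call(rbind, lapply(seq_len(cfg$k), function(k) {
      p <- forward_aug(aug_global, mats[[k]]$Xte, act)
      data.frame(round = r, client = k, record_id = mats[[k]]$test_ids,
                 label = mats[[k]]$yte, prob = p, stringsAsFactors = FALSE)
    }))
  }
  empty_res <- data.frame(round = integer(), client = integer(),
                          record_id = character(), label = integer(),
                          prob = numeric(), stringsAsFactors = FALSE)
  structure(list(
    params = deaugment_params(aug_global, global),
    loss_trace = if (cfg$rounds) do.call(rbind, loss_trace) else
      data.frame(round = integer(), client = integer(), loss = numeric()),
    res = if (cfg$rounds) do.call(rbind, res) else empty_res,
    config = cfg, seed = seed
  ), class = "federation_result")
}

#' @export
print.federation_result <- function(x, ...) {
  cat("Federated run:", x$config$k, "clients,", x$config$rounds,
      "rounds (E =", x$config$train$epochs, ", B =",
      x$config$train$batch_size, ", eta =", x$config$train$eta, ")\n")
  if (nrow(x$loss_trace)) {
    last <- x$loss_trace[x$loss_trace$round == max(x$loss_trace$round), ]
    cat("final-round mean training loss:",
        format(mean(last$loss), digits = 4), "\n")
  }
  invisible(x)
}
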