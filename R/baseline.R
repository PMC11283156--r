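# The comparison arm: every client trains the identical backbone on its own
# shard alone ("CML" in the study's usage — per-site isolated training, no
# parameter mixing). Settings are matched to the federated arm: same
# architecture, same initialization, same split, and a matched gradient-pass
# budget of r * E local epochs, so any federated advantage cannot be
# attributed to extra optimization.

#' Train one client in isolation
#'
#' Runs `total_epochs` of minibatch SGD on the shard's training set from a
#' seeded initialization (or from `params` if supplied) and scores the local
#' test set. Epochs are consumed in blocks of `cfg$epochs`, block `b` seeded
#' with `derive_seed(seed, "round", b)` — the same per-block structure as one
#' federated client, which makes a single-client federation reproduce this
#' function exactly.
#'
#' @param shard A `client_shard`.
#' @param cfg A [train_config()].
#' @param total_epochs Total local epochs (`>= 0`; 0 returns predictions from
#'   the initial parameters).
#' @param seed Integer seed (initialization uses `derive_seed(seed, "init")`
#'   unless `params` is given).
#' @param params Optional starting `fcn_params`.
#' @param hidden,activation Architecture used when `params` is not supplied.
#' @return List with `params` (final `fcn_params`), `predictions`
#'   (`record_id, label, prob` on the local test set), and `loss_trace`
#'   (per-epoch mean training loss).
#' @export
train_local <- function(shard, cfg, total_epochs, seed, params = NULL,
                        hidden = c(32L, 16L), activation = "relu") {
  stopifnot(inherits(cfg, "train_config"), total_epochs >= 0)
  mats <- shard_matrices(shard)
  if (is.null(params)) {
    arch <- network_architecture(ncol(mats$Xtr), hidden, activation)
    params <- init_params(arch, derive_seed(seed, "init"))
  }
  act <- params_arch(params)$activation
  aug <- augment_params(params)
  losses <- numeric(0)
  block_size <- max(cfg$epochs, 1L)
  remaining <- as.integer(total_epochs)
  b <- 0L
  while (remaining > 0L) {
    b <- b + 1L
    e <- min(block_size, remaining)
    out <- with_seed(derive_seed(seed, "round", b),
      train_epochs_aug(aug, mats$Xtr, mats$ytr, e, cfg$batch_size, cfg$eta,
                       act))
    aug <- out$aug
    losses <- c(losses, out$losses)
    remaining <- remaining - e
  }
  p <- forward_aug(aug, mats$Xte, act)
  list(params = deaugment_params(aug, params),
       predictions = data.frame(record_id = mats$test_ids,
                                label = mats$yte, prob = p,
                                stringsAsFactors = FALSE),
       loss_trace = losses)
}

#' Run the isolated-training baseline for all clients
#'
#' Each client trains independently for `rounds * epochs` local epochs (the
#' matched gradient-pass budget of one federated client), starting from the
#' same shared initialization the federated arm uses
#' (`derive_seed(seed, "init")`) and consuming the same per-(client, round)
#' derived seeds. No parameters are exchanged: deleting one client's data can
#' only change that client's result.
#'
#' @param shards List of `cfg$k` `client_shard`s.
#' @param cfg An [fl_config()].
#' @param seed Integer master seed (same convention as [run_federation()]).
#' @return A `baseline_result`: `clients` (per-client list with `params` and
#'   `predictions`), `res` (stacked `round, client, record_id, label, prob`,
#'   with `round = cfg$rounds`), and `loss_trace`
#'   (`round, client, loss` per block).
#' @export
run_baseline <- function(shards, cfg, seed) {
  stopifnot(inherits(cfg, "fl_config"))
  if (length(shards) != cfg$k)
    stop("expected ", cfg$k, " shards, got ", length(shards))
  mats <- lapply(shards, shard_matrices)
  widths <- vapply(mats, function(m) ncol(m$Xtr), integer(1))
  if (length(unique(widths)) != 1) stop("clients disagree on feature width")
  arch <- network_architecture(widths[1], cfg$hidden, cfg$activation)
  init <- init_params(arch, derive_seed(seed, "init"))
  tc <- cfg$train

  clients <- vector("list", cfg$k)
  traces <- vector("list", cfg$k)
  for (k in seq_len(cfg$k)) {
    aug <- augment_params(init)
    block_losses <- numeric(cfg$rounds)
    for (r in seq_len(cfg$rounds)) {
      out <- tryCatch(
        with_seed(client_round_seed(seed, k, r),
          train_epochs_aug(aug, mats[[k]]$Xtr, mats[[k]]$ytr, tc$epochs,
                           tc$batch_size, tc$eta, arch$activation)),
        error = function(e)
          stop("baseline client ", k, " failed in block ", r, ": ",
               conditionMessage(e)))
      aug <- out$aug
      block_losses[r] <- if (length(out$losses)) mean(out$losses) else NA_real_
    }
    p <- forward_aug(aug, mats[[k]]$Xte, arch$activation)
    clients[[k]] <- list(
      params = deaugment_params(aug, init),
      predictions = data.frame(record_id = mats[[k]]$test_ids,
                               label = mats[[k]]$yte, prob = p,
                               stringsAsFactors = FALSE))
    traces[[k]] <- data.frame(round = seq_len(cfg$rounds),
                              client = rep(k, cfg$rounds),
                              loss = block_losses)
  }
  res <- do.call(rbind, lapply(seq_len(cfg$k), function(k)
    cbind(round = cfg$rounds, client = k, clients[[k]]$predictions)))
  structure(list(clients = clients,
                 res = res,
                 loss_trace = do.call(rbind, traces),
                 config = cfg, seed = seed),
            class = "baseline_result")
}
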