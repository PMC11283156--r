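# Fully connected binary classifier: forward pass, binary cross-entropy,
# analytic backpropagation, and the plain gradient-descent update
# theta <- theta - eta * grad(L). Training is deliberately hand-rolled: the
# parameter updates exchanged between clients and server are the mechanism
# under study, so every arithmetic step is explicit and testable against
# finite differences.

#' Define a fully connected architecture
#'
#' @param input_width Number of input features.
#' @param hidden Integer vector of hidden-layer widths (may be empty for a
#'   logistic-regression net). Default `c(32, 16)`, a small two-hidden-layer
#'   net suited to cohorts of a few hundred records.
#' @param activation Hidden activation, `"relu"` (default) or `"tanh"`. The
#'   output unit is always a logistic sigmoid.
#' @return An `fcn_architecture` object.
#' @export
network_architecture <- function(input_width, hidden = c(32L, 16L),
                                 activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  widths <- c(as.integer(input_width), as.integer(hidden), 1L)
  if (any(widths < 1)) stop("all layer widths must be >= 1")
  structure(list(widths = widths, activation = activation),
            class = "fcn_architecture")
}

#' Initialize network parameters
#'
#' Weights are drawn i.i.d. normal with variance `1/fan_in` per layer (a
#' scale-normalized scheme that keeps pre-activations O(1) at depth); biases
#' start at zero. Deterministic given `seed`.
#'
#' @param arch An [network_architecture()].
#' @param seed Integer seed.
#' @return An `fcn_params` object: list of layers, each with weight matrix `W`
#'   (`fan_in x fan_out`) and bias vector `b`.
#' @export
init_params <- function(arch, seed) {
  stopifnot(inherits(arch, "fcn_architecture"))
  w <- arch$widths
  with_seed(seed, {
    layers <- lapply(seq_len(length(w) - 1), function(l) {
      list(W = matrix(stats::rnorm(w[l] * w[l + 1], sd = 1 / sqrt(w[l])),
                      w[l], w[l + 1]),
           b = rep(0, w[l + 1]))
    })
    structure(list(layers = layers), arch = arch, class = "fcn_params")
  })
}

params_arch <- function(params) attr(params, "arch")

activate <- function(Z, activation) {
  if (activation == "relu") pmax(Z, 0) else tanh(Z)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

as_feature_matrix <- function(x, width) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != width)
    stop("feature width ", ncol(X), " does not match architecture input ", width)
  X
}

# Forward pass keeping pre-activations, for backprop.
forward_pass <- function(params, X) {
  layers <- params$layers
  act <- params_arch(params)$activation
  L <- length(layers)
  Z <- vector("list", L)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    A[[l + 1]] <- if (l < L) activate(Z[[l]], act) else sigmoid(Z[[l]])
  }
  list(Z = Z, A = A, p = drop(A[[L + 1]]))
}

#' Forward pass: predicted probability of the severe class
#'
#' @param params An `fcn_params`.
#' @param x Feature vector, or matrix with one record per row.
#' @return Probabilities strictly inside (0, 1) (clipped at 1e-7).
#' @export
forward <- function(params, x) {
  X <- as_feature_matrix(x, params_arch(params)$widths[1])
  clip_prob(forward_pass(params, X)$p)
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`, with probabilities
#' clipped to `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param y Binary labels (0 = mild, 1 = severe).
#' @param p Predicted probabilities of the severe class.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(y, p) {
  if (length(y) != length(p)) stop("labels and probabilities differ in length")
  if (!length(y)) stop("empty batch")
  p <- clip_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Analytic gradient of the batch loss
#'
#' Exact backpropagated gradient of [bce_loss()] composed with [forward()],
#' averaged over the batch. With a sigmoid output the output-layer error
#' simplifies to `(p - y) / N`.
#'
#' @param params An `fcn_params`.
#' @param X Feature matrix (records in rows) or single feature vector.
#' @param y Binary labels.
#' @return An `fcn_params`-shaped list of gradients.
#' @export
network_gradient <- function(params, X, y) {
  X <- as_feature_matrix(X, params_arch(params)$widths[1])
  if (nrow(X) != length(y)) stop("batch features and labels differ in length")
  act <- params_arch(params)$activation
  fp <- forward_pass(params, X)
  L <- length(params$layers)
  grads <- vector("list", L)
  delta <- matrix((fp$p - y) / length(y), ncol = 1)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(fp$A[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      back <- delta %*% t(params$layers[[l]]$W)
      dact <- if (act == "relu") (fp$Z[[l - 1]] > 0) + 0 else 1 - tanh(fp$Z[[l - 1]])^2
      delta <- back * dact
    }
  }
  structure(list(layers = grads), arch = params_arch(params),
            class = "fcn_params")
}

#' One plain gradient-descent step
#'
#' Elementwise `theta - eta * grad`; no momentum, weight decay, or adaptive
#' rates.
#'
#' @param params,grad Matching `fcn_params` objects.
#' @param eta Learning rate.
#' @return Updated `fcn_params`.
#' @export
sgd_step <- function(params, grad, eta) {
  if (length(params$layers) != length(grad$layers))
    stop("parameter and gradient shapes do not match")
  layers <- Map(function(l, g) {
    if (!all(dim(l$W) == dim(g$W))) stop("weight shape mismatch")
    list(W = l$W - eta * g$W, b = l$b - eta * drop(g$b))
  }, params$layers, grad$layers)
  structure(list(layers = layers), arch = params_arch(params),
            class = "fcn_params")
}

#' Local training hyperparameters
#'
#' @param eta Learning rate (default 0.001).
#' @param epochs Local epochs per communication round, `E` (default 5).
#' @param batch_size Minibatch size `B` (default 10). Iterations per epoch is
#'   the derived `ceiling(n_train / B)`; the last short batch is kept.
#' @return A `train_config` object.
#' @export
train_config <- function(eta = 0.001, epochs = 5L, batch_size = 10L) {
  stopifnot(eta >= 0, epochs >= 0, batch_size >= 1)
  structure(list(eta = eta, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "train_config")
}

#' Flatten / restore network parameters
#'
#' `flatten_params` concatenates all weights and biases into one numeric
#' vector (layer by layer, weights column-major then biases);
#' `unflatten_params` inverts it given a template of the right shape. Used for
#' finite-difference checks and flat-file serialization.
#'
#' @param params,template `fcn_params` objects.
#' @param theta Numeric vector from `flatten_params`.
#' @return A numeric vector, or an `fcn_params`.
#' @export
flatten_params <- function(params) {
  unlist(lapply(params$layers, function(l) c(as.vector(l$W), l$b)))
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(theta, template) {
  pos <- 0L
  layers <- lapply(template$layers, function(l) {
    nw <- length(l$W); nb <- length(l$b)
    W <- matrix(theta[pos + seq_len(nw)], nrow(l$W), ncol(l$W))
    b <- theta[pos + nw + seq_len(nb)]
    pos <<- pos + nw + nb
    list(W = W, b = b)
  })
  structure(list(layers = layers), arch = params_arch(template),
            class = "fcn_params")
}

#' Serialize parameters to a flat structured file
#'
#' JSON with the architecture and layer-indexed weight/bias arrays; this is
#' the checkpoint format and the transport contract of the simulated
#' federation (clients exchange parameter copies, never data).
#'
#' @param params An `fcn_params`.
#' @param path File path.
#' @export
write_network_params <- function(params, path) {
  arch <- params_arch(params)
  obj <- list(
    widths = arch$widths, activation = arch$activation,
    layers = lapply(params$layers, function(l)
      list(W = l$W, b = l$b))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_network_params
#' @export
read_network_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  widths <- as.integer(unlist(obj$widths))
  arch <- network_architecture(widths[1], widths[-c(1, length(widths))],
                               obj$activation)
  w <- arch$widths
  # W was written column-major: unlist concatenates the stored columns
  layers <- lapply(seq_along(obj$layers), function(i) {
    list(W = matrix(as.numeric(unlist(obj$layers[[i]]$W)), w[i], w[i + 1]),
         b = as.numeric(unlist(obj$layers[[i]]$b)))
  })
  structure(list(layers = layers), arch = arch, class = "fcn_params")
}

# ---- fast internal training path -------------------------------------------
# Bias folded into an augmented weight matrix rbind(W, b); forward appends a
# ones column. Cuts per-step allocation roughly in half versus sweep().

augment_params <- function(params) {
  lapply(params$layers, function(l) rbind(l$W, l$b))
}

deaugment_params <- function(aug, template) {
  layers <- lapply(aug, function(M) {
    n <- nrow(M)
    list(W = M[-n, , drop = FALSE], b = drop(M[n, ]))
  })
  structure(list(layers = layers), arch = params_arch(template),
            class = "fcn_params")
}

forward_aug <- function(aug, X, activation) {
  L <- length(aug)
  A <- X
  for (l in seq_len(L)) {
    Z <- cbind(A, 1) %*% aug[[l]]
    A <- if (l < L) activate(Z, activation) else sigmoid(Z)
  }
  clip_prob(drop(A))
}

# Minibatch SGD for `epochs` passes; assumes the RNG is already seeded by the
# caller (one shuffle drawn per epoch). Returns updated augmented params and
# the mean minibatch loss per epoch.
train_epochs_aug <- function(aug, X, y, epochs, batch_size, eta, activation) {
  n <- nrow(X)
  L <- length(aug)
  relu <- activation == "relu"
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    tot_loss <- 0
    for (s in starts) {
      rows <- ord[s:min(s + batch_size - 1, n)]
      Xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      m <- length(rows)
      # forward
      Zs <- vector("list", L)
      As <- vector("list", L + 1)
      As[[1]] <- Xb
      for (l in seq_len(L)) {
        Zs[[l]] <- cbind(As[[l]], 1) %*% aug[[l]]
        As[[l + 1]] <- if (l < L) {
          if (relu) pmax(Zs[[l]], 0) else tanh(Zs[[l]])
        } else sigmoid(Zs[[l]])
      }
      p <- drop(As[[L + 1]])
      pc <- clip_prob(p)
      tot_loss <- tot_loss + m * -mean(yb * log(pc) + (1 - yb) * log(1 - pc))
      # backward + update; delta uses the raw sigmoid output, as in
      # network_gradient()
      delta <- matrix((p - yb) / m, ncol = 1)
      for (l in rev(seq_len(L))) {
        g <- crossprod(cbind(As[[l]], 1), delta)
        if (l > 1) {
          nr <- nrow(aug[[l]])
          back <- delta %*% t(aug[[l]][-nr, , drop = FALSE])
          delta <- if (relu) back * (Zs[[l - 1]] > 0)
                   else back * (1 - tanh(Zs[[l - 1]])^2)
        }
        aug[[l]] <- aug[[l]] - eta * g
      }
    }
    losses[e] <- tot_loss / n
  }
  list(aug = aug, losses = losses)
}
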