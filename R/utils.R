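# Internal helpers shared across modules.

#' Derive a reproducible child seed
#'
#' Folds an arbitrary sequence of integers and strings into a master seed with
#' a multiplicative congruential mix (modulus 2^31 - 1, multiplier 48271).
#' Folding is sequential, so `derive_seed(derive_seed(s, a), b)` equals
#' `derive_seed(s, a, b)`; callers rely on this to hand out per-client seed
#' bases that later expand to per-round seeds.
#'
#' @param seed Integer master seed.
#' @param ... Integers or character scalars mixed into the seed, in order.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "client", 1, "round", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  h <- abs(as.double(seed)) %% m
  for (p in list(...)) {
    v <- if (is.character(p)) utf8ToInt(p) else as.double(p)
    for (x in v) {
      if (!is.finite(x)) stop("seed components must be finite")
      h <- (h * 48271 + abs(x) + 1) %% m
    }
  }
  as.integer(h)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library functions do not clobber user randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Probability clipping bound used before any log(); keeps the loss finite and
# forward() output strictly inside (0, 1).
.PROB_EPS <- 1e-7

clip_prob <- function(p) pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)
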