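# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Row-wise log(exp(l1) + exp(l2)), stabilized.
lse2 <- function(logits) {
  m <- pmax(logits[, 1L], logits[, 2L])
  m + log(exp(logits[, 1L] - m) + exp(logits[, 2L] - m))
}

# Row-wise log(exp(l1) + exp(l2) + 1), i.e. the K+1-class partition with the
# synthetic-class logit fixed at 0.
lse3 <- function(logits) {
  m <- pmax(logits[, 1L], logits[, 2L], 0)
  m + log(exp(logits[, 1L] - m) + exp(logits[, 2L] - m) + exp(-m))
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

leaky_relu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)

leaky_relu_grad <- function(x, slope) (x > 0) + slope * (x <= 0)

stop_oncosgan <- function(...) stop(..., call. = FALSE)

assert_matrix_like <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_oncosgan(what, " must be a numeric matrix")
  }
}

# Format doubles so that as.numeric() recovers them bitwise (17 significant
# digits are sufficient for IEEE-754 binary64).
format_exact <- function(x) sprintf("%.17g", x)
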