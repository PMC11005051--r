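# Internal helpers: condition classes, numeric utilities.

hpcm_stop <- function(msg, class = "hpcm_error", call. = FALSE) {
  stop(structure(
    class = c(class, "hpcm_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

usage_error      <- function(msg) hpcm_stop(msg, "hpcm_usage_error")
schema_error     <- function(msg) hpcm_stop(msg, "hpcm_schema_error")
validation_error <- function(msg) hpcm_stop(msg, "hpcm_validation_error")
contract_error   <- function(msg) hpcm_stop(msg, "hpcm_contract_error")
numerical_error  <- function(msg) hpcm_stop(msg, "hpcm_numerical_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg, class = "hpcm_validation_error") {
  if (!isTRUE(cond)) hpcm_stop(msg, class)
  invisible(TRUE)
}

# Per-vector standardization (mean 0, variance 1, population denominator)
# with a small epsilon guarding constant vectors.
standardize <- function(x, eps = 1e-8) {
  m <- mean(x)
  v <- mean((x - m)^2)
  (x - m) / sqrt(v + eps)
}

# Backward pass of standardize: given y = (x - mu)/sigma and upstream dy,
# returns dx. sigma is taken from the forward cache.
standardize_backward <- function(dy, y, sigma) {
  (dy - mean(dy) - y * mean(dy * y)) / sigma
}

softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable log(1 + exp(x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Seeded RNG scoping: evaluates expr with the given seed, restoring the
# caller's RNG state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483629)
}

is_binary_vector <- function(x) all(x %in% c(0, 1))

full_precision <- function(x) formatC(x, format = "g", digits = 17)
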