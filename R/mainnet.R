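# The per-target QSAR main network: a small feed-forward net whose full
# parameter vector theta is emitted by the hypernetwork. The schema defines
# the flattening/reshaping contract between the flat theta and the layers.

#' Specify the QSAR main network architecture
#'
#' @param layer_dims integer vector `[d_x, h_1, ..., 1]`: drug-embedding
#'   input dimension, at least one hidden width, scalar output.
#' @param activation hidden activation, `"relu"` or `"linear"`.
#' @param output_activation `"identity"` (regression) or `"sigmoid"`
#'   (classification probability).
#' @return An object of class `main_net_spec`.
#' @export
main_net_spec <- function(layer_dims, activation = c("relu", "linear"),
                          output_activation = c("identity", "sigmoid")) {
  activation <- match.arg(activation)
  output_activation <- match.arg(output_activation)
  layer_dims <- as.integer(layer_dims)
  assert_that(length(layer_dims) >= 3,
              "layer_dims must contain input, at least one hidden, and output dims")
  assert_that(all(layer_dims >= 1), "layer dimensions must be positive")
  assert_that(layer_dims[length(layer_dims)] == 1L,
              "the QSAR net emits a scalar prediction")
  structure(list(layer_dims = layer_dims, activation = activation,
                 output_activation = output_activation),
            class = "main_net_spec")
}

#' Enumerate the parameter schema of a main network
#'
#' Lists every weight matrix and bias vector of the QSAR net in a fixed
#' order (W then b, first layer to last) with shapes and fan-in; this order
#' plus row-major reshaping defines the contract between the hypernetwork's
#' flat output vector and the main network's layers.
#'
#' @param main_spec a [main_net_spec()].
#' @return An object of class `param_schema`: list of entries
#'   `(name, shape, fan_in, size, offset)` plus `total_count`.
#' @export
build_param_schema <- function(main_spec) {
  dims <- main_spec$layer_dims
  entries <- list()
  offset <- 0L
  for (l in seq_len(length(dims) - 1)) {
    d_in <- dims[l]; d_out <- dims[l + 1]
    for (kind in c("W", "b")) {
      shape <- if (kind == "W") c(d_out, d_in) else d_out
      size <- prod(shape)
      entries[[length(entries) + 1]] <- list(
        name = paste0(kind, l), kind = kind, layer = l,
        shape = shape, fan_in = d_in, size = as.integer(size),
        offset = offset)
      offset <- offset + as.integer(size)
    }
  }
  structure(list(entries = entries, total_count = offset,
                 n_layers = length(dims) - 1L),
            class = "param_schema")
}

#' @export
print.param_schema <- function(x, ...) {
  cat(sprintf("<param_schema> %d entries, total_count %d\n",
              length(x$entries), x$total_count))
  invisible(x)
}

#' Reshape a flat parameter vector into per-layer matrices
#'
#' Inverse of [flatten_params()]: slices the flat vector in schema order and
#' reshapes weight slices row-major (byrow), so `flatten_params(distribute(v))`
#' is the identity.
#'
#' @param flat numeric vector of length `schema$total_count`.
#' @param schema a [build_param_schema()] schema.
#' @return named list of weight matrices and bias vectors.
#' @export
distribute <- function(flat, schema) {
  if (length(flat) != schema$total_count) {
    validation_error(sprintf("flat vector has length %d, schema expects %d",
                             length(flat), schema$total_count))
  }
  out <- list()
  for (e in schema$entries) {
    v <- flat[e$offset + seq_len(e$size)]
    out[[e$name]] <- if (e$kind == "W") {
      matrix(v, nrow = e$shape[1], ncol = e$shape[2], byrow = TRUE)
    } else v
  }
  out
}

#' Flatten per-layer parameters back into a single vector
#' @param params named list as produced by [distribute()].
#' @param schema the same schema.
#' @return numeric vector of length `schema$total_count`.
#' @export
flatten_params <- function(params, schema) {
  flat <- numeric(schema$total_count)
  for (e in schema$entries) {
    v <- params[[e$name]]
    flat[e$offset + seq_len(e$size)] <- if (e$kind == "W") as.vector(t(v)) else v
  }
  flat
}

# forward pass with cache; X is m x d_x
qsar_forward_cache <- function(X, params, main_spec) {
  dims <- main_spec$layer_dims
  L <- length(dims) - 1
  A <- X
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    W <- params[[paste0("W", l)]]
    b <- params[[paste0("b", l)]]
    Z <- A %*% t(W) + matrix(b, nrow(A), length(b), byrow = TRUE)
    caches[[l]] <- list(A_in = A, Z = Z)
    if (l < L && main_spec$activation == "relu") {
      A <- relu(Z)
    } else {
      A <- Z
    }
  }
  z_out <- drop(A)
  pred <- if (main_spec$output_activation == "sigmoid") sigmoid(z_out) else z_out
  list(pred = pred, z_out = z_out, caches = caches)
}

# backward: dz_out is gradient w.r.t. final pre-activation (length m)
qsar_backward <- function(dz_out, fw, params, main_spec, want_dx = FALSE) {
  dims <- main_spec$layer_dims
  L <- length(dims) - 1
  dA <- matrix(dz_out, ncol = 1)
  grads <- list()
  for (l in rev(seq_len(L))) {
    cache <- fw$caches[[l]]
    dZ <- if (l < L && main_spec$activation == "relu") {
      dA * (cache$Z > 0)
    } else dA
    W <- params[[paste0("W", l)]]
    grads[[paste0("W", l)]] <- crossprod(dZ, cache$A_in)
    grads[[paste0("b", l)]] <- colSums(dZ)
    dA <- dZ %*% W
  }
  if (want_dx) list(grads = grads, dX = dA) else list(grads = grads)
}

#' Run the QSAR main network forward
#'
#' Standard feed-forward pass with the spec's hidden activation and output
#' activation (identity for regression, sigmoid for classification).
#'
#' @param x numeric drug embedding (length `d_x`) or an `m x d_x` matrix.
#' @param params per-layer parameters from [distribute()].
#' @param main_spec a [main_net_spec()].
#' @return numeric prediction(s), one per input row.
#' @export
qsar_forward <- function(x, params, main_spec) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != main_spec$layer_dims[1]) {
    validation_error(sprintf("input has %d columns, main net expects %d",
                             ncol(x), main_spec$layer_dims[1]))
  }
  qsar_forward_cache(x, params, main_spec)$pred
}
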