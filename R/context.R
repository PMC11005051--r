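# Modern-Hopfield-Network context module. A target embedding t is enriched
# against the memory of the T unique training-target embeddings:
#
#   t' = LN( V^T softmax( beta * (C_k Wk^T) (Wq LN(t)) ) )
#
# where C_k are the LayerNorm-ed memory rows, Wq/Wk (and optionally Wv) are
# trainable projections into an association space of dimension d_a, and beta
# is the inverse-temperature scale. With one memory row the softmax is
# degenerate and retrieval returns the (normalized transform of the) row;
# as beta grows the retrieval sharpens toward the best-matching row.

#' Build the Hopfield context memory from training targets
#'
#' The memory holds the unique training-target embeddings, each LayerNorm-
#' standardized (mean 0, variance 1 per row), ordered by sorted id. The
#' memory must be built from the training fold only; validation/test targets
#' in the memory would leak zero-shot information.
#'
#' @param target_store an [embedding_store()].
#' @param train_target_ids character vector of training target ids
#'   (duplicates tolerated and removed).
#' @return An object of class `context_memory` with fields `C` (T x d
#'   standardized matrix) and `ids`.
#' @export
build_context <- function(target_store, train_target_ids) {
  ids <- sort(unique(as.character(train_target_ids)))
  assert_that(length(ids) >= 1, "train_target_ids must be non-empty")
  emb <- get_embeddings(target_store, ids)
  C <- t(apply(emb, 1, standardize))
  if (ncol(emb) == 1) C <- matrix(C, ncol = 1)  # apply() drops dims
  rownames(C) <- ids
  structure(list(C = C, ids = ids, dim = ncol(C)), class = "context_memory")
}

#' @export
print.context_memory <- function(x, ...) {
  cat(sprintf("<context_memory> T=%d targets, dim %d\n", length(x$ids), x$dim))
  invisible(x)
}

#' Initialize trainable Hopfield parameters
#'
#' @param d embedding dimension of targets and memory rows.
#' @param d_a association-space dimension (default `d`).
#' @param beta softmax inverse temperature; default `1/sqrt(d_a)`.
#' @param use_value_proj if `TRUE` a trainable value projection `Wv` is
#'   applied to memory rows; default `FALSE` (rows used directly as values).
#' @param seed integer seed for the projection init.
#' @return A named list of parameter arrays plus a `spec` attribute.
#' @export
hopfield_params <- function(d, d_a = d, beta = 1 / sqrt(d_a),
                            use_value_proj = FALSE, seed = 1L) {
  assert_that(beta > 0, "beta must be positive")
  p <- with_seed(seed, {
    p <- list(
      Wq = matrix(stats::rnorm(d_a * d, sd = sqrt(1 / d)), d_a, d),
      Wk = matrix(stats::rnorm(d_a * d, sd = sqrt(1 / d)), d_a, d),
      ln_t_g = rep(1, d), ln_t_b = rep(0, d),
      ln_m_g = rep(1, d), ln_m_b = rep(0, d),
      ln_o_g = rep(1, d), ln_o_b = rep(0, d))
    if (use_value_proj) {
      p$Wv <- matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d)
    }
    p
  })
  attr(p, "spec") <- list(d = d, d_a = d_a, beta = beta,
                          use_value_proj = use_value_proj)
  p
}

# identity-map parameters, used by tests and the retrieval-limit analysis
hopfield_params_identity <- function(d, beta = 1) {
  p <- list(Wq = diag(d), Wk = diag(d),
            ln_t_g = rep(1, d), ln_t_b = rep(0, d),
            ln_m_g = rep(1, d), ln_m_b = rep(0, d),
            ln_o_g = rep(1, d), ln_o_b = rep(0, d))
  attr(p, "spec") <- list(d = d, d_a = d, beta = beta, use_value_proj = FALSE)
  p
}

# forward pass with cache for backprop
enrich_forward <- function(t_vec, memory, params) {
  spec <- attr(params, "spec")
  d <- ncol(memory$C)
  assert_that(length(t_vec) == d,
              sprintf("target embedding has length %d, memory dim is %d",
                      length(t_vec), d))
  ts <- standardize(t_vec)
  q_in <- params$ln_t_g * ts + params$ln_t_b
  M <- sweep(sweep(memory$C, 2, params$ln_m_g, `*`), 2, params$ln_m_b, `+`)
  q <- drop(params$Wq %*% q_in)                      # d_a
  Kp <- M %*% t(params$Wk)                           # T x d_a
  s <- spec$beta * drop(Kp %*% q)                    # T
  a <- softmax(s)
  V <- if (spec$use_value_proj) M %*% t(params$Wv) else M  # T x d
  u <- drop(crossprod(V, a))                         # d
  sd_u <- sqrt(mean((u - mean(u))^2) + 1e-8)
  us <- (u - mean(u)) / sd_u
  out <- params$ln_o_g * us + params$ln_o_b
  list(out = out, weights = a,
       cache = list(t_vec = t_vec, ts = ts, sd_t = sqrt(mean((t_vec - mean(t_vec))^2) + 1e-8),
                    q_in = q_in, M = M, q = q, Kp = Kp, a = a, V = V,
                    u = u, us = us, sd_u = sd_u, spec = spec))
}

# backward pass: upstream gradient d_out -> gradients for all params and t
enrich_backward <- function(d_out, cache, params, memory) {
  spec <- cache$spec
  g <- list()
  g$ln_o_g <- d_out * cache$us
  g$ln_o_b <- d_out
  dus <- d_out * params$ln_o_g
  du <- standardize_backward(dus, cache$us, cache$sd_u)
  # u = V^T a
  da <- drop(cache$V %*% du)                         # T
  dV <- outer(cache$a, du)                           # T x d
  # softmax backward
  ds <- cache$a * (da - sum(da * cache$a))
  dKp_q <- spec$beta * ds                            # T
  dq <- drop(crossprod(cache$Kp, dKp_q))             # d_a
  dKp <- outer(dKp_q, cache$q)                       # T x d_a
  g$Wk <- crossprod(dKp, cache$M)                    # d_a x d
  dM_k <- dKp %*% params$Wk                          # T x d
  if (spec$use_value_proj) {
    g$Wv <- crossprod(dV, cache$M)
    dM_v <- dV %*% params$Wv
  } else {
    dM_v <- dV
  }
  dM <- dM_k + dM_v
  g$ln_m_g <- drop(colSums(dM * memory$C))
  g$ln_m_b <- colSums(dM)
  g$Wq <- outer(dq, cache$q_in)
  dq_in <- drop(crossprod(params$Wq, dq))
  g$ln_t_g <- dq_in * cache$ts
  g$ln_t_b <- dq_in
  dts <- dq_in * params$ln_t_g
  dt <- standardize_backward(dts, cache$ts, cache$sd_t)
  list(grads = g, dt = dt)
}

#' Enrich a target embedding against the context memory
#'
#' Retrieves an updated target embedding as the normalized, attention-
#' weighted combination of the memory rows (softmax over `beta`-scaled
#' key-query similarities). Output dimension equals the input dimension.
#'
#' @param t numeric target embedding of length `memory$dim`.
#' @param memory a [build_context()] memory.
#' @param params [hopfield_params()].
#' @param residual if `TRUE`, average the enriched embedding with the
#'   standardized input instead of replacing it (off by default).
#' @return numeric enriched embedding `t'`.
#' @export
enrich <- function(t, memory, params, residual = FALSE) {
  fw <- enrich_forward(t, memory, params)
  if (residual) {
    (fw$out + standardize(t)) / 2
  } else {
    fw$out
  }
}

#' Hopfield attention weights over the memory rows
#'
#' Inspection hook on the same computation as [enrich()]: the softmax
#' distribution over the T memory rows. Non-negative and sums to 1.
#'
#' @inheritParams enrich
#' @return numeric simplex vector of length T, named by memory ids.
#' @export
attention_weights <- function(t, memory, params) {
  w <- enrich_forward(t, memory, params)$weights
  names(w) <- memory$ids
  w
}
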