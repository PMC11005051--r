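# Minimal concatenation-FCN comparator: a plain feed-forward network on the
# concatenated drug and target embeddings, trained with the same losses and
# Adam. This is the classical PCM fusion baseline the hypernetwork approach
# is compared against; it is used by the acceptance suite.

.fcn_init <- function(dims, seed) {
  with_seed(seed, {
    lapply(seq_len(length(dims) - 1), function(l) {
      fan_in <- dims[l]
      v <- if (l == 1) 1 / fan_in else 2 / fan_in
      list(W = matrix(stats::rnorm(dims[l + 1] * fan_in, sd = sqrt(v)),
                      dims[l + 1], fan_in),
           b = rep(0, dims[l + 1]))
    })
  })
}

.fcn_forward <- function(X, layers) {
  L <- length(layers)
  A <- X
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- A %*% t(layers[[l]]$W) +
      matrix(layers[[l]]$b, nrow(A), length(layers[[l]]$b), byrow = TRUE)
    caches[[l]] <- list(A_in = A, Z = Z)
    A <- if (l < L) relu(Z) else Z
  }
  list(z = drop(A), caches = caches)
}

.fcn_backward <- function(dz, fw, layers) {
  L <- length(layers)
  dA <- matrix(dz, ncol = 1)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    cache <- fw$caches[[l]]
    dZ <- if (l < L) dA * (cache$Z > 0) else dA
    grads[[l]] <- list(W = crossprod(dZ, cache$A_in), b = colSums(dZ))
    dA <- dZ %*% layers[[l]]$W
  }
  grads
}

#' Train the concatenation-FCN baseline
#'
#' @param table an [interaction_table()].
#' @param split a [split_spec()]; trains on the training fold.
#' @param config a [train_config()] (loss, lr, max_epochs, seed are used;
#'   batching is plain minibatch over interactions of size
#'   `meta_batch_size * mini_batch_size`).
#' @param drug_store,target_store [embedding_store()] objects.
#' @param hidden integer vector of hidden widths (default 64).
#' @return list with `predict(drug_ids, target_ids)` closure, `layers`, and
#'   `history` of training losses.
#' @export
baseline_concat_fcn <- function(table, split, config, drug_store, target_store,
                                hidden = 64L) {
  check_loss_labels(config$loss, table)
  cov <- validate_coverage(table, drug_store, target_store)
  if (!cov$ok) validation_error("embeddings missing for some table ids")
  idx <- split$train_idx
  X <- cbind(get_embeddings(drug_store, table$drug_id[idx]),
             get_embeddings(target_store, table$target_id[idx]))
  y <- table$label[idx]
  dims <- c(ncol(X), hidden, 1L)
  layers <- .fcn_init(dims, derive_seed(config$seed, 17L))
  lf <- loss_fn(config$loss)
  opt <- adam_init(layers)
  bs <- config$meta_batch_size * config$mini_batch_size
  losses <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- with_seed(derive_seed(config$seed, 3000L + epoch),
                      sample(seq_len(nrow(X))))
    epoch_loss <- 0; nb <- 0
    for (start in seq(1, length(perm), by = bs)) {
      rows <- perm[start:min(start + bs - 1, length(perm))]
      fw <- .fcn_forward(X[rows, , drop = FALSE], layers)
      epoch_loss <- epoch_loss + mean(lf$value(fw$z, y[rows])); nb <- nb + 1
      dz <- lf$dz(fw$z, y[rows]) / length(rows)
      grads <- .fcn_backward(dz, fw, layers)
      st <- adam_step(layers, grads, opt, config$lr)
      layers <- st$params; opt <- st$state
    }
    losses <- c(losses, epoch_loss / nb)
    if (!is.finite(losses[epoch])) numerical_error("NaN loss in baseline training")
  }
  sigmoid_out <- config$loss == "bce"
  predict_fn <- function(drug_ids, target_ids) {
    Xp <- cbind(get_embeddings(drug_store, drug_ids),
                get_embeddings(target_store, target_ids))
    z <- .fcn_forward(Xp, layers)$z
    if (sigmoid_out) sigmoid(z) else z
  }
  list(predict = predict_fn, layers = layers, history = losses)
}
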