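# Episodic end-to-end training: meta-batches of protein targets, each paired
# with a mini-batch of its drugs; oversampling of underrepresented targets;
# Adam with plateau learning-rate decay and early stopping on validation
# performance. Sampling applies to training only -- validation and test are
# always evaluated on the unmodified fold.

#' Training configuration
#'
#' @param loss `"l1"`, `"mse"` (continuous labels) or `"bce"` (binary).
#' @param meta_batch_size targets per gradient step.
#' @param mini_batch_size drugs sampled per target (with replacement iff a
#'   target has fewer drugs available).
#' @param min_drugs_per_target oversampling floor: targets with fewer
#'   training interactions are duplicated in the epoch roster until their
#'   drawn-drug total reaches this count.
#' @param lr,lr_decay,lr_patience,lr_floor Adam learning rate and plateau
#'   schedule: multiply by `lr_decay` when validation loss fails to improve
#'   for `lr_patience` epochs, never below `lr_floor`.
#' @param max_epochs epoch cap.
#' @param early_stop_patience stop when the validation metric (concordance
#'   index for regression, MCC for classification) fails to improve for this
#'   many epochs.
#' @param val_fraction fallback: when the split has an empty validation
#'   fold, this fraction of training interactions is carved out for
#'   validation (within-training, so no held-out entity is touched).
#' @param threshold activity threshold used for classification metrics when
#'   training on continuous labels.
#' @param seed integer.
#' @return An object of class `train_config`.
#' @export
train_config <- function(loss = c("l1", "mse", "bce"),
                         meta_batch_size = 8L, mini_batch_size = 16L,
                         min_drugs_per_target = 8L,
                         lr = 0.01, lr_decay = 0.5, lr_patience = 5L,
                         lr_floor = 1e-6,
                         max_epochs = 200L, early_stop_patience = 25L,
                         val_fraction = 0.1, threshold = 6.5, seed = 1L) {
  loss <- match.arg(loss)
  assert_that(meta_batch_size >= 1 && mini_batch_size >= 1 &&
                min_drugs_per_target >= 1, "batch sizes must be >= 1")
  assert_that(lr > 0 && lr_decay > 0 && lr_decay <= 1, "invalid lr schedule")
  structure(list(loss = loss, meta_batch_size = as.integer(meta_batch_size),
                 mini_batch_size = as.integer(mini_batch_size),
                 min_drugs_per_target = as.integer(min_drugs_per_target),
                 lr = lr, lr_decay = lr_decay,
                 lr_patience = as.integer(lr_patience), lr_floor = lr_floor,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, threshold = threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

check_loss_labels <- function(loss, table) {
  kind <- label_kind(table)
  if (loss == "bce" && kind != "binary") {
    contract_error("bce loss requires binary labels")
  }
  if (loss %in% c("l1", "mse") && kind != "continuous") {
    contract_error(sprintf("%s loss requires continuous labels", loss))
  }
  invisible(TRUE)
}

# loss value and gradient w.r.t. the final pre-activation, per element;
# division by the total pair count happens at the call site
loss_fn <- function(loss) {
  switch(loss,
         l1 = list(value = function(z, y) abs(z - y),
                   dz = function(z, y) sign(z - y)),
         mse = list(value = function(z, y) (z - y)^2,
                    dz = function(z, y) 2 * (z - y)),
         bce = list(value = function(z, y) softplus(z) - y * z,
                    dz = function(z, y) sigmoid(z) - y))
}

#' Build the episodic batch sequence for one epoch
#'
#' Each meta-batch holds up to `meta_batch_size` roster entries (the last
#' may be short); each entry names a training target and exactly
#' `mini_batch_size` of its training interaction rows, drawn with
#' replacement iff the target has fewer available. Targets with fewer than
#' `min_drugs_per_target` interactions appear multiple times in the epoch
#' roster (oversampling). Fully determined by `epoch_seed`.
#'
#' @param table an [interaction_table()].
#' @param split a [split_spec()]; only the training fold is sampled.
#' @param config a [train_config()].
#' @param epoch_seed integer.
#' @return list of meta-batches; each is a list of
#'   `(target_id, row_idx)` entries (row indices into `table`).
#' @export
make_meta_batches <- function(table, split, config, epoch_seed) {
  idx <- split$train_idx
  assert_that(length(idx) > 0, "training fold is empty")
  by_target <- split(idx, table$target_id[idx])
  counts <- lengths(by_target)
  if (any(counts == 0)) {
    warning("targets with zero training interactions excluded: ",
            paste(names(by_target)[counts == 0], collapse = ", "))
    by_target <- by_target[counts > 0]
    counts <- counts[counts > 0]
  }
  dup <- pmax(1L, ceiling(config$min_drugs_per_target / counts))
  roster <- rep(names(by_target), dup)
  with_seed(epoch_seed, {
    roster <- sample(roster)
    entries <- lapply(roster, function(tid) {
      rows <- by_target[[tid]]
      replace <- length(rows) < config$mini_batch_size
      list(target_id = tid,
           row_idx = sample(rows, config$mini_batch_size, replace = replace))
    })
    n_meta <- ceiling(length(entries) / config$meta_batch_size)
    lapply(seq_len(n_meta), function(m) {
      i0 <- (m - 1L) * config$meta_batch_size
      entries[(i0 + 1L):min(i0 + config$meta_batch_size, length(entries))]
    })
  })
}

# one meta-batch: average loss over all target x drug pairs, full gradients
.batch_loss_grads <- function(model, batch, table, drug_store, target_store,
                              lf, train = TRUE) {
  n_pairs <- sum(vapply(batch, function(e) length(e$row_idx), integer(1)))
  total <- 0
  grads <- NULL
  for (e in batch) {
    t_vec <- drop(get_embeddings(target_store, e$target_id))
    X <- get_embeddings(drug_store, table$drug_id[e$row_idx])
    y <- table$label[e$row_idx]
    fw <- model_forward(model, t_vec, X, train = train)
    total <- total + sum(lf$value(fw$z_out, y))
    dz <- lf$dz(fw$z_out, y) / n_pairs
    g <- model_backward(model, fw, dz)
    grads <- if (is.null(grads)) g else nested_map2(grads, g, `+`)
  }
  list(loss = total / n_pairs, grads = grads)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nested_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nested_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- nested_map2(state$m, state$v,
                     function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  list(params = nested_map2(params, upd, `-`), state = state)
}

.val_metric <- function(model, y, scores, config) {
  if (model$task == "classification") {
    thr <- if (is_binary_vector(y)) 0.5 else config$threshold
    mcc(as.numeric(y >= thr), as.numeric(scores >= 0.5))
  } else {
    tryCatch(concordance_index(y, scores), hpcm_error = function(e) NA_real_)
  }
}

#' Train a hypernetwork-PCM model end to end
#'
#' Builds the context memory from the training-fold targets (never from
#' validation/test), initializes via PWI with measured `var_t`, then runs
#' episodic Adam training. Each gradient step averages the loss over all
#' target x drug pairs of one meta-batch. Learning rate halves (by
#' `lr_decay`) when validation loss plateaus; training stops early when the
#' validation metric (CI for regression, MCC for classification) stops
#' improving; the returned model is the best-validation checkpoint.
#'
#' @param model an [hpcm_model()] (uninitialized is fine).
#' @param table an [interaction_table()].
#' @param split a [split_spec()].
#' @param config a [train_config()].
#' @param drug_store,target_store [embedding_store()] objects covering the
#'   table.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint), `history` (per-epoch data
#'   frame), `best_epoch`.
#' @export
train_hpcm <- function(model, table, split, config, drug_store, target_store,
                       verbose = FALSE) {
  check_loss_labels(config$loss, table)
  cov <- validate_coverage(table, drug_store, target_store)
  if (!cov$ok) {
    validation_error(sprintf(
      "embeddings missing for %d drug(s), %d target(s)",
      length(cov$missing_drugs), length(cov$missing_targets)))
  }
  train_targets <- unique(table$target_id[split$train_idx])
  if (is.null(model$memory) || is.null(model$hyper_state)) {
    model <- init_model(model, target_store, train_targets)
  }
  assert_that(setequal(model$memory$ids, train_targets),
              "context memory must hold exactly the training-fold targets")
  val_idx <- split$val_idx
  if (length(val_idx) == 0) {
    n_val <- max(1L, round(config$val_fraction * length(split$train_idx)))
    val_idx <- with_seed(derive_seed(config$seed, 7L),
                         sample(split$train_idx, n_val))
  }
  lf <- loss_fn(config$loss)
  params <- model_params(model)
  opt <- adam_init(params)
  lr <- config$lr
  history <- data.frame()
  # checkpoint selection follows validation loss (smooth); the stopping rule
  # follows the validation metric (CI / MCC), which is noisier on small
  # zero-shot validation folds
  best <- list(loss = Inf, metric = -Inf, params = params, epoch = 0L)
  val_loss_best <- Inf; lr_wait <- 0L; es_wait <- 0L
  y_val <- table$label[val_idx]
  for (epoch in seq_len(config$max_epochs)) {
    batches <- make_meta_batches(table, split, config,
                                 derive_seed(config$seed, epoch))
    epoch_loss <- 0
    for (b in seq_along(batches)) {
      model <- model_set_params(model, params)
      bl <- with_seed(derive_seed(config$seed, epoch * 10000L + b),
                      .batch_loss_grads(model, batches[[b]], table,
                                        drug_store, target_store, lf))
      if (!is.finite(bl$loss)) {
        numerical_error(sprintf("NaN/Inf training loss at epoch %d batch %d",
                                epoch, b))
      }
      epoch_loss <- epoch_loss + bl$loss
      st <- adam_step(params, bl$grads, opt, lr)
      params <- st$params; opt <- st$state
    }
    epoch_loss <- epoch_loss / length(batches)
    model <- model_set_params(model, params)
    val_scores <- predict_pairs(model, table$drug_id[val_idx],
                                table$target_id[val_idx],
                                drug_store, target_store)
    zs <- if (model$task == "classification") {
      pmin(pmax(val_scores, 1e-12), 1 - 1e-12)
    } else val_scores
    val_loss <- if (config$loss == "bce") {
      mean(-(y_val * log(zs) + (1 - y_val) * log(1 - zs)))
    } else {
      mean(lf$value(val_scores, y_val))
    }
    val_metric <- .val_metric(model, y_val, val_scores, config)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss, val_loss = val_loss,
      val_metric = val_metric, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  metric %.4f  lr %.2g",
                      epoch, epoch_loss, val_loss, val_metric, lr))
    }
    # plateau decay on validation loss
    if (is.finite(val_loss) && val_loss < val_loss_best - 1e-8) {
      val_loss_best <- val_loss; lr_wait <- 0L
    } else {
      lr_wait <- lr_wait + 1L
      if (lr_wait > config$lr_patience) {
        lr <- max(lr * config$lr_decay, config$lr_floor)
        lr_wait <- 0L
      }
    }
    if (is.finite(val_loss) && val_loss < best$loss - 1e-8) {
      best$loss <- val_loss; best$params <- params; best$epoch <- epoch
    }
    # early stopping on validation metric
    if (!is.na(val_metric) && val_metric > best$metric + 1e-8) {
      best$metric <- val_metric
      es_wait <- 0L
    } else {
      es_wait <- es_wait + 1L
      if (es_wait > config$early_stop_patience) break
    }
  }
  model <- model_set_params(model, best$params)
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Evaluate a trained model on one fold
#'
#' Predicts every pair of the fold (no sampling, so the data distribution is
#' untouched) and computes the requested metrics; continuous tasks are
#' additionally thresholded for the classification metrics.
#'
#' @param model a trained [hpcm_model()].
#' @param table the [interaction_table()].
#' @param fold_idx integer row indices of the fold to score.
#' @param metrics character vector, see [compute_metrics()].
#' @param threshold activity threshold for classification metrics on
#'   continuous labels.
#' @param drug_store,target_store [embedding_store()] objects.
#' @return A metrics report: named list of values plus `n`.
#' @export
evaluate_model <- function(model, table, fold_idx,
                           metrics = c("mcc", "auc", "ci", "mse", "mae"),
                           threshold = 6.5, drug_store, target_store) {
  assert_that(length(fold_idx) > 0, "fold is empty")
  scores <- predict_pairs(model, table$drug_id[fold_idx],
                          table$target_id[fold_idx], drug_store, target_store)
  if (label_kind(table) == "binary") {
    bad <- intersect(metrics, c("mse", "mae", "ci"))
    if (length(bad) && !all(table$label[fold_idx] %in% 0:1)) {
      contract_error("regression metrics on binary labels")
    }
  }
  compute_metrics(table$label[fold_idx], scores, metrics,
                  threshold = threshold)
}
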