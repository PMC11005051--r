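# Episodic training: batching contracts, oversampling, determinism,
# optimization sanity, leakage audit, evaluation conventions.

small_world <- function(seed = 7, n_targets = 10, n_drugs = 12, d = 6,
                        noise_sd = 0) {
  syn <- generate_synth(synth_config(n_targets = n_targets, n_drugs = n_drugs,
                                     d_target = d, d_drug = d,
                                     noise_sd = noise_sd, seed = seed))
  spec <- split_entity_holdout(syn$table, "target", c(0.7, 0.15, 0.15),
                               seed = seed)
  list(syn = syn, spec = spec)
}

test_that("meta-batches: replacement pigeonhole, distinct draws, determinism", {
  # one target with 2 drugs, one with 100
  tab <- interaction_table(
    c("Da", "Db", sprintf("D%03d", 1:100)),
    c("T1", "T1", rep("T2", 100)),
    rnorm(102))
  spec <- split_spec(seq_len(102), integer(0), integer(0), "random", 1L)
  cfg <- train_config(meta_batch_size = 2, mini_batch_size = 8,
                      min_drugs_per_target = 1)
  mb <- make_meta_batches(tab, spec, cfg, epoch_seed = 3)
  entries <- unlist(mb, recursive = FALSE)
  by_tid <- split(entries, vapply(entries, `[[`, character(1), "target_id"))
  e1 <- by_tid$T1[[1]]
  expect_length(e1$row_idx, 8)
  expect_true(all(e1$row_idx %in% 1:2))        # replacement is forced
  expect_lt(length(unique(e1$row_idx)), 8)     # pigeonhole
  e2 <- by_tid$T2[[1]]
  expect_length(unique(e2$row_idx), 8)         # enough drugs: no replacement
  mb2 <- make_meta_batches(tab, spec, cfg, epoch_seed = 3)
  expect_identical(mb, mb2)
  expect_false(identical(mb, make_meta_batches(tab, spec, cfg, 4)))
})

test_that("oversampling floor duplicates scarce targets across the epoch", {
  tab <- interaction_table(
    c("Da", "Db", sprintf("D%03d", 1:30)),
    c("T1", "T1", rep("T2", 30)),
    rnorm(32))
  spec <- split_spec(seq_len(32), integer(0), integer(0), "random", 1L)
  cfg <- train_config(meta_batch_size = 4, mini_batch_size = 4,
                      min_drugs_per_target = 8)
  entries <- unlist(make_meta_batches(tab, spec, cfg, 1), recursive = FALSE)
  tids <- vapply(entries, `[[`, character(1), "target_id")
  # T1 has 2 interactions < floor 8 -> ceiling(8/2) = 4 roster entries
  expect_equal(sum(tids == "T1"), 4)
  expect_equal(sum(tids == "T2"), 1)
})

test_that("loss/label compatibility is enforced before training", {
  w <- small_world()
  cfg <- train_config(loss = "bce", max_epochs = 1)
  model <- hpcm_model(6, 6, task = "classification", seed = 1)
  expect_hpcm_error(
    train_hpcm(model, w$syn$table, w$spec, cfg, w$syn$drug_store,
               w$syn$target_store),
    "hpcm_contract_error")
  bin <- binarize_synth(w$syn$table, 0.5)
  cfg2 <- train_config(loss = "l1", max_epochs = 1)
  expect_hpcm_error(
    train_hpcm(model, bin, w$spec, cfg2, w$syn$drug_store,
               w$syn$target_store),
    "hpcm_contract_error")
})

test_that("training on noiseless task-linear data drives the loss down 10x", {
  w <- small_world(seed = 5, noise_sd = 0)
  cfg <- train_config(loss = "mse", lr = 0.01, max_epochs = 200,
                      early_stop_patience = 1000, lr_patience = 1000,
                      seed = 5)
  model <- hpcm_model(6, 6, main_hidden = 8, trunk_hidden = integer(0),
                      c_in = 24, main_activation = "linear", seed = 5)
  fit <- train_hpcm(model, w$syn$table, w$spec, cfg, w$syn$drug_store,
                    w$syn$target_store)
  expect_gt(fit$history$train_loss[1] / min(fit$history$train_loss), 10)
})

test_that("training is seed-deterministic (epoch-1 losses identical)", {
  w <- small_world(seed = 9)
  cfg <- train_config(loss = "l1", max_epochs = 2, seed = 4)
  run <- function() {
    model <- hpcm_model(6, 6, main_hidden = 4, trunk_hidden = 5L, c_in = 8L,
                        seed = 4)
    train_hpcm(model, w$syn$table, w$spec, cfg, w$syn$drug_store,
               w$syn$target_store)$history
  }
  h1 <- run(); h2 <- run()
  expect_identical(h1$train_loss, h2$train_loss)
})

test_that("early stopping: patience 0 with flat metric stops immediately", {
  w <- small_world(seed = 11, noise_sd = 0)
  # lr 0 freezes the model -> validation metric constant across epochs
  cfg <- train_config(loss = "mse", lr = 1e-12, max_epochs = 50,
                      early_stop_patience = 0, seed = 2)
  model <- hpcm_model(6, 6, seed = 2)
  fit <- train_hpcm(model, w$syn$table, w$spec, cfg, w$syn$drug_store,
                    w$syn$target_store)
  expect_lte(nrow(fit$history), 2)  # first epoch sets best, second triggers
})

test_that("context memory is built from training-fold targets only", {
  w <- small_world(seed = 3)
  cfg <- train_config(loss = "l1", max_epochs = 1, seed = 1)
  model <- hpcm_model(6, 6, seed = 1)
  fit <- train_hpcm(model, w$syn$table, w$spec, cfg, w$syn$drug_store,
                    w$syn$target_store)
  train_targets <- unique(w$syn$table$target_id[w$spec$train_idx])
  held_targets <- unique(w$syn$table$target_id[c(w$spec$val_idx,
                                                 w$spec$test_idx)])
  expect_setequal(fit$model$memory$ids, train_targets)
  expect_length(intersect(fit$model$memory$ids, held_targets), 0)
  # and the manifest records the audit trail
  expect_setequal(fit$model$manifest$context_ids, train_targets)
})

test_that("evaluate_model: perfect oracle, constant predictor, n bookkeeping", {
  w <- small_world(seed = 13)
  model <- init_model(hpcm_model(6, 6, seed = 1), w$syn$target_store,
                      unique(w$syn$table$target_id[w$spec$train_idx]))
  fold <- w$spec$test_idx
  # perfect oracle: overwrite predictions via a stub table where labels are
  # reproduced by construction -- instead check compute_metrics contract via
  # evaluate on real predictions and then the oracle path directly
  rep <- evaluate_model(model, w$syn$table, fold,
                        metrics = c("ci", "mse", "mcc", "auc"),
                        threshold = stats::median(w$syn$table$label),
                        drug_store = w$syn$drug_store,
                        target_store = w$syn$target_store)
  expect_equal(rep$n, length(fold))
  expect_true(rep$mse >= 0)
  oracle <- compute_metrics(w$syn$table$label[fold], w$syn$table$label[fold],
                            metrics = c("mcc", "auc", "ci", "mse"),
                            threshold = stats::median(w$syn$table$label))
  expect_equal(oracle$mcc, 1)
  expect_equal(oracle$auc, 1)
  expect_equal(oracle$ci, 1)
  expect_equal(oracle$mse, 0)
  expect_hpcm_error(
    evaluate_model(model, w$syn$table, integer(0),
                   drug_store = w$syn$drug_store,
                   target_store = w$syn$target_store))
})

test_that("baseline concat FCN trains, is deterministic, validates dims", {
  w <- small_world(seed = 21, noise_sd = 0)
  cfg <- train_config(loss = "mse", lr = 0.01, max_epochs = 20, seed = 3)
  b1 <- baseline_concat_fcn(w$syn$table, w$spec, cfg, w$syn$drug_store,
                            w$syn$target_store, hidden = 16L)
  b2 <- baseline_concat_fcn(w$syn$table, w$spec, cfg, w$syn$drug_store,
                            w$syn$target_store, hidden = 16L)
  expect_identical(b1$history, b2$history)
  expect_lt(b1$history[length(b1$history)], b1$history[1])
  p <- b1$predict(w$syn$table$drug_id[w$spec$test_idx],
                  w$syn$table$target_id[w$spec$test_idx])
  expect_length(p, length(w$spec$test_idx))
  # missing embedding coverage -> validation error
  small_ds <- embedding_store(w$syn$drug_store$matrix[1:3, ])
  expect_hpcm_error(
    baseline_concat_fcn(w$syn$table, w$spec, cfg, small_ds,
                        w$syn$target_store))
})

test_that("NaN loss aborts with a numerical diagnostic", {
  w <- small_world(seed = 23, noise_sd = 0)
  cfg <- train_config(loss = "mse", max_epochs = 5, seed = 2)
  model <- init_model(hpcm_model(6, 6, seed = 2), w$syn$target_store,
                      unique(w$syn$table$target_id[w$spec$train_idx]))
  model$ctx_params$Wq[1, 1] <- NaN  # poisoned state -> NaN forward pass
  err <- tryCatch(
    train_hpcm(model, w$syn$table, w$spec, cfg, w$syn$drug_store,
               w$syn$target_store),
    hpcm_numerical_error = identity)
  expect_s3_class(err, "hpcm_numerical_error")
  expect_match(conditionMessage(err), "epoch 1")
})
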