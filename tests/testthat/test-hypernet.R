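# Hypernetwork: PWI head variances, predicted-parameter moments, signal
# propagation, forward determinism, composition and caching contracts.

test_that("pwi weight-head std matches the closed form", {
  # d_in = 64, c_in = 128, var_t = 1, linear main net:
  # std(H) = sqrt(1 / (2 * 64 * 128))
  spec <- main_net_spec(c(64, 64, 1), activation = "linear")
  sch <- build_param_schema(spec)
  hspec <- hyper_net_spec(c(16, 128))
  st <- pwi_initialize(hspec, sch, var_t = 1, main_spec = spec, seed = 3)
  expect_equal(sd(st$heads$W1$H), sqrt(1 / (2 * 64 * 128)), tolerance = 0.02)
  # bias head: sqrt(1 / (2 * 128))
  expect_equal(sd(st$heads$b1$H), sqrt(1 / (2 * 128)), tolerance = 0.03)
  # relu gain doubles the variance on hidden weight heads, not the output
  spec_r <- main_net_spec(c(64, 64, 1), activation = "relu")
  st_r <- pwi_initialize(hspec, build_param_schema(spec_r), var_t = 1,
                         main_spec = spec_r, seed = 3)
  expect_equal(sd(st_r$heads$W1$H), sqrt(2 / (2 * 64 * 128)), tolerance = 0.02)
  expect_equal(sd(st_r$heads$W2$H), sqrt(1 / (2 * 64 * 128)), tolerance = 0.02)
  # head biases are zero; var_t must be positive
  expect_true(all(st$heads$W1$g == 0))
  expect_hpcm_error(pwi_initialize(hspec, sch, var_t = 0, main_spec = spec))
})

test_that("predicted parameter moments: mean ~0, Var(theta_W) ~ 1/(2 d_in)", {
  d_in <- 16; c_in <- 64
  spec <- main_net_spec(c(d_in, 8, 1), activation = "linear")
  sch <- build_param_schema(spec)
  hspec <- hyper_net_spec(c(d_in, c_in))
  # pool over many head inits x standard-normal embeddings (var_t = 1)
  set.seed(5)
  thetas_W1 <- unlist(lapply(1:60, function(s) {
    st <- pwi_initialize(hspec, sch, var_t = 1, main_spec = spec, seed = s)
    t_emb <- rnorm(d_in)
    flat <- hyper_forward(t_emb, st)
    flat[sch$entries[[1]]$offset + seq_len(sch$entries[[1]]$size)]
  }))
  expect_lt(abs(mean(thetas_W1)), 0.02)
  expect_equal(var(thetas_W1), 1 / (2 * d_in), tolerance = 0.2)
})

test_that("pwi keeps Var(out)/Var(in) in [0.5, 2] for depth 1-3; naive blows up", {
  set.seed(42)
  for (depth in 2:4) {  # 1-3 hidden/relu layers before the output
    r <- signal_ratio(depth, "pwi")
    expect_gt(r, 0.5)
    expect_lt(r, 2)
  }
  expect_gt(signal_ratio(4, "naive"), 2)
})

test_that("hyper_forward: zero state -> zeros, distinct inputs, batching", {
  spec <- main_net_spec(c(4, 3, 1))
  sch <- build_param_schema(spec)
  hspec <- hyper_net_spec(c(5, 6))
  st <- pwi_initialize(hspec, sch, var_t = 1, main_spec = spec, seed = 2)
  z <- st
  z$trunk <- lapply(z$trunk, function(l) list(W = l$W * 0, b = l$b * 0))
  z$heads <- lapply(z$heads, function(h) list(H = h$H, g = h$g * 0))
  expect_equal(hyper_forward(rnorm(5), z), numeric(sch$total_count))
  t1 <- rnorm(5); t2 <- rnorm(5)
  expect_false(identical(hyper_forward(t1, st), hyper_forward(t2, st)))
  expect_identical(hyper_forward(t1, st), hyper_forward(t1, st))
  B <- rbind(t1, t2)
  batched <- hyper_forward(B, st)
  expect_equal(unname(batched[1, ]), hyper_forward(t1, st))
  expect_equal(unname(batched[2, ]), hyper_forward(t2, st))
  expect_hpcm_error(hyper_forward(rnorm(4), st))
})

test_that("predict_pairs equals the explicit four-stage composition", {
  syn <- generate_synth(synth_config(n_targets = 6, n_drugs = 8,
                                     d_target = 4, d_drug = 4, seed = 13))
  model <- tiny_model()
  model <- init_model(model, syn$target_store, syn$target_store$ids[1:5])
  set.seed(1)
  rows <- sample(nrow(syn$table), 5)
  got <- predict_pairs(model, syn$table$drug_id[rows], syn$table$target_id[rows],
                       syn$drug_store, syn$target_store)
  for (k in seq_along(rows)) {
    i <- rows[k]
    t_vec <- drop(get_embeddings(syn$target_store, syn$table$target_id[i]))
    e <- enrich(t_vec, model$memory, model$ctx_params)
    flat <- hyper_forward(e, model$hyper_state)
    qp <- distribute(flat, model$schema)
    x <- drop(get_embeddings(syn$drug_store, syn$table$drug_id[i]))
    expect_equal(got[k], qsar_forward(x, qp, model$main_spec))
  }
  # same target, two drugs: cached flat params identical to two calls
  two <- predict_pairs(model, syn$drug_store$ids[1:2],
                       rep(model$memory$ids[1], 2),
                       syn$drug_store, syn$target_store)
  one_by_one <- vapply(1:2, function(j) {
    predict_pair(model, syn$drug_store$ids[j], model$memory$ids[1],
                 syn$drug_store, syn$target_store)
  }, numeric(1))
  expect_equal(two, one_by_one)
  expect_hpcm_error(predict_pair(model, syn$drug_store$ids[1], "T_unknown",
                                 syn$drug_store, syn$target_store))
})

test_that("end-to-end gradients match finite differences", {
  syn <- generate_synth(synth_config(n_targets = 6, n_drugs = 8,
                                     d_target = 4, d_drug = 4,
                                     noise_sd = 0, seed = 3))
  model <- tiny_model()
  model <- init_model(model, syn$target_store, syn$target_store$ids[1:5])
  t_vec <- drop(get_embeddings(syn$target_store, model$memory$ids[2]))
  X <- syn$drug_store$matrix[1:4, ]
  y <- syn$table$label[1:4]
  lf <- hyperpcm:::loss_fn("mse")
  loss_of <- function(m) {
    mean(lf$value(hyperpcm:::model_forward(m, t_vec, X)$z_out, y))
  }
  fw <- hyperpcm:::model_forward(model, t_vec, X)
  dz <- lf$dz(fw$z_out, y) / length(y)
  g <- hyperpcm:::model_backward(model, fw, dz)
  p <- hyperpcm:::model_params(model)
  gg <- list(ctx = g$ctx[names(p$ctx)],
             trunk = lapply(g$trunk, function(l) l[c("W", "b")]),
             heads = lapply(g$heads[names(p$heads)], function(h) h[c("H", "g")]))
  pv <- flatten_nested(p); gv <- flatten_nested(gg)
  set.seed(7)
  eps <- 1e-6
  for (i in sample(length(pv), 40)) {
    f <- function(delta) {
      v <- pv; v[i] <- v[i] + delta
      loss_of(hyperpcm:::model_set_params(model, relist_nested(v, p)))
    }
    fd <- (f(eps) - f(-eps)) / (2 * eps)
    expect_equal(unname(gv[i]), fd, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip predictions exactly", {
  syn <- generate_synth(synth_config(n_targets = 5, n_drugs = 6,
                                     d_target = 4, d_drug = 4, seed = 19))
  model <- init_model(tiny_model(), syn$target_store, syn$target_store$ids)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  p1 <- predict_pairs(model, syn$table$drug_id, syn$table$target_id,
                      syn$drug_store, syn$target_store)
  p2 <- predict_pairs(back, syn$table$drug_id, syn$table$target_id,
                      syn$drug_store, syn$target_store)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(back$manifest$context_ids, model$manifest$context_ids)
})
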