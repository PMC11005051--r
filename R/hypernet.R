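# The hypernetwork h(t; omega): a shared trunk on the (enriched) target
# embedding followed by one linear head per main-network parameter block.
# Weight heads and bias heads are initialized by principled weight
# initialization (PWI) so that the predicted QSAR parameters give a
# variance-preserving forward pass at the start of training:
#
#   Var(H) = 1 / (2 * d_in * c_in * var_t)     (weight head, main fan-in d_in)
#   Var(G) = 1 / (2 * c_in * var_t)            (bias head)
#
# where c_in is the trunk output width and var_t the per-entry variance of
# the trunk's input embedding. The two halves each contribute variance 1/2
# to a main-layer pre-activation, sharing it between weights and biases. A
# gain factor 2 is applied to weight heads whose main layer feeds a ReLU;
# the output layer uses no gain.

#' Specify the hypernetwork architecture
#'
#' @param trunk_dims integer vector starting at the target-embedding
#'   dimension and ending at `c_in`, the trunk output width consumed by the
#'   heads. Intermediate entries are ReLU hidden layers; the final trunk
#'   layer is linear.
#' @param dropout dropout rate in trunk hidden layers (training only; never
#'   in heads).
#' @return An object of class `hyper_net_spec`.
#' @export
hyper_net_spec <- function(trunk_dims, dropout = 0) {
  trunk_dims <- as.integer(trunk_dims)
  assert_that(length(trunk_dims) >= 2, "trunk_dims needs input and output dims")
  assert_that(all(trunk_dims >= 1), "trunk dims must be positive")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(trunk_dims = trunk_dims,
                 c_in = trunk_dims[length(trunk_dims)],
                 dropout = dropout),
            class = "hyper_net_spec")
}

#' Initialize a hypernetwork state with principled weight initialization
#'
#' Trunk layers get fan-in-preserving init with zero biases (variance
#' `1/fan_in` for the first layer, `2/fan_in` for layers consuming ReLU
#' activations). Each weight head for a main layer of fan-in `d_in` gets
#' i.i.d. zero-mean entries of variance `1/(2 d_in c_in var_t)` (doubled
#' when that main layer feeds a ReLU; the output layer has no gain); each
#' bias head gets variance `1/(2 c_in var_t)`. All head biases are zero, so
#' predicted parameters are zero-mean at init.
#'
#' @param hyper_spec a [hyper_net_spec()].
#' @param schema the main network's [build_param_schema()].
#' @param var_t positive scalar: per-entry variance of the hypernetwork's
#'   input embedding (measure it with [measure_var_t()]; LayerNorm makes it
#'   close to 1).
#' @param main_spec the [main_net_spec()], needed to locate ReLU layers.
#' @param seed integer.
#' @return A `hyper_state`: list with `trunk`, `heads`, `spec`, `schema`.
#' @export
pwi_initialize <- function(hyper_spec, schema, var_t, main_spec, seed = 1L) {
  if (!is.numeric(var_t) || length(var_t) != 1 || !is.finite(var_t) || var_t <= 0) {
    validation_error("var_t must be a positive finite scalar")
  }
  .init_hyper_state(hyper_spec, schema, main_spec, seed,
                    head_sd = function(e) {
                      c_in <- hyper_spec$c_in
                      if (e$kind == "W") {
                        gain <- if (main_spec$activation == "relu" &&
                                    e$layer < schema$n_layers) 2 else 1
                        sqrt(gain / (2 * e$fan_in * c_in * var_t))
                      } else {
                        sqrt(1 / (2 * c_in * var_t))
                      }
                    })
}

#' Naive control initialization (no PWI)
#'
#' Diagnostic control used to demonstrate why PWI matters: trunk as in
#' [pwi_initialize()], but heads get plain fan-in variance `1/c_in`, ignoring
#' the main network's fan-in. Predicted parameters then have variance on the
#' order of 1 instead of `1/(2 d_in)`, and main-network activations blow up
#' with depth.
#'
#' @inheritParams pwi_initialize
#' @return A `hyper_state`.
#' @export
naive_initialize <- function(hyper_spec, schema, main_spec, seed = 1L) {
  .init_hyper_state(hyper_spec, schema, main_spec, seed,
                    head_sd = function(e) sqrt(1 / hyper_spec$c_in))
}

.init_hyper_state <- function(hyper_spec, schema, main_spec, seed, head_sd) {
  dims <- hyper_spec$trunk_dims
  with_seed(seed, {
    trunk <- list()
    for (l in seq_len(length(dims) - 1)) {
      fan_in <- dims[l]
      v <- if (l == 1) 1 / fan_in else 2 / fan_in  # layers >1 consume relu
      trunk[[l]] <- list(
        W = matrix(stats::rnorm(dims[l + 1] * fan_in, sd = sqrt(v)),
                   dims[l + 1], fan_in),
        b = rep(0, dims[l + 1]))
    }
    heads <- list()
    for (e in schema$entries) {
      heads[[e$name]] <- list(
        H = matrix(stats::rnorm(e$size * hyper_spec$c_in, sd = head_sd(e)),
                   e$size, hyper_spec$c_in),
        g = rep(0, e$size))
    }
    structure(list(trunk = trunk, heads = heads, spec = hyper_spec,
                   schema = schema),
              class = "hyper_state")
  })
}

# trunk forward with cache; relu on all layers but the last, optional
# inverted dropout on hidden activations during training
trunk_forward <- function(t_in, state, train = FALSE) {
  L <- length(state$trunk)
  a <- t_in
  caches <- vector("list", L)
  p <- state$spec$dropout
  for (l in seq_len(L)) {
    W <- state$trunk[[l]]$W; b <- state$trunk[[l]]$b
    z <- drop(W %*% a) + b
    mask <- NULL
    if (l < L) {
      act <- relu(z)
      if (train && p > 0) {
        mask <- (stats::runif(length(act)) >= p) / (1 - p)
        act <- act * mask
      }
    } else {
      act <- z
    }
    caches[[l]] <- list(a_in = a, z = z, mask = mask)
    a <- act
  }
  list(h = a, caches = caches)
}

trunk_backward <- function(dh, fw, state) {
  L <- length(state$trunk)
  grads <- vector("list", L)
  da <- dh
  for (l in rev(seq_len(L))) {
    cache <- fw$caches[[l]]
    dz <- da
    if (l < L) {
      if (!is.null(cache$mask)) dz <- dz * cache$mask
      dz <- dz * (cache$z > 0)
    }
    grads[[l]] <- list(W = outer(dz, cache$a_in), b = dz)
    da <- drop(crossprod(state$trunk[[l]]$W, dz))
  }
  list(grads = grads, dt = da)
}

heads_forward <- function(h, state) {
  flat <- numeric(state$schema$total_count)
  for (e in state$schema$entries) {
    hd <- state$heads[[e$name]]
    flat[e$offset + seq_len(e$size)] <- drop(hd$H %*% h) + hd$g
  }
  flat
}

heads_backward <- function(dflat, h, state) {
  grads <- list()
  dh <- numeric(length(h))
  for (e in state$schema$entries) {
    dtheta <- dflat[e$offset + seq_len(e$size)]
    grads[[e$name]] <- list(H = outer(dtheta, h), g = dtheta)
    dh <- dh + drop(crossprod(state$heads[[e$name]]$H, dtheta))
  }
  list(grads = grads, dh = dh)
}

#' Run the hypernetwork forward
#'
#' Maps an (enriched) target embedding to the flat parameter vector of the
#' QSAR main network. Deterministic at inference (dropout off). Row-matrix
#' input yields one flat parameter vector per row.
#'
#' @param t_enriched numeric vector of length `trunk_dims[1]`, or a matrix
#'   with such rows.
#' @param hyper_state a state from [pwi_initialize()] / [naive_initialize()].
#' @return numeric vector of length `schema$total_count`, or a matrix with
#'   one such row per input row.
#' @export
hyper_forward <- function(t_enriched, hyper_state) {
  if (is.matrix(t_enriched)) {
    out <- t(apply(t_enriched, 1, hyper_forward, hyper_state = hyper_state))
    if (hyper_state$schema$total_count == 1) out <- matrix(out, ncol = 1)
    return(out)
  }
  if (length(t_enriched) != hyper_state$spec$trunk_dims[1]) {
    validation_error(sprintf("embedding length %d does not match trunk input %d",
                             length(t_enriched), hyper_state$spec$trunk_dims[1]))
  }
  heads_forward(trunk_forward(t_enriched, hyper_state)$h, hyper_state)
}

#' Measure the per-entry variance of enriched training-target embeddings
#'
#' Runs every memory target through [enrich()] at the current parameters and
#' returns the mean over entries of the per-entry variance across targets.
#' This is the `var_t` that keeps the PWI formulas exact (LayerNorm makes it
#' close to, but not exactly, 1 once the affine rescales).
#'
#' @param target_store an [embedding_store()].
#' @param memory a [build_context()] memory.
#' @param ctx_params [hopfield_params()].
#' @param residual passed to [enrich()].
#' @return positive scalar.
#' @export
measure_var_t <- function(target_store, memory, ctx_params, residual = FALSE) {
  E <- t(vapply(memory$ids, function(id) {
    enrich(drop(get_embeddings(target_store, id)), memory, ctx_params,
           residual = residual)
  }, numeric(memory$dim)))
  if (length(memory$ids) < 2) return(1)
  v <- mean(apply(E, 2, stats::var))
  max(v, 1e-6)
}

# ---------------------------------------------------------------------------
# Assembled model

#' Construct a hypernetwork-PCM model
#'
#' Bundles the three components: Hopfield context module over training
#' targets, hypernetwork trunk + PWI heads, and the QSAR main-network
#' architecture they parameterize. The model is untrained and without
#' context memory until [init_model()] attaches a training-target memory and
#' performs PWI with measured `var_t`.
#'
#' @param drug_dim,target_dim embedding dimensions.
#' @param main_hidden integer vector of QSAR hidden widths (default 16).
#' @param trunk_hidden integer vector of trunk hidden widths (default 32).
#' @param c_in trunk output width feeding the heads (default 64).
#' @param task `"regression"` (identity output) or `"classification"`
#'   (sigmoid output).
#' @param main_activation hidden activation of the QSAR net.
#' @param d_a Hopfield association dimension (default `target_dim`).
#' @param beta Hopfield inverse temperature (default `1/sqrt(d_a)`).
#' @param use_value_proj trainable value projection in the context module.
#' @param residual average enriched and raw (standardized) target embedding.
#' @param dropout trunk dropout rate.
#' @param qk_init_scale multiplier on the initial query/key projection
#'   scales. Values below 1 start Hopfield retrieval in the smooth
#'   (near-linear softmax) regime, which helps zero-shot generalization with
#'   small context memories; the effective inverse temperature remains
#'   learnable through the projection norms.
#' @param seed integer init seed.
#' @return An object of class `hpcm_model`.
#' @export
hpcm_model <- function(drug_dim, target_dim,
                       main_hidden = 16L, trunk_hidden = 32L, c_in = 64L,
                       task = c("regression", "classification"),
                       main_activation = c("relu", "linear"),
                       d_a = target_dim, beta = 1 / sqrt(d_a),
                       use_value_proj = FALSE, residual = FALSE,
                       dropout = 0, qk_init_scale = 1, seed = 1L) {
  task <- match.arg(task)
  main_activation <- match.arg(main_activation)
  main_spec <- main_net_spec(c(drug_dim, main_hidden, 1L),
                             activation = main_activation,
                             output_activation = if (task == "regression")
                               "identity" else "sigmoid")
  schema <- build_param_schema(main_spec)
  hyper_spec <- hyper_net_spec(c(target_dim, trunk_hidden, c_in),
                               dropout = dropout)
  ctx <- hopfield_params(target_dim, d_a = d_a, beta = beta,
                         use_value_proj = use_value_proj,
                         seed = derive_seed(seed, 11L))
  if (qk_init_scale != 1) {
    spec_attr <- attr(ctx, "spec")
    ctx$Wq <- ctx$Wq * qk_init_scale
    ctx$Wk <- ctx$Wk * qk_init_scale
    attr(ctx, "spec") <- spec_attr
  }
  structure(list(main_spec = main_spec, schema = schema,
                 hyper_spec = hyper_spec, ctx_params = ctx,
                 hyper_state = NULL, memory = NULL,
                 task = task, residual = residual, seed = as.integer(seed),
                 manifest = list()),
            class = "hpcm_model")
}

#' @export
print.hpcm_model <- function(x, ...) {
  cat(sprintf(
    "<hpcm_model> %s | QSAR dims [%s] | trunk [%s] | %s | %s\n",
    x$task,
    paste(x$main_spec$layer_dims, collapse = ","),
    paste(x$hyper_spec$trunk_dims, collapse = ","),
    if (is.null(x$memory)) "no context memory"
    else sprintf("context T=%d", length(x$memory$ids)),
    if (is.null(x$hyper_state)) "uninitialized" else "initialized"))
  invisible(x)
}

#' Attach the context memory and run PWI
#'
#' Builds the Hopfield memory from the *training* targets only, measures
#' `var_t` over their enriched embeddings at the current context parameters,
#' and initializes the hypernetwork with PWI.
#'
#' @param model an [hpcm_model()].
#' @param target_store an [embedding_store()] of target embeddings.
#' @param train_target_ids ids of the training-fold targets.
#' @return The initialized model (memory, hyper_state, manifest filled in).
#' @export
init_model <- function(model, target_store, train_target_ids) {
  model$memory <- build_context(target_store, train_target_ids)
  var_t <- measure_var_t(target_store, model$memory, model$ctx_params,
                         residual = model$residual)
  model$hyper_state <- pwi_initialize(model$hyper_spec, model$schema,
                                      var_t = var_t,
                                      main_spec = model$main_spec,
                                      seed = derive_seed(model$seed, 13L))
  model$manifest <- list(seed = model$seed, var_t = var_t,
                         context_ids = model$memory$ids)
  model
}

# Full forward for one target and its drug matrix X; returns loss-ready
# predictions plus every cache needed for backward.
model_forward <- function(model, t_vec, X, train = FALSE) {
  ctx_fw <- enrich_forward(t_vec, model$memory, model$ctx_params)
  e <- if (model$residual) (ctx_fw$out + standardize(t_vec)) / 2 else ctx_fw$out
  tr_fw <- trunk_forward(e, model$hyper_state, train = train)
  flat <- heads_forward(tr_fw$h, model$hyper_state)
  qparams <- distribute(flat, model$schema)
  q_fw <- qsar_forward_cache(X, qparams, model$main_spec)
  list(pred = q_fw$pred, z_out = q_fw$z_out,
       ctx_fw = ctx_fw, tr_fw = tr_fw, flat = flat,
       qparams = qparams, q_fw = q_fw)
}

# Backward from gradient w.r.t. the final pre-activation (length m vector).
model_backward <- function(model, fw, dz_out) {
  qb <- qsar_backward(dz_out, fw$q_fw, fw$qparams, model$main_spec)
  dflat <- flatten_params(qb$grads, model$schema)
  hb <- heads_backward(dflat, fw$tr_fw$h, model$hyper_state)
  tb <- trunk_backward(hb$dh, fw$tr_fw, model$hyper_state)
  d_e <- tb$dt
  if (model$residual) d_e <- d_e / 2
  cb <- enrich_backward(d_e, fw$ctx_fw$cache, model$ctx_params, model$memory)
  list(ctx = cb$grads, trunk = tb$grads, heads = hb$grads)
}

#' Predict scores for (drug, target) id pairs
#'
#' Composition of the four stages (enrich, hypernetwork forward, reshape,
#' QSAR forward), with the flat parameter vector computed once per unique
#' target and reused across its drugs.
#'
#' @param model an initialized, typically trained, [hpcm_model()].
#' @param drug_ids,target_ids equal-length character vectors.
#' @param drug_store,target_store [embedding_store()] objects.
#' @return numeric score vector (affinity for regression, probability for
#'   classification), aligned with the input pairs.
#' @export
predict_pairs <- function(model, drug_ids, target_ids, drug_store, target_store) {
  assert_that(length(drug_ids) == length(target_ids),
              "drug_ids and target_ids must have equal length")
  assert_that(!is.null(model$hyper_state) && !is.null(model$memory),
              "model must be initialized (init_model) before prediction")
  out <- numeric(length(drug_ids))
  for (tid in unique(target_ids)) {
    rows <- which(target_ids == tid)
    t_vec <- drop(get_embeddings(target_store, tid))
    e <- enrich(t_vec, model$memory, model$ctx_params,
                residual = model$residual)
    flat <- hyper_forward(e, model$hyper_state)
    qp <- distribute(flat, model$schema)
    X <- get_embeddings(drug_store, drug_ids[rows])
    out[rows] <- qsar_forward(X, qp, model$main_spec)
  }
  out
}

#' Predict a single (drug, target) pair
#' @inheritParams predict_pairs
#' @param drug_id,target_id single ids.
#' @return scalar score.
#' @export
predict_pair <- function(model, drug_id, target_id, drug_store, target_store) {
  predict_pairs(model, drug_id, target_id, drug_store, target_store)
}

# ---------------------------------------------------------------------------
# nested parameter-list plumbing shared with the optimizer

model_params <- function(model) {
  p <- list(ctx = model$ctx_params[.ctx_trainable(model$ctx_params)],
            trunk = lapply(model$hyper_state$trunk, function(l) l[c("W", "b")]),
            heads = lapply(model$hyper_state$heads, function(h) h[c("H", "g")]))
  p
}

.ctx_trainable <- function(ctx) {
  nm <- c("Wq", "Wk", "Wv", "ln_t_g", "ln_t_b", "ln_m_g", "ln_m_b",
          "ln_o_g", "ln_o_b")
  intersect(nm, names(ctx))
}

model_set_params <- function(model, p) {
  spec <- attr(model$ctx_params, "spec")
  for (nm in names(p$ctx)) model$ctx_params[[nm]] <- p$ctx[[nm]]
  attr(model$ctx_params, "spec") <- spec
  for (l in seq_along(p$trunk)) {
    model$hyper_state$trunk[[l]]$W <- p$trunk[[l]]$W
    model$hyper_state$trunk[[l]]$b <- p$trunk[[l]]$b
  }
  for (nm in names(p$heads)) {
    model$hyper_state$heads[[nm]]$H <- p$heads[[nm]]$H
    model$hyper_state$heads[[nm]]$g <- p$heads[[nm]]$g
  }
  model
}

# recursive map over two parallel nested lists of numeric arrays; elements
# are matched by name where names exist (gradient lists may be ordered
# differently from parameter lists)
nested_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  keys <- names(a)
  if (is.null(keys) || any(!nzchar(keys))) keys <- seq_along(a)
  for (nm in keys) out[[nm]] <- nested_map2(a[[nm]], b[[nm]], f)
  out
}

nested_map <- function(a, f) {
  if (is.numeric(a)) return(f(a))
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- nested_map(a[[nm]], f)
  out
}

zero_like <- function(p) nested_map(p, function(x) x * 0)

# ---------------------------------------------------------------------------
# checkpoint serialization (plain JSON, text-only)

.encode_array <- function(x) {
  if (is.matrix(x)) list(dim = dim(x), data = as.vector(x)) else
    list(dim = length(x), data = as.vector(x))
}

.decode_array <- function(a) {
  d <- unlist(a$dim)
  if (length(d) == 2) matrix(unlist(a$data), d[1], d[2]) else unlist(a$data)
}

#' Save a model checkpoint to JSON
#'
#' One text file holding the configuration, parameter schema, all trainable
#' parameters, the context memory, and the run manifest (seed, context ids,
#' measured var_t) -- sufficient to re-execute predictions bit-compatibly.
#'
#' @param model an initialized [hpcm_model()].
#' @param path output path.
#' @export
save_checkpoint <- function(model, path) {
  ctx_arrays <- lapply(model$ctx_params[.ctx_trainable(model$ctx_params)],
                       .encode_array)
  obj <- list(
    package_version = as.character(utils::packageVersion("hyperpcm")),
    task = model$task, residual = model$residual, seed = model$seed,
    main_spec = unclass(model$main_spec),
    hyper_spec = unclass(model$hyper_spec),
    ctx_spec = attr(model$ctx_params, "spec"),
    ctx_params = ctx_arrays,
    trunk = lapply(model$hyper_state$trunk, function(l)
      list(W = .encode_array(l$W), b = .encode_array(l$b))),
    heads = lapply(model$hyper_state$heads, function(h)
      list(H = .encode_array(h$H), g = .encode_array(h$g))),
    memory = list(ids = model$memory$ids, C = .encode_array(model$memory$C)),
    manifest = model$manifest)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model checkpoint saved by [save_checkpoint()]
#' @param path checkpoint path.
#' @return An [hpcm_model()], initialized and ready for [predict_pairs()].
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  main_spec <- structure(list(layer_dims = as.integer(unlist(x$main_spec$layer_dims)),
                              activation = x$main_spec$activation,
                              output_activation = x$main_spec$output_activation),
                         class = "main_net_spec")
  schema <- build_param_schema(main_spec)
  hyper_spec <- hyper_net_spec(as.integer(unlist(x$hyper_spec$trunk_dims)),
                               dropout = x$hyper_spec$dropout)
  ctx <- lapply(x$ctx_params, .decode_array)
  attr(ctx, "spec") <- list(d = x$ctx_spec$d, d_a = x$ctx_spec$d_a,
                            beta = x$ctx_spec$beta,
                            use_value_proj = isTRUE(x$ctx_spec$use_value_proj))
  trunk <- lapply(x$trunk, function(l)
    list(W = .decode_array(l$W), b = .decode_array(l$b)))
  heads <- lapply(x$heads, function(h)
    list(H = .decode_array(h$H), g = .decode_array(h$g)))
  C <- .decode_array(x$memory$C)
  ids <- unlist(x$memory$ids)
  rownames(C) <- ids
  structure(list(
    main_spec = main_spec, schema = schema, hyper_spec = hyper_spec,
    ctx_params = ctx,
    hyper_state = structure(list(trunk = trunk, heads = heads,
                                 spec = hyper_spec, schema = schema),
                            class = "hyper_state"),
    memory = structure(list(C = C, ids = ids, dim = ncol(C)),
                       class = "context_memory"),
    task = x$task, residual = isTRUE(x$residual), seed = as.integer(x$seed),
    manifest = x$manifest), class = "hpcm_model")
}
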