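# Task-conditioned synthetic data generator. Emulates the statistical
# structure hypernetwork-PCM assumes: labels are predictable from the target
# embedding through a smooth per-target function, so zero-shot transfer to
# held-out targets is possible by construction. Default regimes mirror
# chemogenomic benchmarks: tunable sparsity of the pair grid (dense
# kinase-panel-like 100% down to ChEMBL-like fractions of a percent),
# Gaussian label noise, and class imbalance for binary tasks.

#' Configuration for the synthetic generator
#'
#' @param n_targets,n_drugs entity counts.
#' @param d_target,d_drug embedding dimensions.
#' @param noise_sd label noise standard deviation (label units; >= 0).
#' @param sparsity fraction of the target x drug grid that is labeled,
#'   in (0, 1].
#' @param active_fraction active share for binary tasks, in (0, 1).
#' @param ground_truth_rank rank of the linear map from target embedding to
#'   per-task weights (default full rank `d_target`).
#' @param nonlinear if `TRUE`, an elementwise tanh follows the linear map
#'   (stress-test variant; the default linear map admits closed-form
#'   recovery oracles).
#' @param seed integer.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_targets = 50L, n_drugs = 60L,
                         d_target = 16L, d_drug = 16L,
                         noise_sd = 0.1, sparsity = 1,
                         active_fraction = 0.5,
                         ground_truth_rank = d_target,
                         nonlinear = FALSE, seed = 1L) {
  assert_that(n_targets >= 1 && n_drugs >= 1 && d_target >= 1 && d_drug >= 1,
              "counts and dimensions must be positive")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(sparsity > 0 && sparsity <= 1, "sparsity must be in (0, 1]")
  assert_that(active_fraction > 0 && active_fraction < 1,
              "active_fraction must be in (0, 1)")
  assert_that(ground_truth_rank >= 1 && ground_truth_rank <= d_target,
              "ground_truth_rank must be in [1, d_target]")
  assert_that(sparsity * n_targets * n_drugs >= 1,
              "sparsity leaves no labeled pair")
  structure(list(n_targets = as.integer(n_targets),
                 n_drugs = as.integer(n_drugs),
                 d_target = as.integer(d_target), d_drug = as.integer(d_drug),
                 noise_sd = noise_sd, sparsity = sparsity,
                 active_fraction = active_fraction,
                 ground_truth_rank = as.integer(ground_truth_rank),
                 nonlinear = isTRUE(nonlinear), seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic task-conditioned interaction data set
#'
#' Target embeddings `t_i` and drug embeddings `x_j` are i.i.d. standard
#' normal. A fixed random matrix `A` of the configured rank maps each target
#' embedding to its task weight vector `w_i = A t_i` (optionally followed by
#' tanh), and labels are `y_ij = <w_i, x_j>/sqrt(d_drug) + eps` with
#' `eps ~ N(0, noise_sd^2)`; the `1/sqrt(d_drug)` scaling keeps label
#' variance O(1) across dimensions. A `sparsity` fraction of the pair grid
#' is retained uniformly at random. Fully determined by the seed.
#'
#' @param config a [synth_config()].
#' @return list with `drug_store`, `target_store` ([embedding_store()]s),
#'   `table` (continuous [interaction_table()]), and `truth`
#'   (list `A`, `W` (n_targets x d_drug task weights), `clean_labels`).
#' @export
generate_synth <- function(config) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  with_seed(config$seed, {
    tid <- sprintf("T%04d", seq_len(config$n_targets))
    did <- sprintf("D%04d", seq_len(config$n_drugs))
    Tm <- matrix(stats::rnorm(config$n_targets * config$d_target),
                 config$n_targets, config$d_target, dimnames = list(tid, NULL))
    Xm <- matrix(stats::rnorm(config$n_drugs * config$d_drug),
                 config$n_drugs, config$d_drug, dimnames = list(did, NULL))
    r <- config$ground_truth_rank
    B <- matrix(stats::rnorm(config$d_drug * r, sd = sqrt(1 / r)),
                config$d_drug, r)
    Cm <- matrix(stats::rnorm(r * config$d_target, sd = sqrt(1 / config$d_target)),
                 r, config$d_target)
    A <- B %*% Cm                                   # d_drug x d_target
    W <- Tm %*% t(A)                                # n_targets x d_drug
    if (config$nonlinear) W <- tanh(W)
    clean <- W %*% t(Xm) / sqrt(config$d_drug)      # n_targets x n_drugs
    grid <- expand.grid(target = seq_len(config$n_targets),
                        drug = seq_len(config$n_drugs))
    n_keep <- max(1L, round(config$sparsity * nrow(grid)))
    keep <- sort(sample.int(nrow(grid), n_keep))
    g <- grid[keep, ]
    y_clean <- clean[cbind(g$target, g$drug)]
    y <- y_clean + stats::rnorm(length(y_clean), sd = config$noise_sd)
    tab <- interaction_table(did[g$drug], tid[g$target], y,
                             label_kind = "continuous")
    list(drug_store = embedding_store(Xm),
         target_store = embedding_store(Tm),
         table = tab,
         truth = list(A = A, W = W, clean_labels = y_clean))
  })
}

#' Binarize a synthetic table at an empirical quantile
#'
#' Sets the activity threshold at the empirical `(1 - active_fraction)`
#' quantile of the labels, so the resulting active share matches
#' `active_fraction` to within `1/n` -- the mechanism used to emulate
#' benchmark imbalance regimes (e.g. ~8% active kinase panels).
#'
#' @param table a continuous [interaction_table()].
#' @param active_fraction desired active share in (0, 1).
#' @return binary [interaction_table()], with the threshold attached as
#'   attribute `threshold`.
#' @export
binarize_synth <- function(table, active_fraction) {
  if (label_kind(table) != "continuous") {
    contract_error("binarize_synth requires a continuous table")
  }
  assert_that(active_fraction > 0 && active_fraction < 1,
              "active_fraction must be in (0, 1)")
  y <- table$label
  if (max(y) == min(y)) {
    validation_error("degenerate constant labels: no quantile threshold exists")
  }
  thr <- stats::quantile(y, probs = 1 - active_fraction, type = 1, names = FALSE)
  out <- interaction_table(table$drug_id, table$target_id,
                           as.numeric(y > thr), date = table$date,
                           label_kind = "binary", allow_duplicates = TRUE)
  attr(out, "threshold") <- thr
  out
}

#' Canonical small prediction sets for exercising the metric stack
#'
#' @param kind `"perfect"` (scores equal truth), `"inverted"` (scores are
#'   the negated truth), `"random"` (seeded uniform scores), or `"tied"`
#'   (all scores equal).
#' @param n set size.
#' @param seed used by `kind = "random"`.
#' @return list with `true_values`, `scores`, `labels` (binary at the
#'   median), and `n`.
#' @export
metric_fixture <- function(kind = c("perfect", "inverted", "random", "tied"),
                           n = 20L, seed = 1L) {
  kind <- match.arg(kind)
  true_values <- seq_len(n) / 2
  scores <- switch(kind,
                   perfect = true_values,
                   inverted = -true_values,
                   random = with_seed(seed, stats::runif(n)),
                   tied = rep(1, n))
  list(true_values = true_values, scores = scores,
       labels = as.numeric(true_values >= stats::median(true_values)),
       n = n)
}
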