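# Shared in-code fixtures: tiny stores, tables and models built at test time.

tiny_store <- function(ids, dim = 4, seed = 1) {
  m <- hyperpcm:::with_seed(seed, matrix(rnorm(length(ids) * dim), length(ids), dim))
  rownames(m) <- ids
  embedding_store(m)
}

tiny_table <- function(n_drugs = 4, n_targets = 3, seed = 1, dates = FALSE) {
  grid <- expand.grid(drug = sprintf("D%02d", seq_len(n_drugs)),
                      target = sprintf("T%02d", seq_len(n_targets)),
                      stringsAsFactors = FALSE)
  y <- hyperpcm:::with_seed(seed, rnorm(nrow(grid), mean = 6.5))
  d <- if (dates) as.Date("2010-01-01") + seq_len(nrow(grid)) * 50 else NULL
  interaction_table(grid$drug, grid$target, y, date = d)
}

tiny_model <- function(d_drug = 4, d_target = 4, seed = 2, ...) {
  hpcm_model(d_drug, d_target, main_hidden = 3L, trunk_hidden = 5L,
             c_in = 6L, seed = seed, ...)
}

# nested parameter list <-> flat vector, for finite-difference checks
flatten_nested <- function(p) unlist(p)
relist_nested <- function(v, skeleton) utils::relist(v, skeleton)

expect_hpcm_error <- function(expr, class = "hpcm_error") {
  expect_error(expr, class = class)
}
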