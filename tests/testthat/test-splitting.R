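# Hold-out strategies and the leakage audit.

test_that("split_random: exact sizes, determinism, fraction validation", {
  tab <- tiny_table(10, 10, seed = 1)  # 100 records
  s <- split_random(tab, c(0.8, 0.1, 0.1), seed = 7)
  expect_equal(lengths(s[c("train_idx", "val_idx", "test_idx")]),
               c(train_idx = 80L, val_idx = 10L, test_idx = 10L))
  s2 <- split_random(tab, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(s, s2)
  expect_hpcm_error(split_random(tab, c(0.9, 0.2, 0.1), seed = 1))
})

test_that("split_temporal buckets drugs by earliest date", {
  tab <- interaction_table(
    c("A", "B", "C", "A"), c("T1", "T1", "T1", "T2"),
    c(5, 6, 7, 8),
    date = as.Date(c("2010-06-01", "2014-06-01", "2018-06-01", "2018-07-01")))
  s <- split_temporal(tab, as.Date(c("2012-01-01", "2016-01-01")))
  # drug A first seen 2010 -> train, even its 2018 record follows the drug
  expect_setequal(s$train_idx, c(1L, 4L))
  expect_equal(s$val_idx, 2L)
  expect_equal(s$test_idx, 3L)
  expect_true(validate_split(s, tab)$ok)
  und <- interaction_table("A", "T1", 5)
  expect_hpcm_error(split_temporal(und, as.Date(c("2012-01-01", "2016-01-01"))))
})

test_that("entity holdout keeps held-out entities in exactly one fold", {
  tab <- tiny_table(8, 5, seed = 2)  # 5 targets
  s <- split_entity_holdout(tab, "target", c(0.6, 0.2, 0.2), seed = 3)
  tg <- function(i) unique(tab$target_id[i])
  expect_equal(length(tg(s$train_idx)), 3)
  expect_equal(length(tg(s$val_idx)), 1)
  expect_equal(length(tg(s$test_idx)), 1)
  expect_true(validate_split(s, tab)$ok)
  # a target with a single interaction lands wholly in one fold
  one <- interaction_table(c("D1", "D2", "D3"), c("Ta", "Ta", "Tb"), 1:3)
  s1 <- suppressWarnings(split_entity_holdout(one, "target", c(0.5, 0, 0.5),
                                              seed = 1))
  expect_true(validate_split(s1, one)$ok)
})

test_that("cold split test block is held-out-row x held-out-column", {
  # dense 4x4 grid; enumerate the block structure
  tab <- tiny_table(4, 4, seed = 5)
  s <- suppressWarnings(
    split_entity_holdout(tab, "both", c(0.5, 0.25, 0.25), seed = 11))
  train_drugs <- unique(tab$drug_id[s$train_idx])
  train_targets <- unique(tab$target_id[s$train_idx])
  for (i in s$test_idx) {
    expect_false(tab$drug_id[i] %in% train_drugs)
    expect_false(tab$target_id[i] %in% train_targets)
  }
  # pairs with exactly one unseen entity are discarded entirely
  assigned <- c(s$train_idx, s$val_idx, s$test_idx)
  for (i in setdiff(seq_len(nrow(tab)), assigned)) {
    in_train_d <- tab$drug_id[i] %in% train_drugs
    in_train_t <- tab$target_id[i] %in% train_targets
    expect_false(in_train_d && in_train_t)
  }
  expect_true(validate_split(s, tab)$ok)
})

test_that("lcco separates fingerprint blobs and balances interactions", {
  # two well-separated synthetic fingerprint blobs -> k=2 recovers them
  set.seed(4)
  n_bits <- 32
  blob <- function(base, ids) {
    m <- t(vapply(ids, function(i) {
      v <- base
      flip <- sample(n_bits, 2)
      v[flip] <- 1L - v[flip]
      v
    }, integer(n_bits)))
    m
  }
  base1 <- c(rep(1L, 16), rep(0L, 16))
  base2 <- c(rep(0L, 16), rep(1L, 16))
  ids <- sprintf("D%02d", 1:8)
  fp <- rbind(blob(base1, ids[1:4]), blob(base2, ids[5:8]))
  rownames(fp) <- ids
  class(fp) <- c("fingerprint_set", "matrix", "array")
  tab <- tiny_table(8, 3, seed = 6)
  s <- split_lcco(tab, fp, k = 2, seed = 9, fractions = c(0.6, 0, 0.4),
                  held_out_clusters = NULL)
  cl <- attr(s, "clusters")
  # brute-force 2-means on <= 8 points: blobs must not be split
  expect_equal(length(unique(cl[ids[1:4]])), 1)
  expect_equal(length(unique(cl[ids[5:8]])), 1)
  expect_true(length(intersect(unique(tab$drug_id[s$train_idx]),
                               unique(tab$drug_id[s$test_idx]))) == 0)
  expect_identical(s, split_lcco(tab, fp, k = 2, seed = 9,
                                 fractions = c(0.6, 0, 0.4)))
})

test_that("lcco degenerate fingerprints fall back deterministically", {
  ids <- sprintf("D%02d", 1:4)
  fp <- matrix(1L, 4, 16, dimnames = list(ids, NULL))
  class(fp) <- c("fingerprint_set", "matrix", "array")
  tab <- tiny_table(4, 3, seed = 2)
  expect_warning(s <- split_lcco(tab, fp, k = 3, seed = 1,
                                 fractions = c(0.5, 0.25, 0.25)),
                 "degenerate")
  expect_true(validate_split(s, tab)$ok)
  expect_hpcm_error(
    suppressWarnings(split_lcco(tab, fp, k = 10, seed = 1)))
})

test_that("lcco cluster interaction counts are roughly balanced on a blobby fixture", {
  set.seed(12)
  n_drugs <- 40
  ids <- sprintf("D%02d", seq_len(n_drugs))
  fp <- matrix(rbinom(n_drugs * 64, 1, 0.5), n_drugs, 64,
               dimnames = list(ids, NULL))
  class(fp) <- c("fingerprint_set", "matrix", "array")
  tab <- tiny_table(n_drugs, 6, seed = 8)
  s <- split_lcco(tab, fp, k = 5, seed = 3, fractions = c(0.6, 0.2, 0.2))
  cl <- attr(s, "clusters")
  counts <- table(cl[tab$drug_id])
  expect_lte(max(counts) / min(counts), 4)
})

test_that("validate_split reports planted violations exactly", {
  tab <- tiny_table(6, 4, seed = 3)
  s <- split_entity_holdout(tab, "target", c(0.5, 0.25, 0.25), seed = 2)
  expect_true(validate_split(s, tab)$ok)
  # plant: move one test record into train -> shared target + ok indices
  bad <- s
  bad$train_idx <- c(bad$train_idx, bad$test_idx[1])
  bad$test_idx <- bad$test_idx[-1]
  rep <- validate_split(bad, tab)
  expect_false(rep$ok)
  expect_true(any(grepl("target shared", rep$violations)))
  # plant: overlapping indices
  bad2 <- s
  bad2$val_idx <- c(bad2$val_idx, bad2$train_idx[1])
  rep2 <- validate_split(bad2, tab)
  expect_true(any(grepl("overlapping", rep2$violations)))
})

test_that("split spec serializes to JSON and back", {
  tab <- tiny_table(5, 3)
  s <- split_random(tab, c(0.6, 0.2, 0.2), seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_split_spec(s, f)
  back <- read_split_spec(f)
  expect_equal(back$train_idx, s$train_idx)
  expect_equal(back$strategy, "random")
  expect_equal(back$seed, 4L)
})
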