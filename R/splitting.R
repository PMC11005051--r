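# Chemogenomic hold-out strategies. All strategies return a split_spec whose
# index sets point into the rows of an interaction_table; leakage guarantees
# are machine-checked by validate_split().

.split_strategies <- c("random", "temporal", "lcco", "lpo",
                       "cold_drug", "cold_target", "cold")

#' Construct a split specification
#'
#' @param train_idx,val_idx,test_idx integer row indices into the table,
#'   pairwise disjoint.
#' @param strategy one of `random`, `temporal`, `lcco`, `lpo`, `cold_drug`,
#'   `cold_target`, `cold`.
#' @param seed integer seed the split was generated from.
#' @param fold_id optional fold number for cross-validation bookkeeping.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_idx, val_idx, test_idx, strategy, seed,
                       fold_id = NULL) {
  strategy <- match.arg(strategy, .split_strategies)
  train_idx <- as.integer(train_idx); val_idx <- as.integer(val_idx)
  test_idx <- as.integer(test_idx)
  all_idx <- c(train_idx, val_idx, test_idx)
  assert_that(!anyDuplicated(all_idx), "fold index sets must be pairwise disjoint")
  structure(list(train_idx = train_idx, val_idx = val_idx, test_idx = test_idx,
                 strategy = strategy, seed = as.integer(seed),
                 fold_id = fold_id),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> strategy=%s seed=%d sizes %d/%d/%d\n",
              x$strategy, x$seed, length(x$train_idx), length(x$val_idx),
              length(x$test_idx)))
  invisible(x)
}

check_fractions <- function(fractions) {
  assert_that(is.numeric(fractions) && length(fractions) == 3,
              "fractions must be length-3 numeric (train, val, test)")
  assert_that(all(fractions >= 0) && fractions[1] > 0,
              "fractions must be non-negative with positive train share")
  if (sum(fractions) > 1 + 1e-9) {
    validation_error(sprintf("fractions sum to %.3f > 1", sum(fractions)))
  }
  fractions
}

# split a vector of units into 3 folds by fractions, reproducibly
.assign_folds <- function(units, fractions, seed) {
  n <- length(units)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_test <- min(n - n_train - n_val, round(fractions[3] * n))
  perm <- with_seed(seed, sample(units))
  list(train = perm[seq_len(n_train)],
       val = if (n_val) perm[n_train + seq_len(n_val)] else units[0],
       test = if (n_test) perm[n_train + n_val + seq_len(n_test)] else units[0])
}

#' Fully random interaction-level split
#'
#' Assigns individual interactions to folds uniformly at random; both drugs
#' and targets may be shared across folds (the easiest evaluation regime).
#'
#' @param table an [interaction_table()].
#' @param fractions length-3 numeric (train, val, test), non-negative, sum <= 1.
#' @param seed integer.
#' @return A [split_spec()].
#' @export
split_random <- function(table, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  check_fractions(fractions)
  f <- .assign_folds(seq_len(nrow(table)), fractions, seed)
  split_spec(f$train, f$val, f$test, "random", seed)
}

#' Temporal hold-out by first appearance of each drug
#'
#' Every unique drug is assigned a fold by its earliest dated record versus
#' the two cut dates (`< cut1` train, `< cut2` validation, else test); all of
#' a drug's interactions follow the drug, so later folds contain only
#' compounds unseen at training time.
#'
#' @param table an [interaction_table()]; every record must carry a date.
#' @param cut_dates length-2 `Date` (or coercible) vector, ascending.
#' @return A [split_spec()] with strategy `temporal`.
#' @export
split_temporal <- function(table, cut_dates) {
  cut_dates <- as.Date(cut_dates)
  assert_that(length(cut_dates) == 2 && !anyNA(cut_dates) &&
                cut_dates[1] <= cut_dates[2],
              "cut_dates must be two ascending dates")
  undated <- unique(table$drug_id[is.na(table$date)])
  if (length(undated)) {
    validation_error(sprintf("undated records for drug(s): %s",
                             paste(utils::head(undated, 5), collapse = ", ")))
  }
  first_seen <- tapply(as.integer(table$date), table$drug_id, min)
  fold_of_drug <- 1L + (first_seen >= as.integer(cut_dates[1])) +
    (first_seen >= as.integer(cut_dates[2]))
  fold <- fold_of_drug[table$drug_id]
  split_spec(which(fold == 1), which(fold == 2), which(fold == 3),
             "temporal", 0L)
}

#' Leave-cluster-compound-out split via k-means on fingerprints
#'
#' Drugs are clustered by k-means (k-means++-style multi-restart, Euclidean
#' distance over bits as reals) on their circular fingerprints; whole
#' clusters are greedily packed into folds to balance interaction counts, so
#' no compound (and no near-analog cluster) spans folds.
#'
#' @param table an [interaction_table()].
#' @param fingerprints a `fingerprint_set` covering all drugs in the table.
#' @param k number of clusters (default 10).
#' @param seed integer.
#' @param fractions target interaction-count shares (train, val, test).
#' @param held_out_clusters optional integer cluster labels forced into test.
#' @return A [split_spec()] with strategy `lcco` and attribute `clusters`
#'   (named cluster label per drug).
#' @export
split_lcco <- function(table, fingerprints, k = 10L, seed = 1L,
                       fractions = c(0.8, 0.1, 0.1),
                       held_out_clusters = NULL) {
  check_fractions(fractions)
  drugs <- sort(unique(table$drug_id))
  n_folds <- sum(fractions > 0)
  assert_that(k >= n_folds || !is.null(held_out_clusters),
              sprintf("k must be at least the number of populated folds (%d)",
                      n_folds))
  if (k > length(drugs)) {
    validation_error(sprintf("k = %d exceeds number of unique drugs (%d)",
                             k, length(drugs)))
  }
  miss <- setdiff(drugs, rownames(fingerprints))
  if (length(miss)) {
    validation_error(sprintf("drugs without fingerprints: %s",
                             paste(utils::head(miss, 5), collapse = ", ")))
  }
  X <- fingerprints[drugs, , drop = FALSE]
  storage.mode(X) <- "double"
  n_unique <- nrow(unique(X))
  if (n_unique < k) {
    warning("degenerate fingerprints: fewer distinct vectors than k; ",
            "falling back to deterministic round-robin clustering")
    cl <- ((seq_along(drugs) - 1L) %% k) + 1L
  } else {
    km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = 10,
                                        iter.max = 50))
    cl <- km$cluster
  }
  names(cl) <- drugs
  # interactions per cluster
  drug_cluster <- cl[table$drug_id]
  counts <- tapply(seq_len(nrow(table)), drug_cluster, length)
  cluster_ids <- as.integer(names(counts))
  fold_of_cluster <- stats::setNames(integer(length(cluster_ids)),
                                     cluster_ids)
  if (!is.null(held_out_clusters)) {
    fold_of_cluster[as.character(held_out_clusters)] <- 3L
  }
  total <- nrow(table)
  want <- fractions * total
  have <- c(0, 0, 0)
  have[3] <- sum(counts[as.character(held_out_clusters)], na.rm = TRUE)
  remaining <- cluster_ids[fold_of_cluster[as.character(cluster_ids)] == 0L]
  # largest clusters first, each to the fold with the largest deficit
  for (cid in remaining[order(-counts[as.character(remaining)])]) {
    deficit <- want - have
    if (!is.null(held_out_clusters)) deficit[3] <- -Inf
    f <- which.max(deficit)
    fold_of_cluster[as.character(cid)] <- f
    have[f] <- have[f] + counts[as.character(cid)]
  }
  fold <- fold_of_cluster[as.character(drug_cluster)]
  spec <- split_spec(which(fold == 1), which(fold == 2), which(fold == 3),
                     "lcco", seed)
  attr(spec, "clusters") <- cl
  spec
}

#' Entity-level hold-out splits (LPO, cold-drug, cold-target, cold)
#'
#' Holds out whole entities: `entity = "target"` assigns unique protein
#' targets to folds (leave-protein-out / cold-target, the zero-shot regime),
#' `"drug"` assigns unique compounds (cold-drug), `"both"` assigns drugs and
#' targets independently and keeps only pairs whose two entities share a
#' fold (cold), so test pairs have both drug and target unseen in training.
#'
#' @param table an [interaction_table()].
#' @param entity `"target"`, `"drug"`, or `"both"`.
#' @param fractions length-3 numeric (train, val, test).
#' @param seed integer.
#' @param strategy optional strategy tag override (`lpo` vs `cold_target`
#'   for `entity = "target"`; defaults: target -> `lpo`, drug -> `cold_drug`,
#'   both -> `cold`).
#' @return A [split_spec()].
#' @export
split_entity_holdout <- function(table, entity = c("target", "drug", "both"),
                                 fractions = c(0.8, 0.1, 0.1), seed = 1L,
                                 strategy = NULL) {
  entity <- match.arg(entity)
  check_fractions(fractions)
  strategy <- strategy %||% switch(entity, target = "lpo", drug = "cold_drug",
                                   both = "cold")
  if (entity %in% c("target", "drug")) {
    units <- sort(unique(if (entity == "target") table$target_id else table$drug_id))
    f <- .assign_folds(units, fractions, seed)
    col <- if (entity == "target") table$target_id else table$drug_id
    idx <- list(train = which(col %in% f$train),
                val = which(col %in% f$val),
                test = which(col %in% f$test))
  } else {
    fd <- .assign_folds(sort(unique(table$drug_id)), fractions, seed)
    ft <- .assign_folds(sort(unique(table$target_id)), fractions,
                        derive_seed(seed, 1L))
    idx <- lapply(c(train = "train", val = "val", test = "test"), function(f) {
      which(table$drug_id %in% fd[[f]] & table$target_id %in% ft[[f]])
    })
  }
  empty <- names(idx)[vapply(idx, length, integer(1)) == 0]
  if (length(empty)) {
    warning(sprintf("fold(s) with zero interactions: %s",
                    paste(empty, collapse = ", ")))
  }
  split_spec(idx$train, idx$val, idx$test, strategy, seed)
}

#' Audit a split for index and entity leakage
#'
#' Report-only. Checks pairwise disjointness of the fold index sets, index
#' range, and the strategy's entity-disjointness guarantee: targets never
#' shared across folds for `lpo`/`cold_target`, drugs never shared for
#' `cold_drug`/`lcco`/`temporal`, both for `cold`.
#'
#' @param spec a [split_spec()].
#' @param table the [interaction_table()] it indexes.
#' @return list with character vector `violations` and logical `ok`.
#' @export
validate_split <- function(spec, table) {
  v <- character(0)
  folds <- list(train = spec$train_idx, val = spec$val_idx, test = spec$test_idx)
  all_idx <- unlist(folds)
  if (anyDuplicated(all_idx)) {
    v <- c(v, sprintf("overlapping fold indices: %s",
                      paste(utils::head(unique(all_idx[duplicated(all_idx)]), 5),
                            collapse = ", ")))
  }
  if (length(all_idx) && (min(all_idx) < 1 || max(all_idx) > nrow(table))) {
    v <- c(v, "fold indices outside table range")
  }
  ent_check <- function(ids_by_fold, what) {
    pairs <- utils::combn(names(ids_by_fold), 2, simplify = FALSE)
    for (p in pairs) {
      shared <- intersect(ids_by_fold[[p[1]]], ids_by_fold[[p[2]]])
      if (length(shared)) {
        v <<- c(v, sprintf("%s shared between %s and %s: %s", what,
                           p[1], p[2],
                           paste(utils::head(shared, 5), collapse = ", ")))
      }
    }
  }
  targets_by_fold <- lapply(folds, function(i) unique(table$target_id[i]))
  drugs_by_fold <- lapply(folds, function(i) unique(table$drug_id[i]))
  if (spec$strategy %in% c("lpo", "cold_target", "cold")) {
    ent_check(targets_by_fold, "target")
  }
  if (spec$strategy %in% c("cold_drug", "lcco", "temporal", "cold")) {
    ent_check(drugs_by_fold, "drug")
  }
  list(violations = v, ok = length(v) == 0)
}

#' Serialize a split specification to JSON
#' @param spec a [split_spec()].
#' @param path output path.
#' @export
write_split_spec <- function(spec, path) {
  jsonlite::write_json(
    list(strategy = spec$strategy, seed = spec$seed,
         fold_id = spec$fold_id,
         train_idx = spec$train_idx, val_idx = spec$val_idx,
         test_idx = spec$test_idx),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read a split specification from JSON
#' @param path path written by [write_split_spec()] (or a predefined fold
#'   file in the same layout, e.g. externally clustered folds).
#' @return A [split_spec()].
#' @export
read_split_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  split_spec(x$train_idx %||% integer(0), x$val_idx %||% integer(0),
             x$test_idx %||% integer(0), x$strategy, x$seed %||% 0L,
             fold_id = x$fold_id)
}
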