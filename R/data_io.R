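#' Construct an interaction table
#'
#' An interaction table is the core labeled record set of PCM modeling: one
#' row per (drug, target) pair with a measured label, either a continuous
#' log-affinity (e.g. pChEMBL) or a binary active/inactive call, plus an
#' optional assay date used by temporal splitting.
#'
#' @param drug_id,target_id character vectors of non-empty identifiers.
#' @param label numeric vector; finite; in `{0,1}` when `label_kind = "binary"`.
#' @param date optional `Date` vector (or `NA`).
#' @param label_kind `"continuous"` or `"binary"`.
#' @param allow_duplicates if `FALSE` (default) duplicate (drug, target)
#'   pairs are rejected; if `"average"` duplicates are aggregated by their
#'   mean label; if `TRUE` they are kept as-is.
#' @return An object of class `interaction_table`: a data frame with columns
#'   `drug_id`, `target_id`, `label`, `date` and attribute `label_kind`.
#' @export
interaction_table <- function(drug_id, target_id, label,
                              date = NULL,
                              label_kind = c("continuous", "binary"),
                              allow_duplicates = FALSE) {
  label_kind <- match.arg(label_kind)
  drug_id <- as.character(drug_id)
  target_id <- as.character(target_id)
  label <- as.numeric(label)
  n <- length(label)
  assert_that(length(drug_id) == n && length(target_id) == n,
              "drug_id, target_id and label must have equal length")
  assert_that(all(nzchar(drug_id)) && all(nzchar(target_id)),
              "ids must be non-empty strings")
  assert_that(all(is.finite(label)), "labels must be finite")
  if (label_kind == "binary" && !is_binary_vector(label)) {
    validation_error("binary label_kind requires labels in {0, 1}")
  }
  if (is.null(date)) {
    date <- as.Date(rep(NA, n))
  } else {
    date <- as.Date(date)
    assert_that(length(date) == n, "date must match record count")
  }
  df <- data.frame(drug_id = drug_id, target_id = target_id,
                   label = label, date = date,
                   stringsAsFactors = FALSE)
  key <- paste(df$drug_id, df$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    if (identical(allow_duplicates, "average")) {
      agg <- aggregate(label ~ key, data = cbind(df, key = key), FUN = mean)
      first <- !duplicated(key)
      df <- df[first, , drop = FALSE]
      df$label <- agg$label[match(key[first], agg$key)]
    } else if (!isTRUE(allow_duplicates)) {
      dups <- unique(key[duplicated(key)])
      validation_error(sprintf(
        "duplicate (drug_id, target_id) pairs: %s%s",
        paste(utils::head(gsub("\r", "/", dups), 5), collapse = ", "),
        if (length(dups) > 5) sprintf(" (and %d more)", length(dups) - 5) else ""))
    }
  }
  rownames(df) <- NULL
  structure(df, label_kind = label_kind, class = c("interaction_table", "data.frame"))
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %d records, %d drugs, %d targets, labels %s\n",
              nrow(x), length(unique(x$drug_id)), length(unique(x$target_id)),
              attr(x, "label_kind")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

label_kind <- function(table) attr(table, "label_kind")

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) validation_error(sprintf("empty file: %s", path))
  if (grepl("\t", first)) "\t" else ","
}

#' Read an interaction table from delimited text
#'
#' Reads a UTF-8 TSV/CSV file with a header row. The delimiter is
#' auto-detected from {tab, comma} unless given explicitly. Rows whose label
#' does not parse as a number are rejected with their row index reported.
#'
#' @param path file path.
#' @param column_map named list/character mapping the roles `drug`, `target`,
#'   `label` (and optionally `date`) to column names in the file.
#' @param label_kind `"continuous"` or `"binary"`.
#' @param delimiter `NULL` (auto-detect), `"\t"` or `","`.
#' @param allow_duplicates see [interaction_table()].
#' @return An [interaction_table()].
#' @export
load_interaction_table <- function(path,
                                   column_map = list(drug = "drug_id",
                                                     target = "target_id",
                                                     label = "label",
                                                     date = "date"),
                                   label_kind = c("continuous", "binary"),
                                   delimiter = NULL,
                                   allow_duplicates = FALSE) {
  label_kind <- match.arg(label_kind)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  delimiter <- delimiter %||% detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", fileEncoding = "UTF-8")
  if (nrow(df) == 0) validation_error(sprintf("no data rows in %s", path))
  need <- c(drug = column_map$drug %||% "drug_id",
            target = column_map$target %||% "target_id",
            label = column_map$label %||% "label")
  missing_cols <- setdiff(unname(need), names(df))
  if (length(missing_cols)) {
    schema_error(sprintf("missing column(s) %s in %s",
                         paste(missing_cols, collapse = ", "), path))
  }
  lab_raw <- df[[need[["label"]]]]
  lab <- suppressWarnings(as.numeric(lab_raw))
  bad <- which(is.na(lab))
  if (length(bad)) {
    validation_error(sprintf(
      "unparseable label at data row(s) %s (value %s)",
      paste(utils::head(bad, 5), collapse = ", "),
      paste(sQuote(utils::head(lab_raw[bad], 5)), collapse = ", ")))
  }
  date_col <- column_map$date %||% "date"
  dates <- if (date_col %in% names(df)) {
    d <- as.Date(df[[date_col]], optional = TRUE)
    d
  } else NULL
  interaction_table(df[[need[["drug"]]]], df[[need[["target"]]]], lab,
                    date = dates, label_kind = label_kind,
                    allow_duplicates = allow_duplicates)
}

#' Write an interaction table as TSV
#'
#' Labels are serialized at full double precision so that a load/write/load
#' round trip is bit-exact.
#'
#' @param table an [interaction_table()].
#' @param path output path.
#' @export
write_interaction_table <- function(table, path) {
  df <- data.frame(drug_id = table$drug_id,
                   target_id = table$target_id,
                   label = full_precision(table$label),
                   stringsAsFactors = FALSE)
  if (any(!is.na(table$date))) df$date <- format(table$date)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an embedding store
#'
#' An embedding store maps identifiers (drugs or protein targets) to fixed-
#' dimension numeric vectors, standing in for the output of a pretrained
#' encoder (e.g. CDDD for compounds, SeqVec for proteins).
#'
#' @param mat numeric matrix with one row per id; rownames are the ids.
#' @return An object of class `embedding_store` with fields `dim`, `ids`
#'   and the row-per-id `matrix`.
#' @export
embedding_store <- function(mat) {
  assert_that(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  assert_that(nrow(mat) >= 1, "embedding store must contain at least one id")
  ids <- rownames(mat)
  assert_that(!is.null(ids) && all(nzchar(ids)) && !anyDuplicated(ids),
              "mat must have unique non-empty rownames (the ids)")
  if (!all(is.finite(mat))) validation_error("embeddings contain non-finite entries")
  structure(list(dim = ncol(mat), ids = ids, matrix = mat),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %d ids x dim %d\n", length(x$ids), x$dim))
  invisible(x)
}

#' Look up embeddings by id
#'
#' @param store an [embedding_store()].
#' @param ids character vector of ids; all must be present.
#' @return numeric matrix, one row per requested id.
#' @export
get_embeddings <- function(store, ids) {
  miss <- setdiff(ids, store$ids)
  if (length(miss)) {
    validation_error(sprintf("id(s) not in embedding store: %s",
                             paste(utils::head(miss, 5), collapse = ", ")))
  }
  store$matrix[ids, , drop = FALSE]
}

#' Read an embedding store from delimited text
#'
#' Expected layout: header `id<TAB>e1<TAB>e2...`, one row per id, all rows of
#' equal length. The dimension is inferred from the file. This is the
#' package's encoder-agnostic interchange format for precomputed embeddings.
#'
#' @param path file path (TSV or CSV, auto-detected).
#' @return An [embedding_store()].
#' @export
load_embeddings <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  delimiter <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", fileEncoding = "UTF-8")
  if (nrow(df) == 0) validation_error(sprintf("empty embedding container: %s", path))
  if (ncol(df) < 2) schema_error("embedding file needs an id column plus numeric columns")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) {
    validation_error("embedding container has NaN/NA or ragged rows")
  }
  rownames(mat) <- ids
  colnames(mat) <- NULL
  embedding_store(mat)
}

#' Write an embedding store as TSV
#' @param store an [embedding_store()].
#' @param path output path.
#' @export
write_embeddings <- function(store, path) {
  df <- data.frame(id = store$ids, stringsAsFactors = FALSE)
  num <- apply(store$matrix, 2, full_precision)
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  colnames(num) <- paste0("e", seq_len(store$dim))
  utils::write.table(cbind(df, num), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column id/SMILES file
#' @param path TSV/CSV with columns `id` and `smiles` (header required).
#' @return named character vector of SMILES keyed by id.
#' @export
load_smiles <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  delimiter <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", stringsAsFactors = FALSE,
                          comment.char = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(c("id", "smiles"), names(df))
  if (length(missing_cols)) {
    schema_error(sprintf("SMILES file must have columns id, smiles (missing %s)",
                         paste(missing_cols, collapse = ", ")))
  }
  stats::setNames(df$smiles, df$id)
}

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of amino-acid sequences keyed by record id.
#' @export
load_fasta <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readAAStringSet(path)
    out <- as.character(seqs)
    names(out) <- sub("\\s.*$", "", names(seqs))
    return(out)
  }
  # plain-text fallback parser
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) validation_error(sprintf("not a FASTA file: %s", path))
  idx <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  stats::setNames(unname(seqs), ids)
}

#' Threshold continuous labels into binary activity calls
#'
#' Applies the benchmark convention of a fixed log-affinity threshold
#' (6.5 for ChEMBL-derived bioactivity, 7 for kinase-affinity data).
#' The tie side is `label >= threshold -> active (1)`.
#'
#' @param table a continuous [interaction_table()].
#' @param threshold numeric scalar on the label scale.
#' @return A new binary [interaction_table()]; the input is unmodified.
#' @export
binarize_labels <- function(table, threshold) {
  if (label_kind(table) != "continuous") {
    contract_error("binarize_labels requires a continuous table (already binary?)")
  }
  assert_that(is.numeric(threshold) && length(threshold) == 1 && is.finite(threshold),
              "threshold must be a finite scalar")
  interaction_table(table$drug_id, table$target_id,
                    as.numeric(table$label >= threshold),
                    date = table$date, label_kind = "binary",
                    allow_duplicates = TRUE)
}

#' Check that every id in a table is covered by the embedding stores
#'
#' Report-only: never errors. An empty report means full coverage.
#'
#' @param table an [interaction_table()].
#' @param drug_store,target_store [embedding_store()] objects.
#' @return list with `missing_drugs`, `missing_targets`, and logical `ok`.
#' @export
validate_coverage <- function(table, drug_store, target_store) {
  md <- setdiff(unique(table$drug_id), drug_store$ids)
  mt <- setdiff(unique(table$target_id), target_store$ids)
  list(missing_drugs = md, missing_targets = mt,
       ok = length(md) == 0 && length(mt) == 0)
}
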