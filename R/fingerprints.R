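# Circular (Morgan/ECFP-style) fingerprints over a minimal SMILES subset.
#
# The parser covers the organic subset (B C N O P S F Cl Br I, aromatic
# b c n o p s), bracket atoms with charge/H-count, branches, ring closures
# (including %nn), bond symbols - = # : / \ and the fragment dot. Stereo
# marks are read as single bonds. Bit patterns are deterministic but use
# this package's own hash, so they are not bit-compatible with other
# toolkits; splitting only needs a stable structural similarity signal.

.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

# multiply-add hash kept below 2^31 so double arithmetic stays exact
.hash_mod <- 2147483629
.hash_mix <- function(h, v) (h * 31 + v + 7) %% .hash_mod

.hash_seq <- function(values) {
  h <- 17
  for (v in values) h <- .hash_mix(h, v)
  h
}

parse_smiles <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  elem <- character(0); arom <- logical(0); charge <- integer(0); hexp <- integer(0)
  bonds <- list()  # each: c(a, b, order*10)
  prev <- NA_integer_
  pending_bond <- NA_real_
  stack <- integer(0)
  rings <- list()  # key -> list(atom, order)
  i <- 1
  add_atom <- function(el, aromatic, ch = 0L, hx = NA_integer_) {
    elem[length(elem) + 1] <<- el
    arom[length(arom) + 1] <<- aromatic
    charge[length(charge) + 1] <<- ch
    hexp[length(hexp) + 1] <<- hx
    a <- length(elem)
    if (!is.na(prev)) {
      ord <- if (!is.na(pending_bond)) pending_bond
             else if (arom[prev] && aromatic) 1.5 else 1
      bonds[[length(bonds) + 1]] <<- c(prev, a, ord * 10)
    }
    pending_bond <<- NA_real_
    prev <<- a
    a
  }
  close_ring <- function(key) {
    if (!is.null(rings[[key]])) {
      r <- rings[[key]]
      a <- r$atom; b <- prev
      ord <- if (!is.na(pending_bond)) pending_bond
             else if (!is.na(r$order)) r$order
             else if (arom[a] && arom[b]) 1.5 else 1
      bonds[[length(bonds) + 1]] <<- c(a, b, ord * 10)
      rings[[key]] <<- NULL
      pending_bond <<- NA_real_
    } else {
      if (is.na(prev)) validation_error("ring bond before any atom")
      rings[[key]] <<- list(atom = prev, order = pending_bond)
      pending_bond <<- NA_real_
    }
  }
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1]) else ""
    if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE); i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE); i <- i + 1
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE); i <- i + 1
    } else if (ch == "[") {
      j <- i + 1
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) validation_error("unclosed bracket atom")
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(H([0-9]*))?([+-][0-9]*)?$", body))[[1]]
      if (length(m) == 0) validation_error(sprintf("unparseable bracket atom [%s]", body))
      el <- m[3]
      aromatic <- el == tolower(el) && nchar(el) == 1
      el_up <- if (aromatic) toupper(el) else el
      hx <- if (nzchar(m[4])) { if (nzchar(m[5])) as.integer(m[5]) else 1L } else 0L
      chg <- 0L
      if (nzchar(m[6])) {
        sgn <- if (substr(m[6], 1, 1) == "+") 1L else -1L
        mag <- if (nchar(m[6]) > 1) as.integer(substr(m[6], 2, nchar(m[6]))) else 1L
        chg <- sgn * mag
      }
      add_atom(el_up, aromatic, chg, hx)
      i <- j + 1
    } else if (ch == "(") {
      if (is.na(prev)) validation_error("branch opened before any atom")
      stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) validation_error("unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- 1; i <- i + 1
    } else if (ch == "=") {
      pending_bond <- 2; i <- i + 1
    } else if (ch == "#") {
      pending_bond <- 3; i <- i + 1
    } else if (ch == ":") {
      pending_bond <- 1.5; i <- i + 1
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NA_real_; i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n) validation_error("truncated %nn ring closure")
      close_ring(paste0(chars[i + 1], chars[i + 2])); i <- i + 3
    } else {
      validation_error(sprintf("unsupported SMILES character '%s'", ch))
    }
  }
  if (length(stack)) validation_error("unclosed branch '('")
  if (length(rings)) validation_error("unclosed ring closure")
  if (length(elem) == 0) validation_error("SMILES contains no atoms")
  bmat <- if (length(bonds)) do.call(rbind, bonds) else matrix(0, 0, 3)
  list(element = elem, aromatic = arom, charge = charge, h_explicit = hexp,
       bonds = bmat)
}

.atom_invariants <- function(mol) {
  natom <- length(mol$element)
  degree <- integer(natom)
  bond_order_sum <- numeric(natom)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[k, 1]; b <- mol$bonds[k, 2]; o <- mol$bonds[k, 3] / 10
      degree[a] <- degree[a] + 1L; degree[b] <- degree[b] + 1L
      bond_order_sum[a] <- bond_order_sum[a] + o
      bond_order_sum[b] <- bond_order_sum[b] + o
    }
  }
  val <- .default_valence[mol$element]
  hcount <- ifelse(is.na(mol$h_explicit),
                   pmax(0, round(ifelse(is.na(val), 0, val) -
                                   bond_order_sum - abs(mol$charge))),
                   mol$h_explicit)
  elem_code <- match(mol$element, names(.default_valence), nomatch = 99L)
  vapply(seq_len(natom), function(a) {
    .hash_seq(c(elem_code[a], degree[a], hcount[a],
                mol$charge[a] + 10, as.integer(mol$aromatic[a])))
  }, numeric(1))
}

.fingerprint_one <- function(smiles, radius, n_bits) {
  mol <- parse_smiles(smiles)
  natom <- length(mol$element)
  nbrs <- vector("list", natom)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[k, 1]; b <- mol$bonds[k, 2]; o <- mol$bonds[k, 3]
      nbrs[[a]] <- rbind(nbrs[[a]], c(b, o))
      nbrs[[b]] <- rbind(nbrs[[b]], c(a, o))
    }
  }
  ids <- .atom_invariants(mol)
  all_ids <- ids
  r <- 1
  while (r <= radius) {
    new_ids <- numeric(natom)
    for (a in seq_len(natom)) {
      if (is.null(nbrs[[a]])) {
        new_ids[a] <- .hash_seq(c(r, ids[a]))
      } else {
        pairs <- cbind(nbrs[[a]][, 2], ids[nbrs[[a]][, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        new_ids[a] <- .hash_seq(c(r, ids[a], t(pairs[ord, , drop = FALSE])))
      }
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
    r <- r + 1
  }
  bits <- integer(n_bits)
  bits[unique(all_ids %% n_bits) + 1] <- 1L
  bits
}

#' Compute Morgan-style circular fingerprints for a set of compounds
#'
#' Hashes circular substructure environments up to `radius` bonds around each
#' atom and folds them into `n_bits` bits, the representation used for
#' compound clustering in leave-cluster-compound-out splitting.
#'
#' @param smiles_map named character vector: id -> SMILES.
#' @param radius neighborhood radius in bonds (default 2, i.e. ECFP4-like).
#' @param n_bits fingerprint length (default 256).
#' @return A `fingerprint_set`: integer 0/1 matrix (ids x n_bits) with
#'   rownames the compound ids.
#' @export
compute_morgan_fingerprints <- function(smiles_map, radius = 2L, n_bits = 256L) {
  assert_that(length(smiles_map) >= 1, "smiles_map must be non-empty")
  assert_that(!is.null(names(smiles_map)) && all(nzchar(names(smiles_map))),
              "smiles_map must be named by compound id")
  out <- matrix(0L, nrow = length(smiles_map), ncol = n_bits,
                dimnames = list(names(smiles_map), NULL))
  for (i in seq_along(smiles_map)) {
    bits <- tryCatch(.fingerprint_one(smiles_map[[i]], radius, n_bits),
                     hpcm_error = function(e) {
                       validation_error(sprintf(
                         "invalid SMILES for id '%s': %s",
                         names(smiles_map)[i], conditionMessage(e)))
                     })
    out[i, ] <- bits
  }
  structure(out, class = c("fingerprint_set", "matrix", "array"))
}

#' Load precomputed fingerprints from delimited text
#'
#' Alternative to [compute_morgan_fingerprints()] when bit vectors were
#' produced by an external toolkit. Format: header `id b1 b2 ...`, entries 0/1.
#'
#' @param path TSV/CSV path.
#' @return A `fingerprint_set` matrix.
#' @export
load_fingerprints <- function(path) {
  store <- load_embeddings(path)
  m <- store$matrix
  if (!all(m %in% c(0, 1))) validation_error("fingerprint entries must be 0/1")
  storage.mode(m) <- "integer"
  colnames(m) <- NULL
  structure(m, class = c("fingerprint_set", "matrix", "array"))
}

#' Write fingerprints as delimited text
#' @param fps a `fingerprint_set`.
#' @param path output path.
#' @export
write_fingerprints <- function(fps, path) {
  df <- data.frame(id = rownames(fps), stringsAsFactors = FALSE)
  bits <- as.data.frame(unclass(fps))
  colnames(bits) <- paste0("b", seq_len(ncol(fps)))
  utils::write.table(cbind(df, bits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
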