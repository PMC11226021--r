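# Independent oracles and random generators for property tests.

# --- brute-force maximum common connected substructure ----------------------
# Enumerates every connected vertex subset of molecule `a`, every injective
# element/aromaticity-compatible mapping into `b`, and keeps the largest
# whose matching-bond graph (bonds present on both sides with equal order)
# spans the subset. Exhaustive, so only usable for small molecules; written
# without reference to the package's search.

oracle_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(matrix(numeric(), ncol = 3))
  as.matrix(mol$bonds[, c("i", "j", "order")])
}

oracle_bond_order <- function(bm, i, j) {
  k <- which((bm[, 1] == i & bm[, 2] == j) | (bm[, 1] == j & bm[, 2] == i))
  if (length(k)) bm[k[1], 3] else NA_real_
}

# all vertex subsets of `a` connected in a's bond graph
oracle_connected_subsets <- function(mol) {
  n <- nrow(mol$atoms)
  bm <- oracle_bonds(mol)
  subsets <- list()
  for (code in seq_len(2^n - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (length(S) == 1) { subsets[[length(subsets) + 1]] <- S; next }
    # BFS connectivity within S
    seen <- S[1]; frontier <- S[1]
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in setdiff(S, seen))
        if (!is.na(oracle_bond_order(bm, v, w))) nxt <- c(nxt, w)
      nxt <- unique(setdiff(nxt, seen))
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) == length(S)) subsets[[length(subsets) + 1]] <- S
  }
  subsets
}

brute_mcs <- function(a, b) {
  bm_a <- oracle_bonds(a); bm_b <- oracle_bonds(b)
  key_a <- paste(a$atoms$element, a$atoms$aromatic)
  key_b <- paste(b$atoms$element, b$atoms$aromatic)
  best <- 0L
  check_mapping <- function(S, img) {
    # matching-bond graph must connect S
    if (length(S) == 1) return(TRUE)
    edges <- list()
    for (p in seq_along(S)) for (q in seq_along(S)) {
      if (p >= q) next
      oa <- oracle_bond_order(bm_a, S[p], S[q])
      ob <- oracle_bond_order(bm_b, img[p], img[q])
      if (!is.na(oa) && !is.na(ob) && oa == ob)
        edges[[length(edges) + 1]] <- c(p, q)
    }
    if (!length(edges)) return(FALSE)
    seen <- 1L; repeat {
      grew <- FALSE
      for (e in edges) {
        if (e[1] %in% seen && !(e[2] %in% seen)) { seen <- c(seen, e[2]); grew <- TRUE }
        if (e[2] %in% seen && !(e[1] %in% seen)) { seen <- c(seen, e[1]); grew <- TRUE }
      }
      if (!grew) break
    }
    length(seen) == length(S)
  }
  assign_next <- function(S, pos, img, used) {
    if (pos > length(S)) {
      if (check_mapping(S, img)) best <<- max(best, length(S))
      return()
    }
    for (cand in which(key_b == key_a[S[pos]])) {
      if (cand %in% used) next
      assign_next(S, pos + 1, c(img, cand), c(used, cand))
    }
  }
  for (S in oracle_connected_subsets(a)) {
    if (length(S) <= best) next
    assign_next(S, 1, integer(), integer())
  }
  best
}

# --- random structure generator ---------------------------------------------
# Random small molecules as trees with occasional extra ring bond; elements
# biased toward carbon, bond orders toward single. Uses the current RNG
# stream (callers seed).
random_molecule <- function(n_min = 3, n_max = 7) {
  n <- sample(n_min:n_max, 1)
  elements <- sample(c("C", "C", "C", "O", "N"), n, replace = TRUE)
  atoms <- data.frame(element = elements, aromatic = FALSE, charge = 0L,
                      stringsAsFactors = FALSE)
  bonds <- NULL
  for (v in 2:n) {
    u <- sample(seq_len(v - 1), 1)
    bonds <- rbind(bonds, data.frame(i = u, j = v,
                                     order = sample(c(1, 1, 1, 2), 1)))
  }
  if (n >= 4 && stats::runif(1) < 0.3) {
    pair <- sample(seq_len(n), 2)
    dup <- any((bonds$i == min(pair) & bonds$j == max(pair)) |
               (bonds$i == max(pair) & bonds$j == min(pair)))
    if (!dup) bonds <- rbind(bonds, data.frame(i = pair[1], j = pair[2], order = 1))
  }
  molecule(atoms, bonds)
}

# --- random feature tables ---------------------------------------------------
random_feature_table <- function(n_samples = NULL, n_records = NULL) {
  n_samples <- n_samples %||% sample(1:4, 1)
  samples <- sprintf("s%02d", seq_len(n_samples))
  names_pool <- c("undecane", "nonanal", "linalool", "toluene", "styrene",
                  "unknown hit A", "unknown hit B")
  recs <- do.call(rbind, lapply(samples, function(s) {
    k <- n_records %||% sample(1:8, 1)
    data.frame(sample_id = s,
               compound_name = sample(names_pool, k, replace = TRUE),
               rt = round(stats::runif(k, 2, 30), 3),
               base_peak_mz = sample(40:250, k, replace = TRUE),
               match_factor = round(stats::runif(k, 40, 100), 1),
               area = round(10 ^ stats::runif(k, 3, 7)),
               stringsAsFactors = FALSE)
  }))
  ord <- stats::ave(seq_len(nrow(recs)), recs$sample_id, FUN = seq_along)
  recs$uid <- paste0(recs$sample_id, "#", ord)
  feature_table(recs[, c("uid", "sample_id", "compound_name", "rt",
                         "base_peak_mz", "match_factor", "area")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sorted-by-uid record comparison (spread/flatten reorders within sample)
records_equal <- function(t1, t2) {
  r1 <- t1$records[order(t1$records$uid), ]
  r2 <- t2$records[order(t2$records$uid), ]
  rownames(r1) <- rownames(r2) <- NULL
  isTRUE(all.equal(r1, r2, tolerance = 1e-12))
}

# a resolver backend over a plain named list of compound_records
list_backend <- function(recs) {
  names(recs) <- vapply(recs, function(r) r$query_name, "")
  function(name) {
    key <- normalize_name(name)
    for (r in recs)
      if (key %in% normalize_name(c(r$query_name, r$synonyms))) return(r)
    NULL
  }
}

write_tmp_csv <- function(df, ...) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, f, row.names = FALSE, ...)
  f
}
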