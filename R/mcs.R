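# Maximum common connected substructure (MCS) and the Tanimoto coefficient
# over it.
#
# Matching rules: atoms match on element symbol AND aromaticity (an aromatic
# carbon never matches an aliphatic one); bonds match on order, with
# aromatic a distinct order. The common subgraph is a set of atom pairs
# spanned by matching bonds and must be connected (the usual convention in
# molecular MCS work); bonds that disagree between the two molecules are not
# part of the common subgraph. Search is exact up to a configurable
# heavy-atom budget; beyond it a greedy seeded extension is used and the
# result is flagged approximate.

#' Size of the maximum common connected substructure
#'
#' Number of atoms in the largest connected subgraph present in both
#' molecules under strict element/aromaticity atom matching and strict
#' bond-order matching.
#'
#' @param a,b `molecule` objects.
#' @param exact_budget heavy-atom budget for exact search (both molecules
#'   must be at or under it); larger inputs fall back to a greedy heuristic
#'   and the returned value carries `attr(, "approximate") = TRUE`.
#' @return integer atom count (0 when no atom pair is compatible).
#' @export
#' @examples
#' mcs_size(parse_smiles("CC"), parse_smiles("CCC"))  # 2
mcs_size <- function(a, b, exact_budget = 40L) {
  na <- nrow(a$atoms); nb <- nrow(b$atoms)
  compat <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    compat[i, j] <- a$atoms$element[i] == b$atoms$element[j] &&
      a$atoms$aromatic[i] == b$atoms$aromatic[j]
  if (!any(compat)) return(structure(0L, approximate = FALSE))

  lk_a <- bond_lookup(a); lk_b <- bond_lookup(b)
  exact <- na <= exact_budget && nb <= exact_budget

  # static upper bound: compatible atoms per (element, aromatic) class
  class_a <- paste(a$atoms$element, a$atoms$aromatic)
  class_b <- paste(b$atoms$element, b$atoms$aromatic)
  lv <- unique(c(class_a, class_b))
  class_cap <- sum(pmin(table(factor(class_a, lv)), table(factor(class_b, lv))))

  best <- 0L
  seen <- new.env(parent = emptyenv())  # dedup partial mappings across orders

  extend <- function(map_a, map_b, greedy) {
    size <- length(map_a)
    if (size > best) best <<- size
    if (best >= class_cap) return()
    cands <- candidate_pairs(map_a, map_b, compat, lk_a, lk_b)
    if (!nrow(cands)) return()
    if (greedy) {
      extend(c(map_a, cands[1, 1]), c(map_b, cands[1, 2]), TRUE)
      return()
    }
    for (r in seq_len(nrow(cands))) {
      nm_a <- c(map_a, cands[r, 1]); nm_b <- c(map_b, cands[r, 2])
      o <- order(nm_a)
      key <- paste(nm_a[o], nm_b[o], collapse = ",")
      if (exists(key, envir = seen, inherits = FALSE)) next
      assign(key, TRUE, envir = seen)
      extend(nm_a, nm_b, FALSE)
    }
  }

  seeds <- which(compat, arr.ind = TRUE)
  for (s in seq_len(nrow(seeds))) {
    if (best >= class_cap) break
    extend(seeds[s, 1], seeds[s, 2], greedy = !exact)
  }
  structure(as.integer(best), approximate = !exact)
}

# hashed bond-order lookup plus adjacency lists
bond_lookup <- function(mol) {
  n <- nrow(mol$atoms)
  ord <- new.env(parent = emptyenv())
  adj <- vector("list", n); for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
    assign(paste(i, j), o, envir = ord); assign(paste(j, i), o, envir = ord)
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  list(order = ord, adj = adj)
}

bond_order_of <- function(lk, i, j) {
  key <- paste(i, j)
  if (exists(key, envir = lk$order, inherits = FALSE))
    get(key, envir = lk$order) else NA_real_
}

# extension pairs (x in A, y in B): both unmapped, atom-compatible, and
# joined to some mapped pair by bonds of equal order on both sides (which
# keeps the growing common subgraph connected)
candidate_pairs <- function(map_a, map_b, compat, lk_a, lk_b) {
  xs <- setdiff(unique(unlist(lapply(map_a, function(i) lk_a$adj[[i]]))), map_a)
  out <- matrix(integer(), ncol = 2)
  for (x in xs) {
    for (y in setdiff(which(compat[x, ]), map_b)) {
      for (m in seq_along(map_a)) {
        oa <- bond_order_of(lk_a, x, map_a[m])
        if (is.na(oa)) next
        ob <- bond_order_of(lk_b, y, map_b[m])
        if (!is.na(ob) && oa == ob) { out <- rbind(out, c(x, y)); break }
      }
    }
  }
  out
}

#' MCS-based Tanimoto similarity
#'
#' `n / (n_a + n_b - n)` where `n` is [mcs_size()] and `n_a`, `n_b` are the
#' heavy-atom counts. Symmetric; equals 1 exactly when the two graphs are
#' isomorphic under the matching rules.
#'
#' @inheritParams mcs_size
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_mcs <- function(a, b, exact_budget = 40L) {
  n <- as.integer(mcs_size(a, b, exact_budget = exact_budget))
  n / (nrow(a$atoms) + nrow(b$atoms) - n)
}
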