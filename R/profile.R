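# Substructure profiling: rings, atom counts, functional-group counts,
# formal charges. Group recognition is pattern-matching on the heavy-atom
# graph; each atom can anchor at most one occurrence of a given group, and
# the carbonyl-carbon groups (acid / ester / amide / aldehyde / ketone) are
# mutually exclusive per carbonyl, resolved in that priority order.

.group_labels <- c("hydroxyl", "aldehyde", "carboxylic_acid", "ketone",
                   "ester", "ether", "primary_amine", "amide", "nitrile",
                   "halide", "thiol", "nitro")

#' Substructure profile of a molecule
#'
#' Counts rings (cyclomatic number), atoms per element, formal charges and
#' a fixed set of functional groups: hydroxyl, aldehyde, carboxylic acid,
#' ketone, ester, ether, primary amine, amide, nitrile, halide, thiol,
#' nitro.
#'
#' @param mol a `molecule`.
#' @return a `substructure_profile`: list with `ring_count`, `atom_counts`
#'   (named integer), `group_counts` (named integer over the fixed label
#'   set), `charge_count`.
#' @export
#' @examples
#' substructure_profile(parse_smiles("CC(=O)O"))  # acetic acid
substructure_profile <- function(mol) {
  if (is.null(mol$atoms$h_count)) mol$atoms$h_count <- implicit_h(mol)
  at <- mol$atoms
  n <- nrow(at)
  adj <- adjacency_list(mol)
  bond_order <- function(a, b) {
    k <- which((mol$bonds$i == a & mol$bonds$j == b) |
               (mol$bonds$i == b & mol$bonds$j == a))
    if (length(k)) mol$bonds$order[k[1]] else NA_real_
  }
  nbrs <- function(a) adj[[a]]
  is_el <- function(a, el) at$element[a] == el

  # carbonyl carbons: C with a double bond to O
  carbonyl_o <- rep(NA_integer_, n)
  for (a in seq_len(n)) {
    if (!is_el(a, "C") || at$aromatic[a]) next
    for (b in nbrs(a))
      if (is_el(b, "O") && identical(bond_order(a, b), 2)) { carbonyl_o[a] <- b; break }
  }

  g <- stats::setNames(integer(length(.group_labels)), .group_labels)
  claimed_o <- logical(n)   # oxygens consumed by acid/ester groups

  for (a in which(!is.na(carbonyl_o))) {
    oxo <- carbonyl_o[a]
    others <- setdiff(nbrs(a), oxo)
    single_o <- others[at$element[others] == "O" &
                       vapply(others, function(b) identical(bond_order(a, b), 1), TRUE)]
    n_nbr <- others[at$element[others] == "N"]
    c_nbr <- others[at$element[others] == "C"]
    if (length(single_o)) {
      o <- single_o[1]
      o_heavy <- setdiff(nbrs(o), a)
      if (length(o_heavy) == 0L) {           # C(=O)-OH
        g["carboxylic_acid"] <- g["carboxylic_acid"] + 1L
      } else {                               # C(=O)-O-R
        g["ester"] <- g["ester"] + 1L
      }
      claimed_o[c(oxo, o)] <- TRUE
    } else if (length(n_nbr)) {
      g["amide"] <- g["amide"] + 1L
      claimed_o[oxo] <- TRUE
    } else if (length(c_nbr) >= 2L) {
      g["ketone"] <- g["ketone"] + 1L
      claimed_o[oxo] <- TRUE
    } else if (at$h_count[a] >= 1L) {
      g["aldehyde"] <- g["aldehyde"] + 1L
      claimed_o[oxo] <- TRUE
    }
  }

  for (a in seq_len(n)) {
    el <- at$element[a]
    if (el == "O" && !at$aromatic[a] && !claimed_o[a]) {
      heavy <- nbrs(a)
      dbl <- any(vapply(heavy, function(b) identical(bond_order(a, b), 2), TRUE))
      if (!dbl && length(heavy) == 1L && at$h_count[a] >= 1L)
        g["hydroxyl"] <- g["hydroxyl"] + 1L
      if (!dbl && length(heavy) == 2L)
        g["ether"] <- g["ether"] + 1L
    } else if (el == "N" && !at$aromatic[a]) {
      heavy <- nbrs(a)
      triple_c <- heavy[vapply(heavy, function(b)
        is_el(b, "C") && identical(bond_order(a, b), 3), TRUE)]
      if (length(triple_c)) { g["nitrile"] <- g["nitrile"] + 1L; next }
      dbl_o <- heavy[at$element[heavy] == "O" &
                     vapply(heavy, function(b) identical(bond_order(a, b), 2), TRUE)]
      chg_o <- heavy[at$element[heavy] == "O" & at$charge[heavy] < 0L]
      if (length(dbl_o) + length(chg_o) >= 2L) { g["nitro"] <- g["nitro"] + 1L; next }
      amide_n <- any(!is.na(carbonyl_o[heavy]))
      if (!amide_n && length(heavy) == 1L && at$h_count[a] >= 2L)
        g["primary_amine"] <- g["primary_amine"] + 1L
    } else if (el %in% c("F", "Cl", "Br", "I")) {
      g["halide"] <- g["halide"] + 1L
    } else if (el == "S" && !at$aromatic[a]) {
      heavy <- nbrs(a)
      if (length(heavy) == 1L && at$h_count[a] >= 1L)
        g["thiol"] <- g["thiol"] + 1L
    }
  }

  structure(list(
    ring_count = ring_count(mol),
    atom_counts = as.integer(table(at$element)) |>
      stats::setNames(names(table(at$element))),
    group_counts = g,
    charge_count = sum(at$charge != 0L)
  ), class = "substructure_profile")
}

#' @export
print.substructure_profile <- function(x, ...) {
  cat(sprintf("substructure_profile: %d ring(s), %d charged atom(s)\n",
              x$ring_count, x$charge_count))
  cat("  atoms: ", paste(sprintf("%s=%d", names(x$atom_counts), x$atom_counts),
                         collapse = " "), "\n")
  gz <- x$group_counts[x$group_counts > 0]
  if (length(gz))
    cat("  groups:", paste(sprintf("%s=%d", names(gz), gz), collapse = " "), "\n")
  invisible(x)
}
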