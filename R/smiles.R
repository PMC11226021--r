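# SMILES-subset parser producing a heavy-atom molecular graph.
#
# Supported notation: organic-subset atoms (B C N O P S F Cl Br I) and their
# aromatic lowercase forms (b c n o p s), bracket atoms with explicit H
# counts and formal charges, single/double/triple/aromatic bonds (- = # :),
# branches, and ring closures (digits and %nn, up to 99). Stereo bonds (/ \)
# are read as single bonds; chirality marks and isotopes are ignored with a
# warning. Hydrogens are suppressed: the graph holds heavy atoms only, with
# an implicit-H count per atom (Daylight valence rules; aromatic bonds count
# 1.5 toward the valence sum).

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.default_valence <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                         S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

# bond order coding: 1, 2, 3, 1.5 (aromatic)
AROMATIC_BOND <- 1.5

#' Parse a SMILES string into a molecular graph
#'
#' @param text SMILES string (see the supported subset in the package
#'   vignette; no stereochemistry, no isotopes).
#' @param name optional molecule name carried on the result.
#' @return a `molecule`: list with `atoms` (data.frame: `element`,
#'   `aromatic`, `charge`, `h_count`) and `bonds` (data.frame: `i`, `j`,
#'   `order`, where order 1.5 denotes aromatic).
#' @export
#' @examples
#' parse_smiles("CCO")       # ethanol: 3 heavy atoms, 2 bonds
#' parse_smiles("c1ccccc1")  # benzene: aromatic ring
parse_smiles <- function(text, name = NULL) {
  if (is.null(text) || is.na(text) || !nzchar(text))
    mz_stop("mz_smiles_error", "empty SMILES string")
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)

  element <- character(); aromatic <- logical(); charge <- integer()
  h_explicit <- integer()  # NA = implicit per valence rules
  bonds_i <- integer(); bonds_j <- integer(); bonds_o <- numeric()

  pos <- 1L
  prev_atom <- NA_integer_       # atom awaiting the next bond
  pending_order <- NA_real_      # explicit bond symbol seen
  branch_stack <- integer()
  ring_open <- list()            # closure label -> list(atom, order)
  warned_stereo <- FALSE; warned_isotope <- FALSE

  err <- function(fmt, ...) mz_stop("mz_smiles_error",
                                    paste0(fmt, " at position %d in '%s'"),
                                    ..., pos, text)

  add_atom <- function(el, arom, chg = 0L, hexp = NA_integer_) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    h_explicit[length(h_explicit) + 1L] <<- hexp
    idx <- length(element)
    if (!is.na(prev_atom)) {
      o <- pending_order
      if (is.na(o)) o <- if (arom && aromatic[prev_atom]) AROMATIC_BOND else 1
      add_bond(prev_atom, idx, o)
    }
    pending_order <<- NA_real_
    prev_atom <<- idx
    idx
  }
  add_bond <- function(a, b, o) {
    if (a == b) err("self-bond")
    dup <- any((bonds_i == a & bonds_j == b) | (bonds_i == b & bonds_j == a))
    if (dup) err("duplicate bond %d-%d", a, b)
    bonds_i[length(bonds_i) + 1L] <<- a
    bonds_j[length(bonds_j) + 1L] <<- b
    bonds_o[length(bonds_o) + 1L] <<- o
  }
  handle_ring <- function(label) {
    key <- as.character(label)
    if (is.na(prev_atom)) err("ring closure before any atom")
    if (!is.null(ring_open[[key]])) {
      opened <- ring_open[[key]]
      o <- pending_order
      if (is.na(o)) o <- opened$order
      if (is.na(o)) o <- if (aromatic[prev_atom] && aromatic[opened$atom])
        AROMATIC_BOND else 1
      add_bond(opened$atom, prev_atom, o)
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <- list(atom = prev_atom, order = pending_order)
      ring_open <<- ring_open
    }
    pending_order <<- NA_real_
  }

  while (pos <= n) {
    ch <- chars[pos]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (ch %in% c("/", "\\")) {
        if (!warned_stereo) { warning("stereo bonds ignored (read as single)")
          warned_stereo <- TRUE }
        pending_order <- 1
      } else pending_order <- switch(ch, "-" = 1, "=" = 2, "#" = 3,
                                     ":" = AROMATIC_BOND)
      pos <- pos + 1L
    } else if (ch == "(") {
      if (is.na(prev_atom)) err("branch before any atom")
      branch_stack <- c(branch_stack, prev_atom)
      pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(branch_stack)) err("unmatched ')'")
      prev_atom <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      handle_ring(as.integer(ch))
      pos <- pos + 1L
    } else if (ch == "%") {
      if (pos + 2L > n || !grepl("^[0-9]{2}$",
                                 paste(chars[(pos + 1):(pos + 2)], collapse = "")))
        err("'%%' must be followed by two digits")
      handle_ring(as.integer(paste(chars[(pos + 1):(pos + 2)], collapse = "")))
      pos <- pos + 3L
    } else if (ch == "[") {
      close_br <- which(chars == "]" & seq_len(n) > pos)[1]
      if (is.na(close_br)) err("unbalanced bracket")
      body <- paste(chars[(pos + 1):(close_br - 1)], collapse = "")
      m <- regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]?))?([+-][0-9]*|\\+\\+|--)?$",
        body)[[1]]
      g <- regmatches(body, list(m))[[1]]
      if (!length(g)) err("cannot parse bracket atom '[%s]'", body)
      if (nzchar(g[2]) && !warned_isotope) {
        warning("isotope labels ignored"); warned_isotope <- TRUE }
      sym <- g[3]
      arom <- sym == tolower(sym) && sym %in% tolower(.organic_subset)
      el <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
      if (!el %in% names(.isotope_mass)) err("unknown element '%s'", el)
      hexp <- if (nzchar(g[5])) { if (nzchar(g[6])) as.integer(g[6]) else 1L } else 0L
      chg <- 0L
      if (nzchar(g[7])) {
        cs <- g[7]
        chg <- if (cs == "++") 2L else if (cs == "--") -2L
          else if (cs %in% c("+", "-")) { if (cs == "+") 1L else -1L }
          else as.integer(cs)
      }
      add_atom(el, arom, chg, hexp)
      pos <- close_br + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      two <- if (pos < n) paste0(ch, chars[pos + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE); pos <- pos + 2L
      } else if (ch %in% .organic_subset) {
        add_atom(ch, FALSE); pos <- pos + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE); pos <- pos + 1L
      } else err("unknown element or symbol '%s'", ch)
    } else if (ch == ".") {
      prev_atom <- NA_integer_; pending_order <- NA_real_
      pos <- pos + 1L
    } else err("unexpected character '%s'", ch)
  }
  if (length(branch_stack)) err("unmatched '('")
  if (length(ring_open))
    mz_stop("mz_smiles_error", "unclosed ring bond(s) %s in '%s'",
            paste(names(ring_open), collapse = ", "), text)
  if (!length(element)) mz_stop("mz_smiles_error", "no atoms in '%s'", text)

  mol <- molecule(
    atoms = data.frame(element = element, aromatic = aromatic,
                       charge = charge, stringsAsFactors = FALSE),
    bonds = data.frame(i = bonds_i, j = bonds_j, order = bonds_o),
    name = name
  )
  mol$atoms$h_count <- implicit_h(mol, h_explicit)
  mol
}

#' Construct a molecule graph
#'
#' @param atoms data.frame with columns `element`, `aromatic` (logical),
#'   `charge` (integer); optionally `h_count`.
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3 or 1.5
#'   for aromatic).
#' @param name optional name.
#' @return a `molecule`.
#' @export
molecule <- function(atoms, bonds, name = NULL) {
  if (nrow(atoms) == 0L) mz_stop("mz_smiles_error", "molecule needs >= 1 atom")
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (nrow(bonds)) {
    if (any(bonds$i == bonds$j)) mz_stop("mz_integrity_error", "self-bond")
    if (any(bonds$i < 1 | bonds$j < 1 | bonds$i > nrow(atoms) | bonds$j > nrow(atoms)))
      mz_stop("mz_integrity_error", "bond index out of range")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) mz_stop("mz_integrity_error", "duplicate bond")
  }
  structure(list(atoms = atoms, bonds = bonds, name = name), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  comp <- table(x$atoms$element)
  cat(sprintf("molecule%s: %d heavy atoms (%s), %d bonds, %d ring(s)\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$atoms),
              paste(sprintf("%s%d", names(comp), comp), collapse = " "),
              nrow(x$bonds), ring_count(x)))
  invisible(x)
}

# Daylight implicit-hydrogen rule: smallest default valence >= bond-order
# sum; bracket atoms carry their H count explicitly and get none implied.
implicit_h <- function(mol, h_explicit = NULL) {
  n <- nrow(mol$atoms)
  bsum <- numeric(n)
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    bsum[mol$bonds$i[k]] <- bsum[mol$bonds$i[k]] + o
    bsum[mol$bonds$j[k]] <- bsum[mol$bonds$j[k]] + o
  }
  h <- integer(n)
  for (a in seq_len(n)) {
    if (!is.null(h_explicit) && !is.na(h_explicit[a])) { h[a] <- h_explicit[a]; next }
    val <- .default_valence[[mol$atoms$element[a]]]
    if (is.null(val)) { h[a] <- 0L; next }
    # aromatic atoms contribute one bond of the ring pi system implicitly:
    # bsum already counts aromatic bonds at 1.5 each, matching e.g. benzene
    # carbon (3.0 of valence 4 -> 1 H)
    need <- val[val >= floor(bsum[a])]
    v <- if (length(need)) min(need) else max(val)
    h[a] <- max(0L, as.integer(floor(v - bsum[a] + 1e-9)))
  }
  h
}

#' Monoisotopic mass of a molecule (heavy atoms + implicit hydrogens)
#' @param mol a `molecule`.
#' @return mass in Da.
#' @export
molecule_mass <- function(mol) {
  if (is.null(mol$atoms$h_count)) mol$atoms$h_count <- implicit_h(mol)
  comp <- tapply(rep(1L, nrow(mol$atoms)), mol$atoms$element, sum)
  total_h <- sum(mol$atoms$h_count)
  mass <- monoisotopic_mass(comp)
  if (total_h > 0) mass <- mass + total_h * .isotope_mass[["H"]]
  mass
}

# connected components of the heavy-atom graph
graph_components <- function(mol) {
  n <- nrow(mol$atoms)
  comp <- integer(n)
  adj <- adjacency_list(mol)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      if (comp[a] != 0L) next
      comp[a] <- cur
      queue <- c(queue, adj[[a]][comp[adj[[a]]] == 0L])
    }
  }
  comp
}

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (a in seq_len(n)) adj[[a]] <- integer()
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Ring count of a molecule (cyclomatic number)
#'
#' `bonds - atoms + connected components`: the number of independent cycles
#' in the heavy-atom graph.
#'
#' @param mol a `molecule`.
#' @return integer >= 0.
#' @export
ring_count <- function(mol) {
  nrow(mol$bonds) - nrow(mol$atoms) + max(graph_components(mol))
}
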