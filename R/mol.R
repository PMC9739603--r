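#' @keywords internal
"_PACKAGE"

# Molecular graphs are stored as a light S3 object:
#   atoms: data.frame(elem, arom, charge, hcount)  -- hydrogens are implicit counts
#   bonds: data.frame(a1, a2, order, arom)         -- a1 < a2 not guaranteed
# Heavy atoms only; explicit H atoms from file formats are folded into hcount.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

ELEMENT_NUMBERS <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L, Mg = 12L,
  P = 15L, S = 16L, Cl = 17L, K = 19L, Ca = 20L, Zn = 30L, Se = 34L,
  Br = 35L, I = 53L
)

new_mol <- function(atoms, bonds, id = "") {
  structure(list(atoms = atoms, bonds = bonds, id = id), class = "fw_mol")
}

#' @export
print.fw_mol <- function(x, ...) {
  cat(sprintf("<fw_mol %s: %d heavy atoms, %d bonds, formal charge %+d>\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds), sum(x$atoms$charge)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# Default valences used to fill implicit hydrogens (smallest value >= bond sum
# is taken for N, P, S which have several common valence states).
default_valences <- function(elem) {
  switch(elem,
    B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
    S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L,
    integer(0))
}

# Adjacency list (heavy neighbours) as a list of integer vectors.
mol_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Bond lookup key "i:j" with i < j -> row index into mol$bonds.
bond_index <- function(mol) {
  if (!nrow(mol$bonds)) return(character(0))
  lo <- pmin(mol$bonds$a1, mol$bonds$a2)
  hi <- pmax(mol$bonds$a1, mol$bonds$a2)
  stats::setNames(seq_len(nrow(mol$bonds)), paste(lo, hi, sep = ":"))
}

# Edges that lie on at least one cycle (non-bridges), found by DFS bridge
# detection.  Used to decide whether an unmarked bond between two aromatic
# atoms is itself aromatic (it is only inside a ring).
cycle_edges <- function(n, bonds) {
  m <- nrow(bonds)
  if (!m) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
  }
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(m)
  # iterative DFS to avoid recursion limits on large inputs
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, pe = 0L, it = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$it <= length(adj[[v]])) {
        k <- adj[[v]][fr$it]
        stack[[length(stack)]]$it <- fr$it + 1L
        if (k == fr$pe) next
        w <- if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          stack[[length(stack) + 1L]] <- list(v = w, pe = k, it = 1L)
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          p <- stack[[length(stack)]]$v
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) is_bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

# ---------------------------------------------------------------------------
# SMILES parsing

#' Parse a SMILES string into a molecular graph
#'
#' A compact SMILES reader supporting the organic subset, bracket atoms with
#' explicit hydrogen counts and formal charges, branches, ring closures
#' (including `%nn`), aromatic lowercase atoms, and disconnected components
#' (`.`). Aromaticity is taken as written (lowercase); no aromatic perception
#' or kekulization is attempted, so aromatic rings must be written in
#' aromatic form. Implicit hydrogens follow the usual default-valence rules;
#' bracket atoms carry exactly the hydrogens they declare.
#'
#' @param smiles character scalar.
#' @param id identifier attached to the molecule.
#' @return an `fw_mol` object.
#' @examples
#' m <- parse_smiles("Clc1ccccc1Br")
#' m$atoms$elem
#' @export
parse_smiles <- function(smiles, id = "") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop("'smiles' must be a non-empty character scalar")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  prev <- 0L           # index of previous atom (0 = none, e.g. after '.')
  pending_bond <- ""   # explicit bond symbol waiting for the next atom
  branch_stack <- integer(0)
  ring_open <- list()  # closure digit -> list(atom, bond)
  i <- 1L

  add_atom <- function(elem, arom, charge, hcount, bracket) {
    atoms[[length(atoms) + 1L]] <<- list(elem = elem, arom = arom,
                                         charge = charge, hcount = hcount,
                                         bracket = bracket)
    length(atoms)
  }
  add_bond <- function(a, b, sym) {
    if (a == b) stop("self-bond in SMILES: ", smiles)
    ord <- if (sym %in% c("", "-", "/", "\\", ":")) 1L
           else if (sym == "=") 2L
           else if (sym == "#") 3L
           else stop("unsupported bond symbol '", sym, "' in SMILES")
    # default bond between two aromatic atoms: candidate for aromaticity,
    # resolved after parsing (must lie in a ring)
    arom <- identical(sym, ":")
    cand <- identical(sym, "") && atoms[[a]]$arom && atoms[[b]]$arom
    bonds[[length(bonds) + 1L]] <<- list(a1 = a, a2 = b, order = ord,
                                         arom = arom, cand = cand)
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\", "~")) {
      if (ch == "~") stop("'~' is not valid in SMILES input")
      pending_bond <- ch; i <- i + 1L; next
    }
    if (ch == "(") {
      if (prev == 0L) stop("branch with no preceding atom in: ", smiles)
      branch_stack <- c(branch_stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (!length(branch_stack)) stop("unbalanced ')' in: ", smiles)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L; next
    }
    if (ch == ".") { prev <- 0L; pending_bond <- ""; i <- i + 1L; next }
    if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop("truncated %nn ring closure in: ", smiles)
        key <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { key <- ch; i <- i + 1L }
      if (prev == 0L) stop("ring closure with no atom in: ", smiles)
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond)
      } else {
        op <- ring_open[[key]]
        sym <- if (nzchar(pending_bond)) pending_bond else op$bond
        add_bond(op$atom, prev, sym)
        ring_open[[key]] <- NULL
      }
      pending_bond <- ""
      next
    }
    if (ch == "[") {
      close <- i
      while (close <= n && chars[close] != "]") close <- close + 1L
      if (close > n) stop("unterminated bracket atom in: ", smiles)
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      idx <- add_atom(at$elem, at$arom, at$charge, at$hcount, TRUE)
      if (prev != 0L) add_bond(prev, idx, pending_bond)
      pending_bond <- ""; prev <- idx; i <- close + 1L; next
    }
    # organic subset atom, possibly two letters (Cl, Br)
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      idx <- add_atom(two, FALSE, 0L, NA_integer_, FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      idx <- add_atom(ch, FALSE, 0L, NA_integer_, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", smiles)
    }
    if (prev != 0L) add_bond(prev, idx, pending_bond)
    pending_bond <- ""; prev <- idx
  }
  if (length(branch_stack)) stop("unbalanced '(' in: ", smiles)
  open_keys <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_keys)) stop("unclosed ring bond(s) in: ", smiles)
  if (!length(atoms)) stop("SMILES contains no atoms: ", smiles)

  atoms_df <- data.frame(
    elem = vapply(atoms, `[[`, character(1), "elem"),
    arom = vapply(atoms, `[[`, logical(1), "arom"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    hcount = vapply(atoms, `[[`, integer(1), "hcount"),
    stringsAsFactors = FALSE
  )
  if (length(bonds)) {
    bonds_df <- data.frame(
      a1 = vapply(bonds, `[[`, integer(1), "a1"),
      a2 = vapply(bonds, `[[`, integer(1), "a2"),
      order = vapply(bonds, `[[`, integer(1), "order"),
      arom = vapply(bonds, `[[`, logical(1), "arom"),
      stringsAsFactors = FALSE
    )
    cand <- vapply(bonds, `[[`, logical(1), "cand")
    if (any(cand)) {
      in_cycle <- cycle_edges(nrow(atoms_df), bonds_df)
      bonds_df$arom <- bonds_df$arom | (cand & in_cycle)
    }
  } else {
    bonds_df <- data.frame(a1 = integer(0), a2 = integer(0),
                           order = integer(0), arom = logical(0))
  }
  mol <- new_mol(atoms_df, bonds_df, id)
  mol$atoms$hcount <- fill_implicit_h(mol)
  mol
}

# [body] without the surrounding brackets -> element, aromatic flag, charge, H
parse_bracket_atom <- function(body, smiles) {
  s <- body
  # isotope prefix (ignored)
  s <- sub("^[0-9]+", "", s)
  m <- regmatches(s, regexpr("^([A-Z][a-z]?|[bcnops])", s))
  if (!length(m)) stop("cannot read bracket atom '[", body, "]' in: ", smiles)
  sym <- m
  s <- substring(s, nchar(sym) + 1L)
  arom <- sym %in% c("b", "c", "n", "o", "p", "s")
  elem <- if (arom) toupper(sym) else sym
  if (!(elem %in% names(ELEMENT_NUMBERS)))
    stop("unknown element '", elem, "' in SMILES: ", smiles)
  s <- gsub("@", "", s, fixed = TRUE)  # chirality ignored
  hcount <- 0L
  hm <- regmatches(s, regexpr("H[0-9]*", s))
  if (length(hm) && nzchar(hm)) {
    hcount <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
    s <- sub("H[0-9]*", "", s)
  }
  charge <- 0L
  cm <- regmatches(s, regexpr("[+-][0-9]*|\\++|-+", s))
  if (length(cm) && nzchar(cm)) {
    if (grepl("^[+-][0-9]+$", cm)) {
      charge <- as.integer(cm)
    } else {
      charge <- nchar(cm) * (if (substring(cm, 1L, 1L) == "+") 1L else -1L)
    }
  }
  list(elem = elem, arom = arom, charge = charge, hcount = hcount)
}

# Implicit hydrogen counts. Bracket atoms keep their declared count; organic
# subset atoms get (smallest default valence >= bond order sum) - bond sum.
# Aromatic atoms use the degree + 1 rule for the delocalized system.
fill_implicit_h <- function(mol) {
  n <- n_atoms(mol)
  hs <- mol$atoms$hcount
  bondsum <- numeric(n)
  degree <- integer(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      o <- mol$bonds$order[k]
      bondsum[i] <- bondsum[i] + o; bondsum[j] <- bondsum[j] + o
      degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
    }
  }
  for (i in seq_len(n)) {
    if (!is.na(hs[i])) next  # bracket atom: explicit count
    eff <- if (mol$atoms$arom[i]) degree[i] + 1L else bondsum[i]
    vals <- default_valences(mol$atoms$elem[i])
    if (!length(vals)) { hs[i] <- 0L; next }
    v <- vals[vals >= eff]
    hs[i] <- if (length(v)) as.integer(v[1] - eff) else 0L
  }
  as.integer(hs)
}

# Heavy degree and total connectivity (heavy degree + implicit H), used by
# the SMARTS X/D primitives.
mol_degrees <- function(mol) {
  n <- n_atoms(mol)
  degree <- integer(n)
  if (nrow(mol$bonds)) {
    tb <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
    degree <- as.integer(tb)
  }
  list(degree = degree, conn = degree + mol$atoms$hcount)
}
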