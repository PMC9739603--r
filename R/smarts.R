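# SMARTS subset engine.
#
# Supported atom primitives: element symbols (aliphatic uppercase, aromatic
# lowercase), #n atomic number, * any, A aliphatic, a aromatic, Hn total
# hydrogen count, Xn total connectivity (heavy degree + hydrogens), Dn heavy
# degree, +/- formal charge. Logical operators: ! (not), & or juxtaposition
# (high-precedence and), , (or), ; (low-precedence and). Bonds: default
# (single-or-aromatic), - single, = double, # triple, : aromatic, ~ any.
# Branches and ring closures as in SMILES. Recursive SMARTS ($(...)) and
# ring-count primitives are not supported; the shipped feature definitions
# stay within this subset.

#' Compile a SMARTS pattern
#'
#' Parses a SMARTS string (see the package vignette for the supported subset)
#' into a pattern graph usable by [count_feature()] and [match_smarts()].
#'
#' @param smarts character scalar SMARTS pattern.
#' @return an object of class `fw_smarts`.
#' @examples
#' p <- parse_smarts("[CX4]")
#' count_feature(parse_smiles("CCO"), p)
#' @export
parse_smarts <- function(smarts) {
  if (!is.character(smarts) || length(smarts) != 1L || is.na(smarts) || !nzchar(smarts))
    stop("'smarts' must be a non-empty character scalar")
  chars <- strsplit(smarts, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()   # ASTs
  bonds <- list()   # a1, a2, sym
  prev <- 0L; pending_bond <- ""; branch_stack <- integer(0)
  ring_open <- list()
  i <- 1L

  add_atom <- function(ast) { atoms[[length(atoms) + 1L]] <<- ast; length(atoms) }
  add_bond <- function(a, b, sym) {
    bonds[[length(bonds) + 1L]] <<- list(a1 = a, a2 = b, sym = sym)
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "~")) { pending_bond <- ch; i <- i + 1L; next }
    if (ch == "(") {
      if (prev == 0L) stop("branch with no preceding atom in SMARTS: ", smarts)
      branch_stack <- c(branch_stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (!length(branch_stack)) stop("unbalanced ')' in SMARTS: ", smarts)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L; next
    }
    if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop("truncated %nn ring closure in SMARTS: ", smarts)
        key <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { key <- ch; i <- i + 1L }
      if (prev == 0L) stop("ring closure with no atom in SMARTS: ", smarts)
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
      close <- i; depth <- 0L
      repeat {
        if (close > n) stop("unterminated bracket in SMARTS: ", smarts)
        if (chars[close] == "[") depth <- depth + 1L
        if (chars[close] == "]") { depth <- depth - 1L; if (depth == 0L) break }
        close <- close + 1L
      }
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      ast <- parse_smarts_expr(body, smarts)
      idx <- add_atom(ast)
      if (prev != 0L) add_bond(prev, idx, pending_bond)
      pending_bond <- ""; prev <- idx; i <- close + 1L; next
    }
    # bare atom outside brackets
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    ast <- NULL
    if (two %in% c("Cl", "Br")) {
      ast <- smarts_prim("elem_aliph", ELEMENT_NUMBERS[[two]]); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      ast <- smarts_prim("elem_aliph", ELEMENT_NUMBERS[[ch]]); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      ast <- smarts_prim("elem_arom", ELEMENT_NUMBERS[[toupper(ch)]]); i <- i + 1L
    } else if (ch == "*") { ast <- smarts_prim("any", 0L); i <- i + 1L
    } else if (ch == "A") { ast <- smarts_prim("aliphatic", 0L); i <- i + 1L
    } else if (ch == "a") { ast <- smarts_prim("aromatic", 0L); i <- i + 1L
    } else stop("unexpected character '", ch, "' in SMARTS: ", smarts)
    idx <- add_atom(ast)
    if (prev != 0L) add_bond(prev, idx, pending_bond)
    pending_bond <- ""; prev <- idx
  }
  if (length(branch_stack)) stop("unbalanced '(' in SMARTS: ", smarts)
  if (any(!vapply(ring_open, is.null, logical(1))))
    stop("unclosed ring bond(s) in SMARTS: ", smarts)
  if (!length(atoms)) stop("SMARTS contains no atoms: ", smarts)

  bonds_df <- if (length(bonds)) data.frame(
    a1 = vapply(bonds, `[[`, integer(1), "a1"),
    a2 = vapply(bonds, `[[`, integer(1), "a2"),
    sym = vapply(bonds, `[[`, character(1), "sym"),
    stringsAsFactors = FALSE
  ) else data.frame(a1 = integer(0), a2 = integer(0), sym = character(0))

  structure(list(atoms = atoms, bonds = bonds_df, smarts = smarts),
            class = "fw_smarts")
}

#' @export
print.fw_smarts <- function(x, ...) {
  cat(sprintf("<fw_smarts '%s': %d atoms, %d bonds>\n",
              x$smarts, length(x$atoms), nrow(x$bonds)))
  invisible(x)
}

smarts_prim <- function(kind, value) list(op = "prim", kind = kind, value = value)

# Bracket expression parser with SMARTS precedence: ! > & (or juxtaposition)
# > , > ;
parse_smarts_expr <- function(body, smarts) {
  toks <- tokenize_smarts_expr(body, smarts)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }

  parse_low <- function() {
    left <- parse_or()
    while (!is.null(peek()) && identical(peek()$t, ";")) {
      advance(); right <- parse_or()
      left <- list(op = "and", args = list(left, right))
    }
    left
  }
  parse_or <- function() {
    left <- parse_high()
    while (!is.null(peek()) && identical(peek()$t, ",")) {
      advance(); right <- parse_high()
      left <- list(op = "or", args = list(left, right))
    }
    left
  }
  parse_high <- function() {
    left <- parse_unary()
    repeat {
      nx <- peek()
      if (is.null(nx) || nx$t %in% c(",", ";")) break
      if (identical(nx$t, "&")) advance()
      right <- parse_unary()
      left <- list(op = "and", args = list(left, right))
    }
    left
  }
  parse_unary <- function() {
    nx <- peek()
    if (is.null(nx)) stop("truncated bracket expression '[", body, "]' in: ", smarts)
    if (identical(nx$t, "!")) { advance(); return(list(op = "not", arg = parse_unary())) }
    if (identical(nx$t, "prim")) { return(advance()$prim) }
    stop("unexpected token '", nx$t, "' in '[", body, "]' of: ", smarts)
  }

  out <- parse_low()
  if (pos <= length(toks))
    stop("trailing tokens in bracket expression '[", body, "]' of: ", smarts)
  out
}

tokenize_smarts_expr <- function(body, smarts) {
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  n <- length(chars); i <- 1L
  toks <- list()
  push <- function(t, prim = NULL) toks[[length(toks) + 1L]] <<- list(t = t, prim = prim)
  read_int <- function(default) {
    j <- i
    while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
    if (j == i) return(list(v = default, nxt = i))
    list(v = as.integer(paste(chars[i:(j - 1L)], collapse = "")), nxt = j)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("!", "&", ",", ";")) { push(ch); i <- i + 1L; next }
    if (ch == "#") {
      i <- i + 1L
      r <- read_int(NA_integer_)
      if (is.na(r$v)) stop("'#' without atomic number in '[", body, "]' of: ", smarts)
      i <- r$nxt
      push("prim", smarts_prim("elem_num", r$v)); next
    }
    if (ch == "*") { push("prim", smarts_prim("any", 0L)); i <- i + 1L; next }
    if (ch == "H") {
      i <- i + 1L; r <- read_int(1L); i <- r$nxt
      push("prim", smarts_prim("hcount", r$v)); next
    }
    if (ch == "X") {
      i <- i + 1L; r <- read_int(1L); i <- r$nxt
      push("prim", smarts_prim("conn", r$v)); next
    }
    if (ch == "D") {
      i <- i + 1L; r <- read_int(1L); i <- r$nxt
      push("prim", smarts_prim("degree", r$v)); next
    }
    if (ch %in% c("+", "-")) {
      sign <- if (ch == "+") 1L else -1L
      j <- i + 1L; reps <- 1L
      while (j <= n && chars[j] == ch) { reps <- reps + 1L; j <- j + 1L }
      if (reps == 1L && j <= n && grepl("[0-9]", chars[j])) {
        i <- j; r <- read_int(1L); i <- r$nxt
        push("prim", smarts_prim("charge", sign * r$v))
      } else {
        i <- j
        push("prim", smarts_prim("charge", sign * reps))
      }
      next
    }
    if (ch == "A") { push("prim", smarts_prim("aliphatic", 0L)); i <- i + 1L; next }
    if (ch == "a") { push("prim", smarts_prim("aromatic", 0L)); i <- i + 1L; next }
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% names(ELEMENT_NUMBERS) && grepl("^[A-Z][a-z]$", two)) {
      push("prim", smarts_prim("elem_aliph", ELEMENT_NUMBERS[[two]])); i <- i + 2L; next
    }
    if (ch %in% names(ELEMENT_NUMBERS)) {
      push("prim", smarts_prim("elem_aliph", ELEMENT_NUMBERS[[ch]])); i <- i + 1L; next
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      push("prim", smarts_prim("elem_arom", ELEMENT_NUMBERS[[toupper(ch)]])); i <- i + 1L; next
    }
    if (ch == "$")
      stop("recursive SMARTS '$(...)' is not supported (pattern: ", smarts, ")")
    stop("unsupported SMARTS primitive '", ch, "' in '[", body, "]' of: ", smarts)
  }
  toks
}

# ---------------------------------------------------------------------------
# Matching

eval_smarts_atom <- function(ast, props) {
  switch(ast$op,
    prim = {
      v <- ast$value
      switch(ast$kind,
        any = TRUE,
        aliphatic = !props$arom,
        aromatic = props$arom,
        elem_num = props$z == v,
        elem_aliph = props$z == v && !props$arom,
        elem_arom = props$z == v && props$arom,
        hcount = props$hcount == v,
        conn = props$conn == v,
        degree = props$degree == v,
        charge = props$charge == v,
        stop("unknown primitive kind: ", ast$kind))
    },
    not = !eval_smarts_atom(ast$arg, props),
    and = eval_smarts_atom(ast$args[[1]], props) && eval_smarts_atom(ast$args[[2]], props),
    or = eval_smarts_atom(ast$args[[1]], props) || eval_smarts_atom(ast$args[[2]], props),
    stop("unknown AST op: ", ast$op))
}

bond_matches <- function(sym, order, arom) {
  if (sym == "") return((order == 1L && !arom) || arom)
  switch(sym,
    "-" = order == 1L && !arom,
    "=" = order == 2L && !arom,
    "#" = order == 3L,
    ":" = arom,
    "~" = TRUE,
    stop("unsupported SMARTS bond '", sym, "'"))
}

#' Find SMARTS matches in a molecule
#'
#' Backtracking subgraph search. Matches that map the pattern onto the same
#' set of molecule atoms (automorphic duplicates, e.g. a ring matched in both
#' directions) are collapsed to a single hit, so the count is "number of
#' distinct fragment instances".
#'
#' @param mol an `fw_mol`.
#' @param pattern an `fw_smarts` or a SMARTS string.
#' @return list of integer vectors, one per distinct matched atom set
#'   (sorted atom indices).
#' @export
match_smarts <- function(mol, pattern) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  stopifnot(inherits(mol, "fw_mol"), inherits(pattern, "fw_smarts"))
  np <- length(pattern$atoms)
  nm <- n_atoms(mol)
  if (np > nm) return(list())

  deg <- mol_degrees(mol)
  zs <- unname(ELEMENT_NUMBERS[mol$atoms$elem])
  zs[is.na(zs)] <- -1L  # elements outside the table never match an element primitive
  props <- lapply(seq_len(nm), function(i) list(
    z = zs[[i]], arom = mol$atoms$arom[i], charge = mol$atoms$charge[i],
    hcount = mol$atoms$hcount[i], conn = deg$conn[i], degree = deg$degree[i]))

  # candidate molecule atoms per pattern atom
  cand <- lapply(pattern$atoms, function(ast)
    which(vapply(props, function(p) eval_smarts_atom(ast, p), logical(1))))
  if (any(!lengths(cand))) return(list())

  adj <- mol_adjacency(mol)
  bidx <- bond_index(mol)
  get_bond <- function(i, j) {
    k <- bidx[paste(min(i, j), max(i, j), sep = ":")]
    if (is.na(k)) NULL else mol$bonds[k, ]
  }

  # pattern traversal order: each atom after the first must touch a placed one
  # (patterns are connected by construction)
  padj <- vector("list", np)
  for (k in seq_len(nrow(pattern$bonds))) {
    a <- pattern$bonds$a1[k]; b <- pattern$bonds$a2[k]
    padj[[a]] <- c(padj[[a]], k); padj[[b]] <- c(padj[[b]], k)
  }
  order <- integer(0); placed <- logical(np)
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (placed[v]) next
    placed[v] <- TRUE; order <- c(order, v)
    for (k in padj[[v]]) {
      w <- if (pattern$bonds$a1[k] == v) pattern$bonds$a2[k] else pattern$bonds$a1[k]
      if (!placed[w]) queue <- c(queue, w)
    }
  }
  if (length(order) != np)
    stop("disconnected SMARTS patterns are not supported: ", pattern$smarts)

  hits <- new.env(parent = emptyenv())
  map <- integer(np); used <- logical(nm)

  place <- function(pos) {
    if (pos > np) {
      key <- paste(sort(map), collapse = ",")
      assign(key, TRUE, envir = hits)
      return(invisible(NULL))
    }
    pv <- order[pos]
    # pattern bonds from pv into already-placed atoms
    req <- list()
    for (k in padj[[pv]]) {
      other <- if (pattern$bonds$a1[k] == pv) pattern$bonds$a2[k] else pattern$bonds$a1[k]
      if (map[other] != 0L) req[[length(req) + 1L]] <- list(other = other,
                                                           sym = pattern$bonds$sym[k])
    }
    pool <- if (length(req)) intersect(cand[[pv]], adj[[map[req[[1]]$other]]]) else cand[[pv]]
    for (mi in pool) {
      if (used[mi]) next
      ok <- TRUE
      for (r in req) {
        b <- get_bond(mi, map[r$other])
        if (is.null(b) || !bond_matches(r$sym, b$order, b$arom)) { ok <- FALSE; break }
      }
      if (!ok) next
      map[pv] <<- mi; used[mi] <<- TRUE
      place(pos + 1L)
      map[pv] <<- 0L; used[mi] <<- FALSE
    }
    invisible(NULL)
  }
  place(1L)
  keys <- ls(hits)
  lapply(keys, function(k) as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
}
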