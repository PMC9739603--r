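# Ligand structure readers: SMILES (.smi), SDF (V2000), MOL2 (SYBYL).
# All readers fold explicit hydrogen atoms into per-atom hydrogen counts so
# donor/acceptor patterns behave identically across formats.

#' Load ligands from a structure file
#'
#' One record is produced per successfully parsed molecule; molecules that
#' fail to parse are collected in a failure report (attribute `failures`, a
#' data.frame with `id` and `reason`) instead of aborting the run, mirroring
#' how preparation failures are excluded (with a logged reason) rather than
#' silently imputed.
#'
#' @param path input file.
#' @param format one of `"smiles"`, `"sdf"`, `"mol2"`; `"auto"` guesses from
#'   the file extension.
#' @return list of `fw_mol` objects with attribute `failures`.
#' @export
load_ligands <- function(path, format = c("auto", "smiles", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smiles", smiles = "smiles", sdf = "sdf",
                     mol = "sdf", mol2 = "mol2",
                     stop("cannot guess format from extension '.", ext, "'"))
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty input file: ", path)
  switch(format,
         smiles = load_smiles_file(lines),
         sdf = load_sdf_file(lines),
         mol2 = load_mol2_file(lines))
}

with_failures <- function(mols, failures) {
  attr(mols, "failures") <- if (length(failures))
    do.call(rbind, failures)
  else data.frame(id = character(0), reason = character(0))
  mols
}

load_smiles_file <- function(lines) {
  mols <- list(); failures <- list()
  n <- 0L
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line) || startsWith(line, "#")) next
    n <- n + 1L
    toks <- strsplit(line, "[ \t]+")[[1]]
    id <- if (length(toks) >= 2L) toks[2] else sprintf("mol%03d", n)
    m <- tryCatch(parse_smiles(toks[1], id = id), error = function(e) e)
    if (inherits(m, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(id = id, reason = conditionMessage(m))
    } else mols[[length(mols) + 1L]] <- m
  }
  with_failures(mols, failures)
}

# explicit H atoms -> hcount on the heavy neighbour; drop the H nodes
fold_explicit_h <- function(atoms, bonds) {
  is_h <- atoms$elem == "H"
  if (!any(is_h)) return(list(atoms = atoms, bonds = bonds, had_h = FALSE))
  keep <- which(!is_h)
  remap <- integer(nrow(atoms)); remap[keep] <- seq_along(keep)
  extra_h <- integer(length(keep))
  keep_bond <- logical(nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    if (is_h[i] && is_h[j]) next         # H2: drop entirely
    if (is_h[i] || is_h[j]) {
      heavy <- if (is_h[i]) j else i
      extra_h[remap[heavy]] <- extra_h[remap[heavy]] + 1L
    } else keep_bond[k] <- TRUE
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$hcount <- atoms$hcount + extra_h
  bonds <- bonds[keep_bond, , drop = FALSE]
  if (nrow(bonds)) {
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  list(atoms = atoms, bonds = bonds, had_h = TRUE)
}

finish_file_mol <- function(atoms, bonds, id) {
  folded <- fold_explicit_h(atoms, bonds)
  mol <- new_mol(folded$atoms, folded$bonds, id)
  if (!folded$had_h) {
    # structure came without hydrogens at all: fall back to valence filling
    mol$atoms$hcount <- NA_integer_
    mol$atoms$hcount <- fill_implicit_h(mol)
  }
  if (!nrow(mol$atoms)) stop("molecule '", id, "' has no heavy atoms")
  mol
}

load_sdf_file <- function(lines) {
  # split on $$$$ record separators
  seps <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, seps + 1L)
  ends <- c(seps - 1L, length(lines))
  mols <- list(); failures <- list()
  rec_n <- 0L
  for (b in seq_along(starts)) {
    block <- lines[seq.int(starts[b], length.out = max(0L, ends[b] - starts[b] + 1L))]
    if (!length(block) || !any(nzchar(trimws(block)))) next
    rec_n <- rec_n + 1L
    id <- trimws(block[1])
    if (!nzchar(id)) id <- sprintf("sdf%03d", rec_n)
    m <- tryCatch(parse_sdf_block(block, id), error = function(e) e)
    if (inherits(m, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(id = id, reason = conditionMessage(m))
    } else mols[[length(mols) + 1L]] <- m
  }
  with_failures(mols, failures)
}

parse_sdf_block <- function(block, id) {
  if (length(block) < 4L) stop("truncated SDF record")
  counts <- block[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1L) stop("bad V2000 counts line")
  if (length(block) < 4L + na + nb) stop("truncated V2000 atom/bond block")
  atom_lines <- block[5:(4L + na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  bad <- !nzchar(elem)
  if (any(bad)) stop("malformed atom line(s) in SDF record")
  atoms <- data.frame(elem = elem, arom = FALSE, charge = 0L,
                      hcount = 0L, stringsAsFactors = FALSE)
  if (nb > 0L) {
    bond_lines <- block[(5L + na):(4L + na + nb)]
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    ord <- as.integer(substr(bond_lines, 7, 9))
    if (anyNA(a1) || anyNA(a2) || anyNA(ord) ||
        any(a1 < 1L | a1 > na | a2 < 1L | a2 > na))
      stop("malformed bond line(s) in SDF record")
    arom <- ord == 4L
    ord[arom] <- 1L
    if (any(!ord %in% 1:3)) stop("unsupported bond order in SDF record")
    bonds <- data.frame(a1 = a1, a2 = a2, order = ord, arom = arom)
    atoms$arom[unique(c(a1[arom], a2[arom]))] <- TRUE
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                        order = integer(0), arom = logical(0))
  }
  # M  CHG overrides all formal charges
  chg_lines <- grep("^M  CHG", block, value = TRUE)
  for (cl in chg_lines) {
    toks <- strsplit(trimws(sub("^M  CHG", "", cl)), "[ \t]+")[[1]]
    npairs <- as.integer(toks[1])
    for (p in seq_len(npairs)) {
      ai <- as.integer(toks[2L * p]); v <- as.integer(toks[2L * p + 1L])
      atoms$charge[ai] <- v
    }
  }
  finish_file_mol(atoms, bonds, id)
}

load_mol2_file <- function(lines) {
  mol_starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(mol_starts)) stop("no @<TRIPOS>MOLECULE record found")
  bounds <- c(mol_starts, length(lines) + 1L)
  mols <- list(); failures <- list()
  for (b in seq_along(mol_starts)) {
    block <- lines[mol_starts[b]:(bounds[b + 1L] - 1L)]
    id <- trimws(block[2])
    if (!nzchar(id)) id <- sprintf("mol2_%03d", b)
    m <- tryCatch(parse_mol2_block(block, id), error = function(e) e)
    if (inherits(m, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(id = id, reason = conditionMessage(m))
    } else mols[[length(mols) + 1L]] <- m
  }
  with_failures(mols, failures)
}

mol2_section <- function(block, name) {
  hdr <- grep(paste0("^@<TRIPOS>", name), block)
  if (!length(hdr)) return(character(0))
  start <- hdr[1] + 1L
  nxt <- grep("^@<TRIPOS>", block)
  nxt <- nxt[nxt > hdr[1]]
  end <- if (length(nxt)) nxt[1] - 1L else length(block)
  if (start > end) return(character(0))
  out <- trimws(block[start:end])
  out[nzchar(out)]
}

parse_mol2_block <- function(block, id) {
  atom_lines <- mol2_section(block, "ATOM")
  if (!length(atom_lines)) stop("MOL2 record has no ATOM section")
  tok <- strsplit(atom_lines, "[ \t]+")
  if (any(lengths(tok) < 6L)) stop("malformed MOL2 atom line")
  type <- vapply(tok, `[`, character(1), 6L)
  elem_raw <- vapply(strsplit(type, ".", fixed = TRUE), `[`, character(1), 1L)
  # normalize case: "CL" -> "Cl"
  elem <- paste0(toupper(substr(elem_raw, 1, 1)),
                 tolower(substr(elem_raw, 2, nchar(elem_raw))))
  arom <- grepl("\\.ar$", type)
  atoms <- data.frame(elem = elem, arom = arom, charge = 0L, hcount = 0L,
                      stringsAsFactors = FALSE)
  bond_lines <- mol2_section(block, "BOND")
  if (length(bond_lines)) {
    btok <- strsplit(bond_lines, "[ \t]+")
    if (any(lengths(btok) < 4L)) stop("malformed MOL2 bond line")
    a1 <- as.integer(vapply(btok, `[`, character(1), 2L))
    a2 <- as.integer(vapply(btok, `[`, character(1), 3L))
    bt <- vapply(btok, `[`, character(1), 4L)
    ord <- ifelse(bt %in% c("1", "am"), 1L,
           ifelse(bt == "2", 2L, ifelse(bt == "3", 3L,
           ifelse(bt %in% c("ar", "du", "un", "nc"), 1L, NA_integer_))))
    if (anyNA(ord)) stop("unsupported MOL2 bond type")
    barom <- bt == "ar"
    bonds <- data.frame(a1 = a1, a2 = a2, order = ord, arom = barom)
    atoms$arom[unique(c(a1[barom], a2[barom]))] <- TRUE
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                        order = integer(0), arom = logical(0))
  }
  finish_file_mol(atoms, bonds, id)
}

#' Write a set of SMILES strings to a .smi file
#'
#' One `SMILES<TAB>id` pair per line.
#'
#' @param smiles named character vector (names are ids) or unnamed with `ids`.
#' @param path output path.
#' @param ids optional ids when `smiles` is unnamed.
#' @export
write_smiles_file <- function(smiles, path, ids = names(smiles)) {
  if (is.null(ids)) stop("ligand ids are required")
  writeLines(paste(smiles, ids, sep = "\t"), path)
  invisible(path)
}
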