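# Structure sanitization patches for ligands whose charges/bond orders were
# mis-perceived on reading (a common failure for prepared mol2 inputs, where
# delocalized anionic oxygens arrive neutral and amidinium groups arrive with
# all-single C-N bonds).

SANITIZE_RULES <- c("phosphate", "sulfate", "amidine")

#' Sanitize a ligand record
#'
#' Applies named correction rules and returns a new molecule; the heavy-atom
#' graph is never changed, only formal charges, bond orders and hydrogen
#' counts. Applying the same rules twice is a no-op (idempotent).
#'
#' Rules:
#' \describe{
#'   \item{`phosphate`}{terminal oxygens single-bonded to phosphorus that
#'     carry no hydrogen and no charge are assigned the formal charge -1
#'     (the delocalized anion the file failed to record). Changes the total
#'     formal charge by design.}
#'   \item{`sulfate`}{same correction for terminal oxygens on sulfur atoms
#'     bearing at least three oxygen neighbours (sulfate/sulfonate).}
#'   \item{`amidine`}{an aliphatic carbon bonded to two or more nitrogens by
#'     single bonds and carrying no multiple bond is converted to the
#'     amidinium form: the bond to the most hydrogenated nitrogen becomes a
#'     double bond, that nitrogen gains formal charge +1, and the carbon's
#'     hydrogen count is refilled from its valence.}
#' }
#'
#' @param mol an `fw_mol`.
#' @param rules character vector of rule names (default: all).
#' @return corrected `fw_mol`.
#' @export
sanitize_ligand <- function(mol, rules = SANITIZE_RULES) {
  stopifnot(inherits(mol, "fw_mol"))
  unknown <- setdiff(rules, SANITIZE_RULES)
  if (length(unknown))
    stop("unknown sanitize rule(s): ", paste(unknown, collapse = ", "))
  for (r in rules) {
    mol <- switch(r,
      phosphate = fix_oxyanion(mol, "P", min_o = 1L),
      sulfate = fix_oxyanion(mol, "S", min_o = 3L),
      amidine = fix_amidine(mol))
  }
  mol
}

fix_oxyanion <- function(mol, center_elem, min_o) {
  deg <- mol_degrees(mol)$degree
  adj <- mol_adjacency(mol)
  bidx <- bond_index(mol)
  for (i in seq_len(n_atoms(mol))) {
    if (mol$atoms$elem[i] != center_elem) next
    o_nb <- adj[[i]][mol$atoms$elem[adj[[i]]] == "O"]
    if (length(o_nb) < min_o) next
    for (o in o_nb) {
      if (deg[o] != 1L) next                      # terminal oxygens only
      if (mol$atoms$charge[o] != 0L) next
      if (mol$atoms$hcount[o] != 0L) next
      k <- bidx[paste(min(i, o), max(i, o), sep = ":")]
      if (mol$bonds$order[k] != 1L || mol$bonds$arom[k]) next
      mol$atoms$charge[o] <- -1L
    }
  }
  mol
}

fix_amidine <- function(mol) {
  adj <- mol_adjacency(mol)
  bidx <- bond_index(mol)
  n <- n_atoms(mol)
  has_multiple <- logical(n)
  if (nrow(mol$bonds)) {
    mult <- mol$bonds$order > 1L | mol$bonds$arom
    has_multiple[unique(c(mol$bonds$a1[mult], mol$bonds$a2[mult]))] <- TRUE
  }
  for (i in seq_len(n)) {
    if (mol$atoms$elem[i] != "C" || mol$atoms$arom[i] || has_multiple[i]) next
    n_nb <- adj[[i]][mol$atoms$elem[adj[[i]]] == "N" & !mol$atoms$arom[adj[[i]]]]
    if (length(n_nb) < 2L) next
    single_n <- n_nb[vapply(n_nb, function(j) {
      k <- bidx[paste(min(i, j), max(i, j), sep = ":")]
      mol$bonds$order[k] == 1L && !mol$bonds$arom[k]
    }, logical(1))]
    if (length(single_n) < 2L) next
    # prefer the nitrogen already charged, else the most hydrogenated one
    charged <- single_n[mol$atoms$charge[single_n] > 0L]
    target <- if (length(charged)) charged[1] else
      single_n[order(-mol$atoms$hcount[single_n], single_n)][1]
    k <- bidx[paste(min(i, target), max(i, target), sep = ":")]
    mol$bonds$order[k] <- 2L
    mol$atoms$charge[target] <- 1L
    # refill carbon hydrogens from the corrected valence
    bsum <- sum(mol$bonds$order[mol$bonds$a1 == i | mol$bonds$a2 == i])
    mol$atoms$hcount[i] <- max(0L, 4L - as.integer(bsum))
    has_multiple[i] <- TRUE
  }
  mol
}
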