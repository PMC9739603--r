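# Interaction-motif feature definitions and Free-Wilson count matrices.

#' Default interaction-motif feature definitions
#'
#' Eleven named fragments covering the interaction classes a medicinal chemist
#' tracks: hydrogen-bond donors (two near-duplicate definitions, HBD1/HBD2,
#' differing only by thiol inclusion), hydrogen-bond acceptors, hydrophobic
#' sp3/sp2/sp carbon (HP1/HP2/HP3), six-membered aromatic rings (PIPI),
#' nitrogen cations (PICat), anionic oxygens (SaltBridge), heavy halogens
#' (Hal: Cl/Br/I), and fluorine isolated as its own feature (F does not form
#' halogen bonds). Patterns are stored as data in
#' `inst/extdata/feature_definitions.tsv` and stay within the SMARTS subset
#' understood by [parse_smarts()].
#'
#' @param path optional path to a custom definition table (TSV with columns
#'   `name`, `smarts`, `class`).
#' @return data.frame of class `fw_features` with columns `name`, `smarts`,
#'   `class`.
#' @export
default_features <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "feature_definitions.tsv", package = "fwbench",
                        mustWork = TRUE)
  read_features(path)
}

#' Read feature definitions from a TSV table
#'
#' @param path TSV file with header `name`, `smarts`, `class`.
#' @return `fw_features` data.frame; every SMARTS is compiled once to validate
#'   it (compilation results are cached in the `patterns` attribute).
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "smarts", "class")
  if (!all(required %in% names(df)))
    stop("feature table must have columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("duplicate feature names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  pats <- lapply(df$smarts, parse_smarts)
  names(pats) <- df$name
  structure(df[required], patterns = pats, class = c("fw_features", "data.frame"))
}

feature_patterns <- function(fds) {
  pats <- attr(fds, "patterns")
  if (is.null(pats) || !all(fds$name %in% names(pats))) {
    pats <- lapply(fds$smarts, parse_smarts)
    names(pats) <- fds$name
  }
  pats[fds$name]
}

#' Count occurrences of one feature in a molecule
#'
#' Number of distinct atom-set matches of the feature's SMARTS pattern:
#' automorphic duplicates (the same fragment matched through a symmetry of
#' the pattern) are counted once, so a benzene ring matched by a whole-ring
#' pattern counts 1 while four fluorines count 4.
#'
#' @param mol an `fw_mol` (see [parse_smiles()]).
#' @param feature an `fw_smarts`, a SMARTS string, or a single-row subset of
#'   an `fw_features` table.
#' @return non-negative integer count.
#' @examples
#' count_feature(parse_smiles("FC(F)(F)F"), "F")  # 4
#' @export
count_feature <- function(mol, feature) {
  if (inherits(feature, "fw_features")) {
    if (nrow(feature) != 1L) stop("'feature' must be a single feature definition")
    feature <- feature_patterns(feature)[[1]]
  }
  length(match_smarts(mol, feature))
}

#' Build the Free-Wilson count matrix for a set of ligands
#'
#' @param mols list of `fw_mol` objects with unique non-empty ids.
#' @param fds `fw_features` definition table.
#' @return integer matrix (ligands x features) with ligand ids as rownames
#'   and feature names as colnames.
#' @export
build_feature_table <- function(mols, fds) {
  if (!length(mols)) stop("at least one ligand is required")
  if (!nrow(fds)) stop("at least one feature is required")
  ids <- unname(vapply(mols, function(m) m$id, character(1)))
  if (any(!nzchar(ids))) stop("every ligand must carry a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate ligand ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pats <- feature_patterns(fds)
  counts <- matrix(0L, nrow = length(mols), ncol = nrow(fds),
                   dimnames = list(ids, fds$name))
  for (i in seq_along(mols))
    for (j in seq_along(pats))
      counts[i, j] <- length(match_smarts(mols[[i]], pats[[j]]))
  counts
}

#' Write / read a feature count matrix as TSV
#'
#' The on-disk layout is a header row with `id` followed by feature names,
#' then one row per ligand.
#'
#' @param fm integer matrix with rownames (ligand ids) and colnames.
#' @param path output file.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(id = rownames(fm), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop("feature matrix file must start with an 'id' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}
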