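# Solvent-accessible surface area (Shrake-Rupley) and the delta-SAS scoring
# function: half the surface buried on complex formation,
#   deltaSAS = (ligand_sasa + protein_sasa - complex_sasa) / 2.

# Bondi van der Waals radii (Angstrom).
BONDI_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Se = 1.90,
  Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31, Zn = 1.39
)

#' Construct a 3D atom set
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of coordinates in Angstrom.
#' @param radii optional per-atom vdW radii; defaults to the Bondi table
#'   looked up by element (error for unknown elements).
#' @return object of class `fw_atoms`.
#' @export
atom_set <- function(elements, coords, radii = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("'coords' must be an n x 3 matrix")
  n <- length(elements)
  if (nrow(coords) != n) stop("elements and coords disagree in length")
  if (n == 0L) stop("empty atom set")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  if (is.null(radii)) {
    radii <- unname(BONDI_RADII[elements])
    if (anyNA(radii))
      stop("no vdW radius for element(s): ",
           paste(unique(elements[is.na(radii)]), collapse = ", "))
  }
  if (length(radii) == 1L) radii <- rep(radii, n)
  if (length(radii) != n || any(radii <= 0)) stop("radii must be positive, one per atom")
  structure(list(elements = elements, coords = unname(coords),
                 radii = as.numeric(radii)),
            class = "fw_atoms")
}

#' @export
print.fw_atoms <- function(x, ...) {
  cat(sprintf("<fw_atoms: %d atoms, elements %s>\n", length(x$elements),
              paste(unique(x$elements), collapse = "/")))
  invisible(x)
}

# concatenate two atom sets (the complex)
combine_atoms <- function(a, b) {
  atom_set(c(a$elements, b$elements), rbind(a$coords, b$coords),
           radii = c(a$radii, b$radii))
}

#' Load a 3D structure from PDB or MOL2
#'
#' Reads ATOM/HETATM records (PDB) or the `@<TRIPOS>ATOM` section (MOL2) and
#' assigns Bondi vdW radii by element. Waters (residue HOH/WAT) can be
#' stripped; hydrogens are kept unless `strip_hydrogens` is set.
#'
#' @param path input file.
#' @param format `"pdb"`, `"mol2"`, or `"auto"` (by extension).
#' @param strip_waters drop HOH/WAT residues (PDB only). Default TRUE.
#' @param strip_hydrogens drop hydrogen atoms. Default FALSE (prepared
#'   structures come with their hydrogens and they contribute to the surface).
#' @return an `fw_atoms`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mol2"),
                           strip_waters = TRUE, strip_hydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", mol2 = "mol2",
                     stop("cannot guess structure format from '.", ext, "'"))
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
    if (!length(rec)) stop("no ATOM/HETATM records in ", path)
    resname <- trimws(substr(rec, 18, 20))
    if (strip_waters) rec <- rec[!(resname %in% c("HOH", "WAT"))]
    if (!length(rec)) stop("structure is empty after water stripping: ", path)
    x <- as.numeric(substr(rec, 31, 38))
    y <- as.numeric(substr(rec, 39, 46))
    z <- as.numeric(substr(rec, 47, 54))
    if (anyNA(x) || anyNA(y) || anyNA(z)) stop("malformed coordinates in ", path)
    elem <- trimws(substr(rec, 77, 78))
    # fall back to the atom-name column when the element field is blank
    blank <- !nzchar(elem)
    if (any(blank)) {
      nm <- trimws(substr(rec[blank], 13, 16))
      elem[blank] <- sub("^([A-Za-z]{1,2}).*", "\\1", nm)
      one <- substr(elem[blank], 1, 1) %in% c("C", "N", "O", "H", "S", "P")
      elem[blank][one] <- substr(elem[blank][one], 1, 1)
    }
    elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substring(elem, 2)))
    coords <- cbind(x, y, z)
  } else {
    atom_lines <- mol2_section(lines, "ATOM")
    if (!length(atom_lines)) stop("no @<TRIPOS>ATOM section in ", path)
    tok <- strsplit(atom_lines, "[ \t]+")
    if (any(lengths(tok) < 6L)) stop("malformed MOL2 atom line in ", path)
    coords <- cbind(as.numeric(vapply(tok, `[`, character(1), 3L)),
                    as.numeric(vapply(tok, `[`, character(1), 4L)),
                    as.numeric(vapply(tok, `[`, character(1), 5L)))
    type <- vapply(tok, `[`, character(1), 6L)
    elem_raw <- vapply(strsplit(type, ".", fixed = TRUE), `[`, character(1), 1L)
    elem <- paste0(toupper(substr(elem_raw, 1, 1)),
                   tolower(substring(elem_raw, 2)))
  }
  if (strip_hydrogens) {
    keep <- elem != "H"
    if (!any(keep)) stop("structure contains only hydrogens: ", path)
    elem <- elem[keep]; coords <- coords[keep, , drop = FALSE]
  }
  atom_set(elem, coords)
}

#' Write an atom set as a minimal PDB file
#'
#' @param atoms an `fw_atoms`.
#' @param path output path.
#' @param resname residue name stamped on every atom.
#' @export
write_pdb <- function(atoms, path, resname = "LIG") {
  n <- length(atoms$elements)
  lines <- sprintf(
    "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), substr(atoms$elements, 1, 4), resname, 1L,
    atoms$coords[, 1], atoms$coords[, 2], atoms$coords[, 3],
    toupper(atoms$elements))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Deterministic golden-spiral (Fibonacci) unit-sphere point set.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom is inflated by the probe radius and covered with a deterministic
#' golden-spiral point set; the accessible fraction is the fraction of points
#' outside every other inflated sphere. The default 960 points per atom is
#' the package's mapping of the conventional "dot density 3" quadrature.
#'
#' @param atoms an `fw_atoms`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.0).
#' @param n_sphere_points points per atom (>= 12, default 960).
#' @return total area in Angstrom^2; per-atom areas in attribute `per_atom`.
#' @export
sasa <- function(atoms, probe_radius = 1.0, n_sphere_points = 960L) {
  stopifnot(inherits(atoms, "fw_atoms"))
  if (probe_radius < 0) stop("'probe_radius' must be >= 0")
  if (n_sphere_points < 12L) stop("'n_sphere_points' must be >= 12")
  n <- length(atoms$radii)
  ext <- atoms$radii + probe_radius
  pts <- fibonacci_sphere(as.integer(n_sphere_points))
  areas <- numeric(n)
  # neighbour pruning: atoms can only occlude each other within the sum of
  # their extended radii
  d2 <- as.matrix(stats::dist(atoms$coords))^2
  for (i in seq_len(n)) {
    cutoff2 <- (ext[i] + ext)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    full <- 4 * pi * ext[i]^2
    if (!length(nb)) { areas[i] <- full; next }
    p <- sweep(pts * ext[i], 2L, atoms$coords[i, ], "+")
    accessible <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(accessible)) break
      dj <- sweep(p[accessible, , drop = FALSE], 2L, atoms$coords[j, ], "-")
      inside <- rowSums(dj^2) < ext[j]^2
      accessible[accessible] <- !inside
    }
    areas[i] <- full * mean(accessible)
  }
  structure(sum(areas), per_atom = areas)
}

#' The delta-SAS scoring function
#'
#' Half the solvent-accessible surface buried on complex formation:
#' `(sasa(ligand) + sasa(protein) - sasa(complex)) / 2`, all three areas
#' computed with identical parameters. Symmetric in the two partners; zero
#' when they do not touch.
#'
#' @param ligand,protein `fw_atoms` objects in the same coordinate frame.
#' @inheritParams sasa
#' @return delta-SAS in Angstrom^2.
#' @export
delta_sas <- function(ligand, protein, probe_radius = 1.0, n_sphere_points = 960L) {
  ls <- as.numeric(sasa(ligand, probe_radius, n_sphere_points))
  ps <- as.numeric(sasa(protein, probe_radius, n_sphere_points))
  cs <- as.numeric(sasa(combine_atoms(ligand, protein), probe_radius, n_sphere_points))
  (ls + ps - cs) / 2
}

#' Batch delta-SAS over a directory of complexes
#'
#' Scans `dir` for `<id>_ligand.mol2` / `<id>_protein.pdb` pairs and scores
#' each; the result is a table usable as one more scoring-function column.
#'
#' @param dir directory containing the structure pairs.
#' @inheritParams sasa
#' @return data.frame with `id` and `deltaSAS`.
#' @export
delta_sas_batch <- function(dir, probe_radius = 1.0, n_sphere_points = 960L) {
  ligs <- list.files(dir, pattern = "_ligand\\.(mol2|pdb)$", full.names = TRUE)
  if (!length(ligs)) stop("no *_ligand.mol2 / *_ligand.pdb files in ", dir)
  ids <- sub("_ligand\\.(mol2|pdb)$", "", basename(ligs))
  vals <- vapply(seq_along(ligs), function(k) {
    prot <- list.files(dir, pattern = paste0("^", ids[k], "_protein\\.(pdb|mol2)$"),
                       full.names = TRUE)
    if (!length(prot)) stop("no protein structure for complex '", ids[k], "'")
    delta_sas(load_structure(ligs[k]), load_structure(prot[1]),
              probe_radius, n_sphere_points)
  }, numeric(1))
  data.frame(id = ids, deltaSAS = vals, stringsAsFactors = FALSE)
}
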