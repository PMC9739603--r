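# Synthetic-data generators with known ground truth: occurrence-count
# matrices, affinities from a sparse linear model over standardized features,
# and scoring-function outputs distorted by feature-specific biases. Every
# generator is a pure function of (parameters, seed); each call draws from a
# named RNG substream of the single integer seed.

#' Feature occurrence specifications for the synthetic generator
#'
#' @param name feature names (unique).
#' @param occurrence_prob per-feature probability that a ligand contains the
#'   fragment at least once, in \[0, 1\].
#' @param count_mean mean count among ligands containing the fragment
#'   (>= 1; counts are 1 + Poisson(count_mean - 1)).
#' @return data.frame of class `fw_feature_spec`.
#' @export
feature_spec <- function(name, occurrence_prob, count_mean) {
  if (anyDuplicated(name)) stop("feature names must be unique")
  if (any(occurrence_prob < 0 | occurrence_prob > 1))
    stop("occurrence_prob must be in [0, 1]")
  if (any(count_mean < 1)) stop("count_mean must be >= 1")
  structure(data.frame(name = name, occurrence_prob = occurrence_prob,
                       count_mean = count_mean, stringsAsFactors = FALSE),
            class = c("fw_feature_spec", "data.frame"))
}

#' Default synthetic feature specifications
#'
#' Ten features mirroring the post-exclusion shape of a typical benchmark
#' set (one of the two duplicate donor definitions already removed).
#' Occurrence frequencies are illustrative, anchored to the two reported
#' counts available (donors present in almost every ligand; heavy halogens
#' in roughly 15% of ligands).
#'
#' @return `fw_feature_spec` with 10 rows.
#' @export
default_feature_specs <- function() {
  feature_spec(
    name = c("HBD1", "HBA", "HP1", "HP2", "HP3",
             "PIPI", "PICat", "SaltBridge", "Hal", "F"),
    occurrence_prob = c(0.94, 0.92, 0.90, 0.30, 0.05,
                        0.70, 0.15, 0.20, 0.15, 0.20),
    count_mean = c(3.0, 4.0, 6.0, 1.2, 1.0, 1.5, 1.0, 1.2, 1.5, 2.0)
  )
}

#' Ground-truth parameters for synthetic benchmarks
#'
#' The generating model is
#' `pK_ref = intercept + sum_j coef_j z_j + eps` over *standardized* features
#' and `pK_SF = sf_offset + sf_slope pK_ref + sum_j bias_j x_j + eta` over
#' *raw* counts. Because biases act on raw counts while regression runs on
#' standardized features, the combined-model correction expected for feature
#' j is `-bias_j * sd_j` (population sd of the raw column).
#'
#' @param true_coefficients named numeric: effect per standardized unit (pK).
#' @param intercept baseline affinity (pK units).
#' @param affinity_noise_sd Gaussian noise sd on pK_ref (>= 0).
#' @param sf_slope,sf_offset linear transform from pK_ref to the SF score.
#' @param sf_biases named numeric: per-raw-count distortion (pK per count).
#' @param sf_noise_sd Gaussian noise sd on the SF score (>= 0).
#' @param seed integer master seed; all generators derive substreams from it.
#' @return list of class `fw_truth`.
#' @export
synthetic_truth <- function(true_coefficients = c(HP1 = 0.6, PIPI = 0.5, HP2 = 0.25,
                                                  HP3 = -0.2, PICat = -0.3,
                                                  SaltBridge = -0.25, Hal = 0.2,
                                                  F = 0.3, HBD1 = 0.05, HBA = 0),
                            intercept = 6.2,
                            affinity_noise_sd = 0.5,
                            sf_slope = 1, sf_offset = 0,
                            sf_biases = numeric(0),
                            sf_noise_sd = 0.3,
                            seed = 1L) {
  if (affinity_noise_sd < 0 || sf_noise_sd < 0) stop("noise sds must be non-negative")
  if (length(true_coefficients) && is.null(names(true_coefficients)))
    stop("'true_coefficients' must be named by feature")
  if (length(sf_biases) && is.null(names(sf_biases)))
    stop("'sf_biases' must be named by feature")
  structure(list(true_coefficients = true_coefficients, intercept = intercept,
                 affinity_noise_sd = affinity_noise_sd, sf_slope = sf_slope,
                 sf_offset = sf_offset, sf_biases = sf_biases,
                 sf_noise_sd = sf_noise_sd, seed = seed),
            class = "fw_truth")
}

#' Generate a synthetic occurrence-count matrix
#'
#' Zero-inflated shifted-Poisson counts: ligand i contains feature j with
#' probability `occurrence_prob_j` (mildly correlated across features through
#' a shared Gaussian latent factor, correlation `rho`), and the count among
#' containing ligands is `1 + Poisson(count_mean_j - 1)`.
#'
#' @param n_ligands number of ligands (>= 1).
#' @param specs an `fw_feature_spec` (default [default_feature_specs()]).
#' @param seed integer seed.
#' @param rho latent-factor correlation of occurrence indicators in \[0, 1);
#'   0 gives independent features.
#' @return integer matrix (n_ligands x features) with ids `L0001`, ...
#' @export
gen_feature_matrix <- function(n_ligands, specs = default_feature_specs(),
                               seed = 1L, rho = 0.2) {
  if (n_ligands < 1L) stop("'n_ligands' must be >= 1")
  if (!nrow(specs)) stop("'specs' must contain at least one feature")
  if (anyDuplicated(specs$name)) stop("duplicate feature names")
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  set.seed(fw_substream(seed, "feature_matrix"))
  n <- as.integer(n_ligands); p <- nrow(specs)
  f <- stats::rnorm(n)   # shared ligand-level latent factor
  counts <- matrix(0L, n, p,
                   dimnames = list(sprintf("L%04d", seq_len(n)), specs$name))
  for (j in seq_len(p)) {
    z <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n)
    occur <- z < stats::qnorm(specs$occurrence_prob[j])
    k <- sum(occur)
    if (k) counts[occur, j] <- 1L + stats::rpois(k, specs$count_mean[j] - 1)
  }
  counts
}

#' Generate experimental affinities from ground truth
#'
#' `pK_ref = intercept + Z coef + eps` with Z the standardized count matrix
#' (population sd) and `eps ~ N(0, affinity_noise_sd)`.
#'
#' @param fm count matrix from [gen_feature_matrix()].
#' @param truth an `fw_truth`.
#' @return numeric vector of pK_ref, named by ligand id.
#' @export
gen_affinities <- function(fm, truth) {
  stopifnot(inherits(truth, "fw_truth"))
  cf <- truth$true_coefficients
  unknown <- setdiff(names(cf), colnames(fm))
  if (length(unknown))
    stop("unknown feature key(s) in true_coefficients: ",
         paste(unknown, collapse = ", "))
  z <- standardize(fm)
  set.seed(fw_substream(truth$seed, "affinities"))
  mu <- truth$intercept +
    if (length(cf)) as.numeric(z$values[, names(cf), drop = FALSE] %*% cf) else 0
  stats::setNames(mu + stats::rnorm(nrow(fm), sd = truth$affinity_noise_sd),
                  rownames(fm))
}

#' Generate biased scoring-function outputs
#'
#' `pK_SF = sf_offset + sf_slope pK_ref + sum_j bias_j x_j + eta` with x the
#' *raw* counts and `eta ~ N(0, sf_noise_sd)`.
#'
#' @param fm count matrix.
#' @param pk_ref affinities aligned with `fm` rows.
#' @param truth an `fw_truth`.
#' @return numeric vector of pK_SF, named by ligand id.
#' @export
gen_sf_scores <- function(fm, pk_ref, truth) {
  stopifnot(inherits(truth, "fw_truth"))
  if (length(pk_ref) != nrow(fm))
    stop("length mismatch: ", length(pk_ref), " affinities for ", nrow(fm), " ligands")
  bs <- truth$sf_biases
  unknown <- setdiff(names(bs), colnames(fm))
  if (length(unknown))
    stop("unknown feature key(s) in sf_biases: ", paste(unknown, collapse = ", "))
  set.seed(fw_substream(truth$seed, "sf_scores"))
  mu <- truth$sf_offset + truth$sf_slope * as.numeric(pk_ref) +
    if (length(bs)) as.numeric(fm[, names(bs), drop = FALSE] %*% bs) else 0
  stats::setNames(mu + stats::rnorm(nrow(fm), sd = truth$sf_noise_sd),
                  rownames(fm))
}

#' Fixture ligands with known fragment counts
#'
#' A fixed set of 16 small molecules covering every default feature class at
#' known multiplicity, including zero-count negatives. The expected-count
#' table was verified against an independent cheminformatics toolkit and is
#' frozen here; it is the reference for the fragment-counting tests.
#'
#' @return list with `smiles` (named character) and `expected` (integer
#'   matrix, ligands x default features).
#' @export
gen_toy_ligands <- function() {
  smiles <- c(
    methane = "C", benzene = "c1ccccc1", cf4_like = "FC(F)(F)F",
    halobenzene = "Clc1ccccc1Br", ethanol = "CCO", ethylamine = "CCN",
    butadiene = "C=CC=C", propyne = "CC#C",
    glycine_zwitterion = "[NH3+]CC(=O)[O-]", naphthalene = "c1ccc2ccccc2c1",
    pyridine = "c1ccncc1", ethanethiol = "CCS", phenol = "Oc1ccccc1",
    benzamidinium = "NC(=[NH2+])c1ccccc1", cyclohexane = "C1CCCCC1",
    styrene = "C=Cc1ccccc1"
  )
  feats <- c("HBD1", "HBD2", "HBA", "HP1", "HP2", "HP3",
             "PIPI", "PICat", "SaltBridge", "Hal", "F")
  expected <- matrix(as.integer(c(
    # HBD1 HBD2 HBA HP1 HP2 HP3 PIPI PICat Salt Hal F
    0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0,   # methane
    0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0,   # benzene
    0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 4,   # cf4_like
    0, 0, 0, 0, 0, 0, 1, 0, 0, 2, 0,   # halobenzene
    1, 1, 1, 2, 0, 0, 0, 0, 0, 0, 0,   # ethanol
    1, 1, 1, 2, 0, 0, 0, 0, 0, 0, 0,   # ethylamine
    0, 0, 0, 0, 2, 0, 0, 0, 0, 0, 0,   # butadiene
    0, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0,   # propyne
    1, 1, 2, 1, 0, 0, 0, 1, 1, 0, 0,   # glycine_zwitterion
    0, 0, 0, 0, 0, 0, 2, 0, 0, 0, 0,   # naphthalene
    0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0,   # pyridine
    0, 1, 0, 2, 0, 0, 0, 0, 0, 0, 0,   # ethanethiol
    1, 1, 1, 0, 0, 0, 1, 0, 0, 0, 0,   # phenol
    2, 2, 1, 0, 0, 0, 1, 1, 0, 0, 0,   # benzamidinium
    0, 0, 0, 6, 0, 0, 0, 0, 0, 0, 0,   # cyclohexane
    0, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0    # styrene
  )), nrow = length(smiles), ncol = length(feats), byrow = TRUE,
  dimnames = list(names(smiles), feats))
  list(smiles = smiles, expected = expected)
}

#' Deterministic toy protein-ligand complexes for surface-area tests
#'
#' All coordinates are fixed; radii are synthetic (chosen for the geometry,
#' not taken from an element table).
#' \describe{
#'   \item{`distant_pair`}{two carbon-sized atoms 40 A apart: no occlusion
#'     at any sane probe radius.}
#'   \item{`buried_ligand`}{a carbon-sized ligand atom at the center of a
#'     single large protein sphere (radius 6 A): the ligand is completely
#'     buried in the complex while the protein surface is unchanged.}
#'   \item{`overlap_pair`}{two carbon-sized atoms 2 A apart: partial
#'     occlusion.}
#' }
#'
#' @param kind one of `"distant_pair"`, `"buried_ligand"`, `"overlap_pair"`.
#' @return list with `ligand` and `protein`, both `fw_atoms` objects.
#' @export
gen_toy_complex <- function(kind = c("distant_pair", "buried_ligand", "overlap_pair")) {
  kind <- match.arg(kind)
  lig <- atom_set("C", matrix(c(0, 0, 0), 1, 3), radii = 1.7)
  prot <- switch(kind,
    distant_pair = atom_set("C", matrix(c(40, 0, 0), 1, 3), radii = 1.7),
    buried_ligand = atom_set("C", matrix(c(0, 0, 0), 1, 3), radii = 6.0),
    overlap_pair = atom_set("C", matrix(c(2, 0, 0), 1, 3), radii = 1.7))
  list(ligand = lig, protein = prot)
}
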