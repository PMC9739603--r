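# Shared fixtures, built in code at test time.

# small random regression problem
make_problem <- function(n = 30, p = 6, seed = 1, sd = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  beta <- c(2, -1, 0.5, rep(0, p - 3))
  y <- 1 + X %*% beta + rnorm(n, sd = sd)
  list(X = X, y = as.numeric(y), beta = beta)
}

# column-mean-centered orthonormal design (columns orthogonal to each other
# and to the intercept)
make_orthonormal <- function(n = 30, p = 6, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE)))
  colnames(Q) <- paste0("q", seq_len(p))
  Q
}

# Eq.-style penalized objective, used as an independent check
lasso_objective <- function(X, y, beta, b0, lambda, penalize = rep(TRUE, ncol(X))) {
  n <- length(y)
  (1 / n) * sum((y - b0 - X %*% beta)^2) + lambda * sum(abs(beta[penalize]))
}

# ethanol as a minimal V2000 SDF block (heavy atoms only)
write_ethanol_sdf <- function(path, id = "ethanol") {
  atom <- function(x, y, z, e)
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0", x, y, z, e)
  lines <- c(id, "  fwbench", "",
             "  3  2  0  0  0  0  0  0  0  0999 V2000",
             atom(0, 0, 0, "C"), atom(1.5, 0, 0, "C"), atom(2.1, 1.2, 0, "O"),
             "  1  2  1  0", "  2  3  1  0",
             "M  END", "$$$$")
  writeLines(lines, path)
  path
}

# benzamidinium as MOL2 with deliberately wrong all-single C-N bonds and no
# charges: the shape the amidine sanitization rule exists to repair
write_bad_amidine_mol2 <- function(path, id = "amidinium_raw") {
  lines <- c(
    "@<TRIPOS>MOLECULE", id, " 9 9 1", "SMALL", "NO_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 N1   -1.20  1.00  0.00 N.3",
    "  2 C1    0.00  0.40  0.00 C.2",
    "  3 N2    1.20  1.00  0.00 N.3",
    "  4 C2    0.00 -1.10  0.00 C.ar",
    "  5 C3    1.20 -1.80  0.00 C.ar",
    "  6 C4    1.20 -3.20  0.00 C.ar",
    "  7 C5    0.00 -3.90  0.00 C.ar",
    "  8 C6   -1.20 -3.20  0.00 C.ar",
    "  9 C7   -1.20 -1.80  0.00 C.ar",
    "@<TRIPOS>BOND",
    "  1 1 2 1", "  2 2 3 1", "  3 2 4 1",
    "  4 4 5 ar", "  5 5 6 ar", "  6 6 7 ar",
    "  7 7 8 ar", "  8 8 9 ar", "  9 9 4 ar")
  writeLines(lines, path)
  path
}

# synthetic dataset triple (counts, affinities, sf scores) under one truth
make_synth <- function(seed, n = 273, affinity_noise_sd = 0.5, sf_noise_sd = 0,
                       sf_slope = 1, sf_offset = 0, sf_biases = numeric(0)) {
  fm <- gen_feature_matrix(n, seed = seed)
  tr <- synthetic_truth(seed = seed, affinity_noise_sd = affinity_noise_sd,
                        sf_noise_sd = sf_noise_sd, sf_slope = sf_slope,
                        sf_offset = sf_offset, sf_biases = sf_biases)
  pk <- gen_affinities(fm, tr)
  sf <- gen_sf_scores(fm, pk, tr)
  list(fm = fm, truth = tr, pk_ref = pk, pk_sf = sf)
}

# exact solvent-accessible area of two possibly overlapping spheres
# (extended radii R1, R2 at distance d): sphere area minus the occluded
# spherical caps -- the analytic oracle for the quadrature
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  if (d <= abs(R1 - R2)) {   # smaller sphere fully buried
    big <- max(R1, R2)
    return(4 * pi * big^2)
  }
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  h1 <- R1 - x1
  h2 <- R2 - x2
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}
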