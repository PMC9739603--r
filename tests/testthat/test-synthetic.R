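# Synthetic-data generators: determinism, marginal statistics, and the
# generator algebra that downstream recovery tests rely on.

test_that("generators are pure functions of (parameters, seed)", {
  specs <- default_feature_specs()
  a <- gen_feature_matrix(100, specs, seed = 42)
  b <- gen_feature_matrix(100, specs, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, gen_feature_matrix(100, specs, seed = 43)))
  tr <- synthetic_truth(seed = 42)
  expect_identical(gen_affinities(a, tr), gen_affinities(a, tr))
  pk <- gen_affinities(a, tr)
  expect_identical(gen_sf_scores(a, pk, tr), gen_sf_scores(a, pk, tr))
  cx <- gen_toy_complex("overlap_pair")
  expect_identical(cx, gen_toy_complex("overlap_pair"))
})

test_that("count matrices are non-negative integers with stated margins", {
  specs <- feature_spec(c("zero", "half", "all"), c(0, 0.5, 1), c(2, 3, 1.5))
  fm <- gen_feature_matrix(5000, specs, seed = 11)
  expect_true(is.integer(fm))
  expect_true(all(fm >= 0L))
  expect_true(all(fm[, "zero"] == 0L))
  expect_true(all(fm[, "all"] >= 1L))
  # occurrence fraction within 3 binomial standard errors of 0.5
  frac <- mean(fm[, "half"] > 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 5000))
  # conditional count mean near the shifted-Poisson target
  expect_lt(abs(mean(fm[fm[, "half"] > 0, "half"]) - 3), 0.15)
})

test_that("spec validation rejects bad generator inputs", {
  expect_error(feature_spec(c("a", "a"), c(0.5, 0.5), c(1, 1)), "unique")
  expect_error(feature_spec("a", 1.5, 1), "\\[0, 1\\]")
  expect_error(feature_spec("a", 0.5, 0.2), ">= 1")
  expect_error(gen_feature_matrix(0), ">= 1")
  fm <- gen_feature_matrix(10, seed = 1)
  expect_error(gen_affinities(fm, synthetic_truth(true_coefficients = c(nope = 1))),
               "unknown feature key")
  expect_error(gen_sf_scores(fm, numeric(3), synthetic_truth()), "length mismatch")
})

test_that("zero-noise affinities follow the linear model exactly", {
  fm <- gen_feature_matrix(200, seed = 5)
  flat <- synthetic_truth(true_coefficients = stats::setNames(numeric(0), character(0)),
                          intercept = 6.2, affinity_noise_sd = 0, seed = 5)
  expect_equal(unname(gen_affinities(fm, flat)), rep(6.2, 200))
  tr <- synthetic_truth(affinity_noise_sd = 0, seed = 5)
  pk <- gen_affinities(fm, tr)
  Z <- standardize(fm)
  ols <- lm(pk ~ Z$values)
  est <- coef(ols)[-1]
  names(est) <- colnames(fm)
  expect_equal(est[names(tr$true_coefficients)], tr$true_coefficients,
               tolerance = 1e-8)
})

test_that("noisy-affinity OLS estimates are unbiased across seeds", {
  n_seeds <- 20
  ests <- NULL
  tr0 <- synthetic_truth()
  for (s in seq_len(n_seeds)) {
    fm <- gen_feature_matrix(273, seed = s)
    tr <- synthetic_truth(affinity_noise_sd = 0.5, seed = s)
    pk <- gen_affinities(fm, tr)
    Z <- standardize(fm)
    est <- coef(lm(pk ~ Z$values))[-1]
    names(est) <- colnames(fm)
    ests <- rbind(ests, est[names(tr0$true_coefficients)])
  }
  for (f in colnames(ests)) {
    se <- sd(ests[, f]) / sqrt(n_seeds)
    expect_lt(abs(mean(ests[, f]) - tr0$true_coefficients[[f]]), 3 * se,
              label = f)
  }
})

test_that("scoring-function generator algebra holds exactly at zero noise", {
  fm <- gen_feature_matrix(273, seed = 9)
  tr <- synthetic_truth(affinity_noise_sd = 0.5, sf_noise_sd = 0, seed = 9)
  pk <- gen_affinities(fm, tr)
  # identity transform reproduces pk_ref
  expect_equal(unname(gen_sf_scores(fm, pk, tr)), unname(pk))
  # a single raw-count bias is recoverable by direct regression
  trb <- synthetic_truth(affinity_noise_sd = 0.5, sf_noise_sd = 0,
                         sf_biases = c(HP1 = -0.3), seed = 9)
  sf <- gen_sf_scores(fm, pk, trb)
  slope <- fit_linear(fm[, "HP1"], pk - sf)$slope
  expect_equal(slope, 0.3, tolerance = 1e-8)
  # pure linear transforms keep correlation at 1
  tr2 <- synthetic_truth(affinity_noise_sd = 0.5, sf_noise_sd = 0, sf_slope = 2,
                         sf_offset = -3, sf_biases = c(F = 0.05), seed = 9)
  sf2 <- gen_sf_scores(fm, pk, tr2)
  expect_lt(abs(cor(sf2, pk) - 1), 0.05)
})

test_that("toy complexes have the stated geometry", {
  probe <- 1.0
  d <- gen_toy_complex("distant_pair")
  gap <- sqrt(sum((d$ligand$coords[1, ] - d$protein$coords[1, ])^2))
  expect_gt(gap, d$ligand$radii + d$protein$radii + 2 * probe)
  b <- gen_toy_complex("buried_ligand")
  expect_lt(b$ligand$radii + probe,
            b$protein$radii + probe)  # ligand probe sphere inside protein
  expect_equal(b$ligand$coords, b$protein$coords)
  o <- gen_toy_complex("overlap_pair")
  sep <- sqrt(sum((o$ligand$coords[1, ] - o$protein$coords[1, ])^2))
  expect_lt(sep, o$ligand$radii + o$protein$radii)
  expect_error(gen_toy_complex("weird"), "arg")
})

test_that("toy ligand fixture is well-formed", {
  toy <- gen_toy_ligands()
  expect_gte(length(toy$smiles), 12L)
  expect_identical(rownames(toy$expected), names(toy$smiles))
  # every feature is exercised somewhere and has a zero-count negative
  expect_true(all(colSums(toy$expected) > 0))
  expect_true(all(colSums(toy$expected == 0) > 0))
})
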