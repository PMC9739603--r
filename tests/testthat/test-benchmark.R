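# The three analysis schemes, scoring power, and report assembly.

test_that("scheme_ref recovers the generating coefficients at zero noise", {
  d <- make_synth(seed = 12, affinity_noise_sd = 0)
  Z <- standardize(d$fm)
  fit <- scheme_ref(Z, d$pk_ref, c(1e-8, 1e-2))$fits[[1]]
  truth <- d$truth$true_coefficients
  expect_equal(fit$coefficients[names(truth)], truth, tolerance = 1e-6)
  expect_gt(fit$r2, 1 - 1e-9)
})

test_that("constant response zeroes every coefficient at positive lambda", {
  fm <- gen_feature_matrix(50, seed = 2)
  Z <- standardize(fm)
  path <- scheme_ref(Z, rep(5, 50), c(1e-4, 1e-2, 1))
  for (f in path$fits) expect_identical(unname(f$coefficients), rep(0, ncol(fm)))
})

test_that("a dominant generating coefficient survives the strongest penalty", {
  fm <- gen_feature_matrix(273, seed = 15)
  tr <- synthetic_truth(true_coefficients = c(HP1 = 1.2, HBA = 0.1, F = 0.1),
                        affinity_noise_sd = 0.2, seed = 15)
  pk <- gen_affinities(fm, tr)
  Z <- standardize(fm)
  grid <- default_lambda_grid(Z$values, pk)
  path <- scheme_ref(Z, pk, grid[-length(grid)])
  nz <- lapply(path$fits, function(f) names(f$coefficients)[f$coefficients != 0])
  last_alive <- nz[[max(which(lengths(nz) > 0))]]
  expect_identical(last_alive, "HP1")
})

test_that("scheme_sf equals scheme_ref when the SF reproduces pk_ref", {
  d <- make_synth(seed = 18)
  Z <- standardize(d$fm)
  grid <- c(1e-3, 1e-2, 1e-1)
  a <- scheme_ref(Z, d$pk_ref, grid)
  b <- scheme_sf(Z, d$pk_ref, grid)
  for (k in seq_along(grid))
    expect_equal(a$fits[[k]]$coefficients, b$fits[[k]]$coefficients)
})

test_that("an injected raw-count bias shifts the scheme_sf coefficient by bias*sd", {
  d <- make_synth(seed = 23, affinity_noise_sd = 0, sf_noise_sd = 0,
                  sf_biases = c(PIPI = -0.35))
  Z <- standardize(d$fm)
  lam <- c(1e-9)
  ref <- scheme_ref(Z, d$pk_ref, lam)$fits[[1]]
  sf <- scheme_sf(Z, d$pk_sf, lam)$fits[[1]]
  delta <- sf$coefficients["PIPI"] - ref$coefficients["PIPI"]
  expect_equal(unname(delta), -0.35 * unname(Z$sds["PIPI"]), tolerance = 1e-6)
})

test_that("pure-noise scoring functions show no feature signal", {
  fm <- gen_feature_matrix(1e4, seed = 31)
  Z <- standardize(fm)
  set.seed(123)
  noise <- rnorm(1e4)
  fit <- scheme_sf(Z, noise, c(1e-6))$fits[[1]]
  expect_lt(fit$r2, 0.05)
})

test_that("scheme_combined is exact for a perfect scoring function", {
  d <- make_synth(seed = 40)
  Z <- standardize(d$fm)
  fit <- scheme_combined(Z, d$pk_ref, d$pk_ref, 0)$fits[[1]]
  expect_equal(fit$sf_coefficient, 1, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[colnames(d$fm)]),
               rep(0, ncol(d$fm)), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("scheme_combined localizes an injected bias exactly at lambda 0", {
  d <- make_synth(seed = 41, affinity_noise_sd = 0.5, sf_noise_sd = 0,
                  sf_biases = c(HP1 = -0.3))
  Z <- standardize(d$fm)
  fit <- scheme_combined(Z, d$pk_sf, d$pk_ref, 0)$fits[[1]]
  expect_equal(fit$sf_coefficient, 1, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["HP1"]),
               0.3 * unname(Z$sds["HP1"]), tolerance = 1e-6)
  others <- setdiff(colnames(d$fm), "HP1")
  expect_equal(unname(fit$coefficients[others]), rep(0, length(others)),
               tolerance = 1e-6)
})

test_that("beta_SF tracks 1/sf_slope for clean linear transforms", {
  d <- make_synth(seed = 43, affinity_noise_sd = 0.5, sf_noise_sd = 0,
                  sf_slope = 2, sf_offset = -3)
  Z <- standardize(d$fm)
  fit <- scheme_combined(Z, d$pk_sf, d$pk_ref, 0)$fits[[1]]
  expect_equal(fit$sf_coefficient, 0.5, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("scoring_power and pk_delta_to_fold behave as documented", {
  d <- make_synth(seed = 50, sf_noise_sd = 0.3)
  st <- score_table(data.frame(id = rownames(d$fm), pk_ref = as.numeric(d$pk_ref),
                               SF = as.numeric(d$pk_sf)))
  sp <- scoring_power(st, "SF")
  expect_gt(sp$r2, 0.5)
  # perfect and affine-transformed predictors
  st2 <- score_table(data.frame(id = rownames(d$fm), pk_ref = as.numeric(d$pk_ref),
                                exact = as.numeric(d$pk_ref),
                                affine = as.numeric(3 - 2 * d$pk_ref)))
  expect_equal(scoring_power(st2, "exact")$r2, 1)
  expect_equal(scoring_power(st2, "exact")$sd, 0)
  expect_equal(scoring_power(st2, "affine")$r2, 1)
  expect_error(scoring_power(st2, "nope"), "unknown scoring function")
  # permuted reference has no power at n = 1e4
  set.seed(7)
  big <- rnorm(1e4)
  st3 <- score_table(data.frame(id = seq_along(big), pk_ref = big,
                                perm = sample(big)))
  expect_lt(scoring_power(st3, "perm")$r2, 0.01)

  expect_equal(pk_delta_to_fold(0), 1)
  expect_equal(pk_delta_to_fold(1), 10)
  expect_equal(pk_delta_to_fold(0.19), 1.55, tolerance = 5e-3)
})

test_that("score_table validates and negates columns", {
  df <- data.frame(id = c("a", "b", "c"), pk_ref = 1:3, DSX = c(-5, -7, -9))
  st <- score_table(df, negate = "DSX")
  expect_identical(st$DSX, c(5, 7, 9))
  expect_error(score_table(df[, 1:2]), "no scoring-function columns")
  expect_error(score_table(df, negate = "X"), "unknown column")
  df$DSX[2] <- NA
  expect_error(score_table(df), "missing values")
  # TSV and CSV round trips
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(st, path)
  expect_equal(read_score_table(path)$DSX, c(5, 7, 9))
})

test_that("build_report assembles one section per scoring function", {
  d <- make_synth(seed = 55, sf_noise_sd = 0.2)
  tr2 <- synthetic_truth(seed = 56, sf_noise_sd = 0,
                         sf_biases = c(HP1 = -0.4))
  sf2 <- gen_sf_scores(d$fm, d$pk_ref, tr2)
  st <- score_table(data.frame(id = rownames(d$fm), pk_ref = as.numeric(d$pk_ref),
                               SF_good = as.numeric(d$pk_sf),
                               SF_biased = as.numeric(sf2)))
  rep <- build_report(d$fm, st, lambdas = c(1e-3, 1e-2, 1e-1))
  expect_s3_class(rep, "fw_report")
  expect_identical(names(rep$per_sf), c("SF_good", "SF_biased"))
  expect_identical(rep$n_complexes, nrow(d$fm))
  # every surviving feature appears in every scheme's coefficient table
  for (s in names(rep$per_sf)) {
    for (p in list(rep$ref_path, rep$per_sf[[s]]$sf_path,
                   rep$per_sf[[s]]$combined_path)) {
      expect_true(all(rep$feature_names %in%
                        names(p$fits[[1]]$coefficients)))
    }
  }
  # the biased SF needs strictly larger feature corrections at matched lambda
  l1_corr <- function(s, k) {
    f <- rep$per_sf[[s]]$combined_path$fits[[k]]
    sum(abs(f$coefficients[rep$feature_names]))
  }
  expect_gt(l1_corr("SF_biased", 1), l1_corr("SF_good", 1))
})

test_that("report files are byte-identical across identical runs", {
  d <- make_synth(seed = 61, sf_noise_sd = 0.2)
  st <- score_table(data.frame(id = rownames(d$fm), pk_ref = as.numeric(d$pk_ref),
                               SF = as.numeric(d$pk_sf)))
  rep1 <- build_report(d$fm, st, lambdas = c(1e-3, 1e-1))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_report(rep1, dir1, config = list(seed = 61))
  write_report(build_report(d$fm, st, lambdas = c(1e-3, 1e-1)), dir2,
               config = list(seed = 61))
  files <- list.files(dir1)
  expect_true(length(files) >= 5)
  for (f in files)
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     label = f)
})
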