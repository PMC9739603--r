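# Cosine correlation, filtering, standardization, and the Lasso solver.

test_that("cosine_correlation matches hand arithmetic and its invariants", {
  expect_equal(cosine_correlation(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_equal(cosine_correlation(c(1, 0, 0), c(0, 1, 0)), 0)
  v <- c(3, 1, 4, 1, 5)
  expect_equal(cosine_correlation(v, v), 1)
  # scale invariance, symmetry
  for (c in c(0.5, 2, 17)) expect_equal(cosine_correlation(v, c * v), 1)
  a <- c(1, 2, 0, 4); b <- c(0, 1, 3, 1)
  expect_equal(cosine_correlation(a, b), cosine_correlation(b, a))
  # uncentered: differs from Pearson on non-centered data
  expect_false(isTRUE(all.equal(cosine_correlation(a, b),
                                cosine_correlation(a, b, method = "pearson"))))
  expect_error(cosine_correlation(c(0, 0), c(1, 1)), "all-zero")
  expect_error(cosine_correlation(1:3, 1:4), "length mismatch")
})

test_that("correlation_filter drops the feature present in fewer molecules", {
  set.seed(3)
  n <- 273
  base <- rpois(n, 2) + 1L           # present in all rows
  a <- base; a[sample(n, 16)] <- 0L  # 257 molecules
  b <- a; b[which(a > 0)[1]] <- 0L   # 256 molecules, near-identical profile
  other <- rbinom(n, 1, 0.3)
  fm <- cbind(HBD1 = a, HBD2 = b, Hal = other)
  out <- correlation_filter(fm, threshold = 0.9)
  expect_identical(colnames(out$matrix), c("HBD1", "Hal"))
  expect_identical(out$report$dropped, "HBD2")
  expect_identical(out$report$kept, "HBD1")
  expect_gt(out$report$r, 0.9)
})

test_that("correlation_filter edge behaviour", {
  set.seed(4)
  x <- rpois(50, 2); y <- rbinom(50, 3, 0.3)
  # independent-ish columns below threshold: untouched
  fm <- cbind(a = x, b = y)
  out <- correlation_filter(fm, threshold = 0.999)
  expect_identical(out$matrix, fm)
  expect_identical(nrow(out$report), 0L)
  # three mutually identical columns: exactly one survives
  fm3 <- cbind(a = x, b = x, c = x, d = y)
  out3 <- correlation_filter(fm3)
  expect_identical(ncol(out3$matrix), 2L)
  expect_identical(sum(c("a", "b", "c") %in% colnames(out3$matrix)), 1L)
  # all-zero columns are removed first with a report entry
  fmz <- cbind(a = x, zero = 0L)
  outz <- correlation_filter(fmz)
  expect_identical(colnames(outz$matrix), "a")
  expect_identical(outz$report$dropped, "zero")
  expect_true(is.na(outz$report$r))
  expect_error(correlation_filter(fm, threshold = 1.2), "threshold")
})

test_that("standardize uses population sd and inverts exactly", {
  z <- standardize(cbind(x = c(0, 1, 2)))
  expect_equal(as.numeric(z$values), c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(unname(z$means), 1)
  expect_equal(unname(z$sds), sqrt(2 / 3))  # population sd = 0.8165
  set.seed(8)
  fm <- matrix(rpois(200, 3), 50, 4, dimnames = list(NULL, letters[1:4]))
  z <- standardize(fm)
  expect_lt(max(abs(colMeans(z$values))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(z$values^2)) - 1)), 1e-10)
  expect_lt(max(abs(unstandardize(z) - fm)), 1e-10)
  # idempotence on already standardized data
  z2 <- standardize(z$values)
  expect_lt(max(abs(z2$values - z$values)), 1e-12)
  expect_error(standardize(cbind(k = rep(2, 5))), "constant")
})

test_that("fit_lasso at lambda 0 equals ordinary least squares", {
  pb <- make_problem(seed = 2)
  f <- fit_lasso(pb$X, pb$y, 0)
  ols <- coef(lm(pb$y ~ pb$X))
  expect_equal(unname(f$coefficients), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(f$intercept, unname(ols[1]), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("all penalized coefficients vanish at and above lambda_max", {
  for (seed in 1:5) {
    pb <- make_problem(seed = seed)
    n <- length(pb$y)
    lmax <- (2 / n) * max(abs(crossprod(pb$X, pb$y - mean(pb$y))))
    for (lam in c(lmax, 1.5 * lmax)) {
      f <- fit_lasso(pb$X, pb$y, lam)
      expect_identical(unname(f$coefficients), rep(0, ncol(pb$X)))
      expect_equal(f$intercept, mean(pb$y))
    }
  }
})

test_that("orthonormal designs give the closed-form soft threshold", {
  n <- 40
  Q <- make_orthonormal(n = n, seed = 6)
  set.seed(60)
  y <- rnorm(n)
  z <- as.numeric(crossprod(Q, y - mean(y)))
  for (lam in c(0.01, 0.03, 0.08)) {
    f <- fit_lasso(Q, y, lam)
    expected <- sign(z) * pmax(abs(z) - n * lam / 2, 0)
    expect_equal(unname(f$coefficients), expected, tolerance = 1e-8)
    expect_lt(f$kkt_max, 1e-6)
  }
})

test_that("solutions agree with glmnet under the lambda conversion", {
  skip_if_not_installed("glmnet")
  pb <- make_problem(n = 80, p = 8, seed = 13)
  for (lam in c(0.02, 0.1, 0.5)) {
    f <- fit_lasso(pb$X, pb$y, lam)
    g <- glmnet::glmnet(pb$X, pb$y, lambda = lam / 2, standardize = FALSE,
                        thresh = 1e-12)
    expect_equal(unname(f$coefficients), as.numeric(g$beta), tolerance = 1e-6)
    expect_equal(f$intercept, as.numeric(g$a0), tolerance = 1e-6)
  }
})

test_that("unpenalized columns are excluded from the L1 term", {
  pb <- make_problem(n = 100, p = 5, seed = 21)
  lam <- 0.4
  f <- fit_lasso(pb$X, pb$y, lam, penalize = c(FALSE, rep(TRUE, 4)))
  expect_lt(f$kkt_max, 1e-6)
  # the unpenalized coordinate keeps a zero gradient even at large lambda
  lam_big <- 10
  fb <- fit_lasso(pb$X, pb$y, lam_big, penalize = c(FALSE, rep(TRUE, 4)))
  expect_identical(unname(fb$coefficients[-1]), rep(0, 4))
  expect_gt(abs(fb$coefficients[1]), 0)
})

test_that("penalized objective is optimal and monotone in lambda", {
  pb <- make_problem(seed = 31)
  ols <- fit_lasso(pb$X, pb$y, 0)
  lambdas <- c(0.01, 0.05, 0.2, 0.8)
  objs <- numeric(length(lambdas))
  for (k in seq_along(lambdas)) {
    f <- fit_lasso(pb$X, pb$y, lambdas[k])
    obj <- lasso_objective(pb$X, pb$y, f$coefficients, f$intercept, lambdas[k])
    objs[k] <- obj
    # optimality sanity bound against the OLS point
    bound <- lasso_objective(pb$X, pb$y, ols$coefficients, ols$intercept, lambdas[k])
    expect_lte(obj, bound + 1e-10)
  }
  expect_true(all(diff(objs) > -1e-10))
})

test_that("lasso_path warm-starts and satisfies the path invariants", {
  pb <- make_problem(n = 60, p = 6, seed = 44)
  n <- length(pb$y)
  lmax <- (2 / n) * max(abs(crossprod(pb$X, pb$y - mean(pb$y))))
  grid <- exp(seq(log(1e-3), log(1.2 * lmax), length.out = 12))
  path <- lasso_path(pb$X, pb$y, grid)
  l1 <- vapply(path$fits, function(f) sum(abs(f$coefficients)), numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
  expect_identical(unname(path$fits[[12]]$coefficients), rep(0, 6))
  # singleton grid equals a direct fit
  single <- lasso_path(pb$X, pb$y, grid[3])
  direct <- fit_lasso(pb$X, pb$y, grid[3])
  expect_equal(single$fits[[1]]$coefficients, direct$coefficients, tolerance = 1e-9)
  expect_error(lasso_path(pb$X, pb$y, c(0.2, 0.1)), "increasing")
  tab <- path_coefficients(path)
  expect_identical(names(tab)[1:3], c("lambda", "r2", "sd"))
  expect_identical(nrow(tab), 12L)
})

test_that("a dominant feature survives longest along the path", {
  set.seed(77)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("big", "s1", "s2", "s3")))
  y <- 2 * X[, "big"] + 0.2 * X[, "s1"] + rnorm(n, sd = 0.2)
  n2 <- n
  lmax <- (2 / n2) * max(abs(crossprod(X, y - mean(y))))
  path <- lasso_path(X, y, exp(seq(log(1e-3), log(0.95 * lmax), length.out = 20)))
  nz <- lapply(path$fits, function(f) names(f$coefficients)[f$coefficients != 0])
  last <- nz[[max(which(lengths(nz) > 0))]]
  expect_identical(last, "big")
})

test_that("fit_linear matches the normal equations and handles nulls", {
  x <- c(1, 2, 3, 5)
  y <- 2 * x + 1
  f <- fit_linear(x, y)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1); expect_equal(f$sd, 0)
  # brute-force normal equations on a 4-point worked set
  y2 <- c(1.1, 2.3, 2.8, 5.4)
  A <- cbind(1, x)
  beta <- solve(t(A) %*% A, t(A) %*% y2)
  f2 <- fit_linear(x, y2)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f2$slope, beta[2], tolerance = 1e-10)
  expect_equal(f2$sd, sqrt(sum((y2 - A %*% beta)^2) / 2), tolerance = 1e-10)
  # independent response: r2 near zero at n = 1e4
  set.seed(99)
  xn <- rnorm(1e4); yn <- rnorm(1e4)
  expect_lt(fit_linear(xn, yn)$r2, 0.01)
  expect_error(fit_linear(rep(1, 5), rnorm(5)), "constant")
})
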