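# Core statistics: uncentered cosine correlation with the r > 0.9 exclusion
# rule, per-feature standardization, and an L1-penalized least-squares
# (Lasso) solver over regularization paths.
#
# The Lasso objective carries an explicit 1/N factor on the squared loss:
#     (1/N) * ||y - b0 - X b||^2  +  lambda * ||b||_1
# Solvers using the 1/(2N) convention (e.g. glmnet) match at
# lambda_other = lambda_here / 2.

#' Uncentered cosine correlation between two feature vectors
#'
#' `r = a . b / (|a| |b|)`. Deliberately *not* Pearson: occurrence-count
#' vectors are compared without mean-centering, so two features present in
#' exactly the same ligands at proportional counts give r = 1. A Pearson
#' variant is available via `method = "pearson"` for sensitivity analysis.
#'
#' @param a,b numeric vectors of equal length, neither all-zero.
#' @param method `"cosine"` (default) or `"pearson"`.
#' @return correlation in \[-1, 1\].
#' @examples
#' cosine_correlation(c(1, 2, 2), c(2, 1, 2))  # 8/9
#' @export
cosine_correlation <- function(a, b, method = c("cosine", "pearson")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("length mismatch: ", length(a), " vs ", length(b))
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b))
    stop("inputs must be numeric without missing values")
  if (method == "pearson") return(stats::cor(a, b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine correlation undefined for an all-zero vector")
  sum(a * b) / (na * nb)
}

#' Drop highly correlated features from a count matrix
#'
#' All-zero columns are removed first (reported with r = NA). Then, while any
#' pair of remaining columns has correlation above `threshold`, the worst
#' pair is taken and the feature present in *fewer* molecules (fewer nonzero
#' entries) is dropped; ties keep the earlier column. The greedy loop
#' recomputes after every removal, so the survivor set has no pair above the
#' threshold.
#'
#' @param fm count matrix (ligands x features) with colnames.
#' @param threshold exclusion threshold in (0, 1\]; default 0.9.
#' @param method correlation variant passed to [cosine_correlation()].
#' @return list with `matrix` (filtered) and `report` (data.frame with
#'   `kept`, `dropped`, `r`).
#' @export
correlation_filter <- function(fm, threshold = 0.9, method = c("cosine", "pearson")) {
  method <- match.arg(method)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("'threshold' must be in (0, 1]")
  if (is.null(colnames(fm))) stop("'fm' must have feature names as colnames")
  report <- data.frame(kept = character(0), dropped = character(0), r = numeric(0))

  zero <- colSums(abs(fm)) == 0
  for (nm in colnames(fm)[zero])
    report <- rbind(report, data.frame(kept = NA_character_, dropped = nm, r = NA_real_))
  fm <- fm[, !zero, drop = FALSE]
  if (ncol(fm) < 2L) return(list(matrix = fm, report = report))

  repeat {
    p <- ncol(fm)
    if (p < 2L) break
    rmat <- matrix(0, p, p)
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
      rmat[i, j] <- cosine_correlation(fm[, i], fm[, j], method = method)
    worst <- which(rmat == max(rmat), arr.ind = TRUE)[1, ]
    if (rmat[worst[1], worst[2]] <= threshold) break
    i <- worst[[1]]; j <- worst[[2]]
    ni <- sum(fm[, i] != 0); nj <- sum(fm[, j] != 0)
    drop_j <- if (ni == nj) max(i, j) else if (ni < nj) i else j
    keep_j <- if (drop_j == i) j else i
    report <- rbind(report, data.frame(kept = colnames(fm)[keep_j],
                                       dropped = colnames(fm)[drop_j],
                                       r = rmat[worst[1], worst[2]]))
    fm <- fm[, -drop_j, drop = FALSE]
  }
  list(matrix = fm, report = report)
}

#' Standardize feature columns to zero mean and unit variance
#'
#' Population standard deviation (divisor N) is used, matching the usual
#' machine-learning scaler convention. Means and sds are stored for the
#' inverse transform.
#'
#' @param fm numeric matrix (ligands x features).
#' @return object of class `fw_standardized`: list with `values`, `means`,
#'   `sds`, `feature_names`.
#' @export
standardize <- function(fm) {
  fm <- as.matrix(fm)
  n <- nrow(fm)
  means <- colMeans(fm)
  sds <- sqrt(colMeans(sweep(fm, 2L, means)^2))
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(fm)[sds == 0], collapse = ", "),
         " -- exclude before standardizing")
  values <- sweep(sweep(fm, 2L, means), 2L, sds, "/")
  structure(list(values = values, means = means, sds = sds,
                 feature_names = colnames(fm)),
            class = "fw_standardized")
}

#' @rdname standardize
#' @param z an `fw_standardized` object.
#' @export
unstandardize <- function(z) {
  sweep(sweep(z$values, 2L, z$sds, "*"), 2L, z$means, "+")
}

#' @export
print.fw_standardized <- function(x, ...) {
  cat(sprintf("<fw_standardized: %d x %d, population-sd scaling>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# smallest lambda at which every penalized coefficient is zero
lambda_max <- function(X, y, penalize = rep(TRUE, ncol(X))) {
  n <- nrow(X)
  r <- y - mean(y)
  (2 / n) * max(abs(crossprod(X[, penalize, drop = FALSE], r)))
}

#' Fit the Lasso by cyclic coordinate descent
#'
#' Minimizes `(1/N) ||y - b0 - X b||^2 + lambda * sum_j penalize_j |b_j|`.
#' The intercept is never penalized; columns with `penalize = FALSE` are
#' excluded from the L1 term (used for an unpenalized scoring-function
#' coefficient). At `lambda = 0` the problem is ordinary least squares and is
#' solved directly by QR. Coordinate updates use the closed-form soft
#' threshold `b_j = S(x_j' r_j, N lambda / 2) / (x_j' x_j)`; convergence is
#' declared when the largest coefficient change drops below `tol`, and KKT
#' subgradient residuals are checked at the solution.
#'
#' @param X numeric design matrix.
#' @param y numeric response.
#' @param lambda non-negative penalty.
#' @param penalize logical per-column flags (default all TRUE).
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter iteration cap.
#' @param warm_start optional initial coefficient vector.
#' @return object of class `fw_lasso`: `lambda`, `intercept`, `coefficients`
#'   (named), `fitted`, `r2` (squared Pearson of fitted vs observed), `r2_sse`
#'   (1 - SSE/SST), `sd` (residual sd, denominator N - 2), `kkt_max`,
#'   `converged`, `n_iter`.
#' @export
fit_lasso <- function(X, y, lambda, penalize = rep(TRUE, ncol(X)),
                      tol = 1e-8, max_iter = 1e5, warm_start = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("rows of X must match length of y")
  if (n < 2L) stop("need at least 2 observations")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || !is.finite(lambda))
    stop("'lambda' must be a single non-negative number")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite entries in X or y")
  if (length(penalize) != p) stop("'penalize' must have one flag per column")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))

  if (lambda == 0) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    beta <- fit$coefficients[-1]
    beta[is.na(beta)] <- 0
    b0 <- fit$coefficients[1]
    return(finish_lasso_fit(X, y, beta, b0, lambda, penalize, cn,
                            converged = TRUE, n_iter = 0L))
  }

  beta <- if (is.null(warm_start)) numeric(p) else as.numeric(warm_start)
  xtx <- colSums(X^2)
  if (any(xtx == 0 & penalize == FALSE))
    stop("unpenalized all-zero column cannot be fit")
  resid <- y - X %*% beta
  b0 <- mean(resid)
  resid <- resid - b0
  thresh <- n * lambda / 2
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    delta_max <- 0
    b0_new <- b0 + mean(resid)
    resid <- resid - (b0_new - b0)
    delta_max <- max(delta_max, abs(b0_new - b0))
    b0 <- b0_new
    for (j in seq_len(p)) {
      if (xtx[j] == 0) next
      zj <- sum(X[, j] * resid) + xtx[j] * beta[j]
      bj_new <- if (penalize[j]) soft_threshold(zj, thresh) / xtx[j] else zj / xtx[j]
      if (bj_new != beta[j]) {
        resid <- resid - X[, j] * (bj_new - beta[j])
        delta_max <- max(delta_max, abs(bj_new - beta[j]))
        beta[j] <- bj_new
      }
    }
    if (delta_max < tol) { converged <- TRUE; break }
  }
  # snap float dust (e.g. the exact lambda_max boundary) to true zeros
  snap <- penalize & abs(beta) < 1e-12
  if (any(snap & beta != 0)) {
    resid <- resid + X[, snap, drop = FALSE] %*% beta[snap]
    beta[snap] <- 0
  }
  finish_lasso_fit(X, y, beta, b0, lambda, penalize, cn, converged, iter)
}

soft_threshold <- function(z, t) sign(z) * max(abs(z) - t, 0)

finish_lasso_fit <- function(X, y, beta, b0, lambda, penalize, cn,
                             converged, n_iter) {
  n <- nrow(X)
  fitted <- as.numeric(X %*% beta + b0)
  resid <- y - fitted
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (stats::sd(fitted) == 0 || sst == 0) 0 else stats::cor(fitted, y)^2
  r2_sse <- if (sst == 0) 0 else 1 - sse / sst
  # KKT subgradient residuals for the penalized coordinates
  grad <- -(2 / n) * as.numeric(crossprod(X, resid))
  kkt <- numeric(length(beta))
  for (j in seq_along(beta)) {
    kkt[j] <- if (!penalize[j] || lambda == 0) abs(grad[j])
    else if (beta[j] != 0) abs(grad[j] + lambda * sign(beta[j]))
    else max(0, abs(grad[j]) - lambda)
  }
  structure(list(
    lambda = lambda,
    intercept = as.numeric(b0),
    coefficients = stats::setNames(as.numeric(beta), cn),
    penalize = penalize,
    fitted = fitted,
    r2 = r2, r2_sse = r2_sse,
    sd = sqrt(sse / max(1, n - 2)),
    kkt_max = max(kkt),
    converged = converged,
    n_iter = n_iter
  ), class = "fw_lasso")
}

#' @export
print.fw_lasso <- function(x, ...) {
  cat(sprintf("<fw_lasso lambda=%.4g  R2=%.3f  sd=%.3f  nonzero=%d/%d%s>\n",
              x$lambda, x$r2, x$sd, sum(x$coefficients != 0),
              length(x$coefficients),
              if (x$converged) "" else "  NOT CONVERGED"))
  invisible(x)
}

#' Lasso regularization path
#'
#' One fit per lambda, warm-started from the previous solution. Lambdas must
#' be strictly increasing; along the path the L1 norm of the penalized
#' coefficients is non-increasing.
#'
#' @inheritParams fit_lasso
#' @param lambdas strictly increasing non-negative penalties.
#' @return object of class `fw_lasso_path`: list with `lambdas` and `fits`.
#' @export
lasso_path <- function(X, y, lambdas, penalize = rep(TRUE, ncol(X)), ...) {
  if (!length(lambdas)) stop("'lambdas' must be non-empty")
  if (any(lambdas < 0)) stop("lambdas must be non-negative")
  if (is.unsorted(lambdas, strictly = TRUE)) stop("lambdas must be strictly increasing")
  fits <- vector("list", length(lambdas))
  warm <- NULL
  for (k in seq_along(lambdas)) {
    fits[[k]] <- fit_lasso(X, y, lambdas[k], penalize = penalize,
                           warm_start = warm, ...)
    warm <- fits[[k]]$coefficients
  }
  structure(list(lambdas = lambdas, fits = fits), class = "fw_lasso_path")
}

#' @export
print.fw_lasso_path <- function(x, ...) {
  cat(sprintf("<fw_lasso_path: %d fits, lambda in [%.4g, %.4g]>\n",
              length(x$fits), min(x$lambdas), max(x$lambdas)))
  invisible(x)
}

#' Coefficient table of a Lasso path
#'
#' @param path an `fw_lasso_path`.
#' @return data.frame: `lambda`, `r2`, `sd`, then one column per coefficient.
#' @export
path_coefficients <- function(path) {
  stopifnot(inherits(path, "fw_lasso_path"))
  coefs <- t(vapply(path$fits, `[[`, path$fits[[1]]$coefficients, "coefficients"))
  data.frame(lambda = path$lambdas,
             r2 = vapply(path$fits, `[[`, numeric(1), "r2"),
             sd = vapply(path$fits, `[[`, numeric(1), "sd"),
             coefs, check.names = FALSE)
}

#' Simple linear regression with fit statistics
#'
#' Ordinary least squares of `y` on a single predictor. `r2` is the squared
#' Pearson correlation; `sd` is the residual standard deviation with
#' denominator N - 2 (two fitted parameters).
#'
#' @param x,y numeric vectors, length >= 3, `x` not constant.
#' @return list with `slope`, `intercept`, `r2`, `sd`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("'x' is constant")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  list(slope = slope, intercept = intercept, r2 = r2,
       sd = sqrt(sum(resid^2) / (length(x) - 2)))
}
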