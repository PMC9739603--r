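# Benchmark schemes relating experimental affinity, scoring-function output
# and fragment features:
#   scheme_ref:      pK_ref ~ Lasso(FW, lambda)
#   scheme_sf:       pK_SF  ~ Lasso(FW, lambda)
#   scheme_combined: pK_ref ~ Lasso(FW + raw pK_SF column, lambda)
# In the combined scheme the feature columns are standardized but the pK_SF
# column is NOT, so a well-calibrated scoring function shows beta_SF near 1
# with feature corrections near 0; the feature coefficients read directly as
# the residual corrections the scoring function needs.

#' Read a score table
#'
#' Delimited text (tab or comma, auto-detected) with header `id`, `pk_ref`,
#' then one column per scoring function. Scores for functions listed in
#' `negate` are sign-flipped at ingestion so that larger always means
#' stronger predicted binding (knowledge-based scores are conventionally
#' negative-better).
#'
#' @param path input file.
#' @param negate character vector of scoring-function columns to negate.
#' @return data.frame with class `fw_scores`.
#' @export
read_score_table <- function(path, negate = character(0)) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  score_table(df, negate = negate)
}

#' Construct/validate a score table
#'
#' @param df data.frame with columns `id`, `pk_ref`, then scoring functions.
#' @param negate scoring-function columns to sign-flip.
#' @return `fw_scores` data.frame.
#' @export
score_table <- function(df, negate = character(0)) {
  if (!all(c("id", "pk_ref") %in% names(df)))
    stop("score table needs 'id' and 'pk_ref' columns")
  if (anyDuplicated(df$id)) stop("duplicate complex ids in score table")
  sfs <- setdiff(names(df), c("id", "pk_ref"))
  if (!length(sfs)) stop("score table has no scoring-function columns")
  bad <- setdiff(negate, sfs)
  if (length(bad)) stop("cannot negate unknown column(s): ", paste(bad, collapse = ", "))
  for (s in negate) df[[s]] <- -df[[s]]
  if (anyNA(df[c("pk_ref", sfs)])) stop("missing values in score table")
  structure(df, class = c("fw_scores", "data.frame"), sf_names = sfs)
}

#' @export
print.fw_scores <- function(x, ...) {
  cat(sprintf("<fw_scores: %d complexes, SFs: %s>\n", nrow(x),
              paste(attr(x, "sf_names"), collapse = ", ")))
  invisible(x)
}

#' Write a score table as TSV
#'
#' @param st `fw_scores` or plain data.frame with the score-table layout.
#' @param path output file.
#' @export
write_score_table <- function(st, path) {
  utils::write.table(as.data.frame(st), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Scoring power of one scoring function
#'
#' Linear regression of experimental pK on the scoring-function column; the
#' reported `r2` (squared Pearson) and residual `sd` are the two standard
#' scoring-power statistics.
#'
#' @param st an `fw_scores` table.
#' @param sf_name scoring-function column name.
#' @return list with `slope`, `intercept`, `r2`, `sd`.
#' @export
scoring_power <- function(st, sf_name) {
  sfs <- attr(st, "sf_names")
  if (is.null(sfs)) sfs <- setdiff(names(st), c("id", "pk_ref"))
  if (!(sf_name %in% sfs)) stop("unknown scoring function: ", sf_name)
  fit_linear(st[[sf_name]], st$pk_ref)
}

#' Convert a pK difference to a fold change in Kd/Ki
#'
#' pK is a negative decadic logarithm of the dissociation/inhibition
#' constant, so a difference of `delta_pk` units corresponds to a
#' `10^delta_pk`-fold change in Kd/Ki.
#'
#' @param delta_pk numeric pK difference(s).
#' @return fold change(s).
#' @examples
#' pk_delta_to_fold(0.19)  # ~1.55
#' @export
pk_delta_to_fold <- function(delta_pk) 10^delta_pk

align_rows <- function(Z, y, what) {
  if (nrow(Z$values) != length(y))
    stop(what, ": ", length(y), " responses for ", nrow(Z$values), " ligand rows")
  invisible(TRUE)
}

#' Lasso path of experimental affinity on standardized features
#'
#' @param Z an `fw_standardized` feature matrix.
#' @param pk_ref experimental affinities aligned with the rows of `Z`.
#' @param lambdas strictly increasing penalty grid.
#' @return `fw_lasso_path`.
#' @export
scheme_ref <- function(Z, pk_ref, lambdas) {
  stopifnot(inherits(Z, "fw_standardized"))
  align_rows(Z, pk_ref, "scheme_ref")
  lasso_path(Z$values, as.numeric(pk_ref), lambdas)
}

#' Lasso path of scoring-function output on standardized features
#'
#' @param Z an `fw_standardized` feature matrix.
#' @param pk_sf scoring-function predictions aligned with the rows of `Z`.
#' @param lambdas strictly increasing penalty grid.
#' @return `fw_lasso_path`.
#' @export
scheme_sf <- function(Z, pk_sf, lambdas) {
  stopifnot(inherits(Z, "fw_standardized"))
  align_rows(Z, pk_sf, "scheme_sf")
  lasso_path(Z$values, as.numeric(pk_sf), lambdas)
}

#' Combined residual-error model
#'
#' Lasso path of experimental affinity on the standardized features plus the
#' *raw* (unstandardized) scoring-function column. Each fit exposes the
#' scoring-function coefficient as `sf_coefficient`: values near 1 with small
#' feature coefficients indicate a well-calibrated scoring function, while a
#' shrunken coefficient with large feature corrections localizes the residual
#' error on specific fragments.
#'
#' @param Z an `fw_standardized` feature matrix.
#' @param pk_sf raw scoring-function predictions.
#' @param pk_ref experimental affinities.
#' @param lambdas strictly increasing penalty grid.
#' @param penalize_sf should the scoring-function coefficient be inside the
#'   L1 penalty (default TRUE, a plain Lasso over the augmented design)?
#' @return `fw_lasso_path`; each fit carries `sf_coefficient`.
#' @export
scheme_combined <- function(Z, pk_sf, pk_ref, lambdas, penalize_sf = TRUE) {
  stopifnot(inherits(Z, "fw_standardized"))
  align_rows(Z, pk_sf, "scheme_combined")
  align_rows(Z, pk_ref, "scheme_combined")
  X <- cbind(Z$values, pK_SF = as.numeric(pk_sf))
  path <- lasso_path(X, as.numeric(pk_ref), lambdas,
                     penalize = c(rep(TRUE, ncol(Z$values)), penalize_sf))
  path$fits <- lapply(path$fits, function(f) {
    f$sf_coefficient <- unname(f$coefficients["pK_SF"])
    f
  })
  path
}

#' Default log-spaced penalty grid
#'
#' 16 points log-spaced between `lambda_min` and the smallest lambda that
#' zeroes every penalized coefficient (computed from the design).
#'
#' @param X design matrix, `y` response (used for the upper end).
#' @param y response vector.
#' @param n_lambda number of grid points.
#' @param lambda_min lower end of the grid.
#' @return strictly increasing numeric vector.
#' @export
default_lambda_grid <- function(X, y, n_lambda = 16L, lambda_min = 1e-3) {
  lmax <- lambda_max(as.matrix(X), as.numeric(y))
  if (lmax <= lambda_min) lmax <- lambda_min * 10
  exp(seq(log(lambda_min), log(lmax), length.out = n_lambda))
}

#' Run the full Free-Wilson benchmark
#'
#' Pipeline: drop all-zero and highly correlated features
#' ([correlation_filter()]), standardize, fit the reference scheme once and
#' the per-scoring-function schemes (direct and combined), and compute
#' scoring power for every scoring function. Complexes present in only one
#' of the two inputs are dropped listwise (ids recorded in the report).
#'
#' @param fm Free-Wilson count matrix (ligand ids as rownames).
#' @param st `fw_scores` table.
#' @param lambdas penalty grid; default [default_lambda_grid()] on the
#'   filtered standardized design against pk_ref.
#' @param threshold correlation-filter threshold (default 0.9).
#' @param method correlation variant, `"cosine"` (default) or `"pearson"`.
#' @param penalize_sf passed to [scheme_combined()].
#' @return object of class `fw_report`.
#' @export
build_report <- function(fm, st, lambdas = NULL, threshold = 0.9,
                         method = "cosine", penalize_sf = TRUE) {
  sfs <- attr(st, "sf_names")
  if (is.null(sfs)) stop("'st' must be an fw_scores table (see score_table())")
  common <- intersect(rownames(fm), st$id)
  if (!length(common)) stop("no common ids between feature matrix and score table")
  dropped_ids <- list(
    features_only = setdiff(rownames(fm), common),
    scores_only = setdiff(st$id, common))
  if (length(dropped_ids$features_only) || length(dropped_ids$scores_only))
    fw_log("join", sprintf("dropping %d feature-only and %d score-only ids",
                           length(dropped_ids$features_only),
                           length(dropped_ids$scores_only)))
  fm <- fm[common, , drop = FALSE]
  st <- st[match(common, st$id), , drop = FALSE]

  filt <- correlation_filter(fm, threshold = threshold, method = method)
  Z <- standardize(filt$matrix)
  pk_ref <- st$pk_ref
  if (is.null(lambdas)) lambdas <- default_lambda_grid(Z$values, pk_ref)

  ref_path <- scheme_ref(Z, pk_ref, lambdas)
  per_sf <- lapply(sfs, function(s) {
    pk_sf <- st[[s]]
    list(name = s,
         scoring_power = scoring_power(st, s),
         sf_path = scheme_sf(Z, pk_sf, lambdas),
         combined_path = scheme_combined(Z, pk_sf, pk_ref, lambdas,
                                         penalize_sf = penalize_sf))
  })
  names(per_sf) <- sfs
  structure(list(n_complexes = length(common), dropped_ids = dropped_ids,
                 exclusion_report = filt$report,
                 feature_names = colnames(filt$matrix),
                 feature_sds = Z$sds, lambdas = lambdas,
                 ref_path = ref_path, per_sf = per_sf,
                 threshold = threshold, method = method,
                 penalize_sf = penalize_sf),
            class = "fw_report")
}

#' @export
print.fw_report <- function(x, ...) {
  cat(sprintf("<fw_report: %d complexes, %d features, %d scoring functions>\n",
              x$n_complexes, length(x$feature_names), length(x$per_sf)))
  ref0 <- x$ref_path$fits[[1]]
  cat(sprintf("  features-only R2 at lambda=%.3g: %.3f\n",
              x$lambdas[1], ref0$r2))
  for (s in names(x$per_sf)) {
    e <- x$per_sf[[s]]
    comb0 <- e$combined_path$fits[[1]]
    cat(sprintf("  %-12s scoring power R2=%.3f sd=%.3f | combined R2=%.3f beta_SF=%.3f\n",
                s, e$scoring_power$r2, e$scoring_power$sd,
                comb0$r2, comb0$sf_coefficient))
  }
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Emits: `scoring_power.tsv`, `exclusion_report.tsv`, `scheme_ref.tsv`,
#' `scheme_sf_<SF>.tsv`, `scheme_combined_<SF>.tsv` and a plain-text
#' `summary.txt` with run provenance. Output is deterministic: identical
#' inputs give byte-identical files.
#'
#' @param report an `fw_report`.
#' @param dir output directory (created if missing).
#' @param config optional named list echoed into `summary.txt` for
#'   provenance.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir, config = NULL) {
  stopifnot(inherits(report, "fw_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  sp <- do.call(rbind, lapply(names(report$per_sf), function(s) {
    p <- report$per_sf[[s]]$scoring_power
    data.frame(sf = s, slope = p$slope, intercept = p$intercept,
               r2 = p$r2, sd = p$sd)
  }))
  wt(sp, "scoring_power.tsv")
  wt(report$exclusion_report, "exclusion_report.tsv")
  wt(path_coefficients(report$ref_path), "scheme_ref.tsv")
  for (s in names(report$per_sf)) {
    wt(path_coefficients(report$per_sf[[s]]$sf_path),
       sprintf("scheme_sf_%s.tsv", s))
    wt(path_coefficients(report$per_sf[[s]]$combined_path),
       sprintf("scheme_combined_%s.tsv", s))
  }
  lines <- c(
    sprintf("fwbench %s", as.character(utils::packageVersion("fwbench"))),
    sprintf("complexes used: %d", report$n_complexes),
    sprintf("dropped (features only): %s",
            paste(report$dropped_ids$features_only, collapse = " ")),
    sprintf("dropped (scores only): %s",
            paste(report$dropped_ids$scores_only, collapse = " ")),
    sprintf("features after filtering: %s",
            paste(report$feature_names, collapse = " ")),
    sprintf("correlation threshold: %g (%s)", report$threshold, report$method),
    sprintf("lambda grid: %s", paste(signif(report$lambdas, 6), collapse = " ")),
    sprintf("beta_SF penalized: %s", report$penalize_sf))
  if (!is.null(config))
    lines <- c(lines, "", "config:",
               sprintf("  %s = %s", names(config),
                       vapply(config, function(v) paste(format(v), collapse = " "),
                              character(1))))
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
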