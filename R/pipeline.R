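# End-to-end orchestration: configuration handling and the full
# ligands + scores -> benchmark-report pipeline, plus the simulate
# convenience used by the command-line interface.

config_error <- function(...) {
  stop(structure(class = c("fw_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
data_error <- function(...) {
  stop(structure(class = c("fw_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Build a run configuration
#'
#' @param ligands path to the ligand structure file (.smi/.sdf/.mol2).
#' @param scores path to the score table (TSV/CSV: id, pk_ref, SF columns).
#' @param features optional path to a feature-definition TSV; default the
#'   shipped table.
#' @param outdir output directory.
#' @param threshold correlation-filter threshold in (0, 1].
#' @param lambdas optional explicit penalty grid (strictly increasing).
#' @param seed integer seed recorded in the provenance block.
#' @param method `"cosine"` or `"pearson"` feature correlation.
#' @param penalize_sf penalize the scoring-function coefficient? Default TRUE.
#' @param sanitize apply the ligand sanitization rules? Default TRUE.
#' @param negate scoring-function columns to sign-flip at ingestion.
#' @return list of class `fw_config`.
#' @export
run_config <- function(ligands, scores, outdir, features = NULL,
                       threshold = 0.9, lambdas = NULL, seed = 1L,
                       method = "cosine", penalize_sf = TRUE,
                       sanitize = TRUE, negate = character(0)) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    config_error("threshold must be in (0, 1]")
  if (!method %in% c("cosine", "pearson"))
    config_error("method must be 'cosine' or 'pearson'")
  if (!is.null(lambdas) && (any(lambdas < 0) || is.unsorted(lambdas, strictly = TRUE)))
    config_error("lambdas must be strictly increasing and non-negative")
  structure(list(ligands = ligands, scores = scores, outdir = outdir,
                 features = features, threshold = threshold, lambdas = lambdas,
                 seed = as.integer(seed), method = method,
                 penalize_sf = isTRUE(penalize_sf), sanitize = isTRUE(sanitize),
                 negate = negate),
            class = "fw_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognized keys are
#' the arguments of [run_config()]; `lambdas` and `negate` take
#' comma-separated values.
#'
#' @param path configuration file.
#' @param ... overrides applied after the file (CLI flags win).
#' @return `fw_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) config_error("config lines must be 'key = value'")
  vals <- stats::setNames(lapply(kv, function(x) trimws(x[2])),
                          vapply(kv, function(x) trimws(x[1]), character(1)))
  num <- function(v) as.numeric(strsplit(v, ",")[[1]])
  args <- list()
  for (k in names(vals)) {
    v <- vals[[k]]
    args[[k]] <- switch(k,
      threshold = as.numeric(v), seed = as.integer(v),
      lambdas = num(v), negate = trimws(strsplit(v, ",")[[1]]),
      penalize_sf = , sanitize = toupper(v) %in% c("TRUE", "1", "YES"),
      v)
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

#' Run the full benchmark pipeline
#'
#' Loads ligands (logging and excluding parse failures), sanitizes them,
#' counts fragments, joins with the score table, runs
#' [build_report()] and writes every artifact into the configured output
#' directory. Identical configurations produce byte-identical outputs.
#'
#' @param cfg an `fw_config` (see [run_config()] / [read_run_config()]).
#' @return invisibly, the `fw_report`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "fw_config"))
  if (!file.exists(cfg$ligands)) data_error("ligand file not found: ", cfg$ligands)
  if (!file.exists(cfg$scores)) data_error("score file not found: ", cfg$scores)

  ext <- tolower(tools::file_ext(cfg$ligands))
  if (ext %in% c("tsv", "txt")) {
    # precomputed Free-Wilson matrix (e.g. from simulate_inputs())
    fw_log("load", "reading precomputed feature matrix from ", cfg$ligands)
    fm <- read_feature_matrix(cfg$ligands)
    failures <- data.frame(id = character(0), reason = character(0))
  } else {
    fw_log("load", "reading ligands from ", cfg$ligands)
    mols <- load_ligands(cfg$ligands)
    failures <- attr(mols, "failures")
    if (nrow(failures)) {
      for (i in seq_len(nrow(failures)))
        fw_log("load", "EXCLUDED ", failures$id[i], ": ", failures$reason[i])
    }
    if (!length(mols)) data_error("no ligand could be parsed from ", cfg$ligands)
    if (cfg$sanitize) mols <- lapply(mols, sanitize_ligand)

    fds <- if (is.null(cfg$features)) default_features() else read_features(cfg$features)
    fw_log("features", "counting ", nrow(fds), " features in ",
           length(mols), " ligands")
    fm <- build_feature_table(mols, fds)
  }

  st <- tryCatch(read_score_table(cfg$scores, negate = cfg$negate),
                 error = function(e) data_error("score table: ", conditionMessage(e)))
  report <- tryCatch(
    build_report(fm, st, lambdas = cfg$lambdas, threshold = cfg$threshold,
                 method = cfg$method, penalize_sf = cfg$penalize_sf),
    error = function(e) data_error("benchmark: ", conditionMessage(e)))
  fw_log("benchmark", "complexes used: ", report$n_complexes)

  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(fm, file.path(cfg$outdir, "feature_matrix.tsv"))
  if (nrow(failures))
    utils::write.table(failures, file.path(cfg$outdir, "parse_failures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(report, cfg$outdir,
               config = cfg[setdiff(names(cfg), c("lambdas", "outdir"))])
  fw_log("write", "artifacts written to ", cfg$outdir)
  invisible(report)
}

#' Simulate a complete synthetic benchmark input set
#'
#' Writes a feature-matrix TSV and a score table with two synthetic scoring
#' functions -- `SF_good` (a clean linear transform of the truth) and
#' `SF_biased` (the same transform distorted by a feature-specific bias) --
#' so the full pipeline can be exercised with no external data.
#'
#' @param outdir output directory.
#' @param n_ligands number of ligands (default 273, the size of a typical
#'   curated benchmark set after exclusions).
#' @param seed integer seed.
#' @param bias_feature,bias feature distorted in `SF_biased` and the bias in
#'   pK per raw count (default HP1, -0.4).
#' @return invisibly, list with the written file paths.
#' @export
simulate_inputs <- function(outdir, n_ligands = 273L, seed = 1L,
                            bias_feature = "HP1", bias = -0.4) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  specs <- default_feature_specs()
  if (!bias_feature %in% specs$name)
    config_error("bias_feature must be one of: ", paste(specs$name, collapse = ", "))
  fm <- gen_feature_matrix(n_ligands, specs, seed = seed)
  truth_good <- synthetic_truth(seed = seed)
  pk_ref <- gen_affinities(fm, truth_good)
  sf_good <- gen_sf_scores(fm, pk_ref, truth_good)
  truth_bad <- synthetic_truth(seed = seed + 1L,
                               sf_biases = stats::setNames(bias, bias_feature))
  sf_bad <- gen_sf_scores(fm, pk_ref, truth_bad)
  st <- data.frame(id = rownames(fm), pk_ref = as.numeric(pk_ref),
                   SF_good = as.numeric(sf_good), SF_biased = as.numeric(sf_bad),
                   stringsAsFactors = FALSE)
  fm_path <- file.path(outdir, "feature_matrix.tsv")
  st_path <- file.path(outdir, "scores.tsv")
  write_feature_matrix(fm, fm_path)
  write_score_table(st, st_path)
  fw_log("simulate", "wrote ", fm_path, " and ", st_path)
  invisible(list(feature_matrix = fm_path, scores = st_path))
}
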