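#' Pipeline run configuration
#'
#' Composite of the per-stage configurations plus a global seed. Per-stage
#' seeds are derived deterministically from the global seed (stage index
#' times 1000 added), so a stage can be rerun in isolation and still match
#' a full-pipeline run.
#'
#' @param preprocess a [preprocess_config()].
#' @param training a [training_config()]; its own seed field is overridden
#'   by the derived stage seed.
#' @param policy an [impute_policy()].
#' @param n_pcs,n_neighbors,resolution downstream clustering settings.
#' @param algorithms classifier subset for the evaluation stage (`NULL`
#'   skips it).
#' @param seed global seed.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       training = training_config(),
                       policy = impute_policy(),
                       n_pcs = 30L, n_neighbors = 15L, resolution = 0.8,
                       algorithms = c("LR", "RF", "KNN"),
                       seed = 1L) {
  structure(list(preprocess = preprocess, training = training,
                 policy = policy, n_pcs = as.integer(n_pcs),
                 n_neighbors = as.integer(n_neighbors),
                 resolution = resolution, algorithms = algorithms,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Derive a per-stage seed from the global run seed
#'
#' `seed + 1000 * stage_index`, with stages numbered preprocess = 1,
#' train = 2, impute = 3, evaluate = 4, simulate = 5. Documented so a stage
#' rerun in isolation can reproduce its slice of a full pipeline run.
#'
#' @param config a [run_config()].
#' @param stage stage name.
#' @export
stage_seed <- function(config, stage) {
  stages <- c(preprocess = 1L, train = 2L, impute = 3L, evaluate = 4L,
              simulate = 5L)
  config$seed + 1000L * stages[[stage]]
}

#' Serialize a run configuration to a key-value file
#'
#' Flat `key = value` lines (vectors comma-separated), readable back with
#' [read_run_config()].
#'
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  flat <- c(
    min_cells_per_gene = config$preprocess$min_cells_per_gene,
    n_top_genes = config$preprocess$n_top_genes,
    log_threshold = config$preprocess$log_threshold,
    scale = config$preprocess$scale,
    outlier_mads = if (is.null(config$preprocess$outlier_mads)) "none"
                   else config$preprocess$outlier_mads,
    learning_rate = config$training$learning_rate,
    batch_size = config$training$batch_size,
    n_epochs = config$training$n_epochs,
    kl_weight = config$training$kl_weight,
    hidden_dims = paste(config$training$hidden_dims, collapse = ","),
    latent_dim = config$training$latent_dim,
    impute_mode = config$policy$mode,
    sample_latent = config$policy$sample_latent,
    n_pcs = config$n_pcs,
    n_neighbors = config$n_neighbors,
    resolution = config$resolution,
    algorithms = if (is.null(config$algorithms)) "none"
                 else paste(config$algorithms, collapse = ","),
    seed = config$seed)
  writeLines(paste(names(flat), flat, sep = " = "), path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path key-value file path.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  names(vals) <- keys
  num <- function(k, default) if (k %in% keys) as.numeric(vals[[k]]) else default
  run_config(
    preprocess = preprocess_config(
      min_cells_per_gene = num("min_cells_per_gene", 3),
      n_top_genes = num("n_top_genes", 2000),
      log_threshold = num("log_threshold", 100),
      scale = !identical(vals[["scale"]], "FALSE"),
      outlier_mads = if (!"outlier_mads" %in% keys ||
                         vals[["outlier_mads"]] == "none") NULL
                     else as.numeric(vals[["outlier_mads"]])),
    training = training_config(
      learning_rate = num("learning_rate", 0.001),
      batch_size = num("batch_size", 100),
      n_epochs = num("n_epochs", 50),
      kl_weight = num("kl_weight", 1),
      hidden_dims = as.integer(strsplit(vals[["hidden_dims"]], ",")[[1]]),
      latent_dim = num("latent_dim", 32)),
    policy = impute_policy(vals[["impute_mode"]],
                           identical(vals[["sample_latent"]], "TRUE")),
    n_pcs = num("n_pcs", 30), n_neighbors = num("n_neighbors", 15),
    resolution = num("resolution", 0.8),
    algorithms = if (vals[["algorithms"]] == "none") NULL
                 else strsplit(vals[["algorithms"]], ",")[[1]],
    seed = num("seed", 1))
}

#' Run the full imputation pipeline
#'
#' preprocess -> train -> impute -> (optional) evaluate, writing every
#' artifact plus a manifest and the resolved configuration into
#' `out_dir`: the scaled matrix, loss history, imputed matrix (scaled and
#' log layers), and — when labels are given — clustering and classification
#' reports for the input and the imputed matrix side by side.
#'
#' @param input raw-layer [expression_matrix()] or a path readable by
#'   [load_matrix()].
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @param labels optional per-cell labels (vector or file path) enabling
#'   the evaluation stage.
#' @return (invisibly) a list with the in-memory artifacts: `preprocessed`,
#'   `model`, `history`, `imputed`, `imputed_log`, `comparison` (or NULL).
#' @export
run_pipeline <- function(input, out_dir, config = run_config(),
                         labels = NULL) {
  mat <- if (inherits(input, "ExpressionMatrix")) input else load_matrix(input)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- character(0)
  put <- function(name) manifest <<- c(manifest, name)

  write_run_config(config, file.path(out_dir, "config.txt")); put("config.txt")
  if (is.character(labels)) labels <- load_labels(labels, cell_ids(mat))

  pp <- tryCatch(preprocess(mat, config$preprocess),
                 error = function(e) stop("preprocess stage: ",
                                          conditionMessage(e), call. = FALSE))
  save_matrix(pp$matrix, file.path(out_dir, "preprocessed.csv"),
              metadata = TRUE)
  put("preprocessed.csv")

  tc <- config$training
  tc$seed <- stage_seed(config, "train")
  fit <- tryCatch(train_vae(pp$matrix, pp$mask, tc),
                  error = function(e) stop("train stage: ",
                                           conditionMessage(e), call. = FALSE))
  utils::write.table(fit$history, file.path(out_dir, "loss_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  put("loss_history.tsv")

  imputed <- tryCatch(
    impute_matrix(pp$matrix, pp$raw, fit$params, config$policy),
    error = function(e) stop("impute stage: ", conditionMessage(e),
                             call. = FALSE))
  export_imputed(imputed, file.path(out_dir, "imputed.csv"))
  put("imputed.csv")
  imputed_log <- if (config$preprocess$scale)
    unscale_matrix(imputed) else NULL
  if (!is.null(imputed_log)) {
    save_matrix(imputed_log, file.path(out_dir, "imputed_log.csv"),
                metadata = TRUE)
    put("imputed_log.csv")
  }

  comparison <- NULL
  if (!is.null(labels)) {
    labels <- labels[match(cell_ids(pp$matrix), cell_ids(mat))]
    comparison <- tryCatch(
      compare_raw_vs_imputed(pp$matrix, imputed, labels,
                             seed = stage_seed(config, "evaluate"),
                             algorithms = config$algorithms,
                             n_pcs = config$n_pcs,
                             n_neighbors = config$n_neighbors,
                             resolution = config$resolution),
      error = function(e) stop("evaluate stage: ", conditionMessage(e),
                               call. = FALSE))
    utils::write.table(comparison, file.path(out_dir, "evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    put("evaluation.tsv")
  }

  writeLines(manifest, file.path(out_dir, "MANIFEST"))
  invisible(list(preprocessed = pp, model = fit$params,
                 history = fit$history, imputed = imputed,
                 imputed_log = imputed_log, comparison = comparison))
}
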