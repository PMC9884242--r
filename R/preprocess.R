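#' Preprocessing configuration
#'
#' Bundles the tunable knobs of the matrix-level preprocessing chain
#' `filter_genes() -> normalize_library_size() -> log_transform() ->
#' select_top_variance_genes() -> scale_genes()`.
#'
#' @param min_cells_per_gene keep genes detected (nonzero) in at least this
#'   many cells (default 3).
#' @param n_top_genes number of highest-variance genes to retain
#'   (default 2000; a no-op with a warning when the matrix has fewer genes).
#' @param log_threshold the log2 transform fires only when the maximum
#'   normalized value exceeds this (default 100).
#' @param scale whether to run the per-gene scaling step (default TRUE).
#' @param outlier_mads optional outlier-cell pre-filter: drop cells whose
#'   total count deviates from the median by more than this many median
#'   absolute deviations. `NULL` (the default) disables the filter.
#' @return a list of class `PreprocessConfig`.
#' @export
preprocess_config <- function(min_cells_per_gene = 3L,
                              n_top_genes = 2000L,
                              log_threshold = 100,
                              scale = TRUE,
                              outlier_mads = NULL) {
  stopifnot(min_cells_per_gene >= 0, n_top_genes >= 1, log_threshold > 0)
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 n_top_genes = as.integer(n_top_genes),
                 log_threshold = log_threshold,
                 scale = isTRUE(scale),
                 outlier_mads = outlier_mads),
            class = "PreprocessConfig")
}

#' Remove genes detected in too few cells
#'
#' @param mat raw-layer [expression_matrix()].
#' @param min_cells_per_gene minimum number of cells with a nonzero count.
#' @return the matrix restricted to the retained genes, order preserved.
#' @export
filter_genes <- function(mat, min_cells_per_gene = 3L) {
  stop_layer(mat, "raw", "filter_genes")
  v <- expr_values(mat)
  keep <- colSums(v > 0) >= min_cells_per_gene
  if (!any(keep))
    stop("no genes pass the detection filter; lower min_cells_per_gene",
         call. = FALSE)
  expression_matrix(v[, keep, drop = FALSE], cell_ids(mat),
                    gene_ids(mat)[keep], layer = "raw")
}

#' Drop outlier cells by library size
#'
#' Optional pre-filter removing cells whose total count is more than
#' `mads` median absolute deviations from the median total.
#'
#' @param mat raw-layer [expression_matrix()].
#' @param mads MAD multiplier (default 5).
#' @return the filtered matrix; attribute `"dropped_cells"` lists removals.
#' @export
filter_outlier_cells <- function(mat, mads = 5) {
  stop_layer(mat, "raw", "filter_outlier_cells")
  totals <- rowSums(expr_values(mat))
  med <- stats::median(totals)
  sigma <- stats::mad(totals)
  keep <- if (sigma == 0) rep(TRUE, length(totals))
          else abs(totals - med) <= mads * sigma
  out <- expression_matrix(expr_values(mat)[keep, , drop = FALSE],
                           cell_ids(mat)[keep], gene_ids(mat), layer = "raw")
  attr(out, "dropped_cells") <- cell_ids(mat)[!keep]
  out
}

#' Median-scaled library-size normalization
#'
#' Each count is divided by its cell's total and multiplied by the median
#' total across cells, so that every cell's library size equals the pre-op
#' median afterwards.
#'
#' @param mat raw-layer [expression_matrix()]; every cell must have a
#'   positive total count.
#' @return normalized-layer matrix; attribute `"median_total"` records the
#'   scaling target.
#' @export
normalize_library_size <- function(mat) {
  stop_layer(mat, "raw", "normalize_library_size")
  v <- expr_values(mat)
  totals <- rowSums(v)
  if (any(totals == 0))
    stop("cells with zero total count: ",
         paste(utils::head(cell_ids(mat)[totals == 0], 5), collapse = ", "),
         call. = FALSE)
  med <- stats::median(totals)
  out <- set_values(mat, v / totals * med, layer = "normalized")
  attr(out, "median_total") <- med
  out
}

#' Conditional log2 transform
#'
#' When the largest normalized value exceeds `log_threshold`, every entry x
#' becomes log2(1 + x); otherwise values pass through unchanged. The layer
#' becomes `log` either way and the attribute `"log_applied"` records
#' whether the transform fired.
#'
#' @param mat normalized-layer [expression_matrix()], all values >= 0.
#' @param log_threshold trigger threshold on the matrix maximum (default 100).
#' @export
log_transform <- function(mat, log_threshold = 100) {
  stop_layer(mat, "normalized", "log_transform")
  v <- expr_values(mat)
  if (any(v < 0)) stop("log_transform requires non-negative values", call. = FALSE)
  fired <- length(v) > 0 && max(v) > log_threshold
  out <- set_values(mat, if (fired) log2(1 + v) else v, layer = "log")
  attr(out, "log_applied") <- fired
  out
}

#' Retain the highest-variance genes
#'
#' Keeps the `n_top_genes` genes with the largest per-gene sample variance on
#' the current layer, ties broken by original gene order; the relative gene
#' order is preserved. Asking for more genes than exist is a no-op with a
#' warning.
#'
#' @param mat an [expression_matrix()] (any layer).
#' @param n_top_genes number of genes to keep.
#' @export
select_top_variance_genes <- function(mat, n_top_genes = 2000L) {
  stopifnot(n_top_genes >= 1)
  v <- expr_values(mat)
  p <- ncol(v)
  if (n_top_genes >= p) {
    if (n_top_genes > p)
      warning("n_top_genes (", n_top_genes, ") exceeds gene count (", p,
              "); keeping all genes")
    return(mat)
  }
  vars <- apply(v, 2, stats::var)
  # order() is a stable sort, so ties fall back to original column order
  keep <- sort(order(vars, decreasing = TRUE)[seq_len(n_top_genes)])
  out <- expression_matrix(v[, keep, drop = FALSE], cell_ids(mat),
                           gene_ids(mat)[keep], layer = expr_layer(mat))
  out
}

#' Center and scale genes
#'
#' Each gene column is centered to mean zero and divided by its population
#' (n-denominator) standard deviation; constant columns are centered only.
#' The gene means and sds are stored as attributes `"centers"` and
#' `"scales"` so [unscale_matrix()] can map model output back to the log
#' layer.
#'
#' @param mat log-layer [expression_matrix()].
#' @export
scale_genes <- function(mat) {
  stop_layer(mat, "log", "scale_genes")
  v <- expr_values(mat)
  n <- nrow(v)
  centers <- colMeans(v)
  sds <- sqrt(colMeans(sweep(v, 2, centers)^2))  # population sd
  scales <- ifelse(sds == 0, 1, sds)
  out <- set_values(mat, sweep(sweep(v, 2, centers), 2, scales, "/"),
                    layer = "scaled")
  attr(out, "centers") <- centers
  attr(out, "scales") <- scales
  out
}

#' Invert per-gene scaling
#'
#' Maps a matrix on the scaled layer (e.g. a model reconstruction) back to
#' the log layer using the centers and scales recorded by [scale_genes()].
#'
#' @param mat scaled- or imputed-layer [expression_matrix()].
#' @param centers,scales per-gene statistics from [scale_genes()]; taken
#'   from `mat`'s attributes when omitted.
#' @export
unscale_matrix <- function(mat, centers = attr(mat, "centers"),
                           scales = attr(mat, "scales")) {
  if (is.null(centers) || is.null(scales))
    stop("no centers/scales available; pass those recorded by scale_genes()",
         call. = FALSE)
  v <- sweep(sweep(expr_values(mat), 2, scales, "*"), 2, centers, "+")
  set_values(mat, v, layer = "log")
}

#' Build a validity mask
#'
#' Marks which entries of a matrix are valid observations. An entry is
#' invalid (flag `FALSE`) when it is non-finite (NA/NaN/Inf) or equals one
#' of the sentinel values; everything else is valid (`TRUE`). The mask
#' excludes invalid entries from the model's reconstruction loss.
#'
#' @param mat an [expression_matrix()].
#' @param invalid_values numeric vector of sentinel values (default none).
#' @return logical matrix of the same shape.
#' @export
build_mask <- function(mat, invalid_values = numeric(0)) {
  v <- expr_values(mat)
  m <- is.finite(v)
  for (s in invalid_values) m <- m & (v != s)
  m[is.na(m)] <- FALSE
  dimnames(m) <- dimnames(v)
  m
}

#' Run the full preprocessing chain
#'
#' Applies, in order: optional outlier-cell filter, gene detection filter,
#' median-scaled library-size normalization, conditional log2 transform,
#' highest-variance gene selection, and per-gene scaling.
#'
#' @param mat raw-layer [expression_matrix()].
#' @param config a [preprocess_config()].
#' @return a list with elements `matrix` (the scaled matrix ready for the
#'   model), `raw` (raw counts restricted to the same cells and genes — the
#'   dropout-candidacy reference for imputation), `mask` (validity mask of
#'   the scaled matrix), `centers`/`scales` (per-gene statistics),
#'   `median_total` and `log_applied`.
#' @export
preprocess <- function(mat, config = preprocess_config()) {
  stopifnot(inherits(config, "PreprocessConfig"))
  stop_layer(mat, "raw", "preprocess")
  if (!is.null(config$outlier_mads))
    mat <- filter_outlier_cells(mat, config$outlier_mads)
  mat <- filter_genes(mat, config$min_cells_per_gene)
  norm <- normalize_library_size(mat)
  lg <- log_transform(norm, config$log_threshold)
  hvg <- select_top_variance_genes(lg, config$n_top_genes)
  raw_sub <- expression_matrix(
    expr_values(mat)[, gene_ids(hvg), drop = FALSE],
    cell_ids(hvg), gene_ids(hvg), layer = "raw")
  out <- if (config$scale) scale_genes(hvg) else hvg
  list(matrix = out,
       raw = raw_sub,
       mask = build_mask(out),
       centers = attr(out, "centers"),
       scales = attr(out, "scales"),
       median_total = attr(norm, "median_total"),
       log_applied = attr(lg, "log_applied"))
}
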