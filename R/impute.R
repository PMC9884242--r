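#' Imputation policy
#'
#' Controls which entries of the input the trained model is allowed to
#' rewrite. `zeros_only` (the default) treats raw zeros as dropout
#' candidates and passes every observed nonzero through untouched;
#' `full` returns the complete model reconstruction.
#'
#' @param mode `"zeros_only"` or `"full"`.
#' @param sample_latent if `TRUE`, sample the bottleneck code; the default
#'   `FALSE` uses the deterministic code `b = mu` so imputation is exactly
#'   reproducible for a fixed model.
#' @export
impute_policy <- function(mode = c("zeros_only", "full"),
                          sample_latent = FALSE) {
  structure(list(mode = match.arg(mode),
                 sample_latent = isTRUE(sample_latent)),
            class = "ImputePolicy")
}

#' Impute an expression matrix with a trained model
#'
#' Runs each cell through the encoder and decoder (with `eps = 0`, i.e.
#' `b = mu`, unless `policy$sample_latent`) and combines the reconstruction
#' with the input according to the policy: under `zeros_only`, only
#' positions whose raw count is zero take the reconstructed value and all
#' other entries are passed through bit-exactly; under `full` the whole
#' reconstruction is returned.
#'
#' @param mat model-input (scaled-layer) [expression_matrix()].
#' @param raw raw-count [expression_matrix()] on the same cells and genes,
#'   defining dropout candidacy (entries equal to zero). Required for
#'   `zeros_only`.
#' @param model trained [init_model()] parameters.
#' @param policy an [impute_policy()].
#' @return imputed-layer [expression_matrix()]; the `centers`/`scales`
#'   attributes of `mat`, if present, are carried over so the result can be
#'   mapped back to the log layer with [unscale_matrix()].
#' @export
impute_matrix <- function(mat, raw = NULL, model,
                          policy = impute_policy()) {
  x <- expr_values(mat)
  if (ncol(x) != model$n_genes)
    stop(sprintf("matrix has %d genes but the model expects %d",
                 ncol(x), model$n_genes), call. = FALSE)
  enc <- encode(x, model)
  b <- if (policy$sample_latent)
    reparameterize(enc$mu, enc$sigma)
  else enc$mu
  recon <- decode(b, model)$x_hat

  if (policy$mode == "zeros_only") {
    if (is.null(raw))
      stop("zeros_only imputation needs the raw count matrix", call. = FALSE)
    if (!identical(cell_ids(mat), cell_ids(raw)) ||
        !identical(gene_ids(mat), gene_ids(raw)))
      stop("mat and raw must share cell and gene identifiers", call. = FALSE)
    out <- x
    zero <- expr_values(raw) == 0
    out[zero] <- recon[zero]
  } else {
    out <- recon
  }
  res <- expression_matrix(out, cell_ids(mat), gene_ids(mat),
                           layer = "imputed")
  attr(res, "centers") <- attr(mat, "centers")
  attr(res, "scales") <- attr(mat, "scales")
  res
}

#' Write an imputed matrix with metadata
#'
#' Thin wrapper over [save_matrix()] that always writes the `<path>.meta`
#' sidecar recording the layer tag.
#'
#' @inheritParams save_matrix
#' @export
export_imputed <- function(mat, path, format = c("csv", "tsv", "mtx")) {
  save_matrix(mat, path, format = match.arg(format), metadata = TRUE)
}
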