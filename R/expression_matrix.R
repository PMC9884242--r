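#' Expression matrix container
#'
#' A lightweight container for a cells x genes expression matrix. Rows are
#' cells, columns are genes; a `layer` tag records where the matrix sits in
#' the processing chain (`raw` counts, library-size `normalized`, `log`
#' transformed, per-gene `scaled`, or model `imputed`). Operations in the
#' package check the layer tag so the chain cannot be run out of order.
#'
#' @param values numeric matrix, cells in rows, genes in columns. All values
#'   must be finite-or-NA numerics; `raw` additionally requires non-negative
#'   integers.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#'   Defaults to the rownames of `values`.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column. Defaults to the colnames of `values`.
#' @param layer one of `"raw"`, `"normalized"`, `"log"`, `"scaled"`,
#'   `"imputed"`.
#' @return an object of class `ExpressionMatrix`.
#' @examples
#' m <- expression_matrix(matrix(0:5, 2, 3), c("c1", "c2"),
#'                        c("g1", "g2", "g3"), layer = "raw")
#' dim(m)
#' @export
expression_matrix <- function(values,
                              cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              layer = c("raw", "normalized", "log", "scaled",
                                        "imputed")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids))
    cell_ids <- sprintf("cell%d", seq_len(nrow(values)))
  if (is.null(gene_ids))
    gene_ids <- sprintf("gene%d", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) must equal nrow(values)", call. = FALSE)
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) must equal ncol(values)", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  # non-finite entries are permitted (they are flagged by build_mask());
  # layer constraints apply to the finite entries
  fin <- values[is.finite(values)]
  if (layer == "raw") {
    if (any(fin < 0))
      stop("raw counts must be non-negative", call. = FALSE)
    if (any(fin != round(fin)))
      stop("raw counts must be integers", call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, layer = layer), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  zf <- if (length(x$values)) mean(x$values == 0) else NA_real_
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (layer = %s, %.1f%% zeros)\n",
              nrow(x$values), ncol(x$values), x$layer, 100 * zf))
  invisible(x)
}

#' Accessors for ExpressionMatrix components
#'
#' @param x an [expression_matrix()] object.
#' @return `cell_ids()` and `gene_ids()` return character vectors;
#'   `expr_values()` the numeric matrix; `expr_layer()` the layer tag.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' @rdname cell_ids
#' @export
expr_values <- function(x) x$values

#' @rdname cell_ids
#' @export
expr_layer <- function(x) x$layer

# internal: replace values keeping ids, retagging the layer
set_values <- function(x, values, layer = x$layer) {
  expression_matrix(values, cell_ids(x), gene_ids(x), layer = layer)
}

stop_layer <- function(x, expected, op) {
  if (!x$layer %in% expected)
    stop(sprintf("%s expects layer %s but got '%s' (the chain is filter -> normalize -> log -> select -> scale)",
                 op, paste(sQuote(expected), collapse = " or "), x$layer),
         call. = FALSE)
  invisible(x)
}
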