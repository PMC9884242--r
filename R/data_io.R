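#' Read an expression matrix from disk
#'
#' Supports the 10x-style MatrixMarket layout (`matrix.mtx` with `features.tsv`
#' or `genes.tsv` and `barcodes.tsv` sidecars in the same directory, matrix
#' stored genes x cells) and dense CSV/TSV with gene ids in the header row and
#' cell ids in the first column.
#'
#' @param path path to the `.mtx`/`.csv`/`.tsv` file. For `mtx` the sidecar
#'   feature and barcode files must sit alongside it.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`; guessed from the file
#'   extension when omitted.
#' @param orientation `"cells_by_genes"` or `"genes_by_cells"`: how the file
#'   on disk is oriented. Defaults to `genes_by_cells` for mtx (the 10x
#'   convention) and `cells_by_genes` for csv/tsv. The returned matrix always
#'   has cells in rows.
#' @param layer layer tag to stamp on the result (default `"raw"`).
#' @return an [expression_matrix()].
#' @export
load_matrix <- function(path,
                        format = c("guess", "mtx", "csv", "tsv"),
                        orientation = NULL,
                        layer = "raw") {
  format <- match.arg(format)
  if (format == "guess") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension of ", path,
                          call. = FALSE))
  }
  if (!file.exists(path))
    stop("input file does not exist: ", path, call. = FALSE)
  if (is.null(orientation))
    orientation <- if (format == "mtx") "genes_by_cells" else "cells_by_genes"
  orientation <- match.arg(orientation, c("cells_by_genes", "genes_by_cells"))

  if (format == "mtx") {
    dir <- dirname(path)
    feat <- .find_sidecar(dir, c("features.tsv", "genes.tsv"))
    barc <- .find_sidecar(dir, "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    barcodes <- utils::read.table(barc, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (orientation == "genes_by_cells") {
      if (nrow(m) != length(features) || ncol(m) != length(barcodes))
        stop("mtx dimensions do not match sidecar files", call. = FALSE)
      m <- t(m)
      dimnames(m) <- list(barcodes, features)
    } else {
      if (nrow(m) != length(barcodes) || ncol(m) != length(features))
        stop("mtx dimensions do not match sidecar files", call. = FALSE)
      dimnames(m) <- list(barcodes, features)
    }
  } else {
    sep <- if (format == "csv") "," else "\t"
    first <- readLines(path, n = 2)
    if (length(first) <= 1) {          # header-only file: empty matrix
      hdr <- if (length(first)) strsplit(first[1], sep)[[1]][-1] else character(0)
      m <- matrix(0, 0, length(hdr), dimnames = list(character(0), hdr))
    } else {
      tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                               check.names = FALSE, stringsAsFactors = FALSE)
      m <- as.matrix(tab)
    }
    if (orientation == "genes_by_cells") m <- t(m)
  }
  if (layer == "raw" && any(is.finite(m) & m < 0))
    stop("negative entries in ", path, call. = FALSE)
  expression_matrix(m, layer = layer)
}

.find_sidecar <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("missing sidecar file (looked for ",
       paste(names, collapse = ", "), ") in ", dir, call. = FALSE)
}

#' Write an expression matrix to disk
#'
#' Inverse of [load_matrix()]: `mtx` writes a MatrixMarket coordinate file
#' (genes x cells, 10x convention) plus `features.tsv` and `barcodes.tsv`
#' sidecars into the file's directory; `csv`/`tsv` write a dense table with
#' gene ids in the header and cell ids in the first column.
#'
#' @param mat an [expression_matrix()].
#' @param path output file path; parent directory must exist and be writable.
#' @param format `"mtx"`, `"csv"` or `"tsv"`.
#' @param metadata if `TRUE`, also write a `<path>.meta` sidecar recording the
#'   layer tag and dimensions.
#' @export
save_matrix <- function(mat, path, format = c("csv", "tsv", "mtx"),
                        metadata = FALSE) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  v <- expr_values(mat)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(t(v), sparse = TRUE),
                                "generalMatrix"), path)
    utils::write.table(data.frame(gene_ids(mat)),
                       file.path(dir, "features.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(cell_ids(mat)),
                       file.path(dir, "barcodes.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    header <- paste(c("cell_id", gene_ids(mat)), collapse = sep)
    body <- if (nrow(v)) paste(cell_ids(mat),
                               apply(v, 1, paste, collapse = sep),
                               sep = sep) else character(0)
    writeLines(c(header, body), path)
  }
  if (metadata) {
    writeLines(c(paste0("layer\t", expr_layer(mat)),
                 paste0("n_cells\t", nrow(v)),
                 paste0("n_genes\t", ncol(v))),
               paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read per-cell labels aligned to a matrix
#'
#' Accepts either a headerless one-label-per-line file (assumed to be in the
#' same order as `cell_ids`) or a two-column `id<sep>label` table in any
#' order, which is re-aligned by id.
#'
#' @param path label file (tab or comma separated for the two-column form).
#' @param cell_ids cell identifiers the labels must align to.
#' @return factor of length `length(cell_ids)`.
#' @export
load_labels <- function(path, cell_ids) {
  if (!file.exists(path))
    stop("label file does not exist: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sep <- if (any(grepl("\t", lines))) "\t" else if (any(grepl(",", lines))) "," else NULL
  if (!is.null(sep)) {
    parts <- strsplit(lines, sep, fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("two-column label file must have exactly id", sep, "label per line",
           call. = FALSE)
    ids <- vapply(parts, `[`, "", 1L)
    labs <- vapply(parts, `[`, "", 2L)
    if (ids[1] %in% c("cell_id", "id", "barcode")) {   # optional header
      ids <- ids[-1]; labs <- labs[-1]
    }
    missing <- setdiff(cell_ids, ids)
    if (length(missing))
      stop("labels missing for cells: ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
    unknown <- setdiff(ids, cell_ids)
    if (length(unknown))
      stop("label file names unknown cells: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    labs <- labs[match(cell_ids, ids)]
  } else {
    if (length(lines) != length(cell_ids))
      stop(sprintf("label file has %d labels for %d cells",
                   length(lines), length(cell_ids)), call. = FALSE)
    labs <- lines
  }
  factor(labs)
}

#' Write per-cell labels
#'
#' @param labels vector of labels, one per cell.
#' @param path output path.
#' @param cell_ids optional cell ids; when given a two-column table is written.
#' @export
save_labels <- function(labels, path, cell_ids = NULL) {
  if (is.null(cell_ids)) {
    writeLines(as.character(labels), path)
  } else {
    utils::write.table(data.frame(cell_id = cell_ids, label = labels), path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
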