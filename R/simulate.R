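#' Simulation configuration
#'
#' Describes a clustered negative-binomial scRNA-seq count model with
#' per-cell library-size variation and a dropout corruption process, the
#' ground-truth substrate the rest of the package is validated on.
#'
#' @param n_cells,n_genes,n_clusters matrix dimensions and number of cell
#'   populations (`n_clusters <= n_cells`).
#' @param de_fraction fraction of genes differentially expressed in each
#'   cluster (default 0.1; `de_fraction * n_genes` must be >= 1).
#' @param log_fold_change magnitude (log2) of the up/down shift applied to a
#'   cluster's DE genes (default 2, i.e. 4-fold).
#' @param nb_dispersion negative-binomial dispersion phi, so that
#'   `var = mu + phi * mu^2` (default 0.1).
#' @param library_size_sigma log-normal sd of per-cell depth factors
#'   (default 0.3).
#' @param dropout_rate expected fraction of nonzero entries zeroed by the
#'   corruption process (default 0.6).
#' @param dropout_mode `"random"` (each nonzero entry zeroed independently)
#'   or `"expression_dependent"` (low-expression entries zeroed
#'   preferentially).
#' @param mean_expression mean of the log-normal baseline gene-mean profile
#'   (counts; default 2).
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @export
sim_config <- function(n_cells = 600L, n_genes = 300L, n_clusters = 4L,
                       de_fraction = 0.1, log_fold_change = 2,
                       nb_dispersion = 0.1, library_size_sigma = 0.3,
                       dropout_rate = 0.6,
                       dropout_mode = c("random", "expression_dependent"),
                       mean_expression = 2, seed = 1L) {
  dropout_mode <- match.arg(dropout_mode)
  stopifnot(n_cells >= 1, n_genes >= 1, n_clusters >= 1,
            n_clusters <= n_cells,
            de_fraction > 0, de_fraction < 1,
            de_fraction * n_genes >= 1,
            log_fold_change > 0, nb_dispersion > 0,
            library_size_sigma >= 0, dropout_rate >= 0, dropout_rate < 1,
            mean_expression > 0)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 de_fraction = de_fraction, log_fold_change = log_fold_change,
                 nb_dispersion = nb_dispersion,
                 library_size_sigma = library_size_sigma,
                 dropout_rate = dropout_rate, dropout_mode = dropout_mode,
                 mean_expression = mean_expression, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Apply a dropout corruption process
#'
#' Zeroes nonzero entries of a count matrix. In `random` mode each nonzero
#' entry is zeroed independently with probability `rate`. In
#' `expression_dependent` mode the zeroing probability decays with
#' expression as `exp(-lambda * log1p(x))`, with `lambda` solved numerically
#' so the expected overall zeroed fraction of nonzero entries equals
#' `rate` — mimicking the empirical pattern that lowly expressed transcripts
#' drop out more often. True zeros are never touched, so the returned mask
#' cleanly separates false zeros (dropouts) from biological zeros.
#'
#' @param truth non-negative count matrix.
#' @param rate target dropout rate in \[0, 1).
#' @param mode `"random"` or `"expression_dependent"`.
#' @param seed RNG seed.
#' @return list with `corrupted` (matrix) and `dropout_mask` (logical
#'   matrix, `TRUE` where an entry was zeroed).
#' @export
apply_dropout <- function(truth, rate,
                          mode = c("random", "expression_dependent"),
                          seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, rate < 1)
  truth <- as.matrix(truth)
  mask <- matrix(FALSE, nrow(truth), ncol(truth),
                 dimnames = dimnames(truth))
  if (rate > 0) {
    nz <- which(truth > 0)
    if (length(nz)) {
      set.seed(seed)
      p <- if (mode == "random") rate else {
        xs <- log1p(truth[nz])
        lam <- stats::uniroot(function(l) mean(exp(-l * xs)) - rate,
                              c(0, 50), tol = 1e-12)$root
        exp(-lam * xs)
      }
      mask[nz] <- stats::runif(length(nz)) < p
    }
  }
  corrupted <- truth
  corrupted[mask] <- 0
  list(corrupted = corrupted, dropout_mask = mask)
}

#' Simulate clustered scRNA-seq counts with known truth
#'
#' Gene means are drawn from a log-normal baseline profile shared across
#' clusters; each cluster shifts its own random `de_fraction` of genes up or
#' down by `2^log_fold_change`. Counts are negative-binomial around the
#' cluster mean scaled by a log-normal per-cell depth factor, and are then
#' corrupted by [apply_dropout()].
#'
#' @param config a [sim_config()].
#' @return list of class `SimTruth`: `truth` and `corrupted` raw-layer
#'   [expression_matrix()] objects, `dropout_mask` (logical matrix),
#'   `labels` (factor of cluster ids per cell), `de_genes` (list per
#'   cluster of the shifted genes with their signs) and `config`.
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_cells; p <- config$n_genes; k <- config$n_clusters

  base_mean <- stats::rlnorm(p, meanlog = log(config$mean_expression),
                             sdlog = 1)
  n_de <- max(1L, round(config$de_fraction * p))
  labels <- factor(sort(rep_len(seq_len(k), n)))

  cluster_means <- matrix(rep(base_mean, each = k), k, p)
  de_genes <- vector("list", k)
  for (cl in seq_len(k)) {
    genes <- sample.int(p, n_de)
    signs <- sample(c(-1, 1), n_de, replace = TRUE)
    cluster_means[cl, genes] <- cluster_means[cl, genes] *
      2^(signs * config$log_fold_change)
    de_genes[[cl]] <- stats::setNames(signs, genes)
  }

  depth <- stats::rlnorm(n, meanlog = -config$library_size_sigma^2 / 2,
                         sdlog = config$library_size_sigma)
  mu <- cluster_means[as.integer(labels), , drop = FALSE] * depth
  counts <- matrix(stats::rnbinom(n * p, mu = mu,
                                  size = 1 / config$nb_dispersion), n, p)
  dimnames(counts) <- list(paste0("cell", seq_len(n)),
                           paste0("gene", seq_len(p)))

  dp <- apply_dropout(counts, config$dropout_rate, config$dropout_mode,
                      seed = config$seed + 1L)
  structure(list(
    truth = expression_matrix(counts, layer = "raw"),
    corrupted = expression_matrix(dp$corrupted, layer = "raw"),
    dropout_mask = dp$dropout_mask,
    labels = labels,
    de_genes = de_genes,
    config = config), class = "SimTruth")
}

#' Recovery report at dropout positions
#'
#' Compares imputed (and corrupted) values against the truth restricted to
#' the positions the dropout process zeroed. The corrupted values there are
#' all zero, so the corrupted-vs-truth correlation is undefined and is
#' reported as 0 with `corrupted_cor_defined = FALSE`.
#'
#' @param truth,corrupted,imputed matrices of one common shape and on one
#'   common layer (e.g. all on the log layer via [unscale_matrix()]).
#' @param dropout_mask logical matrix from the simulator; must select at
#'   least one position.
#' @return named list: `imputed_cor`, `imputed_rmse`, `corrupted_cor`,
#'   `corrupted_cor_defined`, `corrupted_rmse`, `n_masked`.
#' @export
recovery_report <- function(truth, corrupted, imputed, dropout_mask) {
  g <- function(m) if (inherits(m, "ExpressionMatrix")) expr_values(m) else as.matrix(m)
  truth <- g(truth); corrupted <- g(corrupted); imputed <- g(imputed)
  stopifnot(all(dim(truth) == dim(corrupted)),
            all(dim(truth) == dim(imputed)),
            all(dim(truth) == dim(dropout_mask)))
  idx <- which(dropout_mask)
  if (!length(idx))
    stop("dropout mask selects no positions", call. = FALSE)
  tv <- truth[idx]; cv <- corrupted[idx]; iv <- imputed[idx]
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  cor_def <- stats::sd(cv) > 0 && stats::sd(tv) > 0
  list(imputed_cor = if (stats::sd(iv) > 0 && stats::sd(tv) > 0)
         stats::cor(iv, tv) else 0,
       imputed_rmse = rmse(iv, tv),
       corrupted_cor = if (cor_def) stats::cor(cv, tv) else 0,
       corrupted_cor_defined = cor_def,
       corrupted_rmse = rmse(cv, tv),
       n_masked = length(idx))
}
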