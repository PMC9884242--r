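# Shared fixtures built in code at test time.

random_counts <- function(n, p, seed = 1, lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p)
  expression_matrix(m, layer = "raw")
}

# two well-separated Gaussian blobs in feature space (already "scaled")
two_blob_matrix <- function(n_per = 50, p = 10, sep = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  list(mat = expression_matrix(x, layer = "scaled"),
       labels = rep(c("a", "b"), each = n_per))
}

# the shared training scenario: clustered counts with heavy dropout,
# preprocessed, trained and imputed once per test run
scenario_cache <- new.env(parent = emptyenv())
trained_scenario <- function() {
  if (!is.null(scenario_cache$result)) return(scenario_cache$result)
  sim <- simulate_counts(sim_config(n_cells = 600, n_genes = 300,
                                    n_clusters = 4, dropout_rate = 0.6,
                                    seed = 101))
  pp <- suppressWarnings(preprocess(sim$corrupted,
                                    preprocess_config(n_top_genes = 300)))
  fit <- train_vae(pp$matrix, pp$mask, training_config(seed = 202))
  imputed <- impute_matrix(pp$matrix, pp$raw, fit$params)
  scenario_cache$result <- list(sim = sim, pp = pp, fit = fit,
                                imputed = imputed)
  scenario_cache$result
}

# project a raw count matrix onto the log layer over a given gene set, for
# comparisons in a common space
to_log_layer <- function(raw_mat, genes, log_threshold = 100) {
  sub <- expression_matrix(expr_values(raw_mat)[, genes, drop = FALSE],
                           layer = "raw")
  log_transform(normalize_library_size(sub), log_threshold)
}
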