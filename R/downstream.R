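# Downstream evaluation stages: low-dimensional embedding, graph clustering
# over a PCA/kNN substrate, and a multi-classifier benchmark harness. All
# quantitative metric values are produced by the metrics functions.

#' Embed cells in a low-dimensional space
#'
#' PCA is deterministic up to component sign; the sign of each component is
#' fixed so that its largest-absolute loading is positive. t-SNE and UMAP
#' are stochastic and are seeded; they are intended for visualization only.
#'
#' @param mat [expression_matrix()] on the `scaled` or `imputed` layer, or a
#'   plain matrix.
#' @param method `"pca"`, `"tsne"` or `"umap"`.
#' @param n_components embedding dimension (<= min(n_cells, n_genes) for
#'   PCA).
#' @param seed RNG seed for the stochastic methods.
#' @return numeric matrix n_cells x n_components.
#' @export
embed_cells <- function(mat, method = c("pca", "tsne", "umap"),
                        n_components = 2L, seed = 1L) {
  method <- match.arg(method)
  x <- if (inherits(mat, "ExpressionMatrix")) {
    stop_layer(mat, c("scaled", "imputed", "log"), "embed_cells")
    expr_values(mat)
  } else as.matrix(mat)
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(n_cells, n_genes)", call. = FALSE)
  switch(method,
    pca = {
      pc <- stats::prcomp(x, center = TRUE, scale. = FALSE,
                          rank. = n_components)
      flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
        l <- pc$rotation[, j]
        sign(l[which.max(abs(l))])
      }, 0)
      sweep(pc$x, 2, flip, "*")
    },
    tsne = {
      if (!requireNamespace("Rtsne", quietly = TRUE))
        stop("t-SNE embedding needs the Rtsne package", call. = FALSE)
      set.seed(seed)
      Rtsne::Rtsne(x, dims = n_components,
                   perplexity = min(30, floor((nrow(x) - 1) / 3)),
                   check_duplicates = FALSE)$Y
    },
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("UMAP embedding needs the uwot package", call. = FALSE)
      set.seed(seed)
      uwot::umap(x, n_components = n_components,
                 n_neighbors = min(15, nrow(x) - 1), ret_model = FALSE)
    })
}

#' Choose a PC count by standard-deviation drop-off
#'
#' Elbow heuristic: the smallest number of components after which each
#' additional component explains less than `tol` of the first component's
#' standard deviation.
#'
#' @param mat matrix or [expression_matrix()].
#' @param max_pcs cap on the answer.
#' @param tol relative sd threshold (default 0.05).
#' @export
choose_n_pcs <- function(mat, max_pcs = 50L, tol = 0.05) {
  x <- if (inherits(mat, "ExpressionMatrix")) expr_values(mat) else as.matrix(mat)
  k <- min(max_pcs, dim(x) - 1)
  sd <- stats::prcomp(x, center = TRUE, rank. = min(k))$sdev
  keep <- which(sd / sd[1] >= tol)
  max(2L, max(keep))
}

# symmetric k-nearest-neighbour graph in a score space (Euclidean)
.knn_graph <- function(scores, n_neighbors) {
  n <- nrow(scores)
  if (n_neighbors >= n)
    stop("n_neighbors must be smaller than the number of cells", call. = FALSE)
  d <- as.matrix(stats::dist(scores))
  edges <- lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(n_neighbors + 1)]  # skip self
    cbind(i, nb)
  })
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Cluster cells: PCA, kNN graph, Louvain
#'
#' The four-stage cluster identification procedure: the (already normalized
#' and scaled) matrix is reduced by PCA, a k-nearest-neighbour graph is
#' built in PC space with Euclidean distances, and communities are found by
#' Louvain modularity optimization at the given resolution. Higher
#' resolutions yield more clusters; values between about 0.6 and 1.2 work
#' well on typical data.
#'
#' @param mat [expression_matrix()] on the `scaled` or `imputed` layer, or a
#'   plain matrix.
#' @param n_pcs number of principal components (default 30, capped at the
#'   matrix rank).
#' @param n_neighbors neighbours per cell in the graph (default 15).
#' @param resolution Louvain resolution (default 0.8).
#' @param seed seed for the Louvain optimizer.
#' @return list of class `ClusteringResult`: `labels` (factor), `embedding`
#'   (2-D PCA coordinates for plotting), `pc_scores`, `n_pcs_used`,
#'   `resolution`.
#' @export
cluster_cells <- function(mat, n_pcs = 30L, n_neighbors = 15L,
                          resolution = 0.8, seed = 1L) {
  x <- if (inherits(mat, "ExpressionMatrix")) {
    stop_layer(mat, c("scaled", "imputed", "log"), "cluster_cells")
    expr_values(mat)
  } else as.matrix(mat)
  n_pcs <- min(n_pcs, dim(x) - 1)
  scores <- embed_cells(x, "pca", n_components = n_pcs)
  g <- .knn_graph(scores, n_neighbors)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- factor(igraph::membership(comm))
  structure(list(labels = labels,
                 embedding = scores[, 1:2, drop = FALSE],
                 pc_scores = scores,
                 n_pcs_used = as.integer(n_pcs),
                 resolution = resolution),
            class = "ClusteringResult")
}

#' Evaluate a clustering against reference labels
#'
#' @param result a [cluster_cells()] result.
#' @param truth reference labels (one per cell).
#' @return named numeric: `ari`, `fmi`, `silhouette` (silhouette computed
#'   in the PC space used for clustering), `n_clusters`.
#' @export
evaluate_clustering <- function(result, truth) {
  c(ari = adjusted_rand_index(result$labels, truth),
    fmi = fowlkes_mallows(result$labels, truth),
    silhouette = silhouette_score(result$pc_scores, result$labels),
    n_clusters = length(unique(result$labels)))
}

# ---- classifier benchmark -------------------------------------------------

# stratified split: ceiling(frac * n_k) training per class
.stratified_split <- function(labels, frac = 0.7, seed = 1L) {
  set.seed(seed)
  labels <- as.factor(labels)
  train <- integer(0)
  for (k in levels(labels)) {
    idx <- which(labels == k)
    n_tr <- ceiling(frac * length(idx))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

# per-algorithm fit/predict wrappers; each returns a probability matrix
# (rows = newdata, columns named by class level)
.fit_predict <- function(algo, x_tr, y_tr, x_te, par, seed) {
  lv <- levels(y_tr)
  set.seed(seed)
  prob <- switch(algo,
    LR = {
      if (!requireNamespace("glmnet", quietly = TRUE))
        stop("LR needs glmnet", call. = FALSE)
      fam <- if (length(lv) > 2) "multinomial" else "binomial"
      fit <- glmnet::glmnet(x_tr, y_tr, family = fam, alpha = 0,
                            lambda = par$lambda)
      p <- stats::predict(fit, x_te, type = "response")
      if (fam == "binomial") {
        p <- cbind(1 - p[, 1], p[, 1]); colnames(p) <- lv; p
      } else p[, , 1]
    },
    SVM = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("SVM needs e1071", call. = FALSE)
      fit <- e1071::svm(x_tr, y_tr, kernel = "radial", cost = par$cost,
                        probability = TRUE)
      attr(stats::predict(fit, x_te, probability = TRUE), "probabilities")
    },
    RF = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("RF needs randomForest", call. = FALSE)
      fit <- randomForest::randomForest(x_tr, y_tr, ntree = par$ntree)
      stats::predict(fit, x_te, type = "prob")
    },
    NB = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("NB needs e1071", call. = FALSE)
      fit <- e1071::naiveBayes(x_tr, y_tr, laplace = par$laplace)
      stats::predict(fit, x_te, type = "raw")
    },
    KNN = {
      if (!requireNamespace("caret", quietly = TRUE))
        stop("KNN needs caret", call. = FALSE)
      fit <- caret::knn3(x_tr, y_tr, k = par$k)
      stats::predict(fit, x_te, type = "prob")
    },
    DT = {
      if (!requireNamespace("rpart", quietly = TRUE))
        stop("DT needs rpart", call. = FALSE)
      df <- data.frame(x_tr); df$.y <- y_tr
      fit <- rpart::rpart(.y ~ ., df, method = "class",
                          control = rpart::rpart.control(cp = par$cp))
      stats::predict(fit, data.frame(x_te), type = "prob")
    },
    GB = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("GB needs xgboost", call. = FALSE)
      yk <- as.integer(y_tr) - 1L
      fit <- xgboost::xgboost(data = x_tr, label = yk, nrounds = par$nrounds,
                              max_depth = par$max_depth, eta = 0.3,
                              objective = "multi:softprob",
                              num_class = length(lv), nthread = 1,
                              verbose = 0)
      matrix(stats::predict(fit, x_te), ncol = length(lv), byrow = TRUE,
             dimnames = list(NULL, lv))
    },
    stop("unknown algorithm: ", algo, call. = FALSE))
  prob <- as.matrix(prob)
  prob[, lv, drop = FALSE]
}

# documented hyperparameter grids (small by design)
.algo_grids <- list(
  LR  = list(lambda = c(1e-4, 1e-2, 1)),
  SVM = list(cost = c(0.1, 1, 10)),
  RF  = list(ntree = c(100, 300)),
  NB  = list(laplace = c(0, 1)),
  KNN = list(k = c(3, 5, 11)),
  DT  = list(cp = c(0.01, 0.001)),
  GB  = list(nrounds = 50, max_depth = c(3, 6))
)

.expand_grid <- function(grid) {
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Multi-classifier benchmark
#'
#' Stratified 70/30 split of cells; per algorithm, a small documented
#' hyperparameter grid is searched by stratified cross-validated accuracy
#' on the training 70% (grids: LR ridge penalty over 3 decades, SVM cost
#' \{0.1, 1, 10\}, RF trees \{100, 300\}, NB Laplace \{0, 1\}, KNN k
#' \{3, 5, 11\}, DT complexity \{0.01, 0.001\}, GB depth \{3, 6\} at 50
#' rounds); the winner is refit on the full training set and scored on the
#' held-out 30% with overall accuracy and macro one-vs-rest ROC AUC.
#'
#' @param mat [expression_matrix()] (`scaled` or `imputed`) or plain matrix.
#' @param labels class label per cell; every class needs >= 2 members.
#' @param algorithms subset of `c("LR","SVM","RF","NB","KNN","DT","GB")`.
#' @param seed drives the split, the CV folds and each fit.
#' @param cv_folds folds for the grid search (default 3).
#' @return list of class `ClassificationReport`: `accuracy` and `macro_auc`
#'   (named numerics over algorithms), `best_hyperparameters`,
#'   `split_fractions`, `test_idx`.
#' @export
classify_benchmark <- function(mat, labels,
                               algorithms = c("LR", "SVM", "RF", "NB",
                                              "KNN", "DT", "GB"),
                               seed = 1L, cv_folds = 3L) {
  x <- if (inherits(mat, "ExpressionMatrix")) expr_values(mat) else as.matrix(mat)
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- droplevels(as.factor(labels))
  stopifnot(nrow(x) == length(y))
  if (any(table(y) < 2))
    stop("every class needs at least 2 members for a stratified split",
         call. = FALSE)
  algorithms <- match.arg(algorithms, several.ok = TRUE)

  train <- .stratified_split(y, 0.7, seed)
  test <- setdiff(seq_along(y), train)
  x_tr <- x[train, , drop = FALSE]; y_tr <- droplevels(y[train])
  x_te <- x[test, , drop = FALSE];  y_te <- y[test]

  # stratified CV folds over the training set
  set.seed(seed + 1L)
  fold <- integer(length(y_tr))
  for (k in levels(y_tr)) {
    idx <- sample(which(y_tr == k))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }

  acc <- auc <- stats::setNames(numeric(length(algorithms)), algorithms)
  best <- stats::setNames(vector("list", length(algorithms)), algorithms)
  for (algo in algorithms) {
    grid <- .expand_grid(.algo_grids[[algo]])
    cv_acc <- vapply(grid, function(par) {
      correct <- 0
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        if (length(unique(y_tr[tr])) < length(levels(y_tr))) next
        p <- .fit_predict(algo, x_tr[tr, , drop = FALSE],
                          droplevels(y_tr[tr]),
                          x_tr[!tr, , drop = FALSE], par, seed)
        pred <- colnames(p)[max.col(p, ties.method = "first")]
        correct <- correct + sum(pred == as.character(y_tr[!tr]))
      }
      correct / length(y_tr)
    }, 0)
    best[[algo]] <- grid[[which.max(cv_acc)]]
    p <- .fit_predict(algo, x_tr, y_tr, x_te, best[[algo]], seed)
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    n_correct <- sum(pred == as.character(y_te))
    acc[algo] <- accuracy(TP = n_correct, TN = 0,
                          FP = length(y_te) - n_correct, FN = 0)
    auc[algo] <- roc_auc_ovr(y_te, p)$macro
  }
  structure(list(accuracy = acc, macro_auc = auc,
                 best_hyperparameters = best,
                 split_fractions = c(train = 0.7, test = 0.3),
                 test_idx = test),
            class = "ClassificationReport")
}

#' Side-by-side evaluation of a raw and an imputed matrix
#'
#' Runs [cluster_cells()] + [evaluate_clustering()] and (optionally)
#' [classify_benchmark()] on both matrices with identical settings and
#' seed, and returns a long-format table with one row per
#' (input, metric) pair.
#'
#' @param raw,imputed matrices over the same cells.
#' @param labels reference labels per cell.
#' @param seed common seed.
#' @param algorithms classifier subset; `NULL` skips classification.
#' @param n_pcs,n_neighbors,resolution clustering settings.
#' @return data.frame with columns `input`, `metric`, `value`.
#' @export
compare_raw_vs_imputed <- function(raw, imputed, labels, seed = 1L,
                                   algorithms = c("LR", "RF", "KNN"),
                                   n_pcs = 30L, n_neighbors = 15L,
                                   resolution = 0.8) {
  one <- function(mat, tag) {
    cl <- cluster_cells(mat, n_pcs = n_pcs, n_neighbors = n_neighbors,
                        resolution = resolution, seed = seed)
    m <- evaluate_clustering(cl, labels)
    if (!is.null(algorithms)) {
      rep <- classify_benchmark(mat, labels, algorithms = algorithms,
                                seed = seed)
      m <- c(m,
             stats::setNames(rep$accuracy, paste0("accuracy_", names(rep$accuracy))),
             stats::setNames(rep$macro_auc, paste0("auc_", names(rep$macro_auc))),
             mean_accuracy = mean(rep$accuracy))
    }
    data.frame(input = tag, metric = names(m), value = as.numeric(m),
               row.names = NULL)
  }
  rbind(one(raw, "raw"), one(imputed, "imputed"))
}
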