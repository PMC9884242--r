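# Clustering and classification evaluation metrics, implemented from their
# pair-counting / distance / rank definitions so every reported number has a
# single, auditable source.

# contingency table of two partitions plus the pair counts derived from it
.pair_counts <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  # pairs co-clustered in both / only a / only b / neither
  list(TP = sum_ij, FP = sum_i - sum_ij, FN = sum_j - sum_ij,
       TN = total - sum_i - sum_j + sum_ij, total = total,
       sum_i = sum_i, sum_j = sum_j)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' `ARI = (RI - E[RI]) / (max(RI) - E[RI])` in the Hubert-Arabie form,
#' computed from the contingency table. 1 for identical partitions (up to
#' relabeling), about 0 for independent ones.
#'
#' @param labels_a,labels_b categorical vectors of equal length (>= 2).
#' @return numeric in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  pc <- .pair_counts(labels_a, labels_b)
  expected <- pc$sum_i * pc$sum_j / pc$total
  max_index <- (pc$sum_i + pc$sum_j) / 2
  # degenerate only when both partitions are trivial in the same way (both a
  # single cluster or both all singletons), i.e. identical partitions
  if (max_index == expected) return(1)
  (pc$TP - expected) / (max_index - expected)
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision and recall,
#' `sqrt(TP/(TP+FP) * TP/(TP+FN))`, over pairs of items co-clustered in the
#' two partitions. Two all-singleton partitions are identical, hence 1.
#'
#' @inheritParams adjusted_rand_index
#' @return numeric in \[0, 1\].
#' @export
fowlkes_mallows <- function(labels_a, labels_b) {
  pc <- .pair_counts(labels_a, labels_b)
  if (pc$TP == 0 && pc$FP == 0 && pc$FN == 0) return(1)  # identical singletons
  if (pc$TP + pc$FP == 0 || pc$TP + pc$FN == 0) {
    warning("a partition has no co-clustered pairs; FMI defined as 0")
    return(0)
  }
  sqrt((pc$TP / (pc$TP + pc$FP)) * (pc$TP / (pc$TP + pc$FN)))
}

#' Mean silhouette coefficient
#'
#' For each point, `x` is its mean Euclidean distance to the other members
#' of its own cluster and `y` the minimum over other clusters of the mean
#' distance to that cluster's members; the point's silhouette is
#' `(y - x)/max(x, y)` (0 for singleton clusters by convention) and the
#' score is the mean over points.
#'
#' @param points numeric matrix (n x d), n >= 3.
#' @param labels cluster assignment per row; at least 2 clusters.
#' @return numeric in \[-1, 1\].
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("one label per row required", call. = FALSE)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  cl <- unique(labels)
  if (length(cl) < 2)
    stop("silhouette undefined for a single cluster", call. = FALSE)
  d <- as.matrix(stats::dist(points))
  sizes <- table(labels)
  # mean distance from every point to every cluster, via indicator algebra
  ind <- vapply(cl, function(k) as.numeric(labels == k), numeric(n))
  sums <- d %*% ind                      # n x k total distance to cluster k
  s <- vapply(seq_len(n), function(i) {
    own <- labels[i]
    n_own <- sizes[[own]]
    if (n_own == 1) return(0)
    x <- sums[i, own] / (n_own - 1)
    others <- setdiff(cl, own)
    y <- min(vapply(others, function(k) sums[i, k] / sizes[[k]], 0))
    if (x == 0 && y == 0) 0 else (y - x) / max(x, y)
  }, 0)
  mean(s)
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param TP,TN,FP,FN non-negative counts; their total must be positive.
#' @export
accuracy <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  total <- TP + TN + FP + FN
  if (total == 0) stop("no predictions: accuracy undefined", call. = FALSE)
  (TP + TN) / total
}

# binary AUC by the rank (Mann-Whitney) statistic; ties get midranks
.auc_binary <- function(pos_scores, neg_scores) {
  n_pos <- length(pos_scores); n_neg <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-rest ROC AUC
#'
#' Per class, the area under the ROC curve of that class's score against
#' all other classes, computed by the rank statistic (equivalent to the
#' trapezoid rule with midrank tie handling); plus the unweighted (macro)
#' mean over classes.
#'
#' @param true_labels vector of class labels (n).
#' @param scores numeric matrix n x k of per-class scores, columns named by
#'   class (or in `levels(factor(true_labels))` order when unnamed).
#' @return list with `per_class` (named numeric) and `macro`.
#' @export
roc_auc_ovr <- function(true_labels, scores) {
  true_labels <- as.character(true_labels)
  scores <- as.matrix(scores)
  if (nrow(scores) != length(true_labels))
    stop("scores must have one row per label", call. = FALSE)
  classes <- colnames(scores)
  if (is.null(classes)) {
    classes <- levels(factor(true_labels))
    if (length(classes) != ncol(scores))
      stop("unnamed score columns do not match the observed classes",
           call. = FALSE)
    colnames(scores) <- classes
  }
  aucs <- vapply(classes, function(k) {
    is_pos <- true_labels == k
    if (!any(is_pos) || all(is_pos)) return(NA_real_)
    .auc_binary(scores[is_pos, k], scores[!is_pos, k])
  }, 0)
  if (anyNA(aucs)) {
    warning("classes absent from true_labels excluded from AUC: ",
            paste(classes[is.na(aucs)], collapse = ", "))
    aucs <- aucs[!is.na(aucs)]
  }
  list(per_class = aucs, macro = mean(aucs))
}

#' Write a flat metric report
#'
#' @param metrics named numeric vector or list.
#' @param path output TSV path (name \\t value).
#' @export
write_metric_report <- function(metrics, path) {
  m <- unlist(metrics)
  utils::write.table(data.frame(metric = names(m), value = as.numeric(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
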