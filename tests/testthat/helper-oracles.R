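# Independent brute-force oracles used to validate the metric
# implementations. Each one works directly from the definition by looping
# over all item pairs / points, with no shared code with the package.

oracle_pair_confusion <- function(a, b) {
  n <- length(a)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) tp <- tp + 1
      else if (sa && !sb) fp <- fp + 1
      else if (!sa && sb) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn, total = n * (n - 1) / 2)
}

oracle_ari <- function(a, b) {
  pc <- oracle_pair_confusion(a, b)
  sum_i <- pc$TP + pc$FP   # co-clustered pairs in a
  sum_j <- pc$TP + pc$FN   # co-clustered pairs in b
  expected <- sum_i * sum_j / pc$total
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (pc$TP - expected) / (max_index - expected)
}

oracle_fmi <- function(a, b) {
  pc <- oracle_pair_confusion(a, b)
  if (pc$TP + pc$FP == 0 && pc$FN == 0) return(1)
  if (pc$TP + pc$FP == 0 || pc$TP + pc$FN == 0) return(0)
  sqrt(pc$TP / (pc$TP + pc$FP) * pc$TP / (pc$TP + pc$FN))
}

oracle_silhouette <- function(points, labels) {
  n <- nrow(points)
  labels <- as.character(labels)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (!length(mates)) { s[i] <- 0; next }
    x <- mean(vapply(mates, function(j) d(i, j), 0))
    y <- Inf
    for (k in setdiff(unique(labels), own)) {
      members <- which(labels == k)
      y <- min(y, mean(vapply(members, function(j) d(i, j), 0)))
    }
    s[i] <- if (x == 0 && y == 0) 0 else (y - x) / max(x, y)
  }
  mean(s)
}

# one-vs-rest AUC by exhaustive positive/negative pair counting
oracle_auc_binary <- function(pos, neg) {
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

oracle_auc_ovr_macro <- function(labels, scores) {
  classes <- colnames(scores)
  mean(vapply(classes, function(k) {
    oracle_auc_binary(scores[labels == k, k], scores[labels != k, k])
  }, 0))
}

# Monte-Carlo KL( N(mu, diag(sigma^2)) || N(0, I) ) by E_q[log q - log p]
oracle_kl_mc <- function(mu, sigma, n_samples) {
  d <- length(mu)
  z <- matrix(rnorm(n_samples * d), n_samples, d)
  x <- sweep(sweep(z, 2, sigma, "*"), 2, mu, "+")
  log_q <- rowSums(dnorm(x, rep(mu, each = n_samples),
                         rep(sigma, each = n_samples), log = TRUE))
  log_p <- rowSums(dnorm(x, log = TRUE))
  diff <- log_q - log_p
  list(estimate = mean(diff), se = sd(diff) / sqrt(n_samples))
}
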