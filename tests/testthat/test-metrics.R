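random_partition <- function(n, k) sample.int(k, n, replace = TRUE)

test_that("ARI matches its worked value and the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 2)), 4 / 7)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")

  set.seed(61)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    a <- random_partition(n, sample(2:5, 1))
    b <- random_partition(n, sample(2:5, 1))
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
                 tolerance = 1e-12)
    # symmetry and invariance under label renaming
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
    expect_equal(adjusted_rand_index(a + 10, b), adjusted_rand_index(a, b))
  }
  # cross-check against an independent implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    set.seed(62)
    a <- random_partition(50, 4); b <- random_partition(50, 3)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("FMI matches its worked value and the pair-counting oracle", {
  expect_equal(fowlkes_mallows(c(0, 0, 1, 1), c(0, 0, 1, 2)), sqrt(0.5))
  expect_equal(fowlkes_mallows(c(1, 1, 2), c(7, 7, 8)), 1)
  expect_equal(fowlkes_mallows(1:4, 1:4), 1)   # identical singleton partitions

  set.seed(63)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    a <- random_partition(n, sample(2:5, 1))
    b <- random_partition(n, sample(2:5, 1))
    expect_equal(fowlkes_mallows(a, b), oracle_fmi(a, b), tolerance = 1e-12)
    expect_equal(fowlkes_mallows(a, b), fowlkes_mallows(b, a))
    expect_gte(fowlkes_mallows(a, b), 0)
    expect_lte(fowlkes_mallows(a, b), 1)
  }
})

test_that("silhouette matches hand values and the O(n^2) oracle", {
  # 1-D points {0,1} vs {10,11}: per-point 0.90476, 0.89474, 0.89474, 0.90476
  pts <- matrix(c(0, 1, 10, 11), 4, 1)
  labs <- c("a", "a", "b", "b")
  expect_equal(silhouette_score(pts, labs),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)))
  # coincident clusters far apart: within-distance 0 -> score 1
  tight <- matrix(c(0, 0, 5, 5), 4, 1)
  expect_equal(silhouette_score(tight, labs), 1)
  expect_error(silhouette_score(pts, rep("a", 4)), "single cluster")

  set.seed(64)
  for (i in 1:15) {
    n <- sample(10:40, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    labs <- random_partition(n, sample(2:4, 1))
    if (length(unique(labs)) < 2) next
    expect_equal(silhouette_score(pts, labs), oracle_silhouette(pts, labs),
                 tolerance = 1e-9)
  }
  if (requireNamespace("cluster", quietly = TRUE)) {
    set.seed(65)
    pts <- matrix(rnorm(60), 30, 2)
    labs <- rep(1:3, each = 10)
    sil <- cluster::silhouette(labs, dist(pts))
    expect_equal(silhouette_score(pts, labs), mean(sil[, 3]),
                 tolerance = 1e-9)
  }
})

test_that("accuracy follows the confusion-count formula", {
  expect_equal(accuracy(3, 5, 1, 1), 0.8)
  expect_equal(accuracy(2, 2, 0, 0), 1)
  expect_equal(accuracy(0, 0, 3, 2), 0)
  expect_error(accuracy(0, 0, 0, 0), "undefined")
})

test_that("one-vs-rest AUC matches rank and pair-counting computations", {
  y <- c("a", "a", "b", "b")
  s <- cbind(a = c(0.9, 0.8, 0.1, 0.2), b = c(0.1, 0.2, 0.9, 0.8))
  expect_equal(roc_auc_ovr(y, s)$macro, 1)
  s_anti <- cbind(a = c(0.1, 0.2, 0.9, 0.8), b = c(0.9, 0.8, 0.1, 0.2))
  expect_equal(roc_auc_ovr(y, s_anti)$macro, 0)

  # 8-point binary toy with one tie: count concordant/discordant/tied pairs
  yb <- c(1, 1, 1, 1, 0, 0, 0, 0)
  sc <- c(0.9, 0.7, 0.5, 0.3, 0.8, 0.5, 0.2, 0.1)
  scores <- cbind(`0` = -sc, `1` = sc)
  expect_equal(roc_auc_ovr(yb, scores)$per_class[["1"]],
               oracle_auc_binary(sc[yb == 1], sc[yb == 0]))

  set.seed(66)
  for (i in 1:25) {
    n <- sample(8:50, 1); k <- sample(2:4, 1)
    y <- factor(random_partition(n, k))
    if (length(unique(y)) < 2) next
    s <- matrix(runif(n * length(levels(y))), n,
                dimnames = list(NULL, levels(y)))
    got <- suppressWarnings(roc_auc_ovr(y, s))
    present <- names(got$per_class)
    expect_equal(got$macro,
                 oracle_auc_ovr_macro(as.character(y),
                                      s[, present, drop = FALSE]),
                 tolerance = 1e-9)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(67)
    yb <- rbinom(40, 1, 0.5); sc <- runif(40)
    got <- roc_auc_ovr(yb, cbind(`0` = -sc, `1` = sc))$per_class[["1"]]
    ref <- as.numeric(pROC::auc(pROC::roc(yb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("metric reports round-trip through the flat file format", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metric_report(c(ari = 0.5, fmi = 0.25), f)
  back <- read.delim(f)
  expect_equal(back$metric, c("ari", "fmi"))
  expect_equal(back$value, c(0.5, 0.25))
})
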