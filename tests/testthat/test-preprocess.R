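test_that("filter_genes keeps exactly the genes detected in enough cells", {
  set.seed(11)
  m <- expression_matrix(matrix(rbinom(30 * 50, 1, 0.3), 30, 50),
                         layer = "raw")
  out <- filter_genes(m, 5)
  keep_oracle <- colSums(expr_values(m) > 0) >= 5   # brute-force column scan
  expect_equal(gene_ids(out), gene_ids(m)[keep_oracle])
  expect_equal(expr_values(out), expr_values(m)[, keep_oracle])

  expect_equal(expr_values(filter_genes(m, 0)), expr_values(m))
  z <- expression_matrix(cbind(a = c(0, 0), b = c(1, 2)), layer = "raw")
  expect_equal(gene_ids(filter_genes(z, 1)), "b")
  expect_error(filter_genes(z, 3), "lower min_cells_per_gene")
})

test_that("library-size normalization rescales to the median total", {
  m <- expression_matrix(rbind(c(5, 5), c(10, 20)), layer = "raw")
  out <- normalize_library_size(m)
  # totals {10, 30}, median 20; entry 5 in the total-10 cell -> (5/10)*20
  expect_equal(unname(expr_values(out)[1, 1]), 10)
  expect_equal(unname(rowSums(expr_values(out))), c(20, 20))
  expect_equal(expr_layer(out), "normalized")

  set.seed(2)
  r <- random_counts(25, 40, seed = 2)
  med <- median(rowSums(expr_values(r)))
  nr <- normalize_library_size(r)
  expect_lt(max(abs(rowSums(expr_values(nr)) - med)), 1e-9)

  eq <- expression_matrix(rbind(c(1, 3), c(2, 2)), layer = "raw")
  expect_equal(expr_values(normalize_library_size(eq)), expr_values(eq))

  bad <- expression_matrix(rbind(c(0, 0), c(1, 1)), layer = "raw")
  expect_error(normalize_library_size(bad), "zero total")
})

test_that("log transform fires iff the maximum exceeds the threshold", {
  hot <- expression_matrix(rbind(c(3, 200), c(0, 1)), layer = "normalized")
  out <- log_transform(hot, 100)
  expect_true(attr(out, "log_applied"))
  expect_equal(unname(expr_values(out)[1, 1]), 2)   # log2(1 + 3)
  expect_equal(unname(expr_values(out)[2, 1]), 0)   # log2(1 + 0)

  cold <- expression_matrix(rbind(c(3, 50), c(0, 1)), layer = "normalized")
  out2 <- log_transform(cold, 100)
  expect_false(attr(out2, "log_applied"))
  expect_equal(expr_values(out2), expr_values(cold))
  expect_equal(expr_layer(out2), "log")
})

test_that("highest-variance gene selection matches a brute-force ranking", {
  m <- expression_matrix(cbind(a = c(1, 1, 1), b = c(0, 2, 4), c = c(0, 1, 2)),
                         layer = "log")
  expect_equal(gene_ids(select_top_variance_genes(m, 1)), "b")
  expect_equal(gene_ids(select_top_variance_genes(m, 3)), c("a", "b", "c"))
  expect_warning(out <- select_top_variance_genes(m, 10), "exceeds")
  expect_equal(dim(out), dim(m))

  set.seed(3)
  big <- expression_matrix(matrix(rnorm(40 * 100), 40, 100), layer = "log")
  sel <- select_top_variance_genes(big, 20)
  vars <- apply(expr_values(big), 2, var)
  oracle <- sort(order(vars, decreasing = TRUE)[1:20])
  expect_equal(gene_ids(sel), gene_ids(big)[oracle])
})

test_that("gene scaling yields mean 0 and population sd 1 (or 0)", {
  m <- expression_matrix(cbind(a = c(0, 2), b = c(5, 5)), layer = "log")
  out <- scale_genes(m)
  expect_equal(unname(expr_values(out)[, "a"]), c(-1, 1))  # population sd = 1
  expect_equal(unname(expr_values(out)[, "b"]), c(0, 0))   # constant column

  set.seed(4)
  r <- expression_matrix(matrix(rnorm(30 * 20, sd = 3), 30, 20), layer = "log")
  s <- expr_values(scale_genes(r))
  expect_lt(max(abs(colMeans(s))), 1e-9)
  sds <- sqrt(colMeans(sweep(s, 2, colMeans(s))^2))
  expect_true(all(abs(sds - 1) < 1e-9 | sds == 0))
  # unscale inverts the transform
  back <- unscale_matrix(scale_genes(r))
  expect_lt(max(abs(expr_values(back) - expr_values(r))), 1e-9)
})

test_that("mask flags non-finite entries and sentinels", {
  v <- matrix(c(1, NA, 3, -1, Inf, -1), 2, 3)
  m <- expression_matrix(v, layer = "log")
  expect_true(all(build_mask(expression_matrix(matrix(1, 2, 2), layer = "log"))))
  mk <- build_mask(m)
  expect_equal(sum(!mk), 2)           # NA and Inf
  mk2 <- build_mask(m, invalid_values = -1)
  expect_equal(sum(!mk2), 4)          # plus the two -1 sentinels
  expect_false(mk2[2, 2])
})

test_that("the chain rejects out-of-order layers and is cell-permutation equivariant", {
  r <- random_counts(10, 8, seed = 9)
  expect_error(scale_genes(r), "expects layer")
  expect_error(log_transform(r), "expects layer")
  expect_error(normalize_library_size(normalize_library_size(r)),
               "expects layer")

  perm <- sample(10)
  chain <- function(m) {
    out <- suppressWarnings(preprocess(m, preprocess_config(
      min_cells_per_gene = 1, n_top_genes = 5, log_threshold = 0.1)))
    expr_values(out$matrix)
  }
  permuted <- expression_matrix(expr_values(r)[perm, ],
                                cell_ids(r)[perm], gene_ids(r), layer = "raw")
  expect_equal(unname(chain(permuted)), unname(chain(r)[perm, ]))
})

test_that("outlier-cell filter drops extreme library sizes only when asked", {
  set.seed(7)
  v <- matrix(rpois(20 * 30, 5), 20, 30)
  v[1, ] <- v[1, ] * 100
  m <- expression_matrix(v, layer = "raw")
  kept <- filter_outlier_cells(m, mads = 5)
  expect_equal(attr(kept, "dropped_cells"), cell_ids(m)[1])
  # default pipeline config leaves the filter off
  expect_null(preprocess_config()$outlier_mads)
})
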