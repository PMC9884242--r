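zero_params <- function(p, hidden, latent) {
  params <- init_model(p, hidden, latent)
  wipe <- function(layer) list(W = layer$W * 0, b = layer$b * 0)
  params$encoder <- lapply(params$encoder, wipe)
  params$decoder <- lapply(params$decoder, wipe)
  params$mu_head <- wipe(params$mu_head)
  params$logvar_head <- wipe(params$logvar_head)
  params$out_head <- wipe(params$out_head)
  params
}

test_that("encoder maps zero weights to the standard-normal posterior", {
  p <- zero_params(4, c(3), 2)
  enc <- encode(matrix(rnorm(12), 3, 4), p)
  expect_equal(enc$mu, matrix(0, 3, 2))
  expect_equal(enc$sigma, matrix(1, 3, 2))

  set.seed(1)
  params <- init_model(4, c(3), 2)
  x <- matrix(rnorm(4), 1, 4)
  a <- encode(rbind(x, x), params)
  expect_identical(a$mu[1, ], a$mu[2, ])       # identical inputs, identical stats
  expect_error(encode(matrix(0, 1, 5), params), "expects 4|genes")
})

test_that("encoder and decoder match a hand-propagated forward pass", {
  # 2 genes, one hidden unit pair, 1 latent dim; weights set by hand
  params <- zero_params(2, c(2), 1)
  params$encoder[[1]] <- list(W = rbind(c(1, -1), c(0.5, 2)), b = c(0.1, -0.2))
  params$mu_head <- list(W = cbind(c(1, 1)), b = 0.5)
  params$logvar_head <- list(W = cbind(c(0, 2)), b = 0)
  x <- c(1, 2)
  h <- pmax(c(1 * 1 + 2 * 0.5 + 0.1, 1 * -1 + 2 * 2 - 0.2), 0)  # (2.1, 2.8)
  enc <- encode(x, params)
  expect_equal(as.numeric(enc$mu), sum(h) + 0.5)
  expect_equal(as.numeric(enc$sigma), exp(0.5 * (2 * h[2])))

  dparams <- zero_params(2, c(2), 1)
  dparams$decoder[[1]] <- list(W = matrix(c(2, -3), 1, 2), b = c(0, 1))
  dparams$out_head <- list(W = rbind(c(1, 0), c(1, 1)), b = c(-1, 0))
  hd <- pmax(c(2 * 1.5 + 0, -3 * 1.5 + 1), 0)   # (3, 0)
  expect_equal(as.numeric(decode(1.5, dparams)$x_hat),
               c(hd[1] + hd[2] - 1, hd[2]))
  expect_equal(decode(0, zero_params(2, c(2), 1))$x_hat, matrix(0, 1, 2))
})

test_that("reparameterization is affine in the noise with correct moments", {
  expect_equal(reparameterize(c(1, 2), c(1, 1), c(0, 0)), c(1, 2))
  expect_equal(reparameterize(0.5, 2, 1), 2.5)
  expect_error(reparameterize(0, -1, 0), "strictly positive")

  set.seed(21)
  b <- reparameterize(rep(1, 1e5), rep(2, 1e5))
  expect_lt(abs(mean(b) - 1), 0.02)
  expect_lt(abs(sd(b) - 2), 0.02)

  # affine: b(mu, sigma, e1 + e2) - b(mu, sigma, e2) == sigma * e1
  mu <- rnorm(6); sigma <- rexp(6) + 0.1; e1 <- rnorm(6); e2 <- rnorm(6)
  expect_equal(reparameterize(mu, sigma, e1 + e2) -
                 reparameterize(mu, sigma, e2), sigma * e1)
})

test_that("KL divergence matches the closed form and its Monte-Carlo oracle", {
  expect_equal(kl_divergence(rep(0, 5), rep(1, 5)), 0)
  expect_equal(kl_divergence(1, 1), 0.5)
  expect_error(kl_divergence(0, 0), "strictly positive")

  set.seed(31)
  for (d in c(1, 4, 8)) {
    mu <- rnorm(d); sigma <- rexp(d) + 0.2
    mc <- oracle_kl_mc(mu, sigma, 2e5)
    expect_lt(abs(kl_divergence(mu, sigma) - mc$estimate), 3 * mc$se)
  }
  # non-negativity on random inputs
  for (i in 1:20) {
    mu <- rnorm(3); sigma <- rexp(3) + 0.05
    expect_gte(kl_divergence(mu, sigma), 0)
  }
})

test_that("the composite loss respects the mask and the KL weight", {
  x <- rbind(c(1, 2)); xh <- rbind(c(1, 0))
  mu <- rbind(0); sigma <- rbind(1)
  # matched entry only: generative 0, KL 0 -> total 0
  l <- vae_loss(x, xh, mu, sigma, mask = rbind(c(TRUE, FALSE)), beta = 1)
  expect_equal(l$total, 0)
  expect_equal(l$generative, 0)

  l2 <- vae_loss(x, xh, rbind(1), rbind(1), beta = 0)
  expect_equal(l2$total, l2$generative)              # beta = 0 is pure MSE
  expect_equal(l2$generative, mean((x - xh)^2))
  expect_equal(vae_loss(x, x, mu, sigma)$total, 0)
  expect_error(vae_loss(x, xh, mu, sigma, mask = rbind(c(FALSE, FALSE))),
               "mask")

  # permutation of cells within a batch leaves the loss unchanged
  set.seed(41)
  xb <- matrix(rnorm(20), 5, 4); xhb <- matrix(rnorm(20), 5, 4)
  mub <- matrix(rnorm(10), 5, 2); sgb <- matrix(rexp(10) + 0.1, 5, 2)
  perm <- sample(5)
  expect_equal(vae_loss(xb, xhb, mub, sgb)$total,
               vae_loss(xb[perm, ], xhb[perm, ], mub[perm, ],
                        sgb[perm, ])$total)
})

test_that("a zero-initialised model on a zero observation has zero loss", {
  params <- zero_params(1, c(2), 1)
  x <- matrix(0, 1, 1)
  enc <- encode(x, params)
  xh <- decode(enc$mu, params)$x_hat
  l <- vae_loss(x, xh, enc$mu, enc$sigma, beta = 0)
  expect_equal(l$total, 0)
})

test_that("training is reproducible and autoencodes a tiny noiseless matrix", {
  set.seed(51)
  x <- matrix(rnorm(10 * 5), 10, 5)
  cfg <- training_config(learning_rate = 0.01, batch_size = 10,
                         n_epochs = 500, kl_weight = 0,
                         hidden_dims = 16, latent_dim = 5, seed = 3)
  a <- train_vae(x, config = cfg)
  b <- train_vae(x, config = cfg)
  expect_identical(a$history, b$history)     # bitwise-identical run
  expect_lt(tail(a$history$total, 1), 0.1 * a$history$total[1])

  # masked entries contribute nothing: poisoning them does not change the run
  x2 <- x; x2[1, 1] <- NaN
  mask <- matrix(TRUE, 10, 5); mask[1, 1] <- FALSE
  x3 <- x; x3[1, 1] <- 99
  h2 <- train_vae(x2, mask, cfg)$history
  h3 <- train_vae(x3, mask, cfg)$history
  expect_identical(h2, h3)
})
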