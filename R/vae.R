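#' Training configuration for the variational autoencoder
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size mini-batch size (default 100); the last partial batch of
#'   an epoch is used as-is.
#' @param n_epochs number of passes over the data (default 50).
#' @param kl_weight weight beta on the KL (bottleneck) term of the loss
#'   (default 1).
#' @param hidden_dims encoder hidden-layer widths; the decoder mirrors them
#'   in reverse (default `c(512, 128)`).
#' @param latent_dim dimension of the bottleneck code (default 32).
#' @param seed integer seed controlling weight initialization, mini-batch
#'   shuffling and the reparameterization noise.
#' @return a list of class `TrainingConfig`.
#' @export
training_config <- function(learning_rate = 0.001,
                            batch_size = 100L,
                            n_epochs = 50L,
                            kl_weight = 1,
                            hidden_dims = c(512L, 128L),
                            latent_dim = 32L,
                            seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, n_epochs >= 1,
            kl_weight >= 0, all(hidden_dims >= 1), latent_dim >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 kl_weight = kl_weight,
                 hidden_dims = as.integer(hidden_dims),
                 latent_dim = as.integer(latent_dim),
                 seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Initialize model parameters
#'
#' Dense layers with rectifier activations on the hidden layers and linear
#' mean / log-variance / output heads. Weights are drawn uniformly on
#' +/- 1/sqrt(fan_in) from the current RNG state; biases start at zero.
#'
#' @param n_genes input (and output) dimension.
#' @param hidden_dims encoder hidden widths; decoder mirrors them reversed.
#' @param latent_dim bottleneck dimension.
#' @return a list of class `ModelParams` with fields `encoder` (list of
#'   `W`/`b` pairs), `mu_head`, `logvar_head`, `decoder`, `out_head`,
#'   `hidden_dims`, `latent_dim`, `n_genes`.
#' @export
init_model <- function(n_genes, hidden_dims = c(512L, 128L), latent_dim = 32L) {
  stopifnot(n_genes >= 1, latent_dim >= 1)
  dense <- function(n_in, n_out) {
    r <- 1 / sqrt(n_in)
    list(W = matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out),
         b = rep(0, n_out))
  }
  enc_dims <- c(n_genes, hidden_dims)
  encoder <- lapply(seq_along(hidden_dims),
                    function(i) dense(enc_dims[i], enc_dims[i + 1]))
  dec_hidden <- rev(hidden_dims)
  dec_dims <- c(latent_dim, dec_hidden)
  decoder <- lapply(seq_along(dec_hidden),
                    function(i) dense(dec_dims[i], dec_dims[i + 1]))
  last_enc <- utils::tail(enc_dims, 1)
  last_dec <- utils::tail(dec_dims, 1)
  structure(list(encoder = encoder,
                 mu_head = dense(last_enc, latent_dim),
                 logvar_head = dense(last_enc, latent_dim),
                 decoder = decoder,
                 out_head = dense(last_dec, n_genes),
                 hidden_dims = as.integer(hidden_dims),
                 latent_dim = as.integer(latent_dim),
                 n_genes = as.integer(n_genes)),
            class = "ModelParams")
}

relu <- function(x) pmax(x, 0)

.affine <- function(x, layer) sweep(x %*% layer$W, 2, layer$b, "+")

#' Probabilistic encoder
#'
#' Maps rows of scaled expression to the mean and standard deviation of a
#' diagonal Gaussian over the bottleneck code, with
#' `sigma = exp(logvar / 2) > 0`.
#'
#' @param x numeric matrix (cells x genes) on the model-input layer, or a
#'   single row as a vector.
#' @param params a [init_model()] object.
#' @return list with matrices `mu`, `sigma` and `logvar` (cells x latent),
#'   plus the hidden activations used internally for backpropagation.
#' @export
encode <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != params$n_genes)
    stop(sprintf("encode: input has %d genes but the model expects %d",
                 ncol(x), params$n_genes), call. = FALSE)
  h <- x
  pre <- list(); act <- list(h)
  for (i in seq_along(params$encoder)) {
    a <- .affine(h, params$encoder[[i]])
    h <- relu(a)
    pre[[i]] <- a; act[[i + 1]] <- h
  }
  mu <- .affine(h, params$mu_head)
  logvar <- .affine(h, params$logvar_head)
  list(mu = mu, sigma = exp(0.5 * logvar), logvar = logvar,
       .pre = pre, .act = act)
}

#' Reparameterized bottleneck sample
#'
#' `b = mu + sigma * eps` elementwise, with `eps` standard-normal noise, so
#' randomness enters only through `eps` and gradients flow through `mu` and
#' `sigma`.
#'
#' @param mu,sigma mean and standard-deviation vectors or matrices of equal
#'   shape; `sigma` must be strictly positive.
#' @param eps noise of the same shape; drawn from the current RNG when
#'   omitted.
#' @export
reparameterize <- function(mu, sigma, eps = NULL) {
  if (length(mu) != length(sigma))
    stop("mu and sigma must have equal length", call. = FALSE)
  if (any(sigma <= 0))
    stop("sigma must be strictly positive", call. = FALSE)
  if (is.null(eps)) {
    eps <- stats::rnorm(length(mu))
    if (!is.null(dim(mu))) dim(eps) <- dim(mu)
  }
  if (length(eps) != length(mu))
    stop("eps must match mu in length", call. = FALSE)
  mu + sigma * eps
}

#' Probabilistic decoder
#'
#' Maps bottleneck codes back to expression space; hidden layers are
#' rectified, the output head is linear (unbounded, on the scaled layer).
#'
#' @param b codes (cells x latent), or a single code as a vector.
#' @param params a [init_model()] object.
#' @return list with `x_hat` (cells x genes) and internal activations.
#' @export
decode <- function(b, params) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (ncol(b) != params$latent_dim)
    stop(sprintf("decode: code has dim %d but the model expects %d",
                 ncol(b), params$latent_dim), call. = FALSE)
  h <- b
  pre <- list(); act <- list(h)
  for (i in seq_along(params$decoder)) {
    a <- .affine(h, params$decoder[[i]])
    h <- relu(a)
    pre[[i]] <- a; act[[i + 1]] <- h
  }
  list(x_hat = .affine(h, params$out_head), .pre = pre, .act = act)
}

#' KL divergence from a diagonal Gaussian to the standard normal
#'
#' Closed form `0.5 * sum_d (mu_d^2 + sigma_d^2 - 1 - 2 log sigma_d)`,
#' non-negative, zero iff `mu = 0, sigma = 1`.
#'
#' @param mu,sigma mean and standard-deviation vectors (one cell), or
#'   matrices (cells x latent) for a per-cell vector of divergences.
#' @return scalar for vector input, per-row vector for matrix input.
#' @export
kl_divergence <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive", call. = FALSE)
  term <- mu^2 + sigma^2 - 1 - 2 * log(sigma)
  if (is.null(dim(mu))) 0.5 * sum(term) else 0.5 * rowSums(term)
}

#' Composite training loss
#'
#' `total = generative + beta * bottleneck`, where the generative term is the
#' mean squared error over mask-valid entries and the bottleneck term is the
#' mean per-cell KL divergence. Masked-out entries contribute nothing.
#'
#' @param x,x_hat observed batch and reconstruction (cells x genes).
#' @param mu,sigma encoder outputs for the batch.
#' @param mask logical matrix, `TRUE` = include in the generative term.
#' @param beta KL weight.
#' @return list with `total`, `generative`, `bottleneck`.
#' @export
vae_loss <- function(x, x_hat, mu, sigma, mask = NULL, beta = 1) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  stopifnot(all(dim(x) == dim(x_hat)), all(dim(x) == dim(mask)))
  n_valid <- sum(mask)
  if (n_valid == 0)
    stop("loss undefined: mask excludes every entry in the batch", call. = FALSE)
  gen <- sum(((x - x_hat)^2)[mask]) / n_valid
  bot <- mean(kl_divergence(mu, sigma))
  list(total = gen + beta * bot, generative = gen, bottleneck = bot)
}

# One forward + backward pass on a batch; returns loss components and
# gradients in the same nesting as params. Analytic gradients:
#   d generative / d x_hat = 2 * mask * (x_hat - x) / n_valid
#   d (beta * mean KL) / d mu      = beta * mu / B
#   d (beta * mean KL) / d logvar  = beta * (exp(logvar) - 1) / (2 B)
#   z = mu + exp(logvar/2) * eps  =>  dz/dlogvar = z_noise/2 where
#   z_noise = sigma * eps
.vae_step <- function(x, mask, params, eps, beta) {
  B <- nrow(x)
  enc <- encode(x, params)
  z_noise <- enc$sigma * eps
  z <- enc$mu + z_noise
  dec <- decode(z, params)
  x_hat <- dec$x_hat

  n_valid <- sum(mask)
  if (n_valid == 0)
    stop("all-false mask in a batch: loss undefined", call. = FALSE)
  resid <- (x_hat - x) * mask
  gen <- sum(resid^2) / n_valid
  kl_cell <- 0.5 * rowSums(enc$mu^2 + enc$sigma^2 - 1 - enc$logvar)
  bot <- sum(kl_cell) / B
  total <- gen + beta * bot

  grads <- list(encoder = vector("list", length(params$encoder)),
                decoder = vector("list", length(params$decoder)))

  # decoder backward
  d_a <- 2 * resid / n_valid                     # d gen / d out-head preact
  h_last <- dec$.act[[length(dec$.act)]]
  grads$out_head <- list(W = crossprod(h_last, d_a), b = colSums(d_a))
  d_h <- tcrossprod(d_a, params$out_head$W)
  for (i in rev(seq_along(params$decoder))) {
    d_a <- d_h * (dec$.pre[[i]] > 0)
    grads$decoder[[i]] <- list(W = crossprod(dec$.act[[i]], d_a),
                               b = colSums(d_a))
    d_h <- tcrossprod(d_a, params$decoder[[i]]$W)
  }
  d_z <- d_h

  # latent heads
  d_mu <- d_z + beta * enc$mu / B
  d_logvar <- d_z * (z_noise / 2) + beta * (enc$sigma^2 - 1) / (2 * B)
  h_enc <- enc$.act[[length(enc$.act)]]
  grads$mu_head <- list(W = crossprod(h_enc, d_mu), b = colSums(d_mu))
  grads$logvar_head <- list(W = crossprod(h_enc, d_logvar),
                            b = colSums(d_logvar))

  # encoder backward
  d_h <- tcrossprod(d_mu, params$mu_head$W) +
         tcrossprod(d_logvar, params$logvar_head$W)
  for (i in rev(seq_along(params$encoder))) {
    d_a <- d_h * (enc$.pre[[i]] > 0)
    grads$encoder[[i]] <- list(W = crossprod(enc$.act[[i]], d_a),
                               b = colSums(d_a))
    d_h <- tcrossprod(d_a, params$encoder[[i]]$W)
  }

  list(loss = list(total = total, generative = gen, bottleneck = bot),
       grads = grads)
}

# flatten/apply helpers: walk params and grads in lockstep
.walk_update <- function(params, grads, state, f) {
  upd <- function(p, g, s) {
    if (!is.null(p$W) && is.matrix(p$W)) return(f(p, g, s))
    out_p <- p; out_s <- s
    for (nm in names(p)) {
      if (is.list(p[[nm]])) {
        r <- upd(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
    }
    list(p = out_p, s = out_s)
  }
  upd(params, grads, state)
}

#' Train the variational autoencoder
#'
#' Minimizes the composite loss (masked reconstruction MSE plus
#' beta-weighted KL divergence — the negative evidence lower bound) by Adam
#' over shuffled mini-batches. Weight initialization, batch order and the
#' reparameterization noise are all driven by `config$seed`, so a run is
#' exactly reproducible.
#'
#' @param mat scaled-layer [expression_matrix()] (cells x genes), or a plain
#'   numeric matrix.
#' @param mask logical validity mask of the same shape (default: all valid).
#' @param config a [training_config()].
#' @param verbose print per-epoch losses.
#' @return list with `params` (trained [init_model()] weights) and `history`
#'   (data.frame with one `total`/`generative`/`bottleneck` row per epoch,
#'   averaged over that epoch's batches).
#' @export
train_vae <- function(mat, mask = NULL, config = training_config(),
                      verbose = FALSE) {
  x <- if (inherits(mat, "ExpressionMatrix")) {
    stop_layer(mat, c("scaled", "log"), "train_vae")
    expr_values(mat)
  } else as.matrix(mat)
  n <- nrow(x); p <- ncol(x)
  if (is.null(mask)) mask <- matrix(TRUE, n, p)
  stopifnot(all(dim(mask) == dim(x)))
  mask <- mask & is.finite(x)
  x[!mask] <- 0  # masked entries never touch the loss; zero keeps arithmetic finite
  mode(mask) <- "double"

  set.seed(config$seed)
  params <- init_model(p, config$hidden_dims, config$latent_dim)

  adam <- list(t = 0, b1 = 0.9, b2 = 0.999, eps = 1e-8,
               lr = config$learning_rate)
  zero_like <- function(p) {
    if (!is.null(p$W) && is.matrix(p$W))
      return(list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
    out <- list()
    for (nm in names(p)) if (is.list(p[[nm]])) out[[nm]] <- zero_like(p[[nm]])
    out
  }
  state <- zero_like(params)

  history <- data.frame(epoch = integer(), total = numeric(),
                        generative = numeric(), bottleneck = numeric())
  batch_size <- min(config$batch_size, n)

  for (epoch in seq_len(config$n_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    ep <- c(total = 0, generative = 0, bottleneck = 0)
    for (s in starts) {
      rows <- idx[s:min(s + batch_size - 1, n)]
      xb <- x[rows, , drop = FALSE]
      mb <- mask[rows, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(rows) * config$latent_dim),
                    length(rows), config$latent_dim)
      step <- .vae_step(xb, mb, params, eps, config$kl_weight)
      if (!is.finite(step$loss$total))
        stop(sprintf("non-finite loss at epoch %d, batch starting at %d",
                     epoch, s), call. = FALSE)
      adam$t <- adam$t + 1
      corr1 <- 1 - adam$b1^adam$t
      corr2 <- 1 - adam$b2^adam$t
      res <- .walk_update(params, step$grads, state, function(pl, gl, sl) {
        sl$mW <- adam$b1 * sl$mW + (1 - adam$b1) * gl$W
        sl$vW <- adam$b2 * sl$vW + (1 - adam$b2) * gl$W^2
        sl$mb <- adam$b1 * sl$mb + (1 - adam$b1) * gl$b
        sl$vb <- adam$b2 * sl$vb + (1 - adam$b2) * gl$b^2
        pl$W <- pl$W - adam$lr * (sl$mW / corr1) / (sqrt(sl$vW / corr2) + adam$eps)
        pl$b <- pl$b - adam$lr * (sl$mb / corr1) / (sqrt(sl$vb / corr2) + adam$eps)
        list(p = pl, s = sl)
      })
      params <- res$p; state <- res$s
      w <- length(rows) / n
      ep <- ep + w * c(step$loss$total, step$loss$generative,
                       step$loss$bottleneck)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, total = ep[["total"]],
                                generative = ep[["generative"]],
                                bottleneck = ep[["bottleneck"]]))
    if (verbose)
      message(sprintf("epoch %3d  total %.5f  generative %.5f  kl %.5f",
                      epoch, ep[["total"]], ep[["generative"]],
                      ep[["bottleneck"]]))
  }
  class(params) <- "ModelParams"
  list(params = params, history = history)
}
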