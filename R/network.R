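# Multitask 1D convolutional network: input batch normalization, a stack of
# (valid convolution -> batch normalization -> ReLU) blocks, and a final 1x1
# convolution with two output channels (log-TMRCA and breakpoint logit).
# Forward and backward passes are written against an explicit cache so the
# same machinery serves training, saliency analysis and gradient checking.
#
# Data layout: arrays of dim c(channels, length, batch). A channels x length
# matrix is accepted wherever a single example is meant.

#' Network configuration
#'
#' Valid (unpadded) convolutions consume exactly the window context: the
#' receptive field is `1 + sum(kernels - 1)` and the context per side must
#' equal half of `sum(kernels - 1)`, so that an input of `L1 = L + 2*context`
#' sites yields predictions for the `L` central sites.
#'
#' @param L central window length in sites.
#' @param kernels integer kernel size per convolution block; `sum(kernels-1)`
#'   must be even.
#' @param channels output channels per block.
#' @param in_channels input feature channels (6 for the XOR/AND
#'   representation, or the raw-haplotype channel count).
#' @return An object of class `model_config`.
#' @export
model_config <- function(L = 512L, kernels = c(17L, 9L, 5L),
                         channels = c(8L, 8L, 8L), in_channels = 6L) {
  stopifnot(length(kernels) == length(channels), all(kernels >= 1),
            all(channels >= 1), L >= 1, in_channels >= 1)
  span <- sum(kernels - 1L)
  if (span %% 2L != 0L)
    stop("sum(kernels - 1) must be even so context is integral")
  rf <- receptive_field(kernels)
  L1 <- as.integer(L + span)
  if (rf > L1)
    stop_tmrcanet(sprintf("receptive field (%d) exceeds input length L1 (%d)",
                          rf, L1), "tmrcanet_config_error")
  structure(list(L = as.integer(L), kernels = as.integer(kernels),
                 channels = as.integer(channels),
                 in_channels = as.integer(in_channels),
                 n_blocks = length(kernels),
                 context = as.integer(span %/% 2L), L1 = L1),
            class = "model_config")
}

#' Built-in model presets
#'
#' `"desk"` is a small CPU-friendly model (3 blocks, ~2K parameters,
#' receptive field 29). `"full"` matches the published scale constraints:
#' 5 convolution blocks, 8 channels out of the first block, a large
#' receptive field, and approximately 130K trainable parameters.
#'
#' @param name `"desk"` or `"full"`.
#' @param L central window length.
#' @param in_channels input channel count.
#' @return A [model_config()].
#' @export
model_preset <- function(name = c("desk", "full"), L = 512L, in_channels = 6L) {
  name <- match.arg(name)
  switch(name,
    desk = model_config(L, kernels = c(17L, 9L, 5L), channels = c(8L, 8L, 8L),
                        in_channels = in_channels),
    full = model_config(L, kernels = c(65L, 33L, 17L, 9L, 5L),
                        channels = c(8L, 32L, 64L, 80L, 96L),
                        in_channels = in_channels))
}

#' Receptive field of a stride-1, dilation-1 convolution stack
#'
#' @param kernels integer kernel sizes, or a [model_config()].
#' @return Receptive field in sites: `1 + sum(kernels - 1)`.
#' @export
receptive_field <- function(kernels) {
  if (inherits(kernels, "model_config")) kernels <- kernels$kernels
  as.integer(1L + sum(kernels - 1L))
}

#' Window spec implied by a model configuration
#' @param config a [model_config()].
#' @export
model_window <- function(config) window_spec(config$L, config$context)

#' Build (initialize) a model
#'
#' He-normal initialization for convolution weights; batch-norm scale 1,
#' shift 0; running statistics start at mean 0, variance 1; the two
#' homoscedastic-uncertainty log-variances start at 0.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `tmrca_model` with elements `config`,
#'   `params` (flat named list of trainable arrays) and `running`
#'   (batch-norm running statistics).
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  params <- list()
  running <- list()
  params[["bn0.gamma"]] <- rep(1, config$in_channels)
  params[["bn0.beta"]] <- rep(0, config$in_channels)
  running[["bn0"]] <- list(mean = rep(0, config$in_channels),
                           var = rep(1, config$in_channels))
  cin <- config$in_channels
  for (i in seq_len(config$n_blocks)) {
    k <- config$kernels[i]; cout <- config$channels[i]
    sd <- sqrt(2 / (k * cin))
    params[[sprintf("b%d.W", i)]] <-
      matrix(stats::rnorm(cout * cin * k, 0, sd), nrow = cout)
    params[[sprintf("b%d.b", i)]] <- rep(0, cout)
    params[[sprintf("b%d.gamma", i)]] <- rep(1, cout)
    params[[sprintf("b%d.beta", i)]] <- rep(0, cout)
    running[[sprintf("b%d", i)]] <- list(mean = rep(0, cout), var = rep(1, cout))
    cin <- cout
  }
  params[["head.W"]] <- matrix(stats::rnorm(2 * cin, 0, sqrt(1 / cin)), nrow = 2)
  params[["head.b"]] <- rep(0, 2)
  params[["s_reg"]] <- 0
  params[["s_cls"]] <- 0
  structure(list(config = config, params = params, running = running),
            class = "tmrca_model")
}

#' Number of trainable network parameters
#'
#' Counts convolution weights and biases and batch-norm scale/shift pairs
#' (the two task-uncertainty scalars belong to the loss, not the network).
#'
#' @param model a `tmrca_model`.
#' @export
n_parameters <- function(model) {
  nm <- setdiff(names(model$params), c("s_reg", "s_cls"))
  sum(vapply(model$params[nm], length, 0L))
}

#' @exportS3Method base::print
print.tmrca_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("tmrca_model: %d blocks (kernels %s; channels %s), %d input channels\n",
              cfg$n_blocks, paste(cfg$kernels, collapse = "/"),
              paste(cfg$channels, collapse = "/"), cfg$in_channels))
  cat(sprintf("  L = %d, context = %d, receptive field = %d, %d trainable parameters\n",
              cfg$L, cfg$context, receptive_field(cfg), n_parameters(x)))
  invisible(x)
}

# ---- layer primitives ------------------------------------------------------

as_batch <- function(x, in_channels) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[1L] != in_channels)
    stop(sprintf("input has %d channels; model expects %d", dim(x)[1L], in_channels))
  x
}

conv_fw <- function(x, W, b) {
  d <- dim(x); C <- d[1L]; L <- d[2L]; N <- d[3L]
  k <- ncol(W) %/% C
  Lout <- L - k + 1L
  Xc <- matrix(0, C * k, Lout * N)
  for (t in seq_len(k))
    Xc[((t - 1L) * C + 1L):(t * C), ] <-
      matrix(x[, t:(t + Lout - 1L), , drop = FALSE], nrow = C)
  y <- W %*% Xc + b
  list(y = array(y, c(nrow(W), Lout, N)), Xc = Xc, dims = d, k = k)
}

conv_bw <- function(dy, W, cache) {
  d <- cache$dims; C <- d[1L]; N <- d[3L]; k <- cache$k
  Lout <- d[2L] - k + 1L
  dym <- matrix(dy, nrow = nrow(W))
  dW <- dym %*% t(cache$Xc)
  db <- rowSums(dym)
  dXc <- crossprod(W, dym)
  dx <- array(0, d)
  for (t in seq_len(k))
    dx[, t:(t + Lout - 1L), ] <- dx[, t:(t + Lout - 1L), , drop = FALSE] +
      array(dXc[((t - 1L) * C + 1L):(t * C), ], c(C, Lout, N))
  list(dx = dx, dW = dW, db = db)
}

bn_fw <- function(x, gamma, beta, run, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1L])
  if (training) {
    m <- rowMeans(xm)
    v <- rowMeans(xm * xm) - m * m
    run$mean <- (1 - momentum) * run$mean + momentum * m
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    m <- run$mean
    v <- run$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - m) * invstd
  y <- gamma * xhat + beta
  list(y = array(y, d), xhat = xhat, invstd = invstd, run = run,
       training = training, dims = d)
}

bn_bw <- function(dy, gamma, cache) {
  d <- cache$dims
  dym <- matrix(dy, nrow = d[1L])
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  dxhat <- gamma * dym
  if (cache$training) {
    dx <- cache$invstd *
      (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dx <- cache$invstd * dxhat
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta,
       dxhat = array(dxhat, d))
}

# ---- forward / backward ----------------------------------------------------

#' Forward pass
#'
#' Maps a feature window (channels x `L1`, or an array with a batch
#' dimension) to per-site log-TMRCA and breakpoint logits over the `L`
#' central sites. In evaluation mode (`training = FALSE`, the default) batch
#' normalization uses running statistics and the pass is deterministic.
#'
#' @param model a `tmrca_model`.
#' @param x features: `in_channels` x `L1` matrix or
#'   `in_channels` x `L1` x `N` array.
#' @param training use batch statistics and update running statistics.
#' @param keep_cache retain intermediates for [backward()].
#' @return A list with `log_tmrca` and `breakpoint_logit` (`L` x `N`
#'   matrices), the updated `running` statistics, and (optionally) `cache`.
#' @export
forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  x <- as_batch(x, cfg$in_channels)
  if (dim(x)[2L] != cfg$L1)
    stop(sprintf("input length %d != L1 = %d", dim(x)[2L], cfg$L1))
  if (anyNA(x)) stop_tmrcanet("NaN/NA in network input", "tmrcanet_input_error")
  p <- model$params
  running <- model$running
  cache <- list()
  bn0 <- bn_fw(x, p[["bn0.gamma"]], p[["bn0.beta"]], running[["bn0"]], training)
  running[["bn0"]] <- bn0$run
  cache$bn0 <- bn0
  h <- bn0$y
  for (i in seq_len(cfg$n_blocks)) {
    cv <- conv_fw(h, p[[sprintf("b%d.W", i)]], p[[sprintf("b%d.b", i)]])
    bn <- bn_fw(cv$y, p[[sprintf("b%d.gamma", i)]], p[[sprintf("b%d.beta", i)]],
                running[[sprintf("b%d", i)]], training)
    running[[sprintf("b%d", i)]] <- bn$run
    mask <- bn$y > 0
    h <- bn$y * mask
    cache[[sprintf("b%d", i)]] <- list(conv = cv, bn = bn, mask = mask)
  }
  hd <- conv_fw(h, p[["head.W"]], p[["head.b"]])
  cache$head <- hd
  out <- hd$y                         # 2 x L x N
  list(log_tmrca = matrix(out[1L, , ], nrow = dim(out)[2L]),
       breakpoint_logit = matrix(out[2L, , ], nrow = dim(out)[2L]),
       running = running,
       cache = if (keep_cache) cache else NULL)
}

#' Backward pass
#'
#' Backpropagates output gradients through the network, returning parameter
#' gradients plus the gradient with respect to the normalized input (the
#' activations after the leading batch-norm layer, used by saliency
#' analysis) and with respect to the raw input.
#'
#' @param model a `tmrca_model`.
#' @param fw result of [forward()] with `keep_cache = TRUE`.
#' @param d_log_tmrca,d_breakpoint_logit `L` x `N` gradient matrices.
#' @return List with `grads` (named like `model$params`), `d_normalized_input`
#'   and `d_input` arrays, and `normalized_input`.
#' @export
backward <- function(model, fw, d_log_tmrca, d_breakpoint_logit) {
  cfg <- model$config
  cache <- fw$cache
  if (is.null(cache)) stop("forward() must be called with keep_cache = TRUE")
  p <- model$params
  grads <- list()
  dims_out <- dim(cache$head$y)
  dout <- array(0, dims_out)
  dout[1L, , ] <- as.numeric(d_log_tmrca)
  dout[2L, , ] <- as.numeric(d_breakpoint_logit)
  hb <- conv_bw(dout, p[["head.W"]], cache$head)
  grads[["head.W"]] <- hb$dW
  grads[["head.b"]] <- hb$db
  dh <- hb$dx
  for (i in rev(seq_len(cfg$n_blocks))) {
    blk <- cache[[sprintf("b%d", i)]]
    dh <- dh * blk$mask
    bnb <- bn_bw(dh, p[[sprintf("b%d.gamma", i)]], blk$bn)
    grads[[sprintf("b%d.gamma", i)]] <- bnb$dgamma
    grads[[sprintf("b%d.beta", i)]] <- bnb$dbeta
    cvb <- conv_bw(bnb$dx, p[[sprintf("b%d.W", i)]], blk$conv)
    grads[[sprintf("b%d.W", i)]] <- cvb$dW
    grads[[sprintf("b%d.b", i)]] <- cvb$db
    dh <- cvb$dx
  }
  bn0b <- bn_bw(dh, p[["bn0.gamma"]], cache$bn0)
  grads[["bn0.gamma"]] <- bn0b$dgamma
  grads[["bn0.beta"]] <- bn0b$dbeta
  list(grads = grads,
       d_normalized_input = array(bn0b$dxhat, cache$bn0$dims),
       d_input = bn0b$dx,
       normalized_input = array(cache$bn0$xhat, cache$bn0$dims))
}

# activations after block `i` (conv + bn + relu), eval mode; used by the
# hidden-channel probing analysis
block_activations <- function(model, x, block = 1L) {
  fw <- forward(model, x, training = FALSE, keep_cache = TRUE)
  blk <- fw$cache[[sprintf("b%d", block)]]
  blk$bn$y * blk$mask
}
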