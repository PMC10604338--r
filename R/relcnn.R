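#' ReLCNN configuration
#'
#' Defines the light-CNN murmur classifier: five convolutional and four
#' network-in-network (1x1) layers, each followed by max-feature-map channel
#' halving, with three residual connections, selective batch normalization,
#' a configurable end-of-block activation (Swish by default, with a trainable
#' slope), multi-head self-attention over time frames, mean pooling over
#' time, scalar-feature concatenation and a 2-way softmax head.
#'
#' @param block_filters Nine post-MFM channel counts, alternating
#'   conv/NIN layers (default `c(32, 32, 48, 48, 64, 64, 32, 32, 32)`).
#'   The last NIN/conv pair must share a channel count (its residual skip is
#'   a plain max-pool).
#' @param first_kernel Kernel size of the first convolution (default 5).
#' @param other_kernel Kernel size of the non-NIN convolutions (default 3).
#' @param mha_heads Number of attention heads (default 8).
#' @param mha_dim Frame-embedding dimension for attention (default 64; must
#'   be divisible by `mha_heads`).
#' @param use_mha Set `FALSE` to ablate the attention block.
#' @param activation End-of-block activation: `"swish"`, `"relu"` or
#'   `"none"`.
#' @param n_outputs Number of output classes (default 2).
#' @param n_scalars Number of scalar side-features concatenated before the
#'   final fully connected layer (default 1: the mean peak interval).
#' @return A list with class `relcnn_config`.
#' @export
relcnn_config <- function(block_filters = c(32, 32, 48, 48, 64, 64, 32, 32, 32),
                          first_kernel = 5L, other_kernel = 3L,
                          mha_heads = 8L, mha_dim = 64L, use_mha = TRUE,
                          activation = c("swish", "relu", "none"),
                          n_outputs = 2L, n_scalars = 1L) {
  activation <- match.arg(activation)
  if (length(block_filters) != 9L) stop("`block_filters` must have length 9")
  if (block_filters[7] != block_filters[9]) {
    stop("the last block's input and output channels must match (pool-only skip)")
  }
  if (mha_dim %% mha_heads != 0L) {
    stop("`mha_dim` must be divisible by `mha_heads`")
  }
  structure(
    list(block_filters = as.integer(block_filters),
         first_kernel = as.integer(first_kernel),
         other_kernel = as.integer(other_kernel),
         mha_heads = as.integer(mha_heads), mha_dim = as.integer(mha_dim),
         use_mha = isTRUE(use_mha), activation = activation,
         n_outputs = as.integer(n_outputs), n_scalars = as.integer(n_scalars)),
    class = "relcnn_config"
  )
}

#' Build a ReLCNN model
#'
#' Initializes all parameters (He-scaled Gaussians from the current RNG;
#' wrap in a seeded context for reproducibility) and traces feature-map
#' shapes for the given input.
#'
#' Layer stack (f = `block_filters`): conv(f1, k5) -> pool; block 1:
#' NIN(f2) -> conv(f3) -> pool -> BN; block 2 (residual, pool+1x1 skip):
#' NIN(f4) -> conv(f5) -> pool; block 3 (residual, 1x1 skip): NIN(f6) ->
#' conv(f7) -> BN; block 4 (residual, pool skip): NIN(f8) -> conv(f9) ->
#' pool. Every convolution doubles channels and max-feature-map halves them;
#' the configured activation closes each block. The head flattens channels x
#' mel-bands per frame, projects to `mha_dim`, applies multi-head
#' self-attention over frames, mean-pools over time, appends scalar features
#' and ends in a softmax layer.
#'
#' @param cfg A [relcnn_config].
#' @param input_shape Integer triple `(channels, mel_bands, frames)`.
#' @return A list with class `relcnn_model`: `cfg`, `input_shape`, `params`
#'   (named list of arrays), `state` (batch-norm running moments) and
#'   `shapes` (per-stage feature-map shapes).
#' @export
build_relcnn <- function(cfg = relcnn_config(), input_shape) {
  stopifnot(length(input_shape) == 3L)
  f <- cfg$block_filters
  kk <- cfg$other_kernel
  C <- input_shape[1]
  params <- list()
  params$conv1 <- conv2d_init(C, 2L * f[1], cfg$first_kernel)
  params$g1_nin <- conv2d_init(f[1], 2L * f[2], 1L)
  params$g1_conv <- conv2d_init(f[2], 2L * f[3], kk)
  params$g1_bn <- bn_init(f[3])
  params$g2_nin <- conv2d_init(f[3], 2L * f[4], 1L)
  params$g2_conv <- conv2d_init(f[4], 2L * f[5], kk)
  params$g2_skip <- conv2d_init(f[3], f[5], 1L)
  params$g3_nin <- conv2d_init(f[5], 2L * f[6], 1L)
  params$g3_conv <- conv2d_init(f[6], 2L * f[7], kk)
  params$g3_bn <- bn_init(f[7])
  params$g3_skip <- conv2d_init(f[5], f[7], 1L)
  params$g4_nin <- conv2d_init(f[7], 2L * f[8], 1L)
  params$g4_conv <- conv2d_init(f[8], 2L * f[9], kk)

  # shape trace through the four pools
  hw <- input_shape[2:3]
  pool <- function(hw) hw %/% 2L
  hw1 <- pool(hw)        # after conv1 pool
  hw2 <- pool(hw1)       # after block 1 pool
  hw3 <- pool(hw2)       # after block 2 pool
  hw4 <- pool(hw3)       # after block 4 pool (block 3 keeps shape)
  if (any(hw4 < 1L)) stop("input too small for four pooling stages")
  embed_in <- f[9] * hw4[1]
  params$proj <- linear_init(embed_in, cfg$mha_dim)
  if (cfg$use_mha) params$mha <- mha_init(cfg$mha_dim)
  if (cfg$activation == "swish") params$swish_beta <- 1
  params$fc <- linear_init(cfg$mha_dim + cfg$n_scalars, cfg$n_outputs)

  structure(
    list(
      cfg = cfg,
      input_shape = as.integer(input_shape),
      params = params,
      state = list(g1_bn = bn_state_init(f[3]), g3_bn = bn_state_init(f[7])),
      shapes = list(stem = c(f[1], hw1), block1 = c(f[3], hw2),
                    block2 = c(f[5], hw3), block3 = c(f[7], hw3),
                    block4 = c(f[9], hw4), frames = hw4[2],
                    embed_in = embed_in),
      scalar_center = rep(0, cfg$n_scalars),
      scalar_scale = rep(1, cfg$n_scalars),
      input_center = rep(0, C),
      input_scale = rep(1, C)
    ),
    class = "relcnn_model"
  )
}

#' @export
print.relcnn_model <- function(x, ...) {
  cat(sprintf(
    paste0("<relcnn_model> input (%s), filters [%s], %s, activation=%s\n",
           "  %d parameters in %d tensors\n"),
    paste(x$input_shape, collapse = " x "),
    paste(x$cfg$block_filters, collapse = ","),
    if (x$cfg$use_mha) sprintf("MHA %d heads x dim %d", x$cfg$mha_heads, x$cfg$mha_dim)
    else "no MHA",
    x$cfg$activation,
    sum(vapply(unlist(x$params, recursive = FALSE), length, numeric(1))),
    length(unlist(x$params, recursive = FALSE))
  ))
  invisible(x)
}

#' Forward pass of a ReLCNN model
#'
#' @param model A [build_relcnn()] model.
#' @param x Input batch, array `(channels, mel_bands, frames, N)`.
#' @param scalars Scalar side-feature matrix `(n_scalars, N)` (already
#'   standardized); may be `NULL` when the model has none.
#' @param training Logical; batch-norm uses batch statistics and updates
#'   running moments when `TRUE`.
#' @return A list with `probs` (`n_outputs x N`, columns sum to 1), `logits`,
#'   a `cache` for the backward pass, and updated batch-norm `state`.
#' @export
relcnn_forward <- function(model, x, scalars = NULL, training = FALSE) {
  p <- model$params
  cfg <- model$cfg
  kk <- cfg$other_kernel
  beta <- p$swish_beta %||% 1
  ca <- list()

  ca$conv1 <- conv2d_forward(x, p$conv1$W, p$conv1$b, cfg$first_kernel)
  ca$mfm1 <- mfm_forward(ca$conv1$out)
  ca$pool1 <- maxpool_forward(ca$mfm1$out)
  h <- ca$pool1$out

  # block 1 (no residual)
  ca$g1_nin <- conv2d_forward(h, p$g1_nin$W, p$g1_nin$b, 1L)
  ca$g1_mfm1 <- mfm_forward(ca$g1_nin$out)
  ca$g1_conv <- conv2d_forward(ca$g1_mfm1$out, p$g1_conv$W, p$g1_conv$b, kk)
  ca$g1_mfm2 <- mfm_forward(ca$g1_conv$out)
  ca$g1_pool <- maxpool_forward(ca$g1_mfm2$out)
  ca$g1_bn <- bn_forward(ca$g1_pool$out, p$g1_bn$gamma, p$g1_bn$beta,
                         model$state$g1_bn, training)
  model$state$g1_bn <- ca$g1_bn$state
  ca$g1_act <- act_forward(ca$g1_bn$out, cfg$activation, beta)
  h <- ca$g1_act$out

  # block 2: residual with max-pool + 1x1-conv skip
  ca$g2_in <- h
  ca$g2_nin <- conv2d_forward(h, p$g2_nin$W, p$g2_nin$b, 1L)
  ca$g2_mfm1 <- mfm_forward(ca$g2_nin$out)
  ca$g2_conv <- conv2d_forward(ca$g2_mfm1$out, p$g2_conv$W, p$g2_conv$b, kk)
  ca$g2_mfm2 <- mfm_forward(ca$g2_conv$out)
  ca$g2_pool <- maxpool_forward(ca$g2_mfm2$out)
  ca$g2_skip_pool <- maxpool_forward(h)
  ca$g2_skip <- conv2d_forward(ca$g2_skip_pool$out, p$g2_skip$W, p$g2_skip$b, 1L)
  ca$g2_act <- act_forward(ca$g2_pool$out + ca$g2_skip$out, cfg$activation, beta)
  h <- ca$g2_act$out

  # block 3: residual with 1x1-conv skip (no pooling)
  ca$g3_in <- h
  ca$g3_nin <- conv2d_forward(h, p$g3_nin$W, p$g3_nin$b, 1L)
  ca$g3_mfm1 <- mfm_forward(ca$g3_nin$out)
  ca$g3_conv <- conv2d_forward(ca$g3_mfm1$out, p$g3_conv$W, p$g3_conv$b, kk)
  ca$g3_mfm2 <- mfm_forward(ca$g3_conv$out)
  ca$g3_bn <- bn_forward(ca$g3_mfm2$out, p$g3_bn$gamma, p$g3_bn$beta,
                         model$state$g3_bn, training)
  model$state$g3_bn <- ca$g3_bn$state
  ca$g3_skip <- conv2d_forward(h, p$g3_skip$W, p$g3_skip$b, 1L)
  ca$g3_act <- act_forward(ca$g3_bn$out + ca$g3_skip$out, cfg$activation, beta)
  h <- ca$g3_act$out

  # block 4: residual with plain max-pool skip
  ca$g4_in <- h
  ca$g4_nin <- conv2d_forward(h, p$g4_nin$W, p$g4_nin$b, 1L)
  ca$g4_mfm1 <- mfm_forward(ca$g4_nin$out)
  ca$g4_conv <- conv2d_forward(ca$g4_mfm1$out, p$g4_conv$W, p$g4_conv$b, kk)
  ca$g4_mfm2 <- mfm_forward(ca$g4_conv$out)
  ca$g4_pool <- maxpool_forward(ca$g4_mfm2$out)
  ca$g4_skip_pool <- maxpool_forward(h)
  ca$g4_act <- act_forward(ca$g4_pool$out + ca$g4_skip_pool$out,
                           cfg$activation, beta)
  h <- ca$g4_act$out

  # head: flatten (C, H) per frame, project, attend, mean-pool over frames
  d <- dim(h)
  CH <- d[1] * d[2]; TT <- d[3]; N <- d[4]
  hmat <- h
  dim(hmat) <- c(CH, TT * N)
  ca$proj <- linear_forward(hmat, p$proj$W, p$proj$b)
  e <- ca$proj$out
  dim(e) <- c(cfg$mha_dim, TT, N)
  if (cfg$use_mha) {
    ca$mha <- mha_forward(e, p$mha, cfg$mha_heads)
    e <- ca$mha$out
  }
  pooled <- apply(e, c(1, 3), mean)
  if (N == 1L) pooled <- matrix(pooled, ncol = 1L)
  if (cfg$n_scalars > 0L) {
    if (is.null(scalars)) stop("model expects scalar features")
    z <- rbind(pooled, scalars)
  } else {
    z <- pooled
  }
  ca$fc <- linear_forward(z, p$fc$W, p$fc$b)
  ca$head_dims <- c(CH = CH, TT = TT, N = N)
  logits <- ca$fc$out

  list(probs = softmax_cols(logits), logits = logits, cache = ca,
       state = model$state)
}

#' Backward pass of a ReLCNN model
#'
#' Computes gradients of the loss with respect to every trainable parameter,
#' given the gradient at the logits.
#'
#' @param model A [build_relcnn()] model.
#' @param cache Cache returned by [relcnn_forward()] (with `training = TRUE`).
#' @param dlogits Gradient at the logits, `(n_outputs x N)`.
#' @return Named list of gradients mirroring `model$params`.
#' @export
relcnn_backward <- function(model, cache, dlogits) {
  p <- model$params
  cfg <- model$cfg
  kk <- cfg$other_kernel
  beta <- p$swish_beta %||% 1
  ca <- cache
  g <- list()
  dbeta_total <- 0

  fcb <- linear_backward(dlogits, ca$fc, p$fc$W)
  g$fc <- list(W = fcb$dW, b = fcb$db)
  dz <- fcb$dx
  dm <- cfg$mha_dim
  dpooled <- dz[seq_len(dm), , drop = FALSE]

  CH <- ca$head_dims["CH"]; TT <- ca$head_dims["TT"]; N <- ca$head_dims["N"]
  de <- array(0, c(dm, TT, N))
  for (tt in seq_len(TT)) de[, tt, ] <- dpooled / TT
  if (cfg$use_mha) {
    mb <- mha_backward(de, ca$mha, p$mha)
    g$mha <- mb$grads
    de <- mb$dx
  }
  dim(de) <- c(dm, TT * N)
  pb <- linear_backward(de, ca$proj, p$proj$W)
  g$proj <- list(W = pb$dW, b = pb$db)
  dh <- pb$dx
  dim(dh) <- c(dim(ca$g4_act$out)[1:3], N)

  back_act <- function(dout, cache_act) {
    ab <- act_backward(dout, cache_act, cfg$activation, beta)
    dbeta_total <<- dbeta_total + ab$dbeta
    ab$dx
  }

  # block 4
  dsum <- back_act(dh, ca$g4_act)
  dskip <- maxpool_backward(dsum, ca$g4_skip_pool)
  dmain <- maxpool_backward(dsum, ca$g4_pool)
  dmain <- mfm_backward(dmain, ca$g4_mfm2)
  cb <- conv2d_backward(dmain, ca$g4_conv, p$g4_conv$W, kk)
  g$g4_conv <- list(W = cb$dW, b = cb$db)
  dmain <- mfm_backward(cb$dx, ca$g4_mfm1)
  cb <- conv2d_backward(dmain, ca$g4_nin, p$g4_nin$W, 1L)
  g$g4_nin <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx + dskip

  # block 3
  dsum <- back_act(dh, ca$g3_act)
  cb <- conv2d_backward(dsum, ca$g3_skip, p$g3_skip$W, 1L)
  g$g3_skip <- list(W = cb$dW, b = cb$db)
  dskip <- cb$dx
  bb <- bn_backward(dsum, ca$g3_bn, p$g3_bn$gamma)
  g$g3_bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
  dmain <- mfm_backward(bb$dx, ca$g3_mfm2)
  cb <- conv2d_backward(dmain, ca$g3_conv, p$g3_conv$W, kk)
  g$g3_conv <- list(W = cb$dW, b = cb$db)
  dmain <- mfm_backward(cb$dx, ca$g3_mfm1)
  cb <- conv2d_backward(dmain, ca$g3_nin, p$g3_nin$W, 1L)
  g$g3_nin <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx + dskip

  # block 2
  dsum <- back_act(dh, ca$g2_act)
  cb <- conv2d_backward(dsum, ca$g2_skip, p$g2_skip$W, 1L)
  g$g2_skip <- list(W = cb$dW, b = cb$db)
  dskip <- maxpool_backward(cb$dx, ca$g2_skip_pool)
  dmain <- maxpool_backward(dsum, ca$g2_pool)
  dmain <- mfm_backward(dmain, ca$g2_mfm2)
  cb <- conv2d_backward(dmain, ca$g2_conv, p$g2_conv$W, kk)
  g$g2_conv <- list(W = cb$dW, b = cb$db)
  dmain <- mfm_backward(cb$dx, ca$g2_mfm1)
  cb <- conv2d_backward(dmain, ca$g2_nin, p$g2_nin$W, 1L)
  g$g2_nin <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx + dskip

  # block 1
  dsum <- back_act(dh, ca$g1_act)
  bb <- bn_backward(dsum, ca$g1_bn, p$g1_bn$gamma)
  g$g1_bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
  dmain <- maxpool_backward(bb$dx, ca$g1_pool)
  dmain <- mfm_backward(dmain, ca$g1_mfm2)
  cb <- conv2d_backward(dmain, ca$g1_conv, p$g1_conv$W, kk)
  g$g1_conv <- list(W = cb$dW, b = cb$db)
  dmain <- mfm_backward(cb$dx, ca$g1_mfm1)
  cb <- conv2d_backward(dmain, ca$g1_nin, p$g1_nin$W, 1L)
  g$g1_nin <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx

  # stem
  dmain <- maxpool_backward(dh, ca$pool1)
  dmain <- mfm_backward(dmain, ca$mfm1)
  cb <- conv2d_backward(dmain, ca$conv1, p$conv1$W, cfg$first_kernel)
  g$conv1 <- list(W = cb$dW, b = cb$db)

  if (cfg$activation == "swish") g$swish_beta <- dbeta_total
  g
}
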