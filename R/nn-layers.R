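# Minimal dense NN primitives on (C, H, W, N) arrays with exact backward
# passes. BLAS matrix products do the heavy lifting (im2col convolution);
# correctness is pinned by a finite-difference gradient check in the tests.

conv2d_init <- function(in_ch, out_ch, k) {
  fan_in <- in_ch * k * k
  list(
    W = matrix(stats::rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)),
               nrow = out_ch),
    b = numeric(out_ch)
  )
}

# "same" padding convolution; k odd. Returns output and the im2col matrix.
conv2d_forward <- function(x, W, b, k) {
  d <- dim(x); C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  p <- (k - 1L) %/% 2L
  if (p > 0L) {
    Xp <- array(0, c(C, H + 2L * p, Wd + 2L * p, N))
    Xp[, p + 1:H, p + 1:Wd, ] <- x
  } else {
    Xp <- x
  }
  col <- matrix(0, C * k * k, H * Wd * N)
  blk <- 0L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      m <- Xp[, ki - 1L + 1:H, kj - 1L + 1:Wd, , drop = FALSE]
      col[blk * C + 1:C, ] <- matrix(m, nrow = C)
      blk <- blk + 1L
    }
  }
  out <- W %*% col + b # b recycles per-row down each column
  dim(out) <- c(nrow(W), H, Wd, N)
  list(out = out, col = col, xdim = d)
}

conv2d_backward <- function(dout, cache, W, k) {
  d <- cache$xdim; C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  out_ch <- nrow(W)
  dmat <- matrix(dout, nrow = out_ch)
  dW <- dmat %*% t(cache$col)
  db <- rowSums(dmat)
  dcol <- crossprod(W, dmat)
  p <- (k - 1L) %/% 2L
  dXp <- array(0, c(C, H + 2L * p, Wd + 2L * p, N))
  blk <- 0L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      dm <- dcol[blk * C + 1:C, , drop = FALSE]
      dim(dm) <- c(C, H, Wd, N)
      dXp[, ki - 1L + 1:H, kj - 1L + 1:Wd, ] <-
        dXp[, ki - 1L + 1:H, kj - 1L + 1:Wd, , drop = FALSE] + dm
      blk <- blk + 1L
    }
  }
  dx <- if (p > 0L) dXp[, p + 1:H, p + 1:Wd, , drop = FALSE] else dXp
  list(dx = dx, dW = dW, db = db)
}

#' Max-feature-map activation
#'
#' Halves the channel count by taking the elementwise maximum over paired
#' channels: output channel `i` is `max(x_i, x_{i+f})` for input with `2f`
#' channels.
#'
#' @param x Array of shape `(2f, H, W, N)` (or any array whose first
#'   dimension is even).
#' @return Array with first dimension halved.
#' @export
mfm <- function(x) {
  mfm_forward(x)$out
}

mfm_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L) stop("max-feature-map needs an even channel count")
  f <- d[1] %/% 2L
  a <- x[1:f, , , , drop = FALSE]
  b <- x[f + 1:f, , , , drop = FALSE]
  list(out = pmax(a, b), mask = a >= b, f = f)
}

mfm_backward <- function(dout, cache) {
  d <- dim(dout); f <- cache$f
  dx <- array(0, c(2L * f, d[2], d[3], d[4]))
  dx[1:f, , , ] <- dout * cache$mask
  dx[f + 1:f, , , ] <- dout * !cache$mask
  dx
}

maxpool_forward <- function(x) {
  d <- dim(x)
  H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
  if (H2 < 1L || W2 < 1L) stop("feature map too small to max-pool")
  i1 <- seq_len(H2) * 2L - 1L
  j1 <- seq_len(W2) * 2L - 1L
  a <- x[, i1, j1, , drop = FALSE]
  b <- x[, i1 + 1L, j1, , drop = FALSE]
  cc <- x[, i1, j1 + 1L, , drop = FALSE]
  e <- x[, i1 + 1L, j1 + 1L, , drop = FALSE]
  out <- pmax(pmax(a, b), pmax(cc, e))
  arg <- ifelse(out == a, 1L, ifelse(out == b, 2L, ifelse(out == cc, 3L, 4L)))
  list(out = out, arg = arg, xdim = d)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$xdim
  H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
  i1 <- seq_len(H2) * 2L - 1L
  j1 <- seq_len(W2) * 2L - 1L
  dx <- array(0, d)
  arg <- cache$arg
  dx[, i1, j1, ] <- dout * (arg == 1L)
  dx[, i1 + 1L, j1, ] <- dout * (arg == 2L)
  dx[, i1, j1 + 1L, ] <- dout * (arg == 3L)
  dx[, i1 + 1L, j1 + 1L, ] <- dout * (arg == 4L)
  dx
}

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = numeric(channels))
}

bn_state_init <- function(channels) {
  list(mean = numeric(channels), var = rep(1, channels))
}

bn_forward <- function(x, gamma, beta, state, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[1]
  xm <- matrix(x, nrow = C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  out <- gamma * xhat + beta
  dim(out) <- d
  list(out = out, xhat = xhat, inv = inv, state = state, xdim = d,
       training = training)
}

bn_backward <- function(dout, cache, gamma) {
  d <- cache$xdim; C <- d[1]
  dy <- matrix(dout, nrow = C)
  xhat <- cache$xhat
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * gamma
  dx <- if (cache$training) {
    cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  } else {
    cache$inv * dxhat
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Swish activation
#'
#' `swish(x) = x * sigmoid(beta * x)`, with `sigmoid(z) = 1/(1 + exp(-z))`.
#' `beta` is a trainable scalar in the network (initialized at 1).
#'
#' @param x Numeric vector/array.
#' @param beta Slope parameter.
#' @return Elementwise swish of `x`.
#' @export
swish <- function(x, beta = 1) {
  x * stats::plogis(beta * x)
}

act_forward <- function(x, kind, beta = 1) {
  out <- switch(kind,
    none = x,
    relu = pmax(x, 0),
    swish = swish(x, beta),
    stop("unknown activation: ", kind)
  )
  list(out = out, x = x)
}

act_backward <- function(dout, cache, kind, beta = 1) {
  x <- cache$x
  if (kind == "none") {
    list(dx = dout, dbeta = 0)
  } else if (kind == "relu") {
    list(dx = dout * (x > 0), dbeta = 0)
  } else {
    s <- stats::plogis(beta * x)
    list(
      dx = dout * (s + beta * x * s * (1 - s)),
      dbeta = sum(dout * x^2 * s * (1 - s))
    )
  }
}

linear_init <- function(d_in, d_out) {
  list(
    W = matrix(stats::rnorm(d_out * d_in, sd = sqrt(2 / d_in)), nrow = d_out),
    b = numeric(d_out)
  )
}

linear_forward <- function(x, W, b) {
  list(out = W %*% x + b, x = x)
}

linear_backward <- function(dout, cache, W) {
  list(
    dx = crossprod(W, dout),
    dW = dout %*% t(cache$x),
    db = rowSums(dout)
  )
}

mha_init <- function(d) {
  sd <- sqrt(1 / d)
  list(
    Wq = matrix(stats::rnorm(d * d, sd = sd), d, d),
    Wk = matrix(stats::rnorm(d * d, sd = sd), d, d),
    Wv = matrix(stats::rnorm(d * d, sd = sd), d, d),
    Wo = matrix(stats::rnorm(d * d, sd = sd), d, d)
  )
}

#' Multi-head self-attention over a frame sequence
#'
#' Standard scaled dot-product self-attention in which query, key and value
#' all derive from the same sequence; heads are concatenated and linearly
#' projected. No positional encoding is used, so permuting frames permutes
#' outputs identically.
#'
#' @param x Array `(d, T, N)`: embedding dim, frames, batch.
#' @param params List with `d x d` matrices `Wq`, `Wk`, `Wv`, `Wo`.
#' @param heads Number of heads; must divide `d`.
#' @return Array of the same shape as `x`.
#' @export
multi_head_self_attention <- function(x, params, heads) {
  mha_forward(x, params, heads)$out
}

mha_forward <- function(x, params, heads) {
  d <- dim(x)[1]; TT <- dim(x)[2]; N <- dim(x)[3]
  if (d %% heads != 0L) stop("embedding dimension must be divisible by heads")
  dk <- d %/% heads
  out <- array(0, dim(x))
  caches <- vector("list", N)
  for (i in seq_len(N)) {
    X <- t(matrix(x[, , i], nrow = d)) # T x d
    Q <- X %*% params$Wq
    K <- X %*% params$Wk
    V <- X %*% params$Wv
    O <- matrix(0, TT, d)
    A_list <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dk + 1:dk
      S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
      S <- sweep(S, 1L, apply(S, 1L, max)) # softmax stabilization
      A <- exp(S)
      A <- A / rowSums(A)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
      A_list[[h]] <- A
    }
    out[, , i] <- t(O %*% params$Wo)
    caches[[i]] <- list(X = X, Q = Q, K = K, V = V, O = O, A = A_list)
  }
  list(out = out, caches = caches, heads = heads, dk = dk)
}

mha_backward <- function(dout, fw, params) {
  d <- dim(dout)[1]; N <- dim(dout)[3]
  heads <- fw$heads; dk <- fw$dk
  g <- list(Wq = 0 * params$Wq, Wk = 0 * params$Wk,
            Wv = 0 * params$Wv, Wo = 0 * params$Wo)
  dx <- array(0, dim(dout))
  for (i in seq_len(N)) {
    cc <- fw$caches[[i]]
    dY <- t(matrix(dout[, , i], nrow = d)) # T x d
    dO <- dY %*% t(params$Wo)
    g$Wo <- g$Wo + crossprod(cc$O, dY)
    dQ <- dK <- dV <- matrix(0, nrow(dY), d)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dk + 1:dk
      A <- cc$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- dOh %*% t(cc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A)) / sqrt(dk)
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE]
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE])
    }
    dX <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
    g$Wq <- g$Wq + crossprod(cc$X, dQ)
    g$Wk <- g$Wk + crossprod(cc$X, dK)
    g$Wv <- g$Wv + crossprod(cc$X, dV)
    dx[, , i] <- t(dX)
  }
  list(dx = dx, grads = g)
}

#' Residual addition with automatic skip-path adjustment
#'
#' Adds a main-path output `fx` to the block input `x`. When shapes match the
#' sum is direct; a spatial mismatch by a factor of two is reconciled by
#' max-pooling `x`, and a channel mismatch by a 1x1 convolution (whose
#' parameters must be supplied).
#'
#' @param x Block input, array `(C, H, W, N)`.
#' @param fx Main-path output, array `(C', H', W', N)`.
#' @param proj Optional list `(W, b)` of 1x1-convolution parameters for a
#'   channel mismatch.
#' @return Array of `fx`'s shape.
#' @export
residual_add <- function(x, fx, proj = NULL) {
  df <- dim(fx)
  repeat {
    if (all(dim(x)[2:3] == df[2:3])) break
    if (any(dim(x)[2:3] < df[2:3])) stop("irreconcilable shapes in residual_add")
    x <- maxpool_forward(x)$out
  }
  if (dim(x)[1] != df[1]) {
    if (is.null(proj)) stop("channel mismatch requires 1x1 projection parameters")
    x <- conv2d_forward(x, proj$W, proj$b, 1L)$out
  }
  x + fx
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# weighted categorical cross-entropy; y one-hot/soft (K x N), w per-sample
weighted_ce <- function(logits, y, w) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  loss <- -sum(w * colSums(y * log(pmax(p, 1e-12)))) / n
  dlogits <- sweep(p - y, 2L, w, `*`) / n
  list(loss = loss, dlogits = dlogits, probs = p)
}
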