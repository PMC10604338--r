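test_that("max-feature-map equals the elementwise pairwise maximum", {
  x <- array(5, c(4, 3, 3, 2))
  x[3:4, , , ] <- 1
  out <- mfm(x)
  expect_equal(dim(out)[1], 2L)
  expect_true(all(out == 5))

  a <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  dup <- array(0, c(4, 2, 2, 2))
  dup[1:2, , , ] <- a
  dup[3:4, , , ] <- a
  expect_equal(mfm(dup), a) # identical halves reproduce either half

  # brute-force oracle on 100 random tensors
  set.seed(10)
  for (i in 1:100) {
    f <- sample(1:4, 1)
    d <- c(2L * f, sample(1:4, 1), sample(1:4, 1), sample(1:3, 1))
    x <- array(rnorm(prod(d)), d)
    got <- mfm(x)
    ora <- array(0, c(f, d[2:4]))
    for (c1 in 1:f) for (h in 1:d[2]) for (w in 1:d[3]) for (n in 1:d[4]) {
      ora[c1, h, w, n] <- max(x[c1, h, w, n], x[c1 + f, h, w, n])
    }
    expect_equal(got, ora)
    expect_true(all(got >= x[1:f, , , , drop = FALSE]))
    expect_true(all(got >= x[f + 1:f, , , , drop = FALSE]))
  }
  expect_error(mfm(array(0, c(3, 2, 2, 1))), "even")
})

test_that("swish matches its closed form and saturates", {
  expect_equal(swish(0), 0)
  expect_equal(swish(1, 1), plogis(1))
  expect_equal(swish(1, 1), 0.7310586, tolerance = 1e-6)
  expect_lt(abs(swish(2, 10) - 2), 1e-3) # beta*x = 20 saturation
  expect_equal(swish(c(-1, 0, 2), 2), c(-1, 0, 2) * plogis(2 * c(-1, 0, 2)))
})

test_that("residual addition adjusts the skip path by shape", {
  x <- array(rnorm(3 * 4 * 6 * 2), c(3, 4, 6, 2))
  fx0 <- array(0, dim(x))
  expect_equal(residual_add(x, fx0), x) # zero main path is the identity
  fx <- array(rnorm(prod(dim(x))), dim(x))
  expect_equal(residual_add(x, fx) - fx, x)

  # channel mismatch via 1x1 projection
  proj <- list(W = matrix(rnorm(5 * 3), 5, 3), b = numeric(5))
  fx5 <- array(rnorm(5 * 4 * 6 * 2), c(5, 4, 6, 2))
  out <- residual_add(x, fx5, proj)
  expect_equal(dim(out), c(5L, 4L, 6L, 2L))

  # spatial mismatch by pooling
  fxp <- array(rnorm(3 * 2 * 3 * 2), c(3, 2, 3, 2))
  expect_equal(dim(residual_add(x, fxp)), dim(fxp))

  expect_error(residual_add(x, array(0, c(3, 8, 6, 2))), "irreconcilable")
  expect_error(residual_add(x, fx5), "projection")
})

test_that("self-attention is constant-preserving and permutation-equivariant", {
  set.seed(12)
  d <- 8L; TT <- 5L
  params <- mcheart:::mha_init(d)
  # constant frames give constant outputs
  xc <- array(rep(rnorm(d), TT), c(d, TT, 1))
  oc <- multi_head_self_attention(xc, params, 2L)
  expect_lt(max(abs(sweep(oc[, , 1], 1, oc[, 1, 1]))), 1e-12)

  # permuting frames permutes outputs identically
  x <- array(rnorm(d * TT), c(d, TT, 1))
  perm <- c(3, 1, 5, 2, 4)
  o1 <- multi_head_self_attention(x, params, 2L)
  o2 <- multi_head_self_attention(x[, perm, , drop = FALSE], params, 2L)
  expect_equal(o2[, , 1], o1[, perm, 1])

  # output shape preserved; divisibility enforced
  expect_equal(dim(o1), dim(x))
  expect_error(multi_head_self_attention(x, params, 3L), "divisible")
  expect_error(relcnn_config(mha_heads = 10, mha_dim = 64), "divisible")
  # 64-dim embedding with 8 heads gives 8-dim heads
  cfg <- relcnn_config()
  expect_equal(cfg$mha_dim / cfg$mha_heads, 8)
})

test_that("the model builds, normalizes probabilities and echoes its config", {
  set.seed(20)
  cfg <- tiny_relcnn_config()
  model <- build_relcnn(cfg, c(2, 16, 32))
  x <- array(rnorm(2 * 16 * 32 * 4), c(2, 16, 32, 4))
  s <- matrix(rnorm(4), 1, 4)
  fw <- relcnn_forward(model, x, s)
  expect_equal(dim(fw$probs), c(2L, 4L))
  expect_equal(colSums(fw$probs), rep(1, 4), tolerance = 1e-6)
  expect_equal(model$cfg$block_filters, c(2L, 2L, 3L, 3L, 4L, 4L, 2L, 2L, 2L))
  # default configuration mirrors the published stack
  expect_equal(relcnn_config()$block_filters,
               c(32L, 32L, 48L, 48L, 64L, 64L, 32L, 32L, 32L))
  expect_equal(relcnn_config()$first_kernel, 5L)
  # four pooling stages halve 140 x 782 to 8 x 48
  big <- build_relcnn(relcnn_config(), c(2, 140, 782))
  expect_equal(unname(big$shapes$block4), c(32L, 8L, 48L))
})

test_that("ablation variants build and run", {
  set.seed(21)
  x <- array(rnorm(1 * 16 * 32 * 2), c(1, 16, 32, 2))
  s <- matrix(rnorm(2), 1, 2)
  variants <- list(
    tiny_relcnn_config(use_mha = FALSE),
    tiny_relcnn_config(mha_heads = 4L),
    tiny_relcnn_config(mha_heads = 8L),
    relcnn_config(block_filters = c(2, 2, 3, 3, 4, 4, 2, 2, 2),
                  mha_dim = 10L, mha_heads = 10L),
    tiny_relcnn_config(activation = "none"),
    tiny_relcnn_config(activation = "relu"),
    tiny_relcnn_config(activation = "swish")
  )
  for (cfg in variants) {
    m <- build_relcnn(cfg, c(1, 16, 32))
    fw <- relcnn_forward(m, x, s)
    expect_equal(colSums(fw$probs), rep(1, 2), tolerance = 1e-6)
  }
  # swish beta is a parameter only for the swish variant
  expect_null(build_relcnn(tiny_relcnn_config(activation = "relu"),
                           c(1, 16, 32))$params$swish_beta)
  expect_equal(build_relcnn(tiny_relcnn_config(), c(1, 16, 32))$params$swish_beta, 1)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  model <- build_relcnn(tiny_relcnn_config(), c(1, 16, 32))
  x <- array(rnorm(1 * 16 * 32 * 3), c(1, 16, 32, 3))
  s <- matrix(rnorm(3), 1, 3)
  y <- rbind(c(1, 0, 1), c(0, 1, 0))
  w <- c(3, 1, 3)
  loss_of <- function(m) {
    mcheart:::weighted_ce(relcnn_forward(m, x, s, training = TRUE)$logits,
                          y, w)$loss
  }
  fw <- relcnn_forward(model, x, s, training = TRUE)
  lo <- mcheart:::weighted_ce(fw$logits, y, w)
  grads <- relcnn_backward(model, fw$cache, lo$dlogits)
  flat_p <- unlist(model$params)
  flat_g <- unlist(grads[names(model$params)])
  expect_length(flat_g, length(flat_p))

  eps <- 1e-5
  set.seed(7)
  idx <- sort(sample(length(flat_p), 50))
  for (i in idx) {
    pp <- flat_p
    pp[i] <- flat_p[i] + eps
    m2 <- model; m2$params <- utils::relist(pp, model$params)
    lp <- loss_of(m2)
    pp[i] <- flat_p[i] - eps
    m2$params <- utils::relist(pp, model$params)
    lm <- loss_of(m2)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - flat_g[i]) / max(1e-6, abs(num) + abs(flat_g[i])),
              2e-4)
  }
})

test_that("every parameter tensor moves after one optimizer step", {
  set.seed(33)
  model <- build_relcnn(tiny_relcnn_config(), c(1, 16, 32))
  x <- array(rnorm(1 * 16 * 32 * 4), c(1, 16, 32, 4))
  s <- matrix(rnorm(4), 1, 4)
  y <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  fw <- relcnn_forward(model, x, s, training = TRUE)
  lo <- mcheart:::weighted_ce(fw$logits, y, rep(1, 4))
  grads <- relcnn_backward(model, fw$cache, lo$dlogits)

  # every tensor receives some nonzero gradient
  for (nm in names(model$params)) {
    parts <- if (is.list(grads[[nm]])) grads[[nm]] else list(grads[[nm]])
    for (k in seq_along(parts)) {
      expect_gt(sum(abs(parts[[k]])), 0,
                label = sprintf("gradient %s[%d]", nm, k))
    }
  }

  opt <- mcheart:::adam_init(model$params)
  st <- mcheart:::adam_step(model$params, grads, opt, lr = 1e-3)
  before <- unlist(model$params)
  after <- unlist(st$params)
  moved <- abs(after - before) > 0
  # per-tensor: at least one entry of every tensor changed
  splits <- rep(rapply(model$params, length, how = "unlist"), times = 1)
  grp <- rep(seq_along(splits), splits)
  expect_true(all(tapply(moved, grp, any)))
})
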