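#' Augmentation configuration
#'
#' @param mixup_alpha Beta(alpha, alpha) shape for the mixup coefficient
#'   (default 0.5).
#' @param mixup_prob Per-batch probability of applying mixup (default 0.7).
#' @param cutout_prob Per-batch probability of applying cutout (default 0.8).
#' @param cutout_frac Length-2 numeric `(height fraction, width fraction)` of
#'   the zeroed rectangle (default `c(0.25, 0.25)`).
#' @return A list with class `augment_config`.
#' @export
augment_config <- function(mixup_alpha = 0.5, mixup_prob = 0.7,
                           cutout_prob = 0.8, cutout_frac = c(0.25, 0.25)) {
  if (mixup_alpha <= 0) stop("`mixup_alpha` must be > 0")
  stopifnot_scalar_number(mixup_prob, "mixup_prob", 0, 1)
  stopifnot_scalar_number(cutout_prob, "cutout_prob", 0, 1)
  if (length(cutout_frac) != 2L || any(cutout_frac < 0) || any(cutout_frac > 1)) {
    stop("`cutout_frac` must be two fractions in [0, 1]")
  }
  structure(
    list(mixup_alpha = mixup_alpha, mixup_prob = mixup_prob,
         cutout_prob = cutout_prob, cutout_frac = as.numeric(cutout_frac)),
    class = "augment_config"
  )
}

#' Mixup a batch of feature tensors and labels
#'
#' Draws one mixing coefficient `lambda ~ Beta(alpha, alpha)` per batch and a
#' random partner permutation, then forms the convex combinations
#' `lambda * x_i + (1 - lambda) * x_j` for features and labels alike. Labels
#' on the probability simplex stay on it. Batches of one are returned
#' unchanged. Uses the current RNG stream.
#'
#' @param x Feature batch: an array whose last dimension indexes samples, or
#'   a list of such arrays (all mixed with the same lambda and permutation).
#' @param y Label matrix, one column per sample (one-hot or soft labels).
#' @param cfg An [augment_config].
#' @param lambda Optional fixed lambda (bypasses the Beta draw).
#' @return A list with `x`, `y`, `lambda` and the partner permutation `perm`.
#' @export
mixup <- function(x, y, cfg = augment_config(), lambda = NULL) {
  xs <- if (is.list(x)) x else list(x)
  n <- dim(y)[2] %||% length(y)
  if (n < 2L) {
    return(list(x = x, y = y, lambda = 1, perm = seq_len(n)))
  }
  lam <- lambda %||% stats::rbeta(1, cfg$mixup_alpha, cfg$mixup_alpha)
  perm <- sample.int(n)
  mix_one <- function(a) {
    nd <- length(dim(a) %||% integer(0))
    if (nd == 0L) return(lam * a + (1 - lam) * a[perm])
    partner <- switch(as.character(nd),
      "2" = a[, perm, drop = FALSE],
      "3" = a[, , perm, drop = FALSE],
      "4" = a[, , , perm, drop = FALSE],
      stop("unsupported array rank in mixup")
    )
    lam * a + (1 - lam) * partner
  }
  xs_mixed <- lapply(xs, mix_one)
  list(
    x = if (is.list(x)) xs_mixed else xs_mixed[[1]],
    y = mix_one(y),
    lambda = lam,
    perm = perm
  )
}

#' Cutout: zero a random rectangle of each sample's channels
#'
#' For each sample, one axis-aligned rectangle of size
#' `floor(frac_h * H) x floor(frac_w * W)` is set to zero at a uniformly
#' random position, at the same location in every channel; all other entries
#' are unchanged. Uses the current RNG stream.
#'
#' @param x Feature batch array of shape `(C, H, W, N)` (channels, mel bands,
#'   frames, samples).
#' @param cfg An [augment_config].
#' @return The masked array.
#' @export
cutout <- function(x, cfg = augment_config()) {
  d <- dim(x)
  if (length(d) != 4L) stop("`x` must be a (C, H, W, N) array")
  H <- d[2]; W <- d[3]; n <- d[4]
  hcut <- min(H, floor(cfg$cutout_frac[1] * H))
  wcut <- min(W, floor(cfg$cutout_frac[2] * W))
  if (hcut < 1L || wcut < 1L) return(x)
  for (i in seq_len(n)) {
    r0 <- sample.int(H - hcut + 1L, 1L)
    c0 <- sample.int(W - wcut + 1L, 1L)
    x[, r0:(r0 + hcut - 1L), c0:(c0 + wcut - 1L), i] <- 0
  }
  x
}
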