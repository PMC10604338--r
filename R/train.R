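#' Training configuration
#'
#' @param epochs Number of epochs (default 100).
#' @param batch_size Mini-batch size (default 64).
#' @param lr_start,lr_end Initial and final learning rates (defaults 1e-3 and
#'   1e-5).
#' @param class_weight_present Loss weight of the murmur-present class
#'   (default 3; cost-sensitive learning against the majority class).
#' @param seed Integer seed for shuffling, augmentation draws and parameter
#'   initialization.
#' @return A list with class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L,
                         lr_start = 1e-3, lr_end = 1e-5,
                         class_weight_present = 3, seed = 1L) {
  if (lr_end >= lr_start) stop("`lr_end` must be < `lr_start`")
  if (class_weight_present < 1) stop("`class_weight_present` must be >= 1")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr_start = lr_start, lr_end = lr_end,
         class_weight_present = class_weight_present, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Sigmoid-decay learning-rate schedule
#'
#' Logistic interpolation from `lr_start` to `lr_end`:
#' `lr(e) = lr_end + (lr_start - lr_end) * sigmoid(-gamma (e - E/2))` with
#' `gamma = 20/E`, which places epoch 0 within 1% of `lr_start` and the final
#' epoch within 1% of `lr_end`.
#'
#' @param epoch Zero-based epoch index.
#' @param epochs Total number of epochs E.
#' @param lr_start,lr_end Schedule endpoints.
#' @return Learning rate for `epoch`.
#' @export
lr_schedule <- function(epoch, epochs, lr_start = 1e-3, lr_end = 1e-5) {
  gamma <- 20 / epochs
  lr_end + (lr_start - lr_end) * stats::plogis(-gamma * (epoch - epochs / 2))
}

adam_init <- function(params) {
  flat <- unlist(params)
  list(m = 0 * flat, v = 0 * flat, t = 0L)
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gflat <- unlist(grads[names(params)])
  pflat <- unlist(params)
  stopifnot(length(gflat) == length(pflat))
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * gflat
  opt$v <- beta2 * opt$v + (1 - beta2) * gflat^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  pflat <- pflat - lr * mhat / (sqrt(vhat) + eps)
  params <- utils::relist(pflat, params)
  list(params = params, opt = opt)
}

#' Assemble a model-ready dataset from feature tensors
#'
#' Stacks per-recording feature tensors into one array and collects scalar
#' features, murmur labels and patient ids. All tensors must share shape.
#'
#' @param tensors List of [build_feature_tensor()] outputs.
#' @param labels Character vector of per-recording murmur labels
#'   (`Present`/`Unknown`/`Absent`), typically inherited from the patient.
#' @param patient_ids Character vector mapping recordings to patients.
#' @return A list with class `pcg_dataset`: `x` array
#'   `(channels, mel, frames, n)`, `scalars` matrix, `labels`, `patient_ids`.
#' @export
assemble_dataset <- function(tensors, labels, patient_ids) {
  n <- length(tensors)
  stopifnot(n >= 1L, length(labels) == n, length(patient_ids) == n)
  d <- dim(tensors[[1]]$channels) # mel x frames x channels
  x <- array(0, c(d[3], d[1], d[2], n))
  ns <- length(tensors[[1]]$scalars)
  scalars <- matrix(0, ns, n)
  for (i in seq_len(n)) {
    ci <- tensors[[i]]$channels
    if (!identical(dim(ci), d)) stop("feature tensors have differing shapes")
    x[, , , i] <- aperm(ci, c(3, 1, 2))
    if (ns > 0L) scalars[, i] <- tensors[[i]]$scalars
  }
  if (ns > 0L) rownames(scalars) <- names(tensors[[1]]$scalars)
  structure(
    list(x = x, scalars = scalars,
         labels = as.character(labels),
         patient_ids = as.character(patient_ids)),
    class = "pcg_dataset"
  )
}

#' Extract features for a list of patients
#'
#' Runs [build_feature_tensor()] on every recording of every patient
#' (single-instance learning: each recording is one sample carrying its
#' patient's murmur label) and assembles the result.
#'
#' @param patients List of [patient_record] objects with audio attached.
#' @param fs,mel,smoothing Passed to [build_feature_tensor()].
#' @param keep_other Keep recordings at unspecified ("OTHER") auscultation
#'   sites? Default drops them, per-recording.
#' @return A `pcg_dataset` (see [assemble_dataset()]).
#' @export
featurize_patients <- function(patients, fs = feature_set(feature_id = 9),
                               mel = mel_config(),
                               smoothing = smoothing_config(),
                               keep_other = FALSE) {
  tensors <- list(); labels <- character(0); pids <- character(0)
  for (pt in patients) {
    for (rec in pt$recordings) {
      if (!keep_other && rec$site == "OTHER") next
      tensors[[length(tensors) + 1L]] <- build_feature_tensor(rec, fs, mel, smoothing)
      labels <- c(labels, pt$murmur)
      pids <- c(pids, pt$patient_id)
    }
  }
  if (!length(tensors)) stop("no usable recordings in `patients`")
  assemble_dataset(tensors, labels, pids)
}

subset_dataset <- function(ds, idx) {
  structure(
    list(x = ds$x[, , , idx, drop = FALSE],
         scalars = ds$scalars[, idx, drop = FALSE],
         labels = ds$labels[idx], patient_ids = ds$patient_ids[idx]),
    class = "pcg_dataset"
  )
}

#' Train a ReLCNN murmur classifier
#'
#' Single-instance training: every recording is one sample with a binary
#' target (Present = 1, Absent = 0); recordings labeled Unknown carry no
#' binary target and are excluded from the loss (they re-enter at threshold
#' fitting and evaluation). The loss is categorical cross-entropy with weight
#' `class_weight_present` on present-class samples, optimized with Adam under
#' the sigmoid-decay schedule; mixup/cutout fire per batch with their
#' configured probabilities, in training mode only. Scalar features are
#' standardized with training-set moments stored in the model.
#'
#' @param model A [build_relcnn()] model.
#' @param train_ds Training `pcg_dataset`.
#' @param val_ds Optional validation `pcg_dataset`; when supplied, per-epoch
#'   validation weighted accuracy is recorded (with the unknown band refit on
#'   training probabilities each time).
#' @param cfg A [train_config].
#' @param aug An [augment_config], or `NULL` to disable augmentation.
#' @return A list with `model` (trained), `history` (data frame with epoch,
#'   loss, lr and validation weighted accuracy) and `band` (the unknown band
#'   fitted on training probabilities after the final epoch).
#' @export
train_relcnn <- function(model, train_ds, val_ds = NULL,
                         cfg = train_config(), aug = augment_config()) {
  if (!length(train_ds$labels)) stop("empty training set")
  keep <- train_ds$labels != "Unknown"
  fit_ds <- subset_dataset(train_ds, which(keep))
  n <- length(fit_ds$labels)
  if (!n) stop("training set has no Present/Absent recordings")
  y_present <- as.numeric(fit_ds$labels == "Present")

  if (nrow(fit_ds$scalars) > 0L) {
    ctr <- rowMeans(fit_ds$scalars)
    scl <- apply(fit_ds$scalars, 1L, stats::sd)
    scl[!is.finite(scl) | scl < 1e-8] <- 1
    model$scalar_center <- ctr
    model$scalar_scale <- scl
  }
  std_scalars <- function(s) (s - model$scalar_center) / model$scalar_scale

  # per-channel standardization of the dB inputs, fitted on the training set
  xc <- matrix(fit_ds$x, nrow = dim(fit_ds$x)[1])
  model$input_center <- rowMeans(xc)
  iscale <- sqrt(rowMeans((xc - model$input_center)^2))
  iscale[!is.finite(iscale) | iscale < 1e-8] <- 1
  model$input_scale <- iscale
  std_x <- function(x) (x - model$input_center) / model$input_scale

  opt <- adam_init(model$params)
  hist_loss <- numeric(cfg$epochs)
  hist_wa <- rep(NA_real_, cfg$epochs)
  hist_lr <- numeric(cfg$epochs)

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lr <- lr_schedule(epoch, cfg$epochs, cfg$lr_start, cfg$lr_end)
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        xb <- std_x(fit_ds$x[, , , idx, drop = FALSE])
        sb <- std_scalars(fit_ds$scalars[, idx, drop = FALSE])
        yb <- rbind(Present = y_present[idx], Absent = 1 - y_present[idx])
        wb <- 1 + (cfg$class_weight_present - 1) * y_present[idx]
        if (!is.null(aug) && length(idx) >= 2L) {
          if (stats::runif(1) < aug$mixup_prob) {
            mx <- mixup(list(xb, sb), rbind(yb, wb), aug)
            xb <- mx$x[[1]]; sb <- mx$x[[2]]
            yb <- mx$y[1:2, , drop = FALSE]
            wb <- mx$y[3, ]
          }
          if (stats::runif(1) < aug$cutout_prob) {
            xb <- cutout(xb, aug)
          }
        }
        fw <- relcnn_forward(model, xb, sb, training = TRUE)
        model$state <- fw$state
        lo <- weighted_ce(fw$logits, yb, wb)
        if (!is.finite(lo$loss)) {
          stop(sprintf("non-finite loss at epoch %d (lr %.2g)", epoch, lr))
        }
        grads <- relcnn_backward(model, fw$cache, lo$dlogits)
        st <- adam_step(model$params, grads, opt, lr)
        model$params <- st$params
        opt <- st$opt
        losses <- c(losses, lo$loss)
      }
      hist_loss[epoch + 1L] <- mean(losses)
      hist_lr[epoch + 1L] <- lr
      if (!is.null(val_ds)) {
        tr_probs <- predict_recordings(model, train_ds)
        agg_tr <- aggregate_by_patient(tr_probs, train_ds$patient_ids)
        band <- fit_unknown_band(
          agg_tr$prob, patient_labels(train_ds)[names(agg_tr$prob)])
        va_probs <- predict_recordings(model, val_ds)
        agg <- aggregate_by_patient(va_probs, val_ds$patient_ids)
        pred <- vapply(agg$prob, classify_patient, character(1), band = band)
        truth <- patient_labels(val_ds)
        cm <- murmur_confusion(pred, truth[names(agg$prob)])
        hist_wa[epoch + 1L] <- weighted_accuracy(cm)
      }
    }
  })

  tr_probs <- predict_recordings(model, train_ds)
  agg <- aggregate_by_patient(tr_probs, train_ds$patient_ids)
  truth <- patient_labels(train_ds)
  band <- fit_unknown_band(agg$prob, truth[names(agg$prob)])

  list(
    model = model,
    history = data.frame(epoch = seq_len(cfg$epochs) - 1L, loss = hist_loss,
                         lr = hist_lr, val_weighted_accuracy = hist_wa),
    band = band
  )
}

#' Per-recording murmur probabilities
#'
#' Runs the model in evaluation mode and returns the probability of the
#' present class for each recording.
#'
#' @param model A trained [build_relcnn()] model.
#' @param ds A `pcg_dataset`.
#' @param batch_size Forward-pass batch size.
#' @return Numeric vector of murmur probabilities, one per recording.
#' @export
predict_recordings <- function(model, ds, batch_size = 64L) {
  n <- length(ds$labels)
  std <- (ds$scalars - model$scalar_center) / model$scalar_scale
  probs <- numeric(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    xb <- (ds$x[, , , idx, drop = FALSE] - model$input_center) /
      model$input_scale
    fw <- relcnn_forward(model, xb, std[, idx, drop = FALSE],
                         training = FALSE)
    probs[idx] <- fw$probs[1L, ]
  }
  probs
}

# patient id -> murmur label lookup for a dataset
patient_labels <- function(ds) {
  tapply(ds$labels, ds$patient_ids, function(l) l[1])
}

# per-patient max-probability aggregation, named by patient id
aggregate_by_patient <- function(probs, patient_ids) {
  agg <- tapply(probs, patient_ids, max)
  list(prob = agg)
}
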