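# Shared reduced-size configurations and memoized fixtures. Problem sizes are
# scaled for quick unit runs; the pipeline itself is identical to full scale.

reduced_mel <- function() {
  mel_config(window = 256L, hop = 256L, n_mels = 24L, rate = 4000)
}

reduced_feature_set <- function(feature_id = 9) {
  feature_set(feature_id = feature_id, sample_sec = 10)
}

reduced_relcnn_config <- function(mha_dim = 16L, mha_heads = 8L, ...) {
  relcnn_config(block_filters = c(8, 8, 12, 12, 16, 16, 8, 8, 8),
                mha_dim = mha_dim, mha_heads = mha_heads, ...)
}

tiny_relcnn_config <- function(mha_dim = 8L, mha_heads = 2L, ...) {
  relcnn_config(block_filters = c(2, 2, 3, 3, 4, 4, 2, 2, 2),
                mha_dim = mha_dim, mha_heads = mha_heads, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

# memoized synthetic cohort on disk (regenerated once per test run)
fixture_cohort <- function(n_patients, prevalence, seed, n_seconds = 20,
                           snr_db = 25, sites = 1:4, unknown_fraction = 0,
                           murmur_amplitude = 0.4) {
  key <- paste("cohort", n_patients, prevalence, seed, n_seconds, snr_db,
               paste(range(sites), collapse = "-"), unknown_fraction,
               murmur_amplitude, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("mcheart_", key))
    unlink(dir, recursive = TRUE)
    man <- generate_cohort(n_patients, prevalence, sites_per_patient = sites,
                           seed = seed, out_dir = dir, n_seconds = n_seconds,
                           snr_db = snr_db,
                           unknown_fraction = unknown_fraction,
                           murmur_amplitude = murmur_amplitude)
    .fixture_cache[[key]] <- list(dir = dir, manifest = man)
  }
  .fixture_cache[[key]]
}

# memoized matched murmur-absent/present recordings (paired seeds)
fixture_paired_recordings <- function(n_pairs, seed0 = 900, n_seconds = 20) {
  key <- paste("pairs", n_pairs, seed0, n_seconds, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    absent <- present <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      absent[[i]] <- generate_recording(
        synth_spec(n_seconds = n_seconds, murmur = "none", seed = seed0 + i))
      present[[i]] <- generate_recording(
        synth_spec(n_seconds = n_seconds, murmur = "systolic", seed = seed0 + i))
    }
    .fixture_cache[[key]] <- list(absent = absent, present = present)
  }
  .fixture_cache[[key]]
}

# run the whole pipeline (simulate -> split -> featurize -> train -> evaluate)
# at a chosen size; used by the end-to-end and determinism tests
run_pipeline <- function(n_patients, epochs, seed, out_dir,
                         prevalence = 0.3, snr_db = 30,
                         murmur_amplitude = 0.5) {
  unlink(out_dir, recursive = TRUE)
  manifest <- generate_cohort(n_patients, prevalence, sites_per_patient = 1:4,
                              seed = seed, out_dir = out_dir,
                              n_seconds = 20, snr_db = snr_db,
                              murmur_amplitude = murmur_amplitude)
  patients <- read_cohort(out_dir)
  split <- stratified_split(patients, split_spec(0.8, seed = seed + 1L))
  mel <- reduced_mel()
  fs <- reduced_feature_set(9)
  train_ds <- featurize_patients(split$train, fs, mel)
  val_ds <- featurize_patients(split$validation, fs, mel)
  model <- with_seed_local(seed + 2L, build_relcnn(reduced_relcnn_config(),
                                                   dim(train_ds$x)[1:3]))
  fit <- train_relcnn(model, train_ds, val_ds,
                      train_config(epochs = epochs, batch_size = 32L,
                                   seed = seed + 3L),
                      augment_config())
  report <- evaluate_model(fit$model, val_ds, fit$band)
  list(manifest = manifest, train_ds = train_ds, val_ds = val_ds,
       fit = fit, report = report)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# sample index ranges covered by segments with the given labels
segment_sample_mask <- function(segments, labels, n, rate = 4000) {
  mask <- rep(FALSE, n)
  sel <- segments[segments$label %in% labels, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    i0 <- floor(sel$start[i] * rate) + 1L
    i1 <- min(n, floor(sel$end[i] * rate))
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  mask
}

# envelope -> boundary mask via the standard pipeline stages
boundary_mask_for <- function(samples, rate = 4000, smooth_n = NULL, ...) {
  env <- hilbert_envelope(butterworth_lowpass(normalize_amplitude(samples),
                                              rate), rate)
  if (!is.null(smooth_n)) env <- smooth_moving_average(env, smooth_n)
  detect_fhs_boundaries(env, compute_threshold(env), ...)
}
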