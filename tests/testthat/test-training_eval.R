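test_that("weighted accuracy matches hand evaluation and an exact oracle", {
  cm <- function(...) matrix(c(...), 3, 3, byrow = TRUE)
  # perfect diagonal scores 1 for any positive counts
  expect_equal(weighted_accuracy(diag(c(4, 2, 9))), 1.0)
  # worked example: mPP=2, mUU=1, mAA=10, mAP=1
  m <- matrix(0, 3, 3); m[1, 1] <- 2; m[2, 2] <- 1; m[3, 3] <- 10; m[3, 1] <- 1
  expect_equal(weighted_accuracy(m), 23 / 28)
  # everything predicted Absent against experts 1P/1U/1A
  all_absent <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_equal(weighted_accuracy(all_absent), 1 / 9)

  # independent oracle: explicit weighted sums on 50 random integer matrices;
  # integer numerator/denominator are exact, so the quotient is bit-identical
  set.seed(14)
  for (i in 1:50) {
    m <- matrix(rpois(9, 5), 3, 3)
    if (sum(m) == 0) m[2, 2] <- 1
    w <- c(5, 3, 1)
    num <- 5 * m[1, 1] + 3 * m[2, 2] + m[3, 3]
    den <- sum(rep(w, each = 3) * m)
    expect_identical(weighted_accuracy(m), num / den)
    # invariance under positive integer scaling
    expect_equal(weighted_accuracy(3L * m), weighted_accuracy(m))
  }
  expect_error(weighted_accuracy(matrix(0, 3, 3)), "all-zero")
})

test_that("the outcome score matches hand evaluation", {
  expect_equal(outcome_score(1, 0, 0, 1), 1.0)
  expect_equal(outcome_score(10, 3, 5, 20), 70 / 98)
  expect_equal(outcome_score(0, 1, 1, 0), 0.0)
  expect_equal(outcome_score(rbind(c(10, 3), c(5, 20))), 70 / 98)
  set.seed(15)
  for (i in 1:50) {
    v <- rpois(4, 4); if (sum(v) == 0) v[1] <- 1
    num <- 5 * v[1] + v[4]
    den <- 5 * (v[1] + v[3]) + v[2] + v[4]
    expect_identical(outcome_score(v[1], v[2], v[3], v[4]), num / den)
  }
  expect_error(outcome_score(0, 0, 0, 0), "empty|undefined")
})

test_that("binary metrics agree with brute-force pair counting", {
  # perfectly separated scores
  bm <- binary_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(bm$auroc, 1.0)
  expect_equal(bm$accuracy, 1.0)
  expect_equal(bm$f_measure, 1.0)
  expect_equal(bm$auprc, 1.0)

  # all-tied scores give chance-level AUROC
  expect_equal(binary_metrics(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auroc, 0.5)

  # brute-force oracle: P(score_pos > score_neg) + 0.5 P(tie)
  set.seed(16)
  for (i in 1:20) {
    n <- 10
    lab <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes present
    sc <- round(runif(n), 2)
    pos <- sc[lab == 1]; neg <- sc[lab == 0]
    pairs <- outer(pos, neg, `-`)
    ora <- (sum(pairs > 0) + 0.5 * sum(pairs == 0)) / length(pairs)
    expect_equal(binary_metrics(sc, lab)$auroc, ora)
  }
  expect_error(binary_metrics(c(0.1, 0.9), c(1, 1)), "one class")
})

test_that("patient aggregation takes the maximum site probability", {
  expect_equal(aggregate_patient(c(0.2, 0.9, 0.4)), 0.9)
  expect_equal(aggregate_patient(0.37), 0.37)
  set.seed(17)
  for (i in 1:20) {
    v <- runif(sample(1:5, 1))
    expect_equal(aggregate_patient(v), max(v))
  }
  expect_error(aggregate_patient(numeric(0)), "no per-site")
})

test_that("the unknown band classifies by its two thresholds", {
  band <- unknown_band(0.3, 0.7)
  expect_equal(classify_patient(0.99, band), "Present")
  expect_equal(classify_patient(0.5, band), "Unknown")
  expect_equal(classify_patient(0.1, band), "Absent")
  expect_equal(classify_patient(0.7, band), "Present") # boundary: p >= t_high
  expect_equal(classify_patient(0.3, band), "Unknown") # boundary: p >= t_low
  expect_error(unknown_band(0.8, 0.2), "t_low")
})

test_that("band fitting maximizes training weighted accuracy", {
  # degenerate: all Absent with low probabilities; tie-break -> widest Absent
  b <- fit_unknown_band(c(0.01, 0.05, 0.09), rep("Absent", 3))
  expect_gt(b$t_low, 0.09)
  expect_equal(b$t_low, 1); expect_equal(b$t_high, 1)

  # well-separated three classes recover a band straddling 0.5
  probs <- c(0.92, 0.88, 0.95, 0.51, 0.49, 0.08, 0.12, 0.05)
  labs <- c("Present", "Present", "Present", "Unknown", "Unknown",
            "Absent", "Absent", "Absent")
  b2 <- fit_unknown_band(probs, labs)
  expect_gt(b2$t_low, 0.12); expect_lte(b2$t_low, 0.49)
  expect_gt(b2$t_high, 0.51); expect_lte(b2$t_high, 0.88)
  pred <- vapply(probs, classify_patient, character(1), band = b2)
  expect_equal(weighted_accuracy(murmur_confusion(pred, labs)), 1.0)

  # oracle: with probabilities on the 0.01 lattice, a 10x finer grid cannot
  # improve on the 0.01 grid search
  set.seed(18)
  for (i in 1:5) {
    p <- round(runif(30), 2)
    l <- sample(c("Present", "Unknown", "Absent"), 30, replace = TRUE)
    score_of <- function(band) {
      pr <- vapply(p, classify_patient, character(1), band = band)
      weighted_accuracy(murmur_confusion(pr, l))
    }
    coarse <- score_of(fit_unknown_band(p, l, grid = 0.01))
    fine <- score_of(fit_unknown_band(p, l, grid = 0.001))
    expect_equal(coarse, fine, tolerance = 1e-12)
  }
  expect_error(fit_unknown_band(numeric(0), character(0)), "empty")
})

test_that("the learning-rate schedule hits both endpoints", {
  E <- 100
  expect_equal(lr_schedule(0, E), 1e-3, tolerance = 0.01)
  expect_equal(lr_schedule(E - 1, E), 1e-5, tolerance = 0.01)
  lrs <- lr_schedule(0:(E - 1), E)
  expect_true(all(diff(lrs) < 0)) # strictly decreasing
  expect_equal(lr_schedule(E / 2, E), (1e-3 + 1e-5) / 2, tolerance = 1e-9)
})

test_that("present-class samples incur the configured loss multiple", {
  set.seed(19)
  logits <- matrix(rnorm(2), 2, 1)
  y <- matrix(c(1, 0), 2, 1)
  base <- mcheart:::weighted_ce(logits, y, 1)$loss
  expect_equal(mcheart:::weighted_ce(logits, y, 3)$loss, 3 * base)
})

test_that("confusion pipeline conserves patients and scores oracles", {
  labs <- c("Present", "Present", "Unknown", "Absent", "Absent", "Absent")
  # an oracle emitting the true class probabilities scores 1
  oracle_p <- c(0.95, 0.99, 0.5, 0.02, 0.03, 0.01)
  band <- unknown_band(0.25, 0.75)
  pred <- vapply(oracle_p, classify_patient, character(1), band = band)
  cmx <- murmur_confusion(pred, labs)
  expect_equal(sum(cmx), length(labs)) # patient count conserved
  expect_equal(weighted_accuracy(cmx), 1.0)

  # a constant-probability model scores as the induced single-class column
  const_pred <- vapply(rep(0.5, 6), classify_patient, character(1), band = band)
  cmc <- murmur_confusion(const_pred, labs)
  expect_equal(weighted_accuracy(cmc),
               3 / (5 * 2 + 3 * 1 + 3)) # all Unknown: 3*mUU over weights
  expect_equal(constant_baseline_wa(labs),
               max(5 * 2, 3 * 1, 3) / (5 * 2 + 3 * 1 + 3))
})

test_that("a reduced model separates a strongly murmuring cohort", {
  fx <- fixture_cohort(20, 0.5, seed = 55, n_seconds = 20, snr_db = 40,
                       sites = 2:4, murmur_amplitude = 0.8)
  pats <- read_cohort(fx$dir)
  ds <- featurize_patients(pats, reduced_feature_set(9), reduced_mel())
  model <- with_seed_local(1, build_relcnn(reduced_relcnn_config(),
                                           dim(ds$x)[1:3]))
  fit <- train_relcnn(model, ds, val_ds = NULL,
                      train_config(epochs = 10, batch_size = 8, seed = 2),
                      aug = NULL)
  probs <- predict_recordings(fit$model, ds)
  acc <- mean((probs >= 0.5) == (ds$labels == "Present"))
  expect_gte(acc, 0.95)

  # evaluation report carries the standard metric columns
  rep <- evaluate_model(fit$model, ds, fit$band)
  expect_true(all(c("auroc", "auprc", "f_measure", "accuracy",
                    "weighted_accuracy", "outcome_score") %in% names(rep)))
  expect_equal(sum(rep$confusion), length(unique(ds$patient_ids)))
  expect_equal(dim(rep$confusion), c(3L, 3L))
})
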