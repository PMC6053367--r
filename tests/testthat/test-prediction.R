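test_that("mds_reduce equals the classical-MDS eigendecomposition up to sign", {
  set.seed(40)
  for (rep in 1:5) {
    mat <- matrix(rnorm(80 * 30), 80, 30)
    k <- 5
    scores <- mds_reduce(mat, k)
    # oracle: eigendecomposition of the double-centred squared-distance
    # matrix (classical metric MDS)
    oracle <- cmdscale(dist(t(mat)), k = k)
    for (j in seq_len(k)) {
      expect_gt(abs(cor(scores[, j], oracle[, j])), 1 - 1e-8)
      expect_equal(abs(scores[, j]), abs(oracle[, j]), tolerance = 1e-6)
    }
  }
  # identical samples get identical coordinates
  m2 <- cbind(matrix(rnorm(50 * 10), 50, 10))
  m2 <- cbind(m2, m2[, 3])
  sc <- mds_reduce(m2, 4)
  expect_equal(sc[11, ], sc[3, ], ignore_attr = TRUE)
  # rank limit: components beyond the input rank explain ~0 variance
  r2 <- outer(rnorm(40), rnorm(12)) + outer(rnorm(40), rnorm(12))
  sc2 <- mds_reduce(r2, 5)
  ve <- attr(sc2, "var_explained")
  expect_lt(sum(ve[3:5]), 1e-12)
  expect_error(mds_reduce(r2, 12), "n_components")
})

test_that("a zero-penalty L1 fit equals least squares on toy data", {
  set.seed(41)
  x <- matrix(rnorm(100 * 4), 100, 4)
  y <- 2 + x %*% c(1, -0.5, 0.3, 0) + rnorm(100, 0, 0.1)
  g <- glmnet::glmnet(x, y, lambda = 0, thresh = 1e-12)
  ls <- lm(y ~ x)
  expect_equal(as.numeric(coef(g)), unname(coef(ls)), tolerance = 1e-4)
})

test_that("cv_age_prediction saturates on clean signal and nulls out on noise", {
  set.seed(42)
  ages <- runif(100, 20, 70)
  feats <- cbind(ages, matrix(rnorm(100 * 9), 100, 9))
  cv <- cv_age_prediction(feats, ages, n_repeats = 3, seed = 1)
  expect_gt(cv$accuracy, 0.99)

  # features independent of age: no optimistic bias over 20 seeds (single CV
  # repeat per seed to bound runtime). The procedure is conservatively
  # biased under the null: with the penalty shrinking the model towards the
  # intercept, each fold's prediction is its training-fold mean, which ranks
  # inversely to the held-out ages, so the null expectation of the Spearman
  # accuracy is slightly negative rather than zero.
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    f0 <- matrix(rnorm(100 * 10), 100, 10)
    cv_age_prediction(f0, ages, n_repeats = 1, seed = s)$accuracy
  }, numeric(1))
  expect_lt(mean(accs), 0.05)

  expect_error(cv_age_prediction(feats, rep(50, 100), n_repeats = 1),
               "constant")
  expect_error(cv_age_prediction(feats[, 1, drop = FALSE], ages),
               "2 feature columns")
})

test_that("old/young classification is exact on separable classes", {
  set.seed(43)
  ages <- c(runif(40, 20, 30), runif(40, 60, 70))
  feats <- cbind(ages + rnorm(80, 0, 0.1), matrix(rnorm(80 * 5), 80, 5))
  oc <- old_young_classification(feats, ages, quantile = 0.25,
                                 n_repeats = 3, seed = 2)
  expect_equal(oc$accuracy, 1)
  # median split uses every sample
  oc2 <- old_young_classification(feats, ages, quantile = 0.5,
                                  n_repeats = 2, seed = 3)
  expect_equal(length(oc2$labels), 80)
  expect_error(old_young_classification(feats[1:20, ], ages[1:20],
                                        quantile = 0.1),
               "8 samples")
})

test_that("robust-event selection is monotone and null-safe", {
  expect_error(select_robust_events(matrix(0.5, 2, 2),
                                    data.frame(age = 1:2, gender = 0:1),
                                    n_runs = 5, min_detections = 8),
               "min_detections")

  w <- small_world(seed = 44, n = 120, n_events = 120, frac = 0.25,
                   noise_sd = 0.2, effect_size = 0.03)
  r10 <- select_robust_events(w$psi, w$cohort, n_runs = 10,
                              min_detections = 10, seed = 1,
                              n_factors = 10, n_perm = 50)
  r1 <- select_robust_events(w$psi, w$cohort, n_runs = 10,
                             min_detections = 1, seed = 1,
                             n_factors = 10, n_perm = 50)
  expect_true(all(r10 %in% r1))
  # strong planted effects are found in every run
  flagged <- w$truth$events$event_id[w$truth$events$is_age_assoc]
  expect_gt(mean(flagged %in% r10), 0.8)

  # global-null world: robust set empty
  w0 <- small_world(seed = 45, n = 120, n_events = 120, frac = 0)
  r0 <- select_robust_events(w0$psi, w0$cohort, n_runs = 4,
                             min_detections = 3, seed = 2,
                             n_factors = 10, n_perm = 50)
  expect_length(r0, 0)
})

test_that("relative-age z-scores are centred and aligned", {
  w <- small_world(seed = 46, n = 100, n_events = 80, frac = 0.3,
                   noise_sd = 0.2, effect_size = 0.03, missing_rate = 0)
  events <- w$truth$events$event_id[w$truth$events$is_age_assoc]
  # scoring the training samples themselves: z has mean ~0, sd ~1 per round
  rep_ <- relative_age_zscores(w$psi, w$cohort$age, w$psi, events,
                               n_rounds = 5, seed = 3)
  expect_equal(colMeans(rep_$z), rep(0, 5), tolerance = 1e-10)
  expect_equal(apply(rep_$z, 2, sd), rep(1, 5), tolerance = 1e-10)

  expect_error(relative_age_zscores(w$psi, w$cohort$age,
                                    w$psi[1:10, ], events, n_rounds = 2),
               "absent from test")

  pairs <- data.frame(young = colnames(w$psi)[1], old = colnames(w$psi)[2])
  cmp <- compare_relative_ages(rep_, pairs)
  expect_equal(nrow(cmp), 1)
  expect_identical(cmp$old_called_older,
                   median(rep_$z[2, ]) > median(rep_$z[1, ]))
})
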