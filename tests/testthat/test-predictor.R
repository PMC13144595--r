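# The feed-forward classifier: learning behaviour, determinism, dropout and
# augmentation contracts, checkpoint restoration, serialisation.

test_that("the model learns a separable single-feature problem", {
  spec <- cohort_spec(600, c(y = 0.5), n_continuous = 1L, n_categorical = 0L,
                      effect_sizes = list(cont = 8, cat = list()), seed = 2)
  co <- generate_cohort(spec)
  parts <- split3(co, seed = 3)
  m <- train_model(parts$train, parts$valid, "y", tiny_config(), seed = 4)
  p <- predict_deterministic(m, parts$valid)
  expect_gt(auc(parts$valid$labels[, "y"], p), 0.95)
})

test_that("no-signal data yields chance-level AUC and near-constant output", {
  spec <- cohort_spec(600, c(y = 0.3), seed = 8,
                      effect_sizes = list(cont = rep(0, 8),
                                          cat = rep(list(rep(0, 3)), 2)))
  co <- generate_cohort(spec)
  parts <- split3(co, seed = 9)
  m <- train_model(parts$train, parts$valid, "y", tiny_config(), seed = 10)
  fresh <- generate_cohort(cohort_spec(2000, c(y = 0.3), seed = 99,
                                       effect_sizes = list(cont = rep(0, 8),
                                                           cat = rep(list(rep(0, 3)), 2))))
  p <- predict_deterministic(m, fresh)
  expect_equal(auc(fresh$labels[, "y"], p), 0.5, tolerance = 0.06)
  # cross-entropy optimum is the event rate, so output hovers near it
  expect_equal(mean(p), 0.3, tolerance = 0.1)
  expect_lt(sd(p), 0.15)
})

test_that("training is deterministic given config and seed", {
  co <- make_cohort(300, seed = 14)
  parts <- split3(co, seed = 15)
  m1 <- train_model(parts$train, parts$valid, "y",
                    tiny_config(dropout_rate = 0.2), seed = 16)
  m2 <- train_model(parts$train, parts$valid, "y",
                    tiny_config(dropout_rate = 0.2), seed = 16)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  m3 <- train_model(parts$train, parts$valid, "y",
                    tiny_config(dropout_rate = 0.2), seed = 17)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("single-class training labels are rejected", {
  co <- make_cohort(200, seed = 20)
  parts <- split3(co, seed = 21)
  bad <- parts$train
  bad$labels[, "y"] <- 1L
  expect_error(train_model(bad, parts$valid, "y", tiny_config()),
               "single-class")
})

test_that("the restored checkpoint is at least as good as the final epoch", {
  fit <- fixture_fit()
  expect_lte(fit$model$best_valid_loss,
             fit$model$history$valid_loss[nrow(fit$model$history)])
  expect_equal(fit$model$best_valid_loss,
               min(fit$model$history$valid_loss))
})

test_that("deterministic prediction is repeatable, bounded, and dropout-free", {
  fit <- fixture_fit()
  p1 <- predict_deterministic(fit$model, fit$parts$independent)
  p2 <- predict_deterministic(fit$model, fit$parts$independent)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("stochastic prediction varies with seed and collapses at rate 0", {
  fit <- fixture_fit()
  s1 <- predict_stochastic(fit$model, fit$parts$independent, seed = 1)
  s1b <- predict_stochastic(fit$model, fit$parts$independent, seed = 1)
  s2 <- predict_stochastic(fit$model, fit$parts$independent, seed = 2)
  expect_identical(s1, s1b)
  expect_false(identical(s1, s2))

  m0 <- train_model(fit$parts$train, fit$parts$valid, "y",
                    tiny_config(dropout_rate = 0), seed = 30)
  expect_warning(s0 <- predict_stochastic(m0, fit$parts$independent, seed = 3),
                 "collapses")
  expect_identical(s0, predict_deterministic(m0, fit$parts$independent))
})

test_that("the MC mean is stable across independent large sample sets", {
  fit <- fixture_fit()
  sub <- subset_cohort(fit$parts$independent, 1:20)
  a <- mc_dropout_predict(fit$model, sub, n_samples = 2000, seed = 1)
  b <- mc_dropout_predict(fit$model, sub, n_samples = 2000, seed = 2)
  # CLT: row means agree within a few MC standard errors
  se <- sqrt(rowMeans((a$samples - a$mean_prediction)^2) / 2000)
  expect_true(all(abs(a$mean_prediction - b$mean_prediction) < 6 * se + 1e-8))
})

test_that("augmentation respects domains and adds the nominal variance", {
  co <- make_cohort(4000, seed = 33)
  id_policy <- augmentation_policy(gaussian_sd = 0, jitter_sd = 0,
                                   cat_resample = 0)
  expect_identical(augment_features(co$features, id_policy, seed = 1),
                   co$features)
  noisy <- augment_features(co$features,
                            augmentation_policy(gaussian_sd = 1), seed = 2)
  dv <- var(noisy$cont_1) - var(co$features$cont_1)
  expect_equal(dv, 1, tolerance = 0.15)
  resampled <- augment_features(co$features,
                                augmentation_policy(cat_resample = 0.5),
                                seed = 3)
  expect_true(all(resampled$cat_1 %in% sort(unique(co$features$cat_1))))
  again <- augment_features(co$features,
                            augmentation_policy(gaussian_sd = 1), seed = 2)
  expect_identical(noisy, again)
})

test_that("a model round-trips through its JSON serialisation", {
  fit <- fixture_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit$model, path)
  back <- read_model(path)
  expect_equal(back$weights, fit$model$weights, tolerance = 1e-12)
  expect_equal(predict_deterministic(back, fit$parts$independent),
               predict_deterministic(fit$model, fit$parts$independent),
               tolerance = 1e-12)
})
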