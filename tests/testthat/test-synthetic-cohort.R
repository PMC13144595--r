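# Synthetic cohort generation: intercept calibration, prevalence control,
# splitting arithmetic, determinism, covariate shift, CSV/YAML round-trips.

null_effects <- function(n_cont = 8L, n_cat = 2L, n_lev = 3L) {
  list(cont = rep(0, n_cont), cat = rep(list(rep(0, n_lev)), n_cat))
}

test_that("intercept calibration recovers the closed-form logit when effects vanish", {
  s <- cohort_spec(100, c(y = 0.5), effect_sizes = null_effects())
  expect_equal(calibrate_intercept(s, "y"), 0, tolerance = 1e-6)
  s22 <- cohort_spec(100, c(y = 0.22), effect_sizes = null_effects())
  expect_equal(calibrate_intercept(s22, "y"), log(0.22 / 0.78),
               tolerance = 1e-6)
})

test_that("calibrated intercept hits the target prevalence under nonzero effects", {
  # Monte-Carlo oracle: fresh covariate draws, independent of the calibration
  # sample, must reproduce the marginal within 0.005
  s <- cohort_spec(100, c(y = 0.42), seed = 3)
  b0 <- calibrate_intercept(s, "y")
  big <- generate_cohort(cohort_spec(1e6, c(y = 0.42), seed = 888))
  expect_equal(mean(big$true_prob[, "y"]), 0.42, tolerance = 0.005)
  expect_lt(abs(plogis(b0)), 1) # sanity: finite root
})

test_that("label noise is folded into the prevalence target", {
  s <- cohort_spec(30000, c(y = 0.22), label_noise = 0.1, seed = 5)
  co <- generate_cohort(s)
  se <- sqrt(0.22 * 0.78 / 30000)
  expect_equal(mean(co$labels[, "y"]), 0.22, tolerance = 3 * se)
})

test_that("unreachable prevalence under label noise errors", {
  s <- cohort_spec(100, c(y = 0.05), label_noise = 0.2,
                   effect_sizes = null_effects())
  expect_error(calibrate_intercept(s, "y"), "unreachable")
})

test_that("empirical prevalence converges to the target at n = 20,000", {
  co <- generate_cohort(ntcp_cohort_spec(20000, seed = 7))
  targets <- c(dysphagia = 0.22, xerostomia = 0.42)
  for (ep in names(targets)) {
    se <- sqrt(targets[ep] * (1 - targets[ep]) / 20000)
    expect_lt(abs(mean(co$labels[, ep]) - targets[[ep]]), 3 * se)
  }
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_cohort(cohort_spec(300, c(y = 0.3), seed = 9))
  b <- generate_cohort(cohort_spec(300, c(y = 0.3), seed = 9))
  expect_identical(a$features, b$features)
  expect_identical(a$labels, b$labels)
  expect_identical(cohort_checksum(a), cohort_checksum(b))
  c2 <- generate_cohort(cohort_spec(300, c(y = 0.3), seed = 10))
  expect_false(identical(a$labels, c2$labels))
})

test_that("extreme prevalence target gives nearly all-1 labels", {
  s <- cohort_spec(2000, c(y = 0.999), effect_sizes = null_effects(), seed = 2)
  co <- generate_cohort(s)
  expect_gt(mean(co$labels[, "y"]), 0.99)
})

test_that("split sizes follow round-half-to-even and study arithmetic", {
  co <- generate_cohort(cohort_spec(1205, c(y = 0.22), seed = 1))
  sp <- split_cohort(co, 0.8, seed = 1)
  expect_equal(cohort_size(sp$development), 964)
  expect_equal(cohort_size(sp$independent_validation), 241)

  co2 <- generate_cohort(cohort_spec(340, c(y = 0.24), seed = 1))
  sp2 <- split_cohort(co2, 0.75, seed = 1)
  expect_equal(cohort_size(sp2$development), 255)
  expect_equal(cohort_size(sp2$independent_validation), 85)

  co3 <- generate_cohort(cohort_spec(10, c(y = 0.4), seed = 1))
  sp3 <- split_cohort(co3, 0.8, seed = 1)
  expect_equal(cohort_size(sp3$development), 8)

  inner <- inner_split(sp$development, 0.8, seed = 2)
  expect_equal(cohort_size(inner$train), 771)
  expect_equal(cohort_size(inner$valid), 193)
})

test_that("splits are disjoint, exhaustive, and seed-reproducible", {
  co <- make_cohort(200, seed = 4)
  sp <- split_cohort(co, 0.8, seed = 5)
  ids <- c(sp$development$patient_id, sp$independent_validation$patient_id)
  expect_setequal(ids, co$patient_id)
  expect_length(intersect(sp$development$patient_id,
                          sp$independent_validation$patient_id), 0)
  sp_again <- split_cohort(co, 0.8, seed = 5)
  expect_identical(sp$development$patient_id, sp_again$development$patient_id)
  sp_other <- split_cohort(co, 0.8, seed = 6)
  expect_false(identical(sp$development$patient_id,
                         sp_other$development$patient_id))
  expect_error(split_cohort(co, 0.0001), "empty partition")
})

test_that("true_prob is Bayes-optimal: no classifier beats it on fresh data", {
  fit <- fixture_fit()
  fresh <- generate_cohort(cohort_spec(4000, c(y = 0.3), seed = 777))
  auc_model <- auc(fresh$labels[, "y"], predict_deterministic(fit$model, fresh))
  auc_oracle <- auc(fresh$labels[, "y"], fresh$true_prob[, "y"])
  expect_lte(auc_model, auc_oracle + 0.02)
})

test_that("zero covariate shift is the identity; mean shift moves features", {
  co <- make_cohort(500, seed = 6)
  same <- apply_covariate_shift(co, list(mean = 0, scale = 1),
                                seed = derive_seed(co$spec$seed, "shift-labels"))
  expect_equal(same$features, co$features)
  expect_equal(same$true_prob, co$true_prob)
  shifted <- apply_covariate_shift(co, list(mean = 3))
  d <- colMeans(shifted$features[, 1:8]) - colMeans(co$features[, 1:8])
  expect_equal(unname(d), rep(3, 8), tolerance = 1e-10)
  expect_error(apply_covariate_shift(co, list(mean = c(1, 2))), "dimensions")
})

test_that("ensemble variance is stochastically larger out-of-distribution", {
  # mild shift: strong shifts saturate the output sigmoid and collapse
  # member disagreement, so +0.5 SD on every covariate is the OOD condition
  co <- make_cohort(2500, seed = 21)
  sp <- split_cohort(co, 0.8, seed = 1)
  parts <- inner_split(sp$development, 0.8, seed = 2)
  ens <- train_ensemble(parts$train, parts$valid, "y", n_members = 5,
                        base_config = tiny_config(), seed = 31)
  ind <- subset_cohort(sp$independent_validation, 1:500)
  shifted <- apply_covariate_shift(ind, list(mean = 0.5))
  v_in <- sample_variance(ensemble_predict(ens, ind))$value
  v_out <- sample_variance(ensemble_predict(ens, shifted))$value
  expect_lt(wilcox.test(v_out, v_in, alternative = "greater")$p.value, 0.05)
})

test_that("cohort and spec round-trip through CSV / YAML", {
  co <- make_cohort(80, seed = 12)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, csv)
  back <- read_cohort_csv(csv, spec = co$spec)
  expect_equal(back$labels, co$labels)
  expect_equal(back$true_prob, co$true_prob, tolerance = 1e-12)
  expect_equal(back$features, co$features, tolerance = 1e-12)

  yml <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(co$spec, yml)
  spec_back <- read_cohort_spec(yml)
  expect_identical(generate_cohort(spec_back)$labels, co$labels)
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(1, c(y = 0.3)), "n_patients")
  expect_error(cohort_spec(10, c(0.3)), "named")
  expect_error(cohort_spec(10, c(y = 1.2)), "strictly in")
  expect_error(cohort_spec(10, c(y = 0.3), label_noise = 0.5), "label_noise")
})
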