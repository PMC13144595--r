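# Discrimination, calibration, DeLong, sparsification, bootstrap: unit
# examples plus dual-route checks against brute-force or pROC oracles.

test_that("auc matches hand examples and the degenerate cases", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  y <- c(0, 1, 1, 0, 1)
  expect_equal(auc(y, y), 1)
  expect_error(auc(c(1, 1, 1), c(0.1, 0.2, 0.3)), "both classes")
})

test_that("auc equals the exhaustive pair-counting oracle on random instances", {
  set.seed(501)
  for (trial in 1:100) {
    n <- sample(4:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    s <- if (trial %% 2 == 0) round(runif(n), 1) else runif(n) # force ties half the time
    expect_equal(auc(y, s), pair_count_auc(y, s), tolerance = 1e-12)
  }
})

test_that("accuracy counts threshold agreements", {
  expect_equal(accuracy(c(0, 1), c(0, 1), 0.5), 1)
  expect_equal(accuracy(c(0, 1), c(1, 0), 0.5), 0)
  expect_equal(accuracy(c(0, 1, 1, 0), c(0.4, 0.6, 0.4, 0.6), 0.5), 0.5)
})

test_that("the Youden threshold maximises J with lowest-threshold ties", {
  t1 <- youden_threshold(c(0, 0, 1, 1), c(0.1, 0.2, 0.7, 0.9))
  expect_gt(t1, 0.2)
  expect_lte(t1, 0.7)
  expect_equal(t1, 0.45) # midpoint of the separating gap
  # random balanced scores: optimal J stays near zero
  set.seed(52)
  y <- rep(0:1, each = 250)
  s <- runif(500)
  t_opt <- youden_threshold(y, s)
  j <- mean(s[y == 1] >= t_opt) + mean(s[y == 0] < t_opt) - 1
  expect_lt(j, 0.2)
  # ties -> lowest maximiser
  expect_equal(youden_threshold(c(0, 1, 0, 1), c(0.1, 0.9, 0.1, 0.9)), 0.5)
})

test_that("delong_test agrees with pROC and handles the degenerate case", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(80, 1, 0.4)
  a <- rnorm(80) + y
  b <- rnorm(80)
  mine <- delong_test(y, a, b)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$auc_a, as.numeric(pROC::auc(pROC::roc(y, a, quiet = TRUE))),
               tolerance = 1e-12)

  same <- delong_test(y, a, a)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  expect_error(delong_test(y, a, b[-1]), "identical length")
})

test_that("delong_test rejects informative vs noise and a permutation oracle concurs", {
  set.seed(77)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  a <- y + rnorm(n, sd = 0.8)   # informative
  b <- rnorm(n)                 # pure noise
  dt <- delong_test(y, a, b)
  expect_lt(dt$p_value, 0.01)
  # permutation oracle: swap the paired scores per patient under the null
  obs <- auc(y, a) - auc(y, b)
  perm <- replicate(400, {
    swap <- runif(n) < 0.5
    aa <- ifelse(swap, b, a)
    bb <- ifelse(swap, a, b)
    auc(y, aa) - auc(y, bb)
  })
  p_perm <- mean(abs(perm) >= abs(obs))
  expect_lt(p_perm, 0.01)
})

test_that("adaptive bins honour size arithmetic and tie cohesion", {
  b100 <- adaptive_bins(runif(100), 25)
  expect_equal(as.integer(attr(b100, "sizes")), rep(25L, 4))
  set.seed(3)
  b110 <- adaptive_bins(runif(110), 25)
  expect_equal(as.integer(attr(b110, "sizes")), c(28L, 28L, 27L, 27L))
  expect_error(adaptive_bins(runif(24), 25), "at least")
  # heavy ties: equal values never straddle a boundary
  v <- c(rep(0.2, 40), rep(0.7, 60))
  bt <- adaptive_bins(v, 25)
  expect_equal(length(unique(bt[v == 0.2])), 1L)
  expect_equal(length(unique(bt[v == 0.7])), 1L)
  expect_true(all(attr(bt, "sizes") >= 25))
  # bins are ordered by value and partition the cohort
  set.seed(4)
  v2 <- rnorm(130)
  b2 <- adaptive_bins(v2, 25)
  expect_equal(sum(attr(b2, "sizes")), 130L)
  expect_true(max(v2[b2 == 1]) <= min(v2[b2 == max(b2)]))
})

test_that("prediction ACE separates calibrated from anti-calibrated predictors", {
  set.seed(61)
  n <- 10000
  p <- runif(n)
  y <- rbinom(n, 1, p)
  # with bins of ~n/10 the binomial noise floor is well below 0.03; fixed
  # 25-patient bins keep an irreducible E|gap| ~ sqrt(p(1-p)/25) ~ 0.08
  expect_lt(prediction_ace(y, p, n / 10)$ace, 0.03)
  expect_gt(prediction_ace(y, 1 - p, n / 10)$ace, 0.3)
  expect_gt(prediction_ace(y, 1 - p, 25)$ace, 0.3)
  # perfectly calibrated constant: single tied bin, gap is binomial noise
  const <- prediction_ace(y, rep(mean(y), n), 25)
  expect_lt(const$ace, 0.02)
  expect_equal(nrow(const$bins), 1L)
})

test_that("ACE of the true-probability predictor shrinks like binomial noise", {
  set.seed(62)
  # bins proportional to n: per-bin noise sd ~ sqrt(p(1-p)*10/n), so ACE
  # should fall by about sqrt(10) from n=1k to n=10k
  aces <- vapply(c(1000, 10000), function(n) {
    p <- runif(n)
    prediction_ace(rbinom(n, 1, p), p, n / 10)$ace
  }, 0)
  expect_lt(aces[2], aces[1])
  expect_lt(aces[2], 0.03)
  expect_equal(aces[1] / aces[2], sqrt(10), tolerance = 0.5)
})

test_that("uncertainty-accuracy calibration orders bins by certainty", {
  set.seed(63)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  prob <- ifelse(y == 1, 0.8, 0.2) # always correct at 0.5
  wrong <- sample(n, 120)
  prob[wrong] <- 1 - prob[wrong]
  unc <- as.numeric((prob >= 0.5) != y) # oracle: 1 exactly when wrong
  cal <- uncertainty_accuracy_calibration(y, prob, unc, 0.5, 25)
  expect_true(all(diff(cal$bins$accuracy) >= 0))
  expect_equal(cal$bins$accuracy[nrow(cal$bins)], 1)
  # uncertainty independent of correctness: flat curve near overall accuracy
  unc_rand <- runif(n)
  cal_r <- uncertainty_accuracy_calibration(y, prob, unc_rand, 0.5, 25)
  overall <- accuracy(y, prob, 0.5)
  expect_lt(mean(abs(cal_r$bins$accuracy - overall)), 0.1)
  # constant uncertainty: one effective bin
  cal_c <- uncertainty_accuracy_calibration(y, prob, rep(0.4, n), 0.5, 25)
  expect_equal(nrow(cal_c$bins), 1L)
  expect_error(uncertainty_accuracy_calibration(y, prob, unc * 2, 0.5, 25),
               "normalised")
})

test_that("sparsification with oracle uncertainty is exactly monotone", {
  set.seed(64)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  # an informative predictor, so fewer than half the cases are misclassified
  prob <- ifelse(y == 1, runif(n, 0.3, 1), runif(n, 0, 0.7))
  wrong <- (prob >= 0.5) != y
  curve <- sparsification(y, prob, as.numeric(wrong))
  expect_equal(nrow(curve), floor(n / 2) + 1)
  expect_true(all(diff(curve$accuracy) >= 0))
  expect_true(any(curve$accuracy == 1)) # all errors eventually removed
  # anti-oracle: certain = wrong, so accuracy can only fall
  anti <- sparsification(y, prob, 1 - as.numeric(wrong))
  expect_true(all(diff(anti$accuracy) <= 0))
})

test_that("constant uncertainty matches the random-removal permutation oracle", {
  set.seed(65)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  prob <- runif(n)
  curve <- sparsification(y, prob, rep(0.5, n))
  final_obs <- curve$accuracy[nrow(curve)]
  perm_final <- replicate(400, {
    keep <- sample(n, n - floor(n / 2))
    accuracy(y[keep], prob[keep], 0.5)
  })
  q <- quantile(perm_final, c(0.005, 0.995))
  expect_gte(final_obs, q[[1]])
  expect_lte(final_obs, q[[2]])
})

test_that("sparsification records AUC as missing once a class disappears", {
  y <- c(1, 1, 0, 0, 0, 0)
  prob <- c(0.9, 0.8, 0.3, 0.2, 0.6, 0.4)
  unc <- c(1, 0.9, 0.1, 0.1, 0.2, 0.1) # removes both positives first
  curve <- sparsification(y, prob, unc, max_removed_fraction = 0.5)
  expect_false(is.na(curve$auc[1]))
  expect_true(is.na(curve$auc[3]))
  expect_false(any(is.na(curve$accuracy)))
})

test_that("sparsification is reproducible under patient reordering", {
  set.seed(66)
  n <- 80
  y <- rbinom(n, 1, 0.4)
  prob <- runif(n)
  unc <- runif(n)
  ids <- sprintf("Q%03d", seq_len(n))
  perm <- sample(n)
  a <- sparsification(y, prob, unc, patient_id = ids)
  b <- sparsification(y[perm], prob[perm], unc[perm], patient_id = ids[perm])
  expect_equal(a$auc, b$auc)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("bootstrap intervals behave: degenerate width, containment, coverage", {
  set.seed(67)
  y <- rbinom(300, 1, 0.4)
  s <- y + rnorm(300)
  ci <- bootstrap_ci(auc, y, s, B = 500, seed = 3)
  expect_lte(ci["lower"], auc(y, s))
  expect_gte(ci["upper"], auc(y, s))
  ci2 <- bootstrap_ci(auc, y, s, B = 500, seed = 3)
  expect_identical(ci, ci2)
  const <- bootstrap_ci(function(l, x) 0.7, y, s, B = 100, seed = 4)
  expect_equal(unname(diff(const)), 0)
  # coverage over replicates: the true AUC of the generating process
  true_auc <- {
    big_y <- rbinom(2e5, 1, 0.4)
    auc(big_y, big_y + rnorm(2e5))
  }
  covered <- mean(replicate(120, {
    yy <- rbinom(300, 1, 0.4)
    ss <- yy + rnorm(300)
    ci <- bootstrap_ci(auc, yy, ss, B = 200, seed = sample.int(1e6, 1))
    ci["lower"] <= true_auc && true_auc <= ci["upper"]
  }))
  expect_gt(covered, 0.85)
})

test_that("evaluation metrics are invariant to patient reordering", {
  set.seed(68)
  n <- 150
  y <- rbinom(n, 1, 0.3)
  p <- runif(n)
  perm <- sample(n)
  expect_equal(auc(y, p), auc(y[perm], p[perm]))
  expect_equal(accuracy(y, p), accuracy(y[perm], p[perm]))
  expect_equal(prediction_ace(y, p, 25)$ace,
               prediction_ace(y[perm], p[perm], 25)$ace)
  q <- runif(n)
  expect_equal(delong_test(y, p, q)$p_value,
               delong_test(y[perm], p[perm], q[perm])$p_value)
})
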