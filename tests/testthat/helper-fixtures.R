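# Shared fixtures: small cohorts and quickly trained models, built once per
# test run, plus brute-force oracles kept independent of the package's own
# code paths.

make_cohort <- function(n = 400, prevalence = c(y = 0.3), seed = 1, ...) {
  generate_cohort(cohort_spec(n, prevalence = prevalence, seed = seed, ...))
}

tiny_config <- function(...) {
  model_config(hidden = 8L, max_epochs = 80L, patience = 10L, ...)
}

# development/validation/independent triple from one cohort
split3 <- function(cohort, seed = 1) {
  outer <- split_cohort(cohort, 0.8, seed = derive_seed(seed, "o"))
  inner <- inner_split(outer$development, 0.8, seed = derive_seed(seed, "i"))
  list(train = inner$train, valid = inner$valid,
       independent = outer$independent_validation)
}

# one modest fitted model, trained lazily and cached for the whole run
.fixture_env <- new.env(parent = emptyenv())
fixture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    cohort <- make_cohort(600, seed = 42)
    parts <- split3(cohort, seed = 7)
    model <- train_model(parts$train, parts$valid, "y",
                         tiny_config(dropout_rate = 0.3), seed = 11)
    .fixture_env$fit <- list(cohort = cohort, parts = parts, model = model)
  }
  .fixture_env$fit
}

# O(n^2) pair-counting AUC oracle (ties count one half)
pair_count_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# independent high-precision binary entropy (bits)
entropy_oracle <- function(p) {
  out <- numeric(length(p))
  for (i in seq_along(p)) {
    q <- p[i]
    out[i] <- sum(vapply(c(q, 1 - q),
                         function(x) if (x == 0) 0 else -x * log(x) / log(2), 0))
  }
  out
}
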