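# Uncertainty methods: each turns one patient's prediction into a set of T
# sampled probabilities. MC dropout samples parameter randomness (dropout
# masks live at inference), deep ensembles sample initialisation randomness
# (ten independently initialised models), and test-time augmentation samples
# input randomness (50 augmented copies). The row mean of the samples is
# always the final prediction.

#' Construct a prediction-samples object
#'
#' @param samples numeric matrix (patients x T) of probabilities in `[0, 1]`.
#' @param method one of `"mc_dropout"`, `"deep_ensemble"`, `"tta"`,
#'   or `"baseline"`.
#' @param patient_id optional patient identifiers.
#' @return An object of class `prediction_samples` with fields `samples`,
#'   `mean_prediction` (exact row means), `method`, `n_samples`, `patient_id`.
#' @export
prediction_samples <- function(samples,
                               method = c("mc_dropout", "deep_ensemble",
                                          "tta", "baseline"),
                               patient_id = NULL) {
  method <- match.arg(method)
  samples <- as.matrix(samples)
  if (any(samples < 0 | samples > 1)) {
    stop("prediction samples must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(samples = samples,
         mean_prediction = rowMeans(samples),
         method = method,
         n_samples = ncol(samples),
         patient_id = patient_id %||% sprintf("P%05d", seq_len(nrow(samples)))),
    class = "prediction_samples"
  )
}

#' @export
print.prediction_samples <- function(x, ...) {
  cat(sprintf("Prediction samples [%s]: %d patients x %d samples\n",
              x$method, nrow(x$samples), x$n_samples))
  cat(sprintf("  mean prediction: median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$mean_prediction), min(x$mean_prediction),
              max(x$mean_prediction)))
  invisible(x)
}

#' Select the dropout rate on the validation cohort
#'
#' Trains one model per candidate rate and scores each by the AUC of its
#' MC-dropout mean prediction (over `n_samples` stochastic passes) on the
#' validation cohort; the best-AUC rate is returned, with ties broken towards
#' the smaller rate. The default grid is 0.1--0.5 in steps of 0.1.
#'
#' @param train,valid `uq_cohort`s.
#' @param endpoint endpoint label.
#' @param grid candidate dropout rates.
#' @param base_config a [model_config()]; its `dropout_rate` is overridden.
#' @param n_samples stochastic passes per candidate when scoring.
#' @param seed integer seed.
#' @return A list with `rate` (the selection), `auc` (named per-rate AUCs),
#'   and `models` (the fitted per-rate models, so the winner can be reused).
#' @export
select_dropout_rate <- function(train, valid, endpoint,
                                grid = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                base_config = model_config(),
                                n_samples = 50L, seed = 1L) {
  stopifnot(length(grid) >= 1, all(grid > 0 & grid < 1))
  if (length(unique(valid$labels[, endpoint])) < 2L) {
    stop("validation labels are single-class; AUC-based selection undefined",
         call. = FALSE)
  }
  grid <- sort(grid)
  models <- vector("list", length(grid))
  aucs <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cfg <- base_config
    cfg$dropout_rate <- grid[i]
    models[[i]] <- train_model(train, valid, endpoint, cfg,
                               seed = derive_seed(seed, paste0("rate:", grid[i])))
    ps <- mc_dropout_predict(models[[i]], valid, n_samples = n_samples,
                             seed = derive_seed(seed, paste0("score:", grid[i])))
    aucs[i] <- auc(valid$labels[, endpoint], ps$mean_prediction)
  }
  names(aucs) <- names(models) <- as.character(grid)
  list(rate = grid[which.max(aucs)], auc = aucs, models = models)
}

#' Monte Carlo dropout prediction samples
#'
#' Runs `n_samples` independent dropout-active forward passes (50 by default)
#' per patient; the row mean is the final prediction.
#'
#' @param model a fitted `uq_net` with `dropout_rate > 0` for nontrivial
#'   uncertainty.
#' @param newdata a `uq_cohort` or feature data frame.
#' @param n_samples number of stochastic passes T.
#' @param seed integer seed; pass `t` uses the child seed `"mc:t"`.
#' @return A [prediction_samples] object with method `"mc_dropout"`.
#' @export
mc_dropout_predict <- function(model, newdata, n_samples = 50L, seed = 1L) {
  stopifnot(inherits(model, "uq_net"), n_samples >= 2)
  X <- design_matrix(as_feature_frame(newdata), model$feature_info)
  p_drop <- model$config$dropout_rate
  s <- vapply(seq_len(n_samples), function(t) {
    if (p_drop == 0) net_forward(model$weights, X)
    else with_seed(derive_seed(seed, paste0("mc:", t)),
                   net_forward(model$weights, X, dropout_rate = p_drop))
  }, numeric(nrow(X)))
  prediction_samples(s, method = "mc_dropout",
                     patient_id = if (inherits(newdata, "uq_cohort"))
                       newdata$patient_id)
}

#' Train a deep ensemble
#'
#' Trains `n_members` models on identical training/validation data, differing
#' only in their member seed, which sets both the weight initialisation and
#' the induced minibatch shuffling. Ten members by default.
#'
#' @param train,valid `uq_cohort`s (identical across members).
#' @param endpoint endpoint label.
#' @param n_members ensemble size M.
#' @param base_config a [model_config()] shared by all members.
#' @param seeds optional vector of `n_members` member seeds; derived from
#'   `seed` when omitted.
#' @param seed master seed used when `seeds` is not given.
#' @return A list of `uq_net` models of class `uq_ensemble`.
#' @export
train_ensemble <- function(train, valid, endpoint, n_members = 10L,
                           base_config = model_config(), seeds = NULL,
                           seed = 1L) {
  stopifnot(n_members >= 2)
  seeds <- seeds %||% vapply(seq_len(n_members),
                             function(m) derive_seed(seed, paste0("member:", m)),
                             0L)
  stopifnot(length(seeds) == n_members)
  models <- lapply(seeds, function(s) {
    train_model(train, valid, endpoint, base_config, seed = s)
  })
  structure(models, class = "uq_ensemble", seeds = seeds)
}

#' Deep-ensemble prediction samples
#'
#' One deterministic forward pass per member; T equals the ensemble size and
#' the member mean is the final prediction.
#'
#' @param models a `uq_ensemble` (or plain list of `uq_net`s, at least 2).
#' @param newdata a `uq_cohort` or feature data frame.
#' @return A [prediction_samples] object with method `"deep_ensemble"`.
#' @export
ensemble_predict <- function(models, newdata) {
  stopifnot(length(models) >= 2)
  s <- vapply(models, function(m) predict_deterministic(m, newdata),
              numeric(nrow(as_feature_frame(newdata))))
  prediction_samples(s, method = "deep_ensemble",
                     patient_id = if (inherits(newdata, "uq_cohort"))
                       newdata$patient_id)
}

#' Test-time augmentation prediction samples
#'
#' Generates `n_samples` augmented copies of each patient (50 by default)
#' under the given policy and runs a deterministic (dropout-off) forward pass
#' on each: prediction variability under input perturbation is the
#' uncertainty signal.
#'
#' @param model a fitted `uq_net` (typically the baseline model).
#' @param newdata a `uq_cohort` or feature data frame.
#' @param policy an [augmentation_policy()]; ideally the one used in training.
#' @param n_samples number of augmented copies T.
#' @param seed integer seed.
#' @return A [prediction_samples] object with method `"tta"`.
#' @export
tta_predict <- function(model, newdata, policy, n_samples = 50L, seed = 1L) {
  stopifnot(inherits(model, "uq_net"), inherits(policy, "augmentation_policy"),
            n_samples >= 2)
  features <- as_feature_frame(newdata)
  s <- vapply(seq_len(n_samples), function(t) {
    aug <- augment_features(features, policy,
                            seed = derive_seed(seed, paste0("tta:", t)),
                            n_levels = model$feature_info$n_levels)
    predict_deterministic(model, aug)
  }, numeric(nrow(features)))
  prediction_samples(s, method = "tta",
                     patient_id = if (inherits(newdata, "uq_cohort"))
                       newdata$patient_id)
}
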