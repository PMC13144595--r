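# A small dropout-capable feed-forward binary classifier.
#
# The uncertainty layer only requires a probabilistic classifier that (a)
# trains by minimising binary cross-entropy, (b) can run forward passes with
# dropout masks sampled from a seed, and (c) accepts augmented inputs. A
# two-hidden-layer ReLU network trained with Adam fulfils that contract for
# tabular cohorts; the heavy image backbones used for the original clinical
# models are deliberately out of scope and the UQ pipeline is model-agnostic.

#' Configuration of the feed-forward classifier
#'
#' @param hidden integer vector of hidden layer sizes.
#' @param dropout_rate dropout probability in `[0, 1)` applied to hidden
#'   activations, both during training and (for MC dropout) at inference.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum number of training epochs.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience: training stops after this many
#'   epochs without improvement in validation loss, and the best-validation
#'   weights are restored.
#' @param init_seed optional seed for weight initialisation; when `NULL` it is
#'   derived from the training seed.
#' @return An object of class `model_config`.
#' @export
model_config <- function(hidden = c(16L, 8L),
                         dropout_rate = 0,
                         learning_rate = 0.01,
                         max_epochs = 500L,
                         batch_size = 32L,
                         patience = 20L,
                         init_seed = NULL) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1, max_epochs >= 1,
            batch_size >= 1, all(hidden >= 1))
  structure(
    list(hidden = as.integer(hidden), dropout_rate = dropout_rate,
         learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         init_seed = init_seed),
    class = "model_config"
  )
}

#' Input augmentation policy
#'
#' Describes the stochastic input perturbations applied during training and
#' by test-time augmentation. Continuous features receive additive Gaussian
#' noise and/or multiplicative jitter; each categorical feature is resampled
#' (uniformly over its own level set, so the domain is preserved) with a small
#' probability.
#'
#' @param gaussian_sd SD of additive Gaussian noise on continuous features
#'   (features are on the standard-normal scale, so this is in SD units).
#' @param jitter_sd SD of multiplicative jitter: features are multiplied by
#'   `1 + N(0, jitter_sd^2)`.
#' @param cat_resample probability that a categorical entry is replaced by a
#'   uniform draw from its level set.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(gaussian_sd = 0.25, jitter_sd = 0,
                                cat_resample = 0) {
  stopifnot(gaussian_sd >= 0, jitter_sd >= 0,
            cat_resample >= 0, cat_resample <= 1)
  structure(list(gaussian_sd = gaussian_sd, jitter_sd = jitter_sd,
                 cat_resample = cat_resample),
            class = "augmentation_policy")
}

#' Apply an augmentation policy to a feature frame
#'
#' @param features data frame with `cont_*` (numeric) and `cat_*` (integer
#'   code) columns, as stored in a `uq_cohort`.
#' @param policy an [augmentation_policy()].
#' @param seed integer seed; the same seed reproduces the same perturbation.
#' @param n_levels number of levels of the categorical features.
#' @return A perturbed copy of `features`; categorical columns stay within
#'   their original level set.
#' @export
augment_features <- function(features, policy, seed, n_levels = 3L) {
  stopifnot(inherits(policy, "augmentation_policy"))
  with_seed(seed, {
    out <- features
    cont <- grep("^cont_", names(features), value = TRUE)
    for (cn in cont) {
      x <- out[[cn]]
      if (policy$jitter_sd > 0) {
        x <- x * (1 + stats::rnorm(length(x), sd = policy$jitter_sd))
      }
      if (policy$gaussian_sd > 0) {
        x <- x + stats::rnorm(length(x), sd = policy$gaussian_sd)
      }
      out[[cn]] <- x
    }
    if (policy$cat_resample > 0) {
      for (cn in grep("^cat_", names(features), value = TRUE)) {
        hit <- stats::runif(nrow(out)) < policy$cat_resample
        if (any(hit)) {
          out[[cn]][hit] <- sample.int(n_levels, sum(hit), replace = TRUE)
        }
      }
    }
    out
  })
}

# One-hot expansion of the cat_* codes; continuous columns pass through.
# Column layout is fixed by (n_continuous, n_categorical, n_levels) so train
# and predict always agree.
design_matrix <- function(features, info) {
  n <- nrow(features)
  blocks <- list()
  if (info$n_continuous > 0) {
    blocks$cont <- as.matrix(features[, paste0("cont_",
                                               seq_len(info$n_continuous)),
                                      drop = FALSE])
  }
  if (info$n_categorical > 0) {
    for (j in seq_len(info$n_categorical)) {
      code <- features[[paste0("cat_", j)]]
      oh <- matrix(0, n, info$n_levels,
                   dimnames = list(NULL, paste0("cat_", j, "_l",
                                                seq_len(info$n_levels))))
      oh[cbind(seq_len(n), code)] <- 1
      blocks[[paste0("cat", j)]] <- oh
    }
  }
  do.call(cbind, blocks)
}

feature_info <- function(spec) {
  list(n_continuous = spec$n_continuous, n_categorical = spec$n_categorical,
       n_levels = spec$n_levels)
}

relu <- function(z) pmax(z, 0)

# Forward pass. dropout_rate > 0 samples inverted-dropout masks on hidden
# activations from the current RNG stream; 0 is the deterministic pass.
net_forward <- function(weights, X, dropout_rate = 0) {
  A <- X
  L <- length(weights$W)
  for (l in seq_len(L - 1L)) {
    A <- relu(sweep(A %*% weights$W[[l]], 2, weights$b[[l]], `+`))
    if (dropout_rate > 0) {
      keep <- 1 - dropout_rate
      mask <- matrix(stats::runif(length(A)) < keep, nrow = nrow(A))
      A <- A * mask / keep
    }
  }
  z <- drop(sweep(A %*% weights$W[[L]], 2, weights$b[[L]], `+`))
  stats::plogis(z)
}

bce_loss <- function(y, p) {
  p <- clamp_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

init_weights <- function(dims, seed) {
  with_seed(seed, {
    L <- length(dims) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                    sd = sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- rep(0, dims[l + 1L])
    }
    list(W = W, b = b)
  })
}

#' Train the feed-forward classifier
#'
#' Minimises binary cross-entropy with Adam, dropout active on hidden layers,
#' and (optionally) stochastic input augmentation redrawn every epoch. After
#' each epoch the deterministic validation loss is evaluated; training stops
#' once it has not improved for `config$patience` epochs and the
#' best-validation weights are restored. Fully reproducible given `seed`.
#'
#' @param train,valid `uq_cohort` training and validation sets (disjoint).
#' @param endpoint endpoint label to model.
#' @param config a [model_config()].
#' @param augmentation optional [augmentation_policy()] applied to the
#'   training features (redrawn each epoch).
#' @param seed integer seed controlling initialisation, minibatch order,
#'   dropout masks and augmentation draws.
#' @return An object of class `uq_net` with the fitted weights, the config,
#'   per-epoch training history, and the feature layout.
#' @export
train_model <- function(train, valid, endpoint, config = model_config(),
                        augmentation = NULL, seed = 1L) {
  stopifnot(inherits(train, "uq_cohort"), inherits(valid, "uq_cohort"),
            inherits(config, "model_config"))
  if (!endpoint %in% colnames(train$labels)) {
    stop("endpoint not present in training cohort: ", endpoint, call. = FALSE)
  }
  if (length(intersect(train$patient_id, valid$patient_id)) > 0) {
    stop("train and valid cohorts overlap", call. = FALSE)
  }
  y_tr <- train$labels[, endpoint]
  y_va <- valid$labels[, endpoint]
  if (length(unique(y_tr)) < 2L) {
    stop("training labels are single-class; the model (and AUC) is undefined",
         call. = FALSE)
  }
  info <- feature_info(train$spec)
  X_tr <- design_matrix(train$features, info)
  X_va <- design_matrix(valid$features, info)
  dims <- c(ncol(X_tr), config$hidden, 1L)
  weights <- init_weights(dims, config$init_seed %||% derive_seed(seed, "init"))
  n <- nrow(X_tr)
  lr <- config$learning_rate
  p_drop <- config$dropout_rate
  L <- length(weights$W)
  # Adam state
  mW <- lapply(weights$W, function(w) w * 0); vW <- mW
  mb <- lapply(weights$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t_step <- 0

  history <- matrix(NA_real_, config$max_epochs, 2,
                    dimnames = list(NULL, c("train_loss", "valid_loss")))
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  wait <- 0L
  n_epochs <- 0L

  with_seed(derive_seed(seed, "train"), {
    for (epoch in seq_len(config$max_epochs)) {
      Xe <- if (is.null(augmentation)) X_tr else {
        design_matrix(
          augment_features(train$features, augmentation,
                           seed = sample.int(2^30, 1L),
                           n_levels = info$n_levels),
          info)
      }
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- Xe[idx, , drop = FALSE]
        yb <- y_tr[idx]
        B <- length(idx)
        # forward with caches
        A <- vector("list", L + 1L); A[[1L]] <- Xb
        Z <- vector("list", L); masks <- vector("list", L)
        for (l in seq_len(L - 1L)) {
          Z[[l]] <- sweep(A[[l]] %*% weights$W[[l]], 2, weights$b[[l]], `+`)
          act <- relu(Z[[l]])
          if (p_drop > 0) {
            keep <- 1 - p_drop
            masks[[l]] <- matrix((stats::runif(length(act)) < keep) / keep,
                                 nrow = B)
            act <- act * masks[[l]]
          }
          A[[l + 1L]] <- act
        }
        zout <- drop(sweep(A[[L]] %*% weights$W[[L]], 2, weights$b[[L]], `+`))
        p <- stats::plogis(zout)
        # backward
        delta <- matrix((p - yb) / B, ncol = 1L)
        t_step <- t_step + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            dA <- delta %*% t(weights$W[[l]])
            if (p_drop > 0) dA <- dA * masks[[l - 1L]]
            delta <- dA * (Z[[l - 1L]] > 0)
          }
          # Adam update
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mh <- mW[[l]] / (1 - beta1^t_step)
          vh <- vW[[l]] / (1 - beta2^t_step)
          weights$W[[l]] <- weights$W[[l]] - lr * mh / (sqrt(vh) + adam_eps)
          mhb <- mb[[l]] / (1 - beta1^t_step)
          vhb <- vb[[l]] / (1 - beta2^t_step)
          weights$b[[l]] <- weights$b[[l]] - lr * mhb / (sqrt(vhb) + adam_eps)
        }
      }
      tr_loss <- bce_loss(y_tr, net_forward(weights, X_tr))
      va_loss <- bce_loss(y_va, net_forward(weights, X_va))
      history[epoch, ] <- c(tr_loss, va_loss)
      n_epochs <- epoch
      if (va_loss < best$loss) {
        best <- list(loss = va_loss, weights = weights, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })

  best$weights$W <- lapply(best$weights$W, function(w) {
    dimnames(w) <- NULL
    w
  })
  structure(
    list(
      weights = best$weights,
      config = config,
      endpoint = endpoint,
      feature_info = info,
      history = data.frame(epoch = seq_len(n_epochs),
                           train_loss = history[seq_len(n_epochs), 1],
                           valid_loss = history[seq_len(n_epochs), 2]),
      best_epoch = best$epoch,
      best_valid_loss = best$loss,
      seed = seed
    ),
    class = "uq_net"
  )
}

#' @export
print.uq_net <- function(x, ...) {
  cat(sprintf("Feed-forward classifier for endpoint '%s'\n", x$endpoint))
  cat(sprintf("  hidden: %s, dropout: %.2f\n",
              paste(x$config$hidden, collapse = "-"), x$config$dropout_rate))
  cat(sprintf("  trained %d epochs; best validation loss %.4f at epoch %d\n",
              nrow(x$history), x$best_valid_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.uq_net <- function(object, ...) {
  n_par <- sum(vapply(object$weights$W, length, 0L)) +
    sum(vapply(object$weights$b, length, 0L))
  cat(sprintf("uq_net: %d parameters, endpoint '%s'\n", n_par, object$endpoint))
  print(object)
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.uq_net <- function(object, ...) object$weights

#' @export
plot.uq_net <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$valid_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "valid"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

# Accept a cohort or a raw feature frame.
as_feature_frame <- function(newdata) {
  if (inherits(newdata, "uq_cohort")) newdata$features else newdata
}

#' Deterministic point prediction
#'
#' Forward pass with dropout disabled: the single point prediction a model
#' without uncertainty quantification would report.
#'
#' @param model a fitted `uq_net`.
#' @param newdata a `uq_cohort` or a feature data frame.
#' @return Numeric vector of event probabilities in `[0, 1]`.
#' @export
predict_deterministic <- function(model, newdata) {
  stopifnot(inherits(model, "uq_net"))
  X <- design_matrix(as_feature_frame(newdata), model$feature_info)
  net_forward(model$weights, X, dropout_rate = 0)
}

#' Single stochastic (dropout-active) forward pass
#'
#' Keeps the dropout layers active at inference, so repeated calls with
#' different seeds sample from the model's predictive distribution.
#'
#' @inheritParams predict_deterministic
#' @param seed integer seed for the dropout masks.
#' @return Numeric vector of probabilities.
#' @export
predict_stochastic <- function(model, newdata, seed = 1L) {
  stopifnot(inherits(model, "uq_net"))
  if (model$config$dropout_rate == 0) {
    warning("dropout_rate is 0: stochastic prediction collapses to the ",
            "deterministic prediction")
    return(predict_deterministic(model, newdata))
  }
  X <- design_matrix(as_feature_frame(newdata), model$feature_info)
  with_seed(seed,
            net_forward(model$weights, X,
                        dropout_rate = model$config$dropout_rate))
}

#' @export
predict.uq_net <- function(object, newdata,
                           type = c("deterministic", "stochastic"),
                           seed = 1L, ...) {
  type <- match.arg(type)
  if (type == "deterministic") predict_deterministic(object, newdata)
  else predict_stochastic(object, newdata, seed = seed)
}

#' Serialise / restore a trained model as JSON
#'
#' All weights, the configuration, and the feature layout go into a single
#' human-readable JSON file.
#'
#' @param model a `uq_net`.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` a `uq_net`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "uq_net"))
  payload <- list(
    weights = list(W = lapply(model$weights$W, as.vector),
                   dims = lapply(model$weights$W, dim),
                   b = model$weights$b),
    config = unclass(model$config),
    endpoint = model$endpoint,
    feature_info = model$feature_info,
    history = as.list(model$history),
    best_epoch = model$best_epoch,
    best_valid_loss = model$best_valid_loss,
    seed = model$seed
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  # no vector simplification: ragged weight lists must stay lists
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  W <- mapply(function(w, d) matrix(num(w), num(d)[1], num(d)[2]),
              p$weights$W, p$weights$dims, SIMPLIFY = FALSE)
  b <- lapply(p$weights$b, num)
  cfg <- model_config(hidden = as.integer(unlist(p$config$hidden)),
                      dropout_rate = num(p$config$dropout_rate),
                      learning_rate = num(p$config$learning_rate),
                      max_epochs = num(p$config$max_epochs),
                      batch_size = num(p$config$batch_size),
                      patience = num(p$config$patience))
  structure(
    list(weights = list(W = W, b = b),
         config = cfg, endpoint = p$endpoint,
         feature_info = lapply(p$feature_info, function(x) as.integer(unlist(x))),
         history = data.frame(epoch = num(p$history$epoch),
                              train_loss = num(p$history$train_loss),
                              valid_loss = num(p$history$valid_loss)),
         best_epoch = num(p$best_epoch),
         best_valid_loss = num(p$best_valid_loss),
         seed = num(p$seed)),
    class = "uq_net"
  )
}
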