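# Synthetic patient cohorts with known per-patient event probabilities.
#
# The generator emulates the tabular structure of head-and-neck radiotherapy
# outcome cohorts: mixed continuous/categorical covariates, binary endpoints
# with fixed marginal prevalences (NTCP side-effect endpoints at 22% and 42%,
# TCP survival/control endpoints at 24% and 25%), and a logistic-linear
# outcome model so the per-patient Bernoulli parameter -- the aleatoric
# uncertainty -- is known exactly.

#' Specify a synthetic cohort
#'
#' A `cohort_spec` fixes everything about a synthetic cohort except the random
#' draws: size, endpoints and their target marginal prevalences, covariate
#' structure, per-feature log-odds effects, label-flip noise, and the master
#' seed. Outcomes follow a logistic-linear model in the covariates (the
#' classical NTCP form), with the per-endpoint intercept calibrated so the
#' marginal event rate hits its target.
#'
#' @param n_patients number of patients (>= 2).
#' @param prevalence named numeric vector of target marginal prevalences in
#'   (0,1); names are the endpoint labels.
#' @param n_continuous,n_categorical counts of continuous (standard normal)
#'   and categorical (multinomial, `n_levels` levels) covariates.
#' @param n_levels number of levels per categorical covariate.
#' @param effect_sizes list with elements `cont` (length `n_continuous`
#'   log-odds per SD) and `cat` (list of per-level log-odds vectors, one per
#'   categorical covariate). `NULL` uses defaults with decaying effects giving
#'   a latent-predictor SD of about 1.6 (an informative but imperfect model,
#'   oracle AUC around 0.85).
#' @param label_noise probability in `[0, 0.5)` that a drawn label is flipped;
#'   models irreducible assessment variability in patient/physician-reported
#'   endpoints.
#' @param shift optional covariate shift, a list with `mean` and/or `scale`
#'   applied to the continuous covariates (see [apply_covariate_shift()]).
#' @param seed integer master seed; all draws are derived from it.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [ntcp_cohort_spec()], [tcp_cohort_spec()]
#' @export
#' @examples
#' spec <- cohort_spec(500, prevalence = c(toxicity = 0.22), seed = 1)
#' cohort <- generate_cohort(spec)
#' mean(cohort$labels[, "toxicity"])
cohort_spec <- function(n_patients,
                        prevalence,
                        n_continuous = 8L,
                        n_categorical = 2L,
                        n_levels = 3L,
                        effect_sizes = NULL,
                        label_noise = 0,
                        shift = NULL,
                        seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 2) {
    stop("`n_patients` must be a single number >= 2", call. = FALSE)
  }
  if (is.null(names(prevalence)) || any(!nzchar(names(prevalence)))) {
    stop("`prevalence` must be a named vector (names are endpoint labels)",
         call. = FALSE)
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("all prevalence targets must lie strictly in (0, 1)", call. = FALSE)
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("`label_noise` must lie in [0, 0.5)", call. = FALSE)
  }
  if (is.null(effect_sizes)) {
    effect_sizes <- default_effect_sizes(n_continuous, n_categorical, n_levels)
  }
  stopifnot(length(effect_sizes$cont) == n_continuous,
            length(effect_sizes$cat) == n_categorical)
  if (n_categorical > 0) {
    stopifnot(all(vapply(effect_sizes$cat, length, 0L) == n_levels))
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      endpoints = names(prevalence),
      prevalence = prevalence,
      n_continuous = as.integer(n_continuous),
      n_categorical = as.integer(n_categorical),
      n_levels = as.integer(n_levels),
      effect_sizes = effect_sizes,
      label_noise = label_noise,
      shift = shift,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

default_effect_sizes <- function(n_continuous, n_categorical, n_levels) {
  cont <- c(1.0, 0.8, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
  cont <- if (n_continuous <= 8L) cont[seq_len(n_continuous)] else {
    c(cont, rep(0.1, n_continuous - 8L))
  }
  cat_eff <- if (n_categorical > 0) {
    lapply(seq_len(n_categorical), function(j) {
      base <- seq(0, by = 0.3, length.out = n_levels)
      (base - mean(base)) * 0.7^(j - 1)
    })
  } else list()
  list(cont = cont, cat = cat_eff)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  patients: %d, covariates: %d continuous + %d categorical (%d levels)\n",
              x$n_patients, x$n_continuous, x$n_categorical, x$n_levels))
  cat("  endpoints (target prevalence):",
      paste(sprintf("%s=%.2f", x$endpoints, x$prevalence), collapse = ", "), "\n")
  cat(sprintf("  label noise: %.3f, seed: %d\n", x$label_noise, x$seed))
  invisible(x)
}

#' Default NTCP-style and TCP-style cohort specifications
#'
#' Convenience constructors for the two study-like cohorts: an NTCP-style
#' cohort of 1,205 patients with 6-month toxicity endpoints at 22% (dysphagia)
#' and 42% (xerostomia) marginal prevalence, split 80%/20% into development
#' and independent validation; and a TCP-style cohort of 340 patients with
#' 2-year endpoints at 24% (death) and 25% (locoregional-control failure),
#' split 75%/25%. The recommended development fraction is attached as the
#' `"dev_fraction"` attribute.
#'
#' @param n_patients cohort size.
#' @param seed master seed.
#' @param ... passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
ntcp_cohort_spec <- function(n_patients = 1205L, seed = 1L, ...) {
  spec <- cohort_spec(n_patients,
                      prevalence = c(dysphagia = 0.22, xerostomia = 0.42),
                      seed = seed, ...)
  attr(spec, "dev_fraction") <- 0.80
  spec
}

#' @rdname ntcp_cohort_spec
#' @export
tcp_cohort_spec <- function(n_patients = 340L, seed = 1L, ...) {
  spec <- cohort_spec(n_patients,
                      prevalence = c(death_2y = 0.24, lrc_failure_2y = 0.25),
                      seed = seed, ...)
  attr(spec, "dev_fraction") <- 0.75
  spec
}

# Linear predictor (without intercept) for a feature data.frame under the
# spec's effect sizes. Categorical codes index their per-level effect.
linear_predictor <- function(features, spec) {
  eta <- rep(0, nrow(features))
  if (spec$n_continuous > 0) {
    xc <- as.matrix(features[, paste0("cont_", seq_len(spec$n_continuous)),
                             drop = FALSE])
    eta <- eta + drop(xc %*% spec$effect_sizes$cont)
  }
  if (spec$n_categorical > 0) {
    for (j in seq_len(spec$n_categorical)) {
      code <- features[[paste0("cat_", j)]]
      eta <- eta + spec$effect_sizes$cat[[j]][code]
    }
  }
  eta
}

draw_features <- function(spec, n, seed) {
  with_seed(seed, {
    out <- list()
    for (j in seq_len(spec$n_continuous)) {
      out[[paste0("cont_", j)]] <- stats::rnorm(n)
    }
    if (spec$n_categorical > 0) {
      # mildly imbalanced level frequencies, as in routine clinical covariates
      probs <- rev(seq_len(spec$n_levels))
      probs <- probs / sum(probs)
      for (j in seq_len(spec$n_categorical)) {
        out[[paste0("cat_", j)]] <-
          sample.int(spec$n_levels, n, replace = TRUE, prob = probs)
      }
    }
    as.data.frame(out)
  })
}

#' Calibrate an endpoint's logistic intercept to its target prevalence
#'
#' Solves for the intercept `b0` such that the marginal event rate of the
#' generative model, `E[plogis(b0 + eta)]` pushed through the label-noise
#' channel (`q = p(1 - 2*rho) + rho`), equals the endpoint's prevalence
#' target. The expectation over the covariate distribution is taken by Monte
#' Carlo on a large fixed sample, and the root found with [stats::uniroot()].
#'
#' @param spec a [cohort_spec()].
#' @param endpoint endpoint label (must appear in `spec$prevalence`).
#' @param n_mc Monte Carlo sample size for the marginal expectation.
#' @return The intercept (log-odds scale), a single number.
#' @export
#' @examples
#' # with no covariate effects the intercept is the plain logit
#' s <- cohort_spec(100, c(y = 0.22),
#'                  effect_sizes = list(cont = rep(0, 8),
#'                                      cat = rep(list(rep(0, 3)), 2)))
#' all.equal(calibrate_intercept(s, "y"), qlogis(0.22), tolerance = 1e-6)
calibrate_intercept <- function(spec, endpoint, n_mc = 200000L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!endpoint %in% spec$endpoints) {
    stop("unknown endpoint: ", endpoint, call. = FALSE)
  }
  target <- unname(spec$prevalence[endpoint])
  rho <- spec$label_noise
  features <- draw_features(spec, n_mc, derive_seed(spec$seed, "calibrate"))
  eta <- linear_predictor(features, spec)
  marginal <- function(b0) mean(stats::plogis(b0 + eta)) * (1 - 2 * rho) + rho
  lo <- -30; hi <- 30
  if ((marginal(lo) - target) * (marginal(hi) - target) > 0) {
    stop(sprintf("prevalence target %.3f unreachable under label noise %.3f",
                 target, rho), call. = FALSE)
  }
  stats::uniroot(function(b0) marginal(b0) - target, c(lo, hi),
                 tol = 1e-8)$root
}

#' Generate a synthetic cohort
#'
#' Draws covariates, computes each patient's true event probability
#' `plogis(b0 + eta)` per endpoint (with the intercept calibrated by
#' [calibrate_intercept()]), samples labels as Bernoulli draws from those
#' probabilities, and optionally flips each label independently with
#' probability `label_noise`. Fully deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `uq_cohort`: a list with `patient_id`,
#'   `features` (data frame, `cont_*` numeric and `cat_*` integer codes),
#'   `true_prob` and `labels` (n x endpoints matrices), `split` (character),
#'   `intercepts`, and the generating `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  features <- draw_features(spec, n, derive_seed(spec$seed, "features"))
  eta <- linear_predictor(features, spec)
  intercepts <- vapply(spec$endpoints,
                       function(e) calibrate_intercept(spec, e), 0)
  true_prob <- vapply(intercepts, function(b0) stats::plogis(b0 + eta),
                      numeric(n))
  dimnames(true_prob) <- list(NULL, spec$endpoints)
  labels <- with_seed(derive_seed(spec$seed, "labels"), {
    y <- matrix(stats::rbinom(n * length(spec$endpoints), 1L,
                              as.vector(true_prob)),
                nrow = n, dimnames = list(NULL, spec$endpoints))
    if (spec$label_noise > 0) {
      flip <- matrix(stats::runif(length(y)) < spec$label_noise, nrow = n)
      y[flip] <- 1L - y[flip]
    }
    y
  })
  cohort <- structure(
    list(
      patient_id = sprintf("P%05d", seq_len(n)),
      features = features,
      true_prob = true_prob,
      labels = labels,
      split = rep("unsplit", n),
      intercepts = intercepts,
      spec = spec
    ),
    class = "uq_cohort"
  )
  if (!is.null(spec$shift)) cohort <- apply_covariate_shift(cohort, spec$shift)
  cohort
}

#' @export
print.uq_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d features (%d cont + %d cat)\n",
              length(x$patient_id), ncol(x$features),
              x$spec$n_continuous, x$spec$n_categorical))
  rates <- colMeans(x$labels)
  cat("  endpoints (empirical rate):",
      paste(sprintf("%s=%.3f", names(rates), rates), collapse = ", "), "\n")
  cat("  split:", paste(sprintf("%s=%d", names(table(x$split)),
                                table(x$split)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `uq_cohort`.
#' @return Integer count.
#' @export
cohort_size <- function(cohort) length(cohort$patient_id)

#' Subset a cohort by patient index
#'
#' @param cohort a `uq_cohort`.
#' @param idx integer or logical index over patients.
#' @param split optional split tag to assign to the subset
#'   (train / valid / independent_validation / development).
#' @return A `uq_cohort` with all patient-level fields subset in step.
#' @export
subset_cohort <- function(cohort, idx, split = NULL) {
  stopifnot(inherits(cohort, "uq_cohort"))
  out <- cohort
  out$patient_id <- cohort$patient_id[idx]
  out$features <- cohort$features[idx, , drop = FALSE]
  rownames(out$features) <- NULL
  out$true_prob <- cohort$true_prob[idx, , drop = FALSE]
  out$labels <- cohort$labels[idx, , drop = FALSE]
  out$split <- if (is.null(split)) cohort$split[idx] else {
    rep(split, length(out$patient_id))
  }
  out
}

# round-half-to-even partition size; guards empty partitions
partition_size <- function(n, fraction) {
  k <- round(fraction * n)
  if (k <= 0 || k >= n) {
    stop(sprintf("fraction %.3f yields an empty partition for n=%d", fraction, n),
         call. = FALSE)
  }
  as.integer(k)
}

#' Split a cohort into development and independent validation sets
#'
#' A random, seed-reproducible partition. The development size is
#' `round(dev_fraction * n)` with round-half-to-even, matching the study
#' cohort arithmetic (80% of 1,205 = 964; 75% of 340 = 255).
#'
#' @param cohort a `uq_cohort`.
#' @param dev_fraction development fraction in (0, 1); 0.80 for NTCP-style and
#'   0.75 for TCP-style cohorts.
#' @param seed integer seed for the permutation.
#' @return A list with elements `development` and `independent_validation`;
#'   the two are disjoint and exhaustive.
#' @export
split_cohort <- function(cohort, dev_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(cohort, "uq_cohort"),
            dev_fraction > 0, dev_fraction < 1)
  n <- cohort_size(cohort)
  n_dev <- partition_size(n, dev_fraction)
  perm <- with_seed(seed, sample.int(n))
  dev_idx <- sort(perm[seq_len(n_dev)])
  val_idx <- sort(perm[-seq_len(n_dev)])
  list(
    development = subset_cohort(cohort, dev_idx, split = "development"),
    independent_validation = subset_cohort(cohort, val_idx,
                                           split = "independent_validation")
  )
}

#' Split a development cohort into training and validation sets
#'
#' Same mechanics as [split_cohort()]; 80%/20% by default, as used for model
#' fitting and early stopping.
#'
#' @param development a `uq_cohort` (the development set).
#' @param train_fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return A list with elements `train` and `valid`.
#' @export
inner_split <- function(development, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(development, "uq_cohort"),
            train_fraction > 0, train_fraction < 1)
  n <- cohort_size(development)
  n_train <- partition_size(n, train_fraction)
  perm <- with_seed(seed, sample.int(n))
  tr_idx <- sort(perm[seq_len(n_train)])
  va_idx <- sort(perm[-seq_len(n_train)])
  list(
    train = subset_cohort(development, tr_idx, split = "train"),
    valid = subset_cohort(development, va_idx, split = "valid")
  )
}

#' Apply a covariate shift to a cohort
#'
#' Offsets and/or rescales the continuous covariates and regenerates true
#' probabilities and labels from the shifted covariates under the cohort's own
#' generative model. Used to create out-of-distribution test sets on which
#' epistemic uncertainty should rise.
#'
#' @param cohort a `uq_cohort` produced by [generate_cohort()].
#' @param shift list with `mean` (scalar or per-continuous-feature offset,
#'   default 0) and `scale` (scalar or per-feature multiplier, default 1).
#' @param seed integer seed for regenerating labels.
#' @return A shifted `uq_cohort`.
#' @export
apply_covariate_shift <- function(cohort, shift, seed = NULL) {
  stopifnot(inherits(cohort, "uq_cohort"))
  spec <- cohort$spec
  mu <- shift$mean %||% 0
  sc <- shift$scale %||% 1
  if (!length(mu) %in% c(1L, spec$n_continuous) ||
      !length(sc) %in% c(1L, spec$n_continuous)) {
    stop("shift dimensions must be scalar or match n_continuous", call. = FALSE)
  }
  out <- cohort
  if (spec$n_continuous > 0) {
    cols <- paste0("cont_", seq_len(spec$n_continuous))
    shifted <- sweep(sweep(as.matrix(cohort$features[, cols, drop = FALSE]),
                           2, rep(sc, length.out = spec$n_continuous), `*`),
                     2, rep(mu, length.out = spec$n_continuous), `+`)
    out$features[, cols] <- shifted
  }
  eta <- linear_predictor(out$features, spec)
  out$true_prob <- vapply(cohort$intercepts,
                          function(b0) stats::plogis(b0 + eta),
                          numeric(nrow(out$features)))
  dimnames(out$true_prob) <- dimnames(cohort$true_prob)
  seed <- seed %||% derive_seed(spec$seed, "shift-labels")
  out$labels <- with_seed(seed, {
    y <- matrix(stats::rbinom(length(out$true_prob), 1L,
                              as.vector(out$true_prob)),
                nrow = nrow(out$true_prob),
                dimnames = dimnames(out$true_prob))
    if (spec$label_noise > 0) {
      flip <- matrix(stats::runif(length(y)) < spec$label_noise, nrow = nrow(y))
      y[flip] <- 1L - y[flip]
    }
    y
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
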