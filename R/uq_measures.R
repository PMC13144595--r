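# Uncertainty measures: reduce a patient's T prediction samples to one
# scalar. Binary entropy of the mean prediction is total predictive
# uncertainty in bits (range [0,1]); the population variance of the samples
# measures their dispersion (range [0,0.25]); mutual information (BALD) is
# the epistemic component, the gap between the entropy of the mean and the
# mean per-sample entropy.

#' Binary entropy in bits
#'
#' `H(p) = -p log2(p) - (1-p) log2(1-p)` with the convention `0 log 0 = 0`,
#' so `H` maps `[0,1]` onto `[0,1]` with its maximum of 1 bit at `p = 0.5`.
#'
#' @param p probabilities in `[0, 1]` (vectorised).
#' @return Entropy values in bits, same length as `p`.
#' @export
#' @examples
#' binary_entropy(c(0, 0.2, 0.5, 1))
binary_entropy <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

new_uncertainty_scores <- function(value, measure, method = NULL,
                                   patient_id = NULL, normalised = FALSE,
                                   bounds = NULL, reference = NULL) {
  structure(
    list(value = value, measure = measure, method = method,
         patient_id = patient_id, normalised = normalised,
         bounds = bounds, reference = reference),
    class = "uncertainty_scores"
  )
}

#' @export
print.uncertainty_scores <- function(x, ...) {
  cat(sprintf("Uncertainty scores [%s%s], %d patients%s\n",
              x$measure,
              if (!is.null(x$method)) paste0(", ", x$method) else "",
              length(x$value),
              if (x$normalised) " (min-max normalised)" else ""))
  print(summary(x$value))
  invisible(x)
}

#' @export
as.numeric.uncertainty_scores <- function(x, ...) x$value

#' Predictive entropy of the mean prediction
#'
#' Binary entropy of each patient's mean prediction: the total predictive
#' uncertainty, already bounded in `[0, 1]` bits so it needs no rescaling.
#'
#' @param samples a [prediction_samples] object.
#' @return An `uncertainty_scores` object with measure `"entropy"`.
#' @export
predictive_entropy <- function(samples) {
  stopifnot(inherits(samples, "prediction_samples"))
  new_uncertainty_scores(binary_entropy(samples$mean_prediction),
                         measure = "entropy", method = samples$method,
                         patient_id = samples$patient_id)
}

#' Variance of the prediction samples
#'
#' Per-patient population variance (divisor T, not T-1: T is fixed by design,
#' not an estimate of a larger sample) of the sampled probabilities. Bounded
#' by `pbar(1-pbar) <= 0.25`.
#'
#' @param samples a [prediction_samples] object with at least 2 samples.
#' @return An `uncertainty_scores` object with measure `"variance"`.
#' @export
sample_variance <- function(samples) {
  stopifnot(inherits(samples, "prediction_samples"), samples$n_samples >= 2)
  v <- rowMeans((samples$samples - samples$mean_prediction)^2)
  new_uncertainty_scores(v, measure = "variance", method = samples$method,
                         patient_id = samples$patient_id)
}

#' Mutual information between prediction and model draw (BALD)
#'
#' `MI = H(pbar) - mean_t H(p_t)`: the information the sampled model draws
#' carry about the outcome, interpreted as epistemic uncertainty. Always
#' non-negative by Jensen's inequality (strict concavity of `H`); tiny
#' negative values from floating-point cancellation -- MI is a difference of
#' two nearly equal entropies, which is what makes it numerically fragile in
#' binary problems -- are clamped to 0.
#'
#' @param samples a [prediction_samples] object with at least 2 samples.
#' @return An `uncertainty_scores` object with measure `"mutual_information"`,
#'   values in bits.
#' @export
mutual_information <- function(samples) {
  stopifnot(inherits(samples, "prediction_samples"), samples$n_samples >= 2)
  h_mean <- binary_entropy(samples$mean_prediction)
  mean_h <- rowMeans(matrix(binary_entropy(as.vector(samples$samples)),
                            nrow = nrow(samples$samples)))
  mi <- h_mean - mean_h
  mi[mi < 0] <- 0 # Jensen guarantees mi >= -eps; eps is float cancellation
  new_uncertainty_scores(mi, measure = "mutual_information",
                         method = samples$method,
                         patient_id = samples$patient_id)
}

#' Min-max normalise uncertainty scores
#'
#' Rescales scores to `[0, 1]` using the minimum and maximum observed in a
#' reference cohort (by default the scores themselves, i.e. the independent
#' validation cohort on which they were computed). Values outside the
#' reference range are clipped. Variance and mutual information need this
#' before calibration analyses; entropy is already bounded in `[0, 1]`.
#'
#' @param scores an `uncertainty_scores` object.
#' @param reference an `uncertainty_scores` object supplying the bounds.
#' @return A normalised `uncertainty_scores` object with the bounds recorded.
#'   A degenerate reference (max equal to min) maps everything to 0, with a
#'   warning.
#' @export
minmax_normalise <- function(scores, reference = scores) {
  stopifnot(inherits(scores, "uncertainty_scores"),
            inherits(reference, "uncertainty_scores"),
            length(reference$value) >= 1)
  lo <- min(reference$value)
  hi <- max(reference$value)
  if (hi <= lo) {
    warning("degenerate reference (max == min): all normalised scores set to 0")
    val <- rep(0, length(scores$value))
  } else {
    val <- pmin(pmax((scores$value - lo) / (hi - lo), 0), 1)
  }
  new_uncertainty_scores(val, measure = scores$measure, method = scores$method,
                         patient_id = scores$patient_id, normalised = TRUE,
                         bounds = c(min = lo, max = hi),
                         reference = reference$method)
}

#' Compute all three uncertainty measures for one sample set
#'
#' @param samples a [prediction_samples] object.
#' @param normalise normalise variance and MI by min-max over the samples'
#'   own cohort (entropy is left on its natural `[0,1]` bit scale).
#' @return Named list of `uncertainty_scores`: `entropy`, `variance`,
#'   `mutual_information`.
#' @export
uncertainty_measures <- function(samples, normalise = FALSE) {
  out <- list(entropy = predictive_entropy(samples),
              variance = sample_variance(samples),
              mutual_information = mutual_information(samples))
  if (normalise) {
    out$variance <- minmax_normalise(out$variance)
    out$mutual_information <- minmax_normalise(out$mutual_information)
  }
  out
}
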