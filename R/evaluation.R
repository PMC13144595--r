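# Evaluation of predictions and uncertainties: discrimination (AUC,
# accuracy at a fixed or Youden threshold), calibration with adaptive
# equal-frequency bins of at least 25 patients (ACE), DeLong comparison of
# correlated AUCs, sparsification analysis, and bootstrap intervals.

check_binary <- function(labels) {
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(labels)
}

#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, with ties counting one half: the Mann-Whitney U statistic
#' normalised by the number of positive-negative pairs, computed via midranks.
#'
#' @param labels 0/1 outcome vector (both classes present).
#' @param scores numeric scores, higher meaning more probably positive.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)) # 0.75
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  check_binary(labels)
  r <- rank(scores, ties.method = "average")
  n1 <- as.numeric(sum(labels == 1)) # numeric: n1*n0 overflows int at n ~ 1e5
  n0 <- as.numeric(sum(labels == 0))
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy at a probability threshold
#'
#' @param labels 0/1 outcome vector.
#' @param probabilities predicted probabilities.
#' @param threshold classification threshold in (0, 1); 0.5 throughout the
#'   reference analyses.
#' @return Fraction of patients with `(probability >= threshold) == label`.
#' @export
accuracy <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities),
            threshold > 0, threshold < 1)
  mean((probabilities >= threshold) == (labels == 1))
}

#' Youden's J-optimal threshold
#'
#' Maximises `J = sensitivity + specificity - 1` over cut-points placed at
#' midpoints between consecutive distinct scores; ties are broken towards the
#' lowest threshold, and perfectly separated classes yield the midpoint of
#' the separating gap.
#'
#' @param labels 0/1 outcome vector (both classes present).
#' @param probabilities numeric scores.
#' @return The threshold, a single number.
#' @export
youden_threshold <- function(labels, probabilities) {
  stopifnot(length(labels) == length(probabilities))
  check_binary(labels)
  u <- sort(unique(probabilities))
  if (length(u) == 1L) return(u)
  cand <- (u[-1] + u[-length(u)]) / 2
  pos <- probabilities[labels == 1]
  neg <- probabilities[labels == 0]
  j <- vapply(cand, function(t) mean(pos >= t) + mean(neg < t) - 1, 0)
  cand[which.max(j)]
}

# Midrank structural components (V10 over positives, V01 over negatives).
delong_components <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = sum(v10) / m, v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided test of equality of the AUCs of two score vectors evaluated on
#' the same patients, using the structural-components covariance estimate.
#' A degenerate zero-variance difference (e.g. identical scores) gives
#' p = 1 by convention.
#'
#' @param labels 0/1 outcome vector (both classes present).
#' @param scores_a,scores_b paired score vectors on the identical patients.
#' @return An object of class `delong_test`: list with `auc_a`, `auc_b`,
#'   `delta`, `z`, `p_value`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) ||
      length(labels) != length(scores_a)) {
    stop("labels, scores_a and scores_b must have identical length",
         call. = FALSE)
  }
  check_binary(labels)
  ca <- delong_components(labels, scores_a)
  cb <- delong_components(labels, scores_b)
  s10 <- stats::var(ca$v10 - cb$v10)
  s01 <- stats::var(ca$v01 - cb$v01)
  var_diff <- s10 / ca$m + s01 / ca$n
  delta <- ca$auc - cb$auc
  if (!is.finite(var_diff) || var_diff < 1e-16) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
                 z = z, p_value = p),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong test: AUC_a = %.4f, AUC_b = %.4f, delta = %+.4f\n",
              x$auc_a, x$auc_b, x$delta))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$z, x$p_value))
  invisible(x)
}

#' Adaptive equal-frequency bin assignment
#'
#' Partitions patients into quantile bins of at least `min_per_bin` patients
#' each: `floor(n / min_per_bin)` bins, the remainder distributed one patient
#' at a time to the lowest bins. Tied values are never split across a bin
#' boundary (the boundary moves up, so counts may exceed the nominal size);
#' any bin starved below the floor by tie absorption is merged with its
#' neighbour.
#'
#' @param values numeric values to bin (predicted probability or certainty).
#' @param min_per_bin minimum patients per bin (25 in the reference setup).
#' @return Integer vector of bin indices (1 = lowest values), with the bin
#'   sizes in the `"sizes"` attribute.
#' @export
#' @examples
#' table(adaptive_bins(runif(110), 25)) # sizes 28, 28, 27, 27
adaptive_bins <- function(values, min_per_bin = 25L) {
  n <- length(values)
  if (n < min_per_bin) {
    stop(sprintf("need at least min_per_bin = %d values, got %d",
                 min_per_bin, n), call. = FALSE)
  }
  n_bins <- n %/% min_per_bin
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(values)
  v <- values[ord]
  bounds <- cumsum(sizes)
  if (n_bins > 1L) {
    for (i in seq_len(n_bins - 1L)) {
      k <- bounds[i]
      while (k < n && v[k + 1L] == v[k]) k <- k + 1L
      bounds[i] <- k
    }
    bounds <- unique(cummax(bounds))
  }
  # merge any bin pushed below the floor by tie absorption
  repeat {
    bsz <- diff(c(0L, bounds))
    small <- which(bsz < min_per_bin)
    if (length(small) == 0L || length(bounds) == 1L) break
    i <- small[1L]
    bounds <- if (i == 1L) bounds[-1L] else bounds[-(i - 1L)]
  }
  assignment <- integer(n)
  lo <- 1L
  for (b in seq_along(bounds)) {
    assignment[ord[lo:bounds[b]]] <- b
    lo <- bounds[b] + 1L
  }
  structure(assignment, sizes = diff(c(0L, bounds)))
}

new_calibration_result <- function(variant, bins, ace, min_per_bin,
                                   threshold = NA_real_) {
  structure(list(variant = variant, bins = bins, ace = ace,
                 min_per_bin = min_per_bin, threshold = threshold),
            class = "calibration_result")
}

#' Adaptive calibration error of predicted probabilities
#'
#' Bins patients by predicted probability into adaptive equal-frequency bins
#' (at least `min_per_bin` each) and reports the unweighted mean over bins of
#' the absolute gap between the observed event fraction and the mean
#' predicted probability.
#'
#' @param labels 0/1 outcome vector.
#' @param probabilities predicted probabilities.
#' @param min_per_bin minimum patients per bin.
#' @return A `calibration_result` with variant `"prediction_calibration"`:
#'   per-bin table (`n`, `confidence`, `observed`) and the ACE value.
#' @export
prediction_ace <- function(labels, probabilities, min_per_bin = 25L) {
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0, 1)))
  bin <- adaptive_bins(probabilities, min_per_bin)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel),
               confidence = mean(probabilities[sel]),
               observed = mean(labels[sel]))
  }))
  ace <- mean(abs(tab$observed - tab$confidence))
  new_calibration_result("prediction_calibration", tab, ace, min_per_bin)
}

#' Calibration of uncertainty against prediction accuracy
#'
#' Converts normalised uncertainty to certainty (`1 - uncertainty`), bins
#' patients by certainty into adaptive equal-frequency bins, and compares
#' each bin's classification accuracy (at `threshold`) with its mean
#' certainty. A well-calibrated uncertainty measure gives accuracy rising
#' with certainty and a small ACE-style gap.
#'
#' @param labels 0/1 outcome vector.
#' @param probabilities predicted probabilities (the mean prediction).
#' @param uncertainties normalised uncertainty values in `[0, 1]` (see
#'   [minmax_normalise()]); an `uncertainty_scores` object or numeric vector.
#' @param threshold classification threshold for accuracy.
#' @param min_per_bin minimum patients per bin.
#' @return A `calibration_result` with variant `"uncertainty_accuracy"`:
#'   per-bin table (`n`, `certainty`, `accuracy`) and the mean absolute
#'   certainty-accuracy gap as `ace`.
#' @export
uncertainty_accuracy_calibration <- function(labels, probabilities,
                                             uncertainties, threshold = 0.5,
                                             min_per_bin = 25L) {
  if (inherits(uncertainties, "uncertainty_scores")) {
    uncertainties <- uncertainties$value
  }
  stopifnot(length(labels) == length(probabilities),
            length(uncertainties) == length(labels))
  if (any(uncertainties < 0 | uncertainties > 1)) {
    stop("uncertainties must be normalised to [0, 1]", call. = FALSE)
  }
  certainty <- 1 - uncertainties
  correct <- (probabilities >= threshold) == (labels == 1)
  bin <- adaptive_bins(certainty, min_per_bin)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel),
               certainty = mean(certainty[sel]),
               accuracy = mean(correct[sel]))
  }))
  ace <- mean(abs(tab$accuracy - tab$certainty))
  new_calibration_result("uncertainty_accuracy", tab, ace, min_per_bin,
                         threshold = threshold)
}

#' @export
print.calibration_result <- function(x, ...) {
  lab <- if (x$variant == "prediction_calibration") {
    "prediction calibration (confidence vs event fraction)"
  } else "uncertainty-accuracy calibration (certainty vs accuracy)"
  cat(sprintf("%s\n  %d bins (>= %d patients each), ACE = %.4f\n",
              lab, nrow(x$bins), x$min_per_bin, x$ace))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' @export
plot.calibration_result <- function(x, ...) {
  if (x$variant == "prediction_calibration") {
    graphics::plot(x$bins$confidence, x$bins$observed, type = "b", pch = 19,
                   xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "mean predicted probability",
                   ylab = "observed event fraction", ...)
  } else {
    graphics::plot(x$bins$certainty, x$bins$accuracy, type = "b", pch = 19,
                   xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "mean certainty (1 - normalised uncertainty)",
                   ylab = "accuracy", ...)
  }
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Sparsification analysis
#'
#' Ranks patients by descending uncertainty (ties broken by patient id for
#' determinism), removes the single most uncertain patient per step, and
#' recomputes AUC and accuracy on the retained set after each removal, up to
#' `max_removed_fraction` of the cohort. Rising curves mean the uncertainty
#' ranks unreliable predictions first. If removal leaves a single class, AUC
#' is recorded as missing from that step on.
#'
#' @param labels 0/1 outcome vector (both classes present initially, n >= 4).
#' @param probabilities predicted probabilities.
#' @param uncertainties uncertainty values (`uncertainty_scores` or numeric).
#' @param threshold classification threshold for the accuracy curve.
#' @param max_removed_fraction stop after this fraction is removed (0.5 in
#'   the reference analyses: curves run to half the cohort).
#' @param patient_id optional ids for deterministic tie-breaking.
#' @return A `sparsification_curve`: data frame with `n_removed`,
#'   `fraction_removed`, `auc`, `accuracy` (one row per step, step 0 first).
#' @export
sparsification <- function(labels, probabilities, uncertainties,
                           threshold = 0.5, max_removed_fraction = 0.5,
                           patient_id = NULL) {
  if (inherits(uncertainties, "uncertainty_scores")) {
    if (is.null(patient_id)) patient_id <- uncertainties$patient_id
    uncertainties <- uncertainties$value
  }
  n <- length(labels)
  stopifnot(n >= 4, length(probabilities) == n, length(uncertainties) == n)
  check_binary(labels)
  patient_id <- patient_id %||% sprintf("P%05d", seq_len(n))
  ord <- order(-uncertainties, patient_id)
  max_removed <- floor(n * max_removed_fraction)
  keep <- rep(TRUE, n)
  steps <- 0:max_removed
  auc_v <- acc_v <- rep(NA_real_, length(steps))
  for (i in seq_along(steps)) {
    if (steps[i] > 0) keep[ord[steps[i]]] <- FALSE
    y <- labels[keep]
    p <- probabilities[keep]
    acc_v[i] <- accuracy(y, p, threshold)
    if (length(unique(y)) == 2L) auc_v[i] <- auc(y, p)
  }
  structure(
    data.frame(n_removed = steps, fraction_removed = steps / n,
               auc = auc_v, accuracy = acc_v),
    class = c("sparsification_curve", "data.frame"),
    threshold = threshold
  )
}

#' @export
plot.sparsification_curve <- function(x, metric = c("auc", "accuracy"), ...) {
  metric <- match.arg(metric)
  graphics::plot(x$fraction_removed, x[[metric]], type = "l", lwd = 2,
                 xlab = "fraction of most-uncertain patients removed",
                 ylab = toupper(metric), ...)
  invisible(x)
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples patients with replacement within each outcome class (so every
#' replicate keeps both classes) and returns percentile quantiles of the
#' metric.
#'
#' @param metric_fn function of `(labels, scores)` returning a scalar, e.g.
#'   [auc()] or a closure around [prediction_ace()].
#' @param labels 0/1 outcome vector.
#' @param scores numeric scores passed to `metric_fn`.
#' @param B number of bootstrap replicates (>= 100).
#' @param alpha two-sided level; 0.05 gives a 95% interval.
#' @param seed integer seed.
#' @return Named vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(metric_fn, labels, scores, B = 1000L, alpha = 0.05,
                         seed = 1L) {
  stopifnot(B >= 100, length(labels) == length(scores))
  idx1 <- which(labels == 1)
  idx0 <- which(labels == 0)
  stats_b <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(sample(idx1, length(idx1), replace = TRUE),
               sample(idx0, length(idx0), replace = TRUE))
      metric_fn(labels[idx], scores[idx])
    }, 0)
  })
  q <- stats::quantile(stats_b, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(lower = q[1], upper = q[2])
}
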