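# End-to-end experiment designs: the method x measure comparison (metrics
# table, uncertainty-accuracy calibration grid, sparsification curves) and
# the training-set-size experiment, both on synthetic cohorts and fully
# reproducible from one master seed.

#' Experiment configuration
#'
#' Bundles everything one experiment needs. Defaults mirror the reference
#' study design: 50 MC-dropout passes, ensembles of 10, 50 TTA copies,
#' dropout grid 0.1--0.5, calibration bins of at least 25 patients,
#' classification threshold 0.5, and training-size increments of 100 (NTCP)
#' or 50 (TCP) patients repeated 10 times.
#'
#' @param spec a [cohort_spec()] for the synthetic cohort; its
#'   `"dev_fraction"` attribute, if any, supplies the development fraction.
#' @param dev_fraction development / independent-validation split fraction.
#' @param train_fraction train / valid split fraction within development.
#' @param base_config a [model_config()] for the baseline and ensemble
#'   members; the MC-dropout model overrides its dropout rate by grid search.
#' @param dropout_grid candidate dropout rates for MC dropout.
#' @param n_mc_samples,n_tta_samples stochastic passes / augmented copies T.
#' @param n_members ensemble size M.
#' @param augmentation an [augmentation_policy()]; used for training-time
#'   augmentation of the baseline model and for TTA.
#' @param threshold classification threshold for accuracy.
#' @param min_per_bin minimum patients per calibration bin.
#' @param bootstrap_B bootstrap replicates for the confidence intervals.
#' @param scaling list for [training_size_experiment()]: `increment` (N
#'   patients added per step), `repeats` (independent repeats R), `method`
#'   (which UQ method to retrain per cell), and `dropout_rate` (fixed rate
#'   for the MC-dropout scaling model; `NULL` selects it once at full size).
#' @param seed master seed; every stage derives child seeds from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(spec = ntcp_cohort_spec(),
                              dev_fraction = attr(spec, "dev_fraction") %||% 0.8,
                              train_fraction = 0.8,
                              base_config = model_config(),
                              dropout_grid = c(0.1, 0.2, 0.3, 0.4, 0.5),
                              n_mc_samples = 50L,
                              n_tta_samples = 50L,
                              n_members = 10L,
                              augmentation = augmentation_policy(),
                              threshold = 0.5,
                              min_per_bin = 25L,
                              bootstrap_B = 1000L,
                              scaling = list(increment = 100L, repeats = 10L,
                                             method = "mc_dropout",
                                             dropout_rate = 0.2),
                              seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), scaling$increment >= 1,
            scaling$repeats >= 1)
  structure(
    list(spec = spec, dev_fraction = dev_fraction,
         train_fraction = train_fraction, base_config = base_config,
         dropout_grid = dropout_grid, n_mc_samples = as.integer(n_mc_samples),
         n_tta_samples = as.integer(n_tta_samples),
         n_members = as.integer(n_members), augmentation = augmentation,
         threshold = threshold, min_per_bin = as.integer(min_per_bin),
         bootstrap_B = as.integer(bootstrap_B), scaling = scaling,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# Shared first stage: generate, split, inner-split.
prepare_cohorts <- function(config) {
  cohort <- generate_cohort(config$spec)
  outer <- split_cohort(cohort, config$dev_fraction,
                        seed = derive_seed(config$seed, "outer-split"))
  inner <- inner_split(outer$development, config$train_fraction,
                       seed = derive_seed(config$seed, "inner-split"))
  list(full = cohort, development = outer$development,
       independent = outer$independent_validation,
       train = inner$train, valid = inner$valid)
}

measure_set <- c("entropy", "variance", "mutual_information")

#' Run the UQ method x measure comparison
#'
#' For each endpoint: trains the baseline model, selects the MC-dropout rate
#' on the validation cohort, trains the deep ensemble, then evaluates all
#' three methods on the independent validation cohort: AUC and ACE with
#' bootstrap intervals, accuracy at the fixed and Youden thresholds, DeLong
#' tests against the baseline, the 3 x 3 uncertainty-accuracy calibration
#' grid (variance and MI min-max normalised on the independent cohort), and
#' sparsification curves per method-measure pair.
#'
#' @param config an [experiment_config()].
#' @param endpoints endpoints to analyse (default: all in the spec).
#' @return An object of class `uq_comparison`: per-endpoint results plus the
#'   config. Use [render_report()] to write tables, curves and figures.
#' @export
run_uq_comparison <- function(config, endpoints = config$spec$endpoints) {
  stopifnot(inherits(config, "experiment_config"))
  ch <- prepare_cohorts(config)
  results <- lapply(endpoints, function(ep) {
    seed_ep <- function(key) derive_seed(config$seed, paste0(ep, ":", key))
    y <- ch$independent$labels[, ep]

    baseline <- train_model(ch$train, ch$valid, ep, config$base_config,
                            augmentation = config$augmentation,
                            seed = seed_ep("baseline"))
    p_base <- predict_deterministic(baseline, ch$independent)

    sel <- select_dropout_rate(ch$train, ch$valid, ep,
                               grid = config$dropout_grid,
                               base_config = config$base_config,
                               n_samples = config$n_mc_samples,
                               seed = seed_ep("dropout-grid"))
    mc_model <- sel$models[[as.character(sel$rate)]]
    ensemble <- train_ensemble(ch$train, ch$valid, ep,
                               n_members = config$n_members,
                               base_config = config$base_config,
                               seed = seed_ep("ensemble"))

    samples <- list(
      mc_dropout = mc_dropout_predict(mc_model, ch$independent,
                                      n_samples = config$n_mc_samples,
                                      seed = seed_ep("mc")),
      deep_ensemble = ensemble_predict(ensemble, ch$independent),
      tta = tta_predict(baseline, ch$independent, config$augmentation,
                        n_samples = config$n_tta_samples,
                        seed = seed_ep("tta"))
    )

    raw <- lapply(samples, uncertainty_measures)
    norm <- lapply(raw, function(ms) {
      list(entropy = ms$entropy, # already on [0,1] bits
           variance = minmax_normalise(ms$variance),
           mutual_information = minmax_normalise(ms$mutual_information))
    })

    metric_row <- function(method, prob, ref = NULL) {
      auc_ci <- bootstrap_ci(auc, y, prob, B = config$bootstrap_B,
                             seed = seed_ep(paste0("boot-auc:", method)))
      ace_fn <- function(l, s) prediction_ace(l, s, config$min_per_bin)$ace
      ace_ci <- bootstrap_ci(ace_fn, y, prob, B = config$bootstrap_B,
                             seed = seed_ep(paste0("boot-ace:", method)))
      data.frame(
        endpoint = ep, method = method,
        auc = auc(y, prob), auc_lower = auc_ci[1], auc_upper = auc_ci[2],
        ace = ace_fn(y, prob), ace_lower = ace_ci[1], ace_upper = ace_ci[2],
        accuracy = accuracy(y, prob, config$threshold),
        accuracy_youden = accuracy(y, prob, youden_threshold(y, prob)),
        delong_p = if (is.null(ref)) NA_real_ else
          delong_test(y, prob, ref)$p_value,
        row.names = NULL
      )
    }
    metrics <- rbind(
      metric_row("baseline", p_base),
      metric_row("mc_dropout", samples$mc_dropout$mean_prediction, p_base),
      metric_row("deep_ensemble", samples$deep_ensemble$mean_prediction,
                 p_base),
      metric_row("tta", samples$tta$mean_prediction, p_base)
    )

    calibration <- lapply(names(samples), function(m) {
      stats::setNames(lapply(measure_set, function(ms) {
        uncertainty_accuracy_calibration(
          y, samples[[m]]$mean_prediction, norm[[m]][[ms]],
          threshold = config$threshold, min_per_bin = config$min_per_bin)
      }), measure_set)
    })
    names(calibration) <- names(samples)

    curves <- lapply(names(samples), function(m) {
      stats::setNames(lapply(measure_set, function(ms) {
        sparsification(y, samples[[m]]$mean_prediction, raw[[m]][[ms]],
                       threshold = config$threshold,
                       patient_id = ch$independent$patient_id)
      }), measure_set)
    })
    names(curves) <- names(samples)

    list(endpoint = ep, n_independent = length(y),
         dropout_selection = sel[c("rate", "auc")],
         baseline_prob = p_base, samples = samples,
         measures_raw = raw, measures_norm = norm,
         metrics = metrics, calibration = calibration,
         sparsification = curves)
  })
  names(results) <- endpoints
  structure(list(endpoints = results, config = config,
                 cohort_sizes = vapply(ch, cohort_size, 0L)),
            class = "uq_comparison")
}

#' @export
print.uq_comparison <- function(x, ...) {
  cat("UQ method x measure comparison\n")
  cat(sprintf("  cohorts: %s\n",
              paste(sprintf("%s=%d", names(x$cohort_sizes), x$cohort_sizes),
                    collapse = ", ")))
  for (ep in names(x$endpoints)) {
    r <- x$endpoints[[ep]]
    cat(sprintf("\nEndpoint '%s' (selected dropout rate %.1f):\n",
                ep, r$dropout_selection$rate))
    print(r$metrics[, c("method", "auc", "ace", "accuracy", "delong_p")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Run the training-set-size experiment
#'
#' Retrains one UQ model on nested training subsets of increasing size
#' (N, 2N, 3N, ... patients sampled without replacement from the training
#' cohort, stopping when fewer than N unsampled patients remain) while the
#' validation and independent validation cohorts stay fixed, and repeats the
#' whole procedure R times with fresh sampling orders. Per cell it records
#' the mean and SD over patients of each raw uncertainty measure on the
#' independent cohort, the AUC and accuracy of the mean prediction, the
#' uncertainty-accuracy calibration error, and a checksum of the independent
#' cohort (constant across cells by construction).
#'
#' @param config an [experiment_config()]; `config$scaling` sets the
#'   increment N, the repeats R, the UQ method, and (for MC dropout) the
#'   fixed dropout rate, selected once at full size when `NULL`.
#' @param endpoint endpoint to model (default: first in the spec).
#' @return An object of class `scaling_result`: `cells` (one row per
#'   repeat x size), `uncertainty` (one row per repeat x size x measure),
#'   `sampling_orders` (per-repeat patient order; the size-k subset is its
#'   first k ids, so subsets are nested by construction), and `summary`
#'   (mean and SD over repeats).
#' @export
training_size_experiment <- function(config,
                                     endpoint = config$spec$endpoints[1]) {
  stopifnot(inherits(config, "experiment_config"))
  sc <- config$scaling
  method <- match.arg(sc$method %||% "mc_dropout",
                      c("mc_dropout", "deep_ensemble", "tta"))
  ch <- prepare_cohorts(config)
  n_pool <- cohort_size(ch$train)
  N <- as.integer(sc$increment)
  if (n_pool < 2L * N) {
    stop(sprintf("training cohort (%d) too small for two increments of N=%d",
                 n_pool, N), call. = FALSE)
  }
  sizes <- seq(N, (n_pool %/% N) * N, by = N)
  y <- ch$independent$labels[, endpoint]
  indep_hash <- cohort_checksum(ch$independent)

  cfg <- config$base_config
  if (method == "mc_dropout") {
    rate <- sc$dropout_rate
    if (is.null(rate)) {
      rate <- select_dropout_rate(ch$train, ch$valid, endpoint,
                                  grid = config$dropout_grid,
                                  base_config = cfg,
                                  n_samples = config$n_mc_samples,
                                  seed = derive_seed(config$seed,
                                                     "scaling-rate"))$rate
    }
    cfg$dropout_rate <- rate
  }

  cells <- list()
  unc <- list()
  sampling_orders <- vector("list", sc$repeats)
  for (r in seq_len(sc$repeats)) {
    perm <- with_seed(derive_seed(config$seed, paste0("scaling-perm:", r)),
                      sample.int(n_pool))
    sampling_orders[[r]] <- ch$train$patient_id[perm]
    for (size in sizes) {
      sub <- subset_cohort(ch$train, sort(perm[seq_len(size)]))
      seed_cell <- derive_seed(config$seed,
                               sprintf("scaling:%d:%d", r, size))
      ps <- switch(method,
        mc_dropout = {
          m <- train_model(sub, ch$valid, endpoint, cfg, seed = seed_cell)
          mc_dropout_predict(m, ch$independent,
                             n_samples = config$n_mc_samples,
                             seed = derive_seed(seed_cell, "mc"))
        },
        deep_ensemble = {
          ens <- train_ensemble(sub, ch$valid, endpoint,
                                n_members = config$n_members,
                                base_config = cfg, seed = seed_cell)
          ensemble_predict(ens, ch$independent)
        },
        tta = {
          m <- train_model(sub, ch$valid, endpoint, cfg,
                           augmentation = config$augmentation,
                           seed = seed_cell)
          tta_predict(m, ch$independent, config$augmentation,
                      n_samples = config$n_tta_samples,
                      seed = derive_seed(seed_cell, "tta"))
        })
      raw <- uncertainty_measures(ps)
      cal <- uncertainty_accuracy_calibration(
        y, ps$mean_prediction, raw$entropy,
        threshold = config$threshold, min_per_bin = config$min_per_bin)
      cells[[length(cells) + 1L]] <- data.frame(
        repeat_id = r, size = size, method = method,
        auc = auc(y, ps$mean_prediction),
        accuracy = accuracy(y, ps$mean_prediction, config$threshold),
        cal_error = cal$ace,
        indep_checksum = indep_hash)
      for (ms in measure_set) {
        unc[[length(unc) + 1L]] <- data.frame(
          repeat_id = r, size = size, method = method, measure = ms,
          mean = mean(raw[[ms]]$value), sd = stats::sd(raw[[ms]]$value))
      }
    }
  }
  cells <- do.call(rbind, cells)
  unc <- do.call(rbind, unc)
  summary_metrics <- do.call(rbind, lapply(split(cells, cells$size),
    function(d) data.frame(size = d$size[1],
                           auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc),
                           cal_error_mean = mean(d$cal_error))))
  summary_unc <- do.call(rbind, lapply(
    split(unc, interaction(unc$size, unc$measure)),
    function(d) data.frame(size = d$size[1], measure = d$measure[1],
                           mean = mean(d$mean), sd_between = stats::sd(d$mean),
                           sd_within = mean(d$sd))))
  summary_unc <- summary_unc[order(summary_unc$measure, summary_unc$size), ]
  rownames(summary_metrics) <- rownames(summary_unc) <- NULL
  structure(
    list(endpoint = endpoint, method = method, sizes = sizes,
         repeats = sc$repeats, sampling_orders = sampling_orders,
         cells = cells, uncertainty = unc,
         summary = list(metrics = summary_metrics, uncertainty = summary_unc),
         indep_checksum = indep_hash),
    class = "scaling_result"
  )
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("Training-set-size experiment [%s, endpoint '%s']\n",
              x$method, x$endpoint))
  cat(sprintf("  sizes %s, %d repeats\n",
              paste(range(x$sizes), collapse = "-"), x$repeats))
  print(x$summary$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.scaling_result <- function(x, ...) {
  su <- x$summary$uncertainty
  ent <- su[su$measure == "entropy", ]
  other <- su[su$measure != "entropy", ]
  # entropy lives on a much larger (bit) scale; it gets its own axis
  old <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(old))
  graphics::plot(other$size, other$mean, type = "n",
                 ylim = range(0, other$mean + other$sd_between),
                 xlab = "training set size",
                 ylab = "mean uncertainty (variance / MI)", ...)
  for (ms in unique(other$measure)) {
    d <- other[other$measure == ms, ]
    graphics::lines(d$size, d$mean, type = "b", pch = 19,
                    col = if (ms == "variance") "darkorange" else "purple")
  }
  graphics::par(new = TRUE)
  graphics::plot(ent$size, ent$mean, type = "b", pch = 17, col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4, col.axis = "steelblue")
  graphics::mtext("mean entropy (bits)", side = 4, line = 2.5,
                  col = "steelblue")
  graphics::legend("topleft",
                   c("variance", "mutual information", "entropy (right)"),
                   col = c("darkorange", "purple", "steelblue"),
                   pch = c(19, 19, 17), bty = "n", cex = 0.8)
  invisible(x)
}

#' Write tables, curves and figures for a results bundle
#'
#' Writes deterministic-named CSV/JSON tables and PNG figures emulating the
#' reference layouts: the per-endpoint metrics table, the 3 x 3
#' uncertainty-accuracy calibration grid, one sparsification figure per
#' endpoint, and (for scaling results) the size-vs-uncertainty plot with
#' entropy on its own axis. Re-rendering the same bundle reproduces
#' byte-identical CSV output.
#'
#' @param results a `uq_comparison` or `scaling_result`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
render_report <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  if (inherits(results, "uq_comparison")) {
    if (length(results$endpoints) == 0) {
      stop("empty results bundle: nothing to report", call. = FALSE)
    }
    metrics <- do.call(rbind, lapply(results$endpoints, `[[`, "metrics"))
    rownames(metrics) <- NULL
    w(metrics, "metrics.csv")
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         digits = NA, dataframe = "rows")
    files <- c(files, file.path(out_dir, "metrics.json"))
    for (ep in names(results$endpoints)) {
      r <- results$endpoints[[ep]]
      cal <- do.call(rbind, lapply(names(r$calibration), function(m) {
        do.call(rbind, lapply(measure_set, function(ms) {
          cbind(endpoint = ep, method = m, measure = ms,
                r$calibration[[m]][[ms]]$bins,
                ace = r$calibration[[m]][[ms]]$ace)
        }))
      }))
      w(cal, sprintf("calibration_%s.csv", ep))
      sp <- do.call(rbind, lapply(names(r$sparsification), function(m) {
        do.call(rbind, lapply(measure_set, function(ms) {
          cbind(endpoint = ep, method = m, measure = ms,
                as.data.frame(r$sparsification[[m]][[ms]]))
        }))
      }))
      w(sp, sprintf("sparsification_%s.csv", ep))
      # calibration grid figure (3 methods x 3 measures)
      png_path <- file.path(out_dir, sprintf("calibration_grid_%s.png", ep))
      grDevices::png(png_path, width = 1200, height = 1200, res = 150)
      old <- graphics::par(mfrow = c(3, 3), mar = c(4, 4, 2, 1))
      for (m in names(r$calibration)) {
        for (ms in measure_set) {
          plot(r$calibration[[m]][[ms]], main = paste(m, ms, sep = " / "))
        }
      }
      graphics::par(old)
      grDevices::dev.off()
      files <- c(files, png_path)
      png_path <- file.path(out_dir, sprintf("sparsification_%s.png", ep))
      grDevices::png(png_path, width = 1200, height = 500, res = 150)
      old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
      for (ms in measure_set) {
        first <- TRUE
        cols <- c(mc_dropout = "firebrick", deep_ensemble = "steelblue",
                  tta = "darkgreen")
        for (m in names(r$sparsification)) {
          d <- r$sparsification[[m]][[ms]]
          if (first) {
            graphics::plot(d$fraction_removed, d$accuracy, type = "l",
                           lwd = 2, col = cols[[m]], ylim = c(0, 1),
                           xlab = "fraction removed", ylab = "accuracy",
                           main = ms)
            first <- FALSE
          } else {
            graphics::lines(d$fraction_removed, d$accuracy, lwd = 2,
                            col = cols[[m]])
          }
        }
        graphics::legend("bottomright", names(cols), col = cols, lwd = 2,
                         bty = "n", cex = 0.7)
      }
      graphics::par(old)
      grDevices::dev.off()
      files <- c(files, png_path)
    }
  } else if (inherits(results, "scaling_result")) {
    w(results$cells, "scaling_cells.csv")
    w(results$uncertainty, "scaling_uncertainty.csv")
    w(results$summary$metrics, "scaling_summary_metrics.csv")
    w(results$summary$uncertainty, "scaling_summary_uncertainty.csv")
    png_path <- file.path(out_dir,
                          sprintf("scaling_%s_%s.png", results$method,
                                  results$endpoint))
    grDevices::png(png_path, width = 1000, height = 700, res = 150)
    plot(results)
    grDevices::dev.off()
    files <- c(files, png_path)
  } else {
    stop("unsupported results object: ", paste(class(results), collapse = "/"),
         call. = FALSE)
  }
  invisible(files)
}
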