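# Plain-text persistence: cohorts and specs round-trip through CSV/YAML so
# experiments can be archived and re-read without any binary formats.

#' Write / read a cohort as CSV
#'
#' One row per patient with columns `patient_id`, the `cont_*`/`cat_*`
#' features, one 0/1 column per endpoint, `true_prob_<endpoint>`, and `split`.
#'
#' @param cohort a `uq_cohort`.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `uq_cohort`. A cohort read back from CSV carries the spec only
#'   if one is supplied, so operations needing the generative model (e.g.
#'   [apply_covariate_shift()]) require `spec`.
#' @param spec optional [cohort_spec()] to re-attach on read.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "uq_cohort"))
  tp <- cohort$true_prob
  colnames(tp) <- paste0("true_prob_", colnames(tp))
  df <- cbind(patient_id = cohort$patient_id, cohort$features,
              as.data.frame(cohort$labels), as.data.frame(tp),
              split = cohort$split)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, spec = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feat_cols <- grep("^(cont|cat)_", names(df), value = TRUE)
  tp_cols <- grep("^true_prob_", names(df), value = TRUE)
  endpoints <- sub("^true_prob_", "", tp_cols)
  structure(
    list(
      patient_id = as.character(df$patient_id),
      features = df[, feat_cols, drop = FALSE],
      true_prob = as.matrix(stats::setNames(df[, tp_cols, drop = FALSE],
                                            endpoints)),
      labels = as.matrix(df[, endpoints, drop = FALSE]),
      split = as.character(df$split),
      intercepts = NULL,
      spec = spec
    ),
    class = "uq_cohort"
  )
}

#' Write / read a cohort specification as YAML
#'
#' @param spec a [cohort_spec()].
#' @param path file path.
#' @return `write_cohort_spec` returns `path` invisibly; `read_cohort_spec`
#'   a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  lst <- unclass(spec)
  lst$prevalence <- as.list(lst$prevalence)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  cohort_spec(
    n_patients = lst$n_patients,
    prevalence = unlist(lst$prevalence),
    n_continuous = lst$n_continuous,
    n_categorical = lst$n_categorical,
    n_levels = lst$n_levels,
    effect_sizes = list(cont = unlist(lst$effect_sizes$cont),
                        cat = lapply(lst$effect_sizes$cat, unlist)),
    label_noise = lst$label_noise,
    shift = lst$shift,
    seed = lst$seed
  )
}

#' Write prediction samples as CSV
#'
#' Persists a [prediction_samples] object as one row per patient:
#' `patient_id`, `sample_000` ... `sample_<T-1>`, `mean_prediction`, `method`.
#'
#' @param ps a `prediction_samples` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(ps, path) {
  stopifnot(inherits(ps, "prediction_samples"))
  s <- ps$samples
  colnames(s) <- sprintf("sample_%03d", seq_len(ncol(s)) - 1L)
  df <- cbind(patient_id = ps$patient_id, as.data.frame(s),
              mean_prediction = ps$mean_prediction, method = ps$method)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write uncertainty scores as CSV
#'
#' Columns: `patient_id`, `method`, `measure`, `raw_value`,
#' `normalised_value` (NA when the scores are unnormalised).
#'
#' @param scores an `uncertainty_scores` object (see [predictive_entropy()]).
#' @param path file path.
#' @param raw optional unnormalised companion scores; defaults to `scores`
#'   when `scores` is itself raw.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path, raw = NULL) {
  stopifnot(inherits(scores, "uncertainty_scores"))
  if (scores$normalised) {
    raw_value <- if (!is.null(raw)) raw$value else NA_real_
    norm_value <- scores$value
  } else {
    raw_value <- scores$value
    norm_value <- NA_real_
  }
  df <- data.frame(patient_id = scores$patient_id %||%
                     sprintf("P%05d", seq_along(scores$value)),
                   method = scores$method %||% NA_character_,
                   measure = scores$measure,
                   raw_value = raw_value,
                   normalised_value = norm_value)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
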