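# Internal utilities: hierarchical seed derivation, RNG scoping, numeric guards.

#' Derive a child seed from a master seed and a key
#'
#' Experiments use one master seed; every stochastic sub-step (cohort
#' generation, splitting, weight initialisation, dropout masks, ...) draws its
#' own seed from the master seed and a short string key, so that changing one
#' stage's key never perturbs another stage's stream.
#'
#' @param seed integer master seed.
#' @param key character key naming the sub-stream (e.g. "split", "init:3").
#' @return An integer in `[1, 2^31 - 2]`, deterministic in `(seed, key)`.
#' @export
#' @examples
#' derive_seed(42, "split")
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; multiplicative stream stays in range
  h <- (abs(as.numeric(seed)) %% m)
  for (ch in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 31 + ch) %% m
  }
  h <- (h * 48271) %% m
  as.integer(h + 1)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never disturbs user-level randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Clamp probabilities away from {0, 1} before taking logarithms.
clamp_prob <- function(p, eps = 1e-7) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Checksum of a cohort's patient-level content
#'
#' MD5 digest of a canonical text serialisation (ids, features, labels, true
#' probabilities, split). Used by the training-set-size experiment to assert
#' that the independent validation set is bitwise identical across all cells.
#'
#' @param cohort a [generate_cohort()] object.
#' @return A character MD5 digest.
#' @export
cohort_checksum <- function(cohort) {
  stopifnot(inherits(cohort, "uq_cohort"))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  df <- cbind(
    patient_id = cohort$patient_id,
    as.data.frame(round(cohort$features, 12)),
    as.data.frame(cohort$labels),
    as.data.frame(round(cohort$true_prob, 12)),
    split = cohort$split
  )
  utils::write.csv(df, tmp, row.names = FALSE, eol = "\n")
  unname(tools::md5sum(tmp))
}
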