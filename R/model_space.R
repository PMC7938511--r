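#' Enumerate the adjustment-set model universe
#'
#' Builds one Cox model specification per subset of the optional adjustment
#' variables, with the baseline adjustments (typically age and sex) forced
#' into every model. With `k` optional variables this yields `2^k` models;
#' the canonical all-cause-mortality analysis with 13 optional adjustments
#' gives `2^13 = 8192` models.
#'
#' Enumeration order is the binary-counter order: `model_id` runs from 0 to
#' `2^k - 1` and bit `i` (least significant bit = first listed optional
#' variable) indicates inclusion of `optional_vars[i]`. The order is fixed so
#' model ids are reproducible across runs.
#'
#' @param optional_vars Character vector of `k` optional adjustment names.
#' @param baseline_vars Character vector of always-included adjustment names.
#' @param exposure Name of the exposure variable.
#' @param max_k Safety cap on `k` (default 20); raise explicitly for larger
#'   universes.
#' @return A list of `model_spec` objects with fields `exposure`,
#'   `adjustments` (baseline first, then included optionals) and `model_id`.
#' @export
enumerate_models <- function(optional_vars, baseline_vars = character(),
                             exposure, max_k = 20) {
  optional_vars <- as.character(optional_vars)
  baseline_vars <- as.character(baseline_vars)
  if (length(intersect(optional_vars, baseline_vars))) {
    stop("optional and baseline adjustment sets must be disjoint",
         call. = FALSE)
  }
  if (exposure %in% c(optional_vars, baseline_vars)) {
    stop("the exposure cannot appear among the adjustment variables",
         call. = FALSE)
  }
  k <- length(optional_vars)
  if (k > max_k) {
    stop("k = ", k, " optional variables would enumerate 2^", k,
         " models; raise max_k to allow this", call. = FALSE)
  }
  lapply(seq_len(2^k) - 1L, function(id) {
    included <- if (k == 0) character() else
      optional_vars[bitwAnd(id, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    structure(
      list(exposure = exposure,
           adjustments = c(baseline_vars, included),
           model_id = id),
      class = "model_spec"
    )
  })
}

#' The favourite (all-adjustments) model for a cohort
#'
#' The single pre-chosen specification used for sampling and measurement
#' vibration: the exposure adjusted for every baseline and optional
#' adjustment variable in the schema.
#'
#' @param cohort A `voe_cohort`.
#' @return A `model_spec` with `model_id = NA`.
#' @export
favourite_model <- function(cohort) {
  stopifnot(inherits(cohort, "voe_cohort"))
  structure(
    list(exposure = schema_names_by_role(cohort$schema, "exposure"),
         adjustments = schema_names_by_role(
           cohort$schema, c("baseline_adjustment", "adjustment")),
         model_id = NA_integer_),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$exposure, " ~ ",
      paste(x$adjustments, collapse = " + "),
      if (!is.na(x$model_id)) paste0("  [id ", x$model_id, "]"),
      "\n", sep = "")
  invisible(x)
}
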