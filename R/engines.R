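new_voe_result <- function(vibration_type, estimates, reference = NULL,
                           scenario = NULL, settings = list(), seed = NULL) {
  structure(
    list(vibration_type = vibration_type, scenario = scenario,
         estimates = estimates, reference = reference,
         settings = settings, seed = seed),
    class = "voe_result"
  )
}

#' @export
print.voe_result <- function(x, ...) {
  cat("<voe_result> ", x$vibration_type,
      if (!is.null(x$scenario)) paste0(" (", x$scenario, ")"),
      ": ", nrow(x$estimates), " estimates, ",
      sum(!x$estimates$converged), " failed\n", sep = "")
  invisible(x)
}

# deterministic, order-independent per-iteration seed derived from the
# master seed; kept inside the 32-bit integer range
substream_seed <- function(seed, b) {
  as.integer((as.numeric(seed) %% 2147483647 + b * 104729) %% 2147483646 + 1)
}

subset_cohort <- function(cohort, idx) {
  cohort$data <- cohort$data[idx, , drop = FALSE]
  rownames(cohort$data) <- NULL
  cohort$n <- nrow(cohort$data)
  cohort
}

#' Model vibration: refit under every adjustment set
#'
#' Fits the exposure effect once per model in the enumerated adjustment-set
#' universe (see [enumerate_models()]): every subset of the optional
#' adjustment variables, with the baseline adjustments held in every model.
#' By default the optional and baseline sets are read off the schema roles
#' `adjustment` and `baseline_adjustment`.
#'
#' @param cohort A `voe_cohort`.
#' @param optional_vars,baseline_vars Adjustment-variable names; default to
#'   the schema roles.
#' @param use_design Use survey-design columns when present.
#' @param max_k Safety cap forwarded to [enumerate_models()].
#' @return A `voe_result` with `2^k` estimates tagged by `model_id`.
#' @export
model_vibration <- function(cohort, optional_vars = NULL,
                            baseline_vars = NULL, use_design = TRUE,
                            max_k = 20) {
  stopifnot(inherits(cohort, "voe_cohort"))
  if (is.null(optional_vars)) {
    optional_vars <- schema_names_by_role(cohort$schema, "adjustment")
  }
  if (is.null(baseline_vars)) {
    baseline_vars <- schema_names_by_role(cohort$schema, "baseline_adjustment")
  }
  exposure <- schema_names_by_role(cohort$schema, "exposure")
  specs <- enumerate_models(optional_vars, baseline_vars, exposure,
                            max_k = max_k)
  estimates <- fit_all(cohort, specs, use_design = use_design)
  new_voe_result("model", estimates,
                 settings = list(k = length(optional_vars),
                                 optional_vars = optional_vars,
                                 baseline_vars = baseline_vars,
                                 exposure = exposure))
}

#' Sampling vibration: refit the favourite model on random subsamples
#'
#' Draws `B` simple random subsets (without replacement) of size
#' `floor(fraction * n)` and refits the favourite model on each. The
#' reference estimate is the favourite-model fit on the full cohort.
#' Subsets are drawn ignoring any survey strata or clusters, but the fits
#' themselves still use the design columns.
#'
#' @param cohort A `voe_cohort`.
#' @param favourite A `model_spec`; defaults to [favourite_model()], the
#'   all-adjustments specification.
#' @param B Number of subsamples (default 1000).
#' @param fraction Subsample fraction in (0, 1) (default 0.5).
#' @param use_design Use survey-design columns in the fits.
#' @param seed Master seed; each iteration runs on its own substream.
#' @param max_fail Maximum tolerated fraction of non-converged fits.
#' @return A `voe_result` with `B` estimates tagged by iteration and an
#'   `n_used` settings entry recording the subset size.
#' @export
sampling_vibration <- function(cohort, favourite = NULL, B = 1000,
                               fraction = 0.5, use_design = TRUE,
                               seed = 1, max_fail = 0.05) {
  stopifnot(inherits(cohort, "voe_cohort"), B >= 1,
            fraction > 0, fraction < 1)
  if (is.null(favourite)) favourite <- favourite_model(cohort)
  m <- floor(fraction * cohort$n)
  if (m < 2) stop("subsample size floor(fraction * n) is too small",
                  call. = FALSE)

  reference <- fit_cox_effect(cohort, favourite, use_design = use_design)
  rows <- lapply(seq_len(B), function(b) {
    set.seed(substream_seed(seed, b))
    idx <- sample.int(cohort$n, m)
    est <- fit_cox_effect(subset_cohort(cohort, idx),
                          favourite, use_design = use_design)
    est$provenance_id <- b
    est
  })
  estimates <- do.call(rbind, rows)
  check_fail_fraction(estimates, max_fail, "sampling vibration")
  new_voe_result("sampling", estimates, reference = reference,
                 settings = list(B = B, fraction = fraction,
                                 subset_size = m),
                 seed = seed)
}

#' Measurement vibration: refit under simulated measurement error
#'
#' Repeats `B` times: draw one set of measurement-error parameters from the
#' uniform ranges, inject error into the targeted variables of the cohort
#' ([corrupt_cohort()]), re-standardize a continuous exposure when it was
#' corrupted (so hazard ratios stay per standard deviation), and refit the
#' favourite model. The reference estimate is the favourite-model fit on
#' the uncorrupted cohort.
#'
#' @inheritParams sampling_vibration
#' @param scenario Which variables receive error: `"exposure_only"`,
#'   `"adjustment_only"` or `"both"` (default).
#' @param ranges An [me_ranges()] object.
#' @return A `voe_result` with `B` estimates tagged by iteration, plus the
#'   realized parameter draws (`rho`, `sensitivity`, `specificity`) as
#'   estimate columns.
#' @export
measurement_vibration <- function(cohort, favourite = NULL,
                                  scenario = c("both", "exposure_only",
                                               "adjustment_only"),
                                  ranges = me_ranges(), B = 1000,
                                  use_design = TRUE, seed = 1,
                                  max_fail = 0.05) {
  stopifnot(inherits(cohort, "voe_cohort"), B >= 1)
  scenario <- match.arg(scenario)
  if (is.null(favourite)) favourite <- favourite_model(cohort)
  exp_var <- schema_names_by_role(cohort$schema, "exposure")
  exp_cont <- cohort$schema[[exp_var]]$kind == "continuous"

  reference <- fit_cox_effect(cohort, favourite, use_design = use_design)
  rows <- lapply(seq_len(B), function(b) {
    set.seed(substream_seed(seed, b))
    draw <- draw_me_params(ranges)
    corrupted <- corrupt_cohort(cohort, draw, scenario)
    if (exp_cont &&
        !identical(corrupted$data[[exp_var]], cohort$data[[exp_var]])) {
      corrupted <- standardize_continuous(corrupted, exp_var)
    }
    est <- fit_cox_effect(corrupted, favourite, use_design = use_design)
    est$provenance_id <- b
    est$rho <- draw$rho
    est$sensitivity <- draw$sensitivity
    est$specificity <- draw$specificity
    est
  })
  estimates <- do.call(rbind, rows)
  check_fail_fraction(estimates, max_fail, "measurement vibration")
  new_voe_result("measurement", estimates, reference = reference,
                 scenario = scenario,
                 settings = list(B = B, ranges = unclass(ranges)),
                 seed = seed)
}

check_fail_fraction <- function(estimates, max_fail, what) {
  frac <- mean(!estimates$converged)
  if (frac > max_fail) {
    stop(sprintf("%s: %.1f%% of fits failed to converge (threshold %.0f%%)",
                 what, 100 * frac, 100 * max_fail), call. = FALSE)
  }
  invisible(estimates)
}

#' Vibration across a sweep of sample sizes
#'
#' For each sample size, generates one synthetic cohort from the generator
#' specification and runs the selected vibration engines on it, returning
#' per-(size, engine) summary rows. The measurement engine uses the
#' both-variables error scenario. This is the simulation-study workhorse
#' for studying how vibration behaves as cohorts grow.
#'
#' @param gspec A [generator_spec()].
#' @param sizes Increasing vector of cohort sizes.
#' @param engines Subset of `c("model", "sampling", "measurement")`.
#' @param B Iterations for the sampling and measurement engines.
#' @param fraction Subsample fraction for the sampling engine.
#' @param ranges Measurement-error ranges.
#' @param seed Master seed; each size gets its own substream.
#' @param alpha,pct_lo,pct_hi Summary parameters.
#' @param max_k Cap for the model engine.
#' @return A data.frame with columns `n`, `vibration_type`, `rhr`, `rp`,
#'   `janus`, `n_neg_sig`, `n_nonsig`, `n_pos_sig`, `n_failed`.
#' @export
vibration_over_sample_sizes <- function(gspec, sizes,
                                        engines = c("model", "sampling",
                                                    "measurement"),
                                        B = 1000, fraction = 0.5,
                                        ranges = me_ranges(), seed = 1,
                                        alpha = 0.05, pct_lo = 1,
                                        pct_hi = 99, max_k = 20) {
  stopifnot(inherits(gspec, "generator_spec"), length(sizes) >= 1)
  if (is.unsorted(sizes, strictly = TRUE) || any(sizes <= 0)) {
    stop("sizes must be positive and strictly increasing", call. = FALSE)
  }
  engines <- match.arg(engines, several.ok = TRUE)

  rows <- list()
  for (i in seq_along(sizes)) {
    n <- sizes[i]
    set.seed(substream_seed(seed, 1000000 + i))
    cohort <- generate_cohort(gspec, n = n)
    for (eng in engines) {
      res <- switch(eng,
        model = model_vibration(cohort, max_k = max_k),
        sampling = sampling_vibration(cohort, B = B, fraction = fraction,
                                      seed = substream_seed(seed, 2000000 + i)),
        measurement = measurement_vibration(
          cohort, scenario = "both", ranges = ranges, B = B,
          seed = substream_seed(seed, 3000000 + i)))
      s <- summarize_vibration(res, alpha = alpha,
                               pct_lo = pct_lo, pct_hi = pct_hi)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, vibration_type = eng, rhr = s$rhr, rp = s$rp,
        janus = s$janus, n_neg_sig = s$n_neg_sig, n_nonsig = s$n_nonsig,
        n_pos_sig = s$n_pos_sig, n_failed = s$n_failed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
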