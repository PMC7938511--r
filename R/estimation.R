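#' Fit one Cox model and extract the exposure effect
#'
#' Fits a Cox proportional-hazards model for the given specification and
#' returns the exposure coefficient as a log hazard ratio together with its
#' robust (sandwich) standard error and two-sided Wald P-value. When the
#' cohort carries survey-design columns, sampling weights enter the partial
#' likelihood, strata enter as baseline-hazard strata and the sandwich
#' variance is clustered on the primary sampling units. Ties are handled by
#' the Efron approximation.
#'
#' Degenerate inputs (constant exposure, no events) and optimizer failures
#' yield a non-converged estimate (`converged = FALSE`, `se`/`p_value` NA)
#' rather than an error, so that vibration runs can tolerate occasional bad
#' iterations.
#'
#' @param cohort A `voe_cohort`.
#' @param spec A `model_spec` from [enumerate_models()] or
#'   [favourite_model()].
#' @param use_design Use the cohort's weight/stratum/cluster columns when
#'   present (default `TRUE`).
#' @return A one-row data.frame with columns `provenance_id`, `log_hr`, `hr`,
#'   `se`, `p_value`, `converged`.
#' @export
fit_cox_effect <- function(cohort, spec, use_design = TRUE) {
  stopifnot(inherits(cohort, "voe_cohort"), inherits(spec, "model_spec"))
  df <- cohort$data
  time_var <- schema_names_by_role(cohort$schema, "time")
  event_var <- schema_names_by_role(cohort$schema, "event")

  failed <- function() data.frame(
    provenance_id = spec$model_id, log_hr = NA_real_, hr = NA_real_,
    se = NA_real_, p_value = NA_real_, converged = FALSE)

  if (sum(df[[event_var]]) < 1 || length(unique(df[[spec$exposure]])) < 2) {
    return(failed())
  }

  rhs <- paste(c(spec$exposure, spec$adjustments), collapse = " + ")
  stratum <- if (use_design) cohort$design$stratum else NULL
  if (!is.null(stratum)) {
    rhs <- paste0(rhs, " + survival::strata(", stratum, ")")
  }
  fml <- stats::as.formula(
    paste0("survival::Surv(", time_var, ", ", event_var, ") ~ ", rhs))

  wts <- if (use_design && !is.null(cohort$design$weight)) {
    df[[cohort$design$weight]]
  }
  clst <- if (use_design && !is.null(cohort$design$cluster)) {
    df[[cohort$design$cluster]]
  }

  ok <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(fml, data = df, weights = wts, cluster = clst,
                      robust = TRUE, ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite|Infinite|singular|Loglik", conditionMessage(w))) {
          ok <<- FALSE
        }
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit) || !ok) return(failed())

  i <- match(spec$exposure, names(fit$coefficients))
  beta <- unname(fit$coefficients[i])
  se <- sqrt(diag(fit$var))[i]            # robust variance
  if (!is.finite(beta) || !is.finite(se) || se <= 0) return(failed())

  data.frame(
    provenance_id = spec$model_id,
    log_hr = beta,
    hr = exp(beta),
    se = se,
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    converged = TRUE
  )
}

#' Fit the exposure effect under a sequence of model specifications
#'
#' Runs [fit_cox_effect()] for each specification on the same cohort. Fits
#' are independent, so the result does not depend on execution order. The
#' run aborts if more than `max_fail` of the fits fail to converge, which
#' signals a structurally degenerate cohort rather than occasional bad luck.
#'
#' @param cohort A `voe_cohort`.
#' @param specs Non-empty list of `model_spec` objects.
#' @param use_design Use survey-design columns when present.
#' @param max_fail Maximum tolerated fraction of non-converged fits
#'   (default 0.05).
#' @return A data.frame with one row per specification, in input order.
#' @export
fit_all <- function(cohort, specs, use_design = TRUE, max_fail = 0.05) {
  if (length(specs) == 0L) stop("specs must be non-empty", call. = FALSE)
  out <- do.call(rbind, lapply(specs, function(s) {
    fit_cox_effect(cohort, s, use_design = use_design)
  }))
  rownames(out) <- NULL
  fail_frac <- mean(!out$converged)
  if (fail_frac > max_fail) {
    stop(sprintf("%.1f%% of model fits failed to converge (threshold %.0f%%)",
                 100 * fail_frac, 100 * max_fail), call. = FALSE)
  }
  if (fail_frac > 0) {
    message("fit_all: ", sum(!out$converged), " of ", nrow(out),
            " fits did not converge")
  }
  out
}
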