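#' Relative hazard ratio (RHR)
#'
#' The ratio of an upper to a lower percentile (by default the 99th and 1st)
#' of the hazard ratios observed across a vibration run. An RHR of 1 means
#' no vibration at all; larger values mean the estimate moves more across
#' analytic choices. Percentiles use linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @param hrs Numeric vector of at least two finite positive hazard ratios.
#' @param pct_lo,pct_hi Percentile levels in percent (defaults 1 and 99).
#' @return The relative hazard ratio (>= 1 when `pct_hi > pct_lo`).
#' @export
relative_hazard_ratio <- function(hrs, pct_lo = 1, pct_hi = 99) {
  hrs <- as.numeric(hrs)
  if (length(hrs) < 2) {
    stop("need at least two hazard ratios", call. = FALSE)
  }
  if (any(!is.finite(hrs)) || any(hrs <= 0)) {
    stop("hazard ratios must be finite and positive", call. = FALSE)
  }
  q <- stats::quantile(hrs, c(pct_lo, pct_hi) / 100, names = FALSE, type = 7)
  q[2] / q[1]
}

#' Relative P-value (RP)
#'
#' The difference between an upper and a lower percentile (by default the
#' 99th and 1st) of `-log10(p)` across a vibration run; 0 means the
#' statistical evidence is unchanged across analyses, and each unit is one
#' order of magnitude of P-value.
#'
#' @param pvals Numeric vector of P-values in (0, 1].
#' @param pct_lo,pct_hi Percentile levels in percent.
#' @return The relative P-value (>= 0 when `pct_hi > pct_lo`).
#' @export
relative_p <- function(pvals, pct_lo = 1, pct_hi = 99) {
  pvals <- as.numeric(pvals)
  if (length(pvals) < 2) stop("need at least two P-values", call. = FALSE)
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  nl <- -log10(pvals)
  q <- stats::quantile(nl, c(pct_lo, pct_hi) / 100, names = FALSE, type = 7)
  q[2] - q[1]
}

#' Classify estimates by direction and significance
#'
#' Splits converged estimates into negative significant (`p < alpha` and
#' log-HR < 0), positive significant (`p < alpha` and log-HR > 0) and
#' non-significant. A log-HR of exactly 0 is counted non-significant
#' regardless of its P-value, since it carries no direction.
#'
#' @param estimates Data.frame with columns `log_hr`, `p_value`, `converged`.
#' @param alpha Significance level (default 0.05).
#' @return Named integer vector `c(n_neg_sig, n_nonsig, n_pos_sig)`.
#' @export
classify_significance <- function(estimates, alpha = 0.05) {
  est <- estimates[estimates$converged, , drop = FALSE]
  sig <- est$p_value < alpha
  neg <- sum(sig & est$log_hr < 0)
  pos <- sum(sig & est$log_hr > 0)
  c(n_neg_sig = neg,
    n_nonsig = nrow(est) - neg - pos,
    n_pos_sig = pos)
}

#' Detect the Janus pattern
#'
#' The Janus pattern is the most alarming form of vibration: within one set
#' of analyses of the same association, some estimates are significantly
#' harmful (HR > 1) and others significantly protective (HR < 1).
#'
#' @inheritParams classify_significance
#' @return `TRUE` iff at least one significant estimate exists on each side
#'   of HR = 1.
#' @export
detect_janus <- function(estimates, alpha = 0.05) {
  counts <- classify_significance(estimates, alpha)
  counts[["n_neg_sig"]] >= 1 && counts[["n_pos_sig"]] >= 1
}

#' Summarize a vibration run
#'
#' Computes the vibration summary over the converged estimates of a run:
#' relative hazard ratio, relative P-value, significance classification and
#' the Janus flag. Non-converged fits are excluded from all statistics; their
#' count is reported as `n_failed`.
#'
#' @param result A `voe_result` (or a bare estimates data.frame).
#' @param alpha Significance level.
#' @param pct_lo,pct_hi Percentile levels for RHR and RP.
#' @return A `voe_summary` list with fields `rhr`, `rp`, `janus`,
#'   `n_neg_sig`, `n_nonsig`, `n_pos_sig`, `n_failed`, `alpha`, `pct_lo`,
#'   `pct_hi`.
#' @export
summarize_vibration <- function(result, alpha = 0.05,
                                pct_lo = 1, pct_hi = 99) {
  estimates <- if (inherits(result, "voe_result")) result$estimates else result
  conv <- estimates[estimates$converged, , drop = FALSE]
  if (nrow(conv) < 2) {
    stop("need at least two converged estimates to summarize", call. = FALSE)
  }
  counts <- classify_significance(estimates, alpha)
  structure(
    list(rhr = relative_hazard_ratio(conv$hr, pct_lo, pct_hi),
         rp = relative_p(conv$p_value, pct_lo, pct_hi),
         janus = detect_janus(estimates, alpha),
         n_neg_sig = unname(counts["n_neg_sig"]),
         n_nonsig = unname(counts["n_nonsig"]),
         n_pos_sig = unname(counts["n_pos_sig"]),
         n_failed = sum(!estimates$converged),
         alpha = alpha, pct_lo = pct_lo, pct_hi = pct_hi),
    class = "voe_summary"
  )
}

#' @export
print.voe_summary <- function(x, ...) {
  cat("<voe_summary>\n")
  cat(sprintf("  RHR %.4f  RP %.4f  Janus %s\n", x$rhr, x$rp, x$janus))
  cat(sprintf("  significance at alpha = %g: %d neg / %d nonsig / %d pos (%d failed)\n",
              x$alpha, x$n_neg_sig, x$n_nonsig, x$n_pos_sig, x$n_failed))
  invisible(x)
}

#' @export
summary.voe_result <- function(object, ...) summarize_vibration(object, ...)
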