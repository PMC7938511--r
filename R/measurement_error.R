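#' Uniform ranges for measurement-error parameters
#'
#' In measurement vibration each iteration draws one set of error parameters
#' from uniform distributions: a correlation `rho` between true and observed
#' values (continuous and ordinal variables) and a sensitivity/specificity
#' pair (binary variables). The defaults are representative ranges for
#' self-reported and examination-based epidemiological variables:
#' correlation 0.73-0.9, sensitivity 0.56-0.85, specificity 0.73-0.98.
#'
#' @param rho Length-2 numeric, bounds for the true-observed correlation.
#' @param sensitivity Length-2 numeric, bounds for P(observed = 1 | true = 1).
#' @param specificity Length-2 numeric, bounds for P(observed = 0 | true = 0).
#' @return An `me_ranges` object.
#' @export
me_ranges <- function(rho = c(0.73, 0.9),
                      sensitivity = c(0.56, 0.85),
                      specificity = c(0.73, 0.98)) {
  check_range <- function(x, nm) {
    if (length(x) != 2 || !is.numeric(x) || anyNA(x)) {
      stop(nm, " must be a numeric vector of two bounds", call. = FALSE)
    }
    if (x[1] > x[2]) stop(nm, ": lower bound exceeds upper", call. = FALSE)
    if (x[1] <= 0 || x[2] > 1) {
      stop(nm, " bounds must lie in (0, 1]", call. = FALSE)
    }
    as.numeric(x)
  }
  structure(
    list(rho = check_range(rho, "rho"),
         sensitivity = check_range(sensitivity, "sensitivity"),
         specificity = check_range(specificity, "specificity")),
    class = "me_ranges"
  )
}

#' Measurement-error variance for a target correlation
#'
#' Under the classical additive error model `Z = X + U` with `U` independent
#' of `X`, requiring correlation `rho` between `X` and `Z` fixes the error
#' variance at
#' \deqn{Var(U) = Var(X)/\rho^2 - Var(X).}
#'
#' @param var_x Variance of the true variable (> 0).
#' @param rho Target correlation in (0, 1].
#' @return The required error variance (>= 0, and 0 when `rho = 1`).
#' @export
variance_of_error <- function(var_x, rho) {
  if (!is.numeric(var_x) || var_x <= 0) {
    stop("var_x must be a positive number", call. = FALSE)
  }
  if (!is.numeric(rho) || rho <= 0 || rho > 1) {
    stop("rho must lie in (0, 1]", call. = FALSE)
  }
  var_x / rho^2 - var_x
}

#' Add classical additive measurement error to a continuous variable
#'
#' Treats the recorded values as the true exposure `X` and returns
#' `Z = X + U` with `U ~ N(0, Var(U))`, where `Var(U)` is chosen via
#' [variance_of_error()] from the sample variance of `x` so that the
#' correlation between `X` and `Z` equals `rho` in expectation. Uses the
#' current R random stream.
#'
#' @param x Numeric vector with positive sample variance.
#' @param rho Target correlation in (0, 1]; `rho = 1` returns `x` unchanged.
#' @return The error-prone version of `x`.
#' @export
add_classical_error <- function(x, rho) {
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) {
    stop("x has zero sample variance; cannot add classical error",
         call. = FALSE)
  }
  if (!is.numeric(rho) || rho <= 0 || rho > 1) {
    stop("rho must lie in (0, 1]", call. = FALSE)
  }
  if (rho == 1) return(x)
  x + stats::rnorm(length(x), mean = 0, sd = sqrt(variance_of_error(v, rho)))
}

#' Misclassify a binary variable given sensitivity and specificity
#'
#' Each true 1 is observed as 1 with probability `sensitivity`; each true 0
#' is observed as 1 with probability `1 - specificity`. Rows are perturbed
#' independently using the current R random stream.
#'
#' @param x Vector with values in \{0, 1\}.
#' @param sensitivity P(observed = 1 | true = 1), in (0, 1].
#' @param specificity P(observed = 0 | true = 0), in (0, 1].
#' @return The misclassified version of `x`.
#' @export
misclassify_binary <- function(x, sensitivity, specificity) {
  if (!all(x %in% c(0, 1))) {
    stop("x must be binary with values in {0, 1}", call. = FALSE)
  }
  for (p in c(sensitivity = sensitivity, specificity = specificity)) {
    if (!is.numeric(p) || p <= 0 || p > 1) {
      stop("sensitivity and specificity must lie in (0, 1]", call. = FALSE)
    }
  }
  if (sensitivity == 1 && specificity == 1) return(x)
  z <- x
  ones <- x == 1
  z[ones] <- stats::rbinom(sum(ones), 1, sensitivity)
  z[!ones] <- stats::rbinom(sum(!ones), 1, 1 - specificity)
  z
}

#' Perturb an ordinal variable through a latent-normal error model
#'
#' Mirrors the classical additive scheme on a latent scale. Thresholds
#' `tau_1 < ... < tau_{L-1}` are set from the empirical cumulative level
#' frequencies via the standard-normal quantile function. For each row a
#' latent value is drawn from the standard normal truncated to its observed
#' level's interval, normal noise with variance `1/rho^2 - 1` is added, and
#' the noisy latent value - rescaled back to unit variance, which leaves the
#' latent correlation at `rho` and keeps the level marginals stable - is
#' re-discretized with the same thresholds. With `rho = 1` the input is
#' returned unchanged.
#'
#' @param x Integer scores `1..L` with `L >= 3`; every level must be observed.
#' @param rho Target latent correlation in (0, 1].
#' @param n_levels Number of levels `L`; defaults to `max(x)`.
#' @return The perturbed ordinal scores.
#' @export
perturb_ordinal <- function(x, rho, n_levels = max(x)) {
  if (!is.numeric(rho) || rho <= 0 || rho > 1) {
    stop("rho must lie in (0, 1]", call. = FALSE)
  }
  L <- as.integer(n_levels)
  if (L < 3) {
    stop("ordinal perturbation needs >= 3 levels; use misclassify_binary ",
         "for binary variables", call. = FALSE)
  }
  if (!all(x %in% seq_len(L))) {
    stop("x must contain integer scores in 1..", L, call. = FALSE)
  }
  freq <- tabulate(x, nbins = L)
  if (any(freq == 0)) {
    stop("every ordinal level must be observed at least once", call. = FALSE)
  }
  if (rho == 1) return(x)

  cum <- c(0, cumsum(freq) / length(x))      # cumulative probs, 0..1
  # latent draw: inverse-CDF sampling of the standard normal truncated to
  # the level's probability slice, then additive noise, then re-discretize
  p_lo <- cum[x]
  p_hi <- cum[x + 1L]
  u <- stats::runif(length(x))
  latent <- stats::qnorm(p_lo + u * (p_hi - p_lo))
  noisy <- latent + stats::rnorm(length(x), 0,
                                 sqrt(variance_of_error(1, rho)))
  # Var(noisy) = 1/rho^2; rescaling by rho restores unit variance without
  # changing cor(latent, noisy) = rho, so the same thresholds apply
  noisy <- noisy * rho
  tau <- stats::qnorm(cum[2:L])              # interior thresholds
  findInterval(noisy, tau) + 1L
}

#' Draw one set of measurement-error parameters
#'
#' Draws the per-iteration correlation, sensitivity and specificity
#' independently and uniformly from their ranges.
#'
#' @param ranges An [me_ranges()] object.
#' @return An `me_draw` with fields `rho`, `sensitivity`, `specificity`.
#' @export
draw_me_params <- function(ranges) {
  stopifnot(inherits(ranges, "me_ranges"))
  structure(
    list(rho = stats::runif(1, ranges$rho[1], ranges$rho[2]),
         sensitivity = stats::runif(1, ranges$sensitivity[1],
                                    ranges$sensitivity[2]),
         specificity = stats::runif(1, ranges$specificity[1],
                                    ranges$specificity[2])),
    class = "me_draw"
  )
}

#' Inject measurement error into a cohort
#'
#' Replaces the targeted error-prone variables by error-contaminated versions
#' using the kind-appropriate generator with one shared parameter draw:
#' continuous variables receive classical additive error at the draw's
#' correlation, binary variables are misclassified at the draw's sensitivity
#' and specificity, and ordinal variables go through the latent-normal
#' scheme at the draw's correlation. Variables flagged `error_free` in the
#' schema, the time/event columns and any design columns are returned
#' unchanged, and the error processes of different variables are independent.
#'
#' @param cohort A `voe_cohort`.
#' @param draw An `me_draw` from [draw_me_params()].
#' @param scenario One of `"exposure_only"` (error only in the exposure),
#'   `"adjustment_only"` (error only in the adjustment variables) or
#'   `"both"`.
#' @return The corrupted cohort.
#' @export
corrupt_cohort <- function(cohort, draw,
                           scenario = c("both", "exposure_only",
                                        "adjustment_only")) {
  stopifnot(inherits(cohort, "voe_cohort"), inherits(draw, "me_draw"))
  scenario <- match.arg(scenario)

  exp_var <- schema_names_by_role(cohort$schema, "exposure")
  adj_vars <- schema_names_by_role(
    cohort$schema, c("adjustment", "baseline_adjustment"))
  targets <- switch(scenario,
    exposure_only = exp_var,
    adjustment_only = adj_vars,
    both = c(exp_var, adj_vars))

  for (nm in targets) {
    v <- cohort$schema[[nm]]
    if (v$error_free) next
    x <- cohort$data[[nm]]
    cohort$data[[nm]] <- switch(v$kind,
      continuous = add_classical_error(x, draw$rho),
      binary = misclassify_binary(x, draw$sensitivity, draw$specificity),
      ordinal = perturb_ordinal(x, draw$rho, n_levels = length(v$levels)))
  }
  cohort
}
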