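#' Specification for the synthetic survival-cohort generator
#'
#' Describes a cohort with `p` covariates drawn from a Gaussian copula:
#' latent multivariate-normal rows with the given correlation matrix, kept
#' as-is for continuous covariates and discretized at fixed thresholds for
#' binary and ordinal covariates. Event times follow a Cox model with an
#' exponential baseline hazard, `T ~ Exp(rate = baseline_rate *
#' exp(sum(beta_j x_j)))`, with independent exponential censoring.
#'
#' @param n Cohort size.
#' @param corr `p x p` latent correlation matrix (unit diagonal, positive
#'   definite).
#' @param var_defs List of `p` covariate definitions; each is a list with
#'   `name`, `kind` (`continuous`/`binary`/`ordinal`), optional `role`
#'   (`exposure`, `adjustment` or `baseline_adjustment`; the first covariate
#'   defaults to `exposure`), optional `error_free` flag and, for binary and
#'   ordinal kinds, strictly increasing latent `thresholds` (1 for binary,
#'   `L - 1` for ordinal).
#' @param log_hazards Numeric vector of `p` true log hazard ratios.
#' @param baseline_rate Exponential baseline hazard rate (> 0).
#' @param censor_rate Exponential censoring rate (>= 0; 0 disables
#'   censoring).
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(n, corr, var_defs, log_hazards,
                           baseline_rate = 0.1, censor_rate = 0) {
  corr <- as.matrix(corr)
  p <- nrow(corr)
  if (ncol(corr) != p || any(abs(diag(corr) - 1) > 1e-8) ||
      any(abs(corr - t(corr)) > 1e-8)) {
    stop("corr must be a symmetric correlation matrix with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("corr is not positive definite", call. = FALSE)
  }
  if (length(var_defs) != p || length(log_hazards) != p) {
    stop("var_defs and log_hazards must match the dimension of corr",
         call. = FALSE)
  }
  if (baseline_rate <= 0) stop("baseline_rate must be > 0", call. = FALSE)
  if (censor_rate < 0) stop("censor_rate must be >= 0", call. = FALSE)

  var_defs <- lapply(seq_along(var_defs), function(i) {
    v <- var_defs[[i]]
    v$name <- v$name %||% paste0("x", i)
    v$kind <- v$kind %||% "continuous"
    v$role <- v$role %||% if (i == 1) "exposure" else "adjustment"
    v$error_free <- isTRUE(v$error_free)
    if (v$kind %in% c("binary", "ordinal")) {
      thr <- as.numeric(v$thresholds)
      need <- if (v$kind == "binary") 1L else NA
      if (length(thr) == 0 || is.unsorted(thr, strictly = TRUE)) {
        stop("covariate '", v$name, "' needs strictly increasing thresholds",
             call. = FALSE)
      }
      if (v$kind == "binary" && length(thr) != 1) {
        stop("binary covariate '", v$name, "' needs exactly one threshold",
             call. = FALSE)
      }
      if (v$kind == "ordinal" && length(thr) < 2) {
        stop("ordinal covariate '", v$name, "' needs >= 2 thresholds",
             call. = FALSE)
      }
      v$thresholds <- thr
    }
    v
  })
  if (sum(vapply(var_defs, function(v) v$role == "exposure", TRUE)) != 1) {
    stop("exactly one covariate must have role 'exposure'", call. = FALSE)
  }

  structure(
    list(n = n, corr = corr, var_defs = var_defs,
         log_hazards = as.numeric(log_hazards),
         baseline_rate = baseline_rate, censor_rate = censor_rate),
    class = "generator_spec"
  )
}

#' Generate a synthetic survival cohort
#'
#' Draws `n` rows from the Gaussian copula defined by the generator
#' specification, builds mixed-type covariates by thresholding the latent
#' normals, and simulates event and censoring times from the exponential
#' Cox model. Ordinal covariates are emitted as integer scores `1..L`.
#' Uses the current R random stream; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param gspec A [generator_spec()].
#' @param n Optional override of the cohort size in `gspec`.
#' @param standardize_exposure Standardize a continuous exposure (default
#'   `TRUE`, matching [load_cohort()]).
#' @return A `voe_cohort` whose schema is derived from `var_defs` plus
#'   `time`/`event` columns.
#' @export
generate_cohort <- function(gspec, n = gspec$n, standardize_exposure = TRUE) {
  stopifnot(inherits(gspec, "generator_spec"))
  p <- nrow(gspec$corr)
  latent <- matrix(stats::rnorm(n * p), n, p) %*% chol(gspec$corr)

  x <- matrix(0, n, p)
  for (j in seq_len(p)) {
    v <- gspec$var_defs[[j]]
    x[, j] <- switch(v$kind,
      continuous = latent[, j],
      binary = as.numeric(latent[, j] > v$thresholds),
      ordinal = findInterval(latent[, j], v$thresholds) + 1)
  }
  colnames(x) <- vapply(gspec$var_defs, `[[`, "", "name")

  lp <- drop(x %*% gspec$log_hazards)
  t_event <- stats::rexp(n, rate = gspec$baseline_rate * exp(lp))
  if (gspec$censor_rate > 0) {
    t_cens <- stats::rexp(n, rate = gspec$censor_rate)
  } else {
    t_cens <- rep(Inf, n)
  }

  df <- as.data.frame(x)
  df$time <- pmin(t_event, t_cens)
  df$event <- as.numeric(t_event <= t_cens)

  schema_raw <- lapply(gspec$var_defs, function(v) {
    s <- list(kind = v$kind, role = v$role, error_free = v$error_free)
    if (v$kind == "ordinal") {
      s$levels <- as.character(seq_len(length(v$thresholds) + 1))
    }
    s
  })
  names(schema_raw) <- colnames(x)
  schema_raw$time <- list(kind = "continuous", role = "time",
                          error_free = TRUE)
  schema_raw$event <- list(kind = "binary", role = "event",
                           error_free = TRUE)
  new_cohort(df, as_schema(schema_raw),
             standardize_exposure = standardize_exposure)
}

#' Estimate a generator specification from a cohort
#'
#' Recovers the pieces needed to emulate an observed cohort: the latent
#' correlation matrix (Pearson correlation for continuous-continuous pairs;
#' moment-based polyserial estimates for continuous-discrete pairs and
#' polychoric estimates, solved numerically, for discrete-discrete pairs,
#' with thresholds fixed at the observed category frequencies), the log
#' hazard ratios from the all-adjustments Cox fit, thresholds from the
#' observed category frequencies, and baseline/censoring rates matched by
#' moments from the observed event fraction and follow-up time. If the
#' assembled correlation matrix is not positive definite it is repaired by
#' eigenvalue clipping (and a message is emitted).
#'
#' @param cohort A `voe_cohort`.
#' @param use_design Use survey-design columns in the Cox fit.
#' @return A [generator_spec()] with `n` equal to the cohort size.
#' @export
spec_from_cohort <- function(cohort, use_design = TRUE) {
  stopifnot(inherits(cohort, "voe_cohort"))
  covars <- schema_names_by_role(
    cohort$schema, c("exposure", "baseline_adjustment", "adjustment"))
  p <- length(covars)
  df <- cohort$data
  kinds <- vapply(covars, function(nm) cohort$schema[[nm]]$kind, "")

  for (nm in covars) {
    if (length(unique(df[[nm]])) < 2) {
      stop("covariate '", nm, "' is constant; cannot estimate a generator ",
           "specification", call. = FALSE)
    }
  }

  taus <- lapply(seq_len(p), function(i) {
    if (kinds[i] == "continuous") return(NULL)
    x <- df[[covars[i]]]
    L <- if (kinds[i] == "binary") 2L else
      length(cohort$schema[[covars[i]]]$levels)
    cum <- cumsum(tabulate(x + (kinds[i] == "binary"), nbins = L) /
                    length(x))
    stats::qnorm(pmin(pmax(cum[-L], 1e-12), 1 - 1e-12))
  })
  corr <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r <- latent_cor(df[[covars[i]]], df[[covars[j]]],
                      taus[[i]], taus[[j]])
      corr[i, j] <- corr[j, i] <- max(-0.999, min(0.999, r))
    }
  }
  eg <- eigen(corr, symmetric = TRUE)
  if (min(eg$values) <= 1e-8) {
    message("spec_from_cohort: correlation matrix repaired by eigenvalue clipping")
    vals <- pmax(eg$values, 1e-6)
    corr <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
    d <- sqrt(diag(corr))
    corr <- corr / outer(d, d)
  }
  dimnames(corr) <- list(covars, covars)

  var_defs <- lapply(seq_len(p), function(i) {
    nm <- covars[i]
    v <- list(name = nm, kind = kinds[i],
              role = cohort$schema[[nm]]$role,
              error_free = cohort$schema[[nm]]$error_free)
    if (kinds[i] == "binary") {
      v$thresholds <- stats::qnorm(1 - mean(df[[nm]]))
    } else if (kinds[i] == "ordinal") {
      L <- length(cohort$schema[[nm]]$levels)
      cum <- cumsum(tabulate(df[[nm]], nbins = L) / nrow(df))
      v$thresholds <- stats::qnorm(pmin(pmax(cum[-L], 1e-12), 1 - 1e-12))
    }
    v
  })

  # effect sizes from the favourite (all-adjustments) fit; per-covariate
  # betas from the same model so confounding structure is carried over
  fml <- stats::as.formula(
    paste0("survival::Surv(",
           schema_names_by_role(cohort$schema, "time"), ", ",
           schema_names_by_role(cohort$schema, "event"), ") ~ ",
           paste(covars, collapse = " + ")))
  wts <- if (use_design && !is.null(cohort$design$weight)) {
    df[[cohort$design$weight]]
  }
  fit <- survival::coxph(fml, data = df, weights = wts, ties = "efron")
  beta <- fit$coefficients[covars]
  beta[!is.finite(beta)] <- 0

  # moment-match exponential rates: overall event rate per unit follow-up,
  # split by the observed censoring share
  total_time <- sum(df[[schema_names_by_role(cohort$schema, "time")]])
  n_event <- sum(df[[schema_names_by_role(cohort$schema, "event")]])
  baseline_rate <- max(n_event / total_time, 1e-8)
  censor_rate <- max((nrow(df) - n_event) / total_time, 0)

  generator_spec(n = nrow(df), corr = corr, var_defs = var_defs,
                 log_hazards = unname(beta),
                 baseline_rate = baseline_rate, censor_rate = censor_rate)
}

# latent (Gaussian-copula) correlation estimators used by spec_from_cohort.
# Discretized margins carry their empirical interior thresholds tau;
# continuous margins pass tau = NULL.
latent_cor <- function(x, y, tau_x = NULL, tau_y = NULL) {
  if (is.null(tau_x) && is.null(tau_y)) return(stats::cor(x, y))
  if (is.null(tau_x)) return(polyserial_cor(x, y, tau_y))
  if (is.null(tau_y)) return(polyserial_cor(y, x, tau_x))
  polychoric_cor(x, y, tau_x, tau_y)
}

# x continuous (treated as the latent normal itself), y discretized at tau:
# cov(x_std, y) = rho * sum_k phi(tau_k), since y = const + sum_k 1{L > tau_k}
polyserial_cor <- function(x, y, tau) {
  r <- stats::cov(as.numeric(scale(x)), y) / sum(stats::dnorm(tau))
  max(-0.999, min(0.999, r))
}

# both margins discretized: match the observed covariance of the category
# scores to its bivariate-normal expectation, solving for rho numerically
polychoric_cor <- function(x, y, tau_x, tau_y) {
  cov_obs <- stats::cov(x, y)
  joint_upper <- function(a, b, rho) {
    s <- sqrt(1 - rho^2)
    stats::integrate(function(t) {
      stats::dnorm(t) * stats::pnorm((rho * t - b) / s)
    }, lower = a, upper = Inf, rel.tol = 1e-9)$value
  }
  cov_model <- function(rho) {
    tot <- 0
    for (a in tau_x) {
      for (b in tau_y) {
        tot <- tot + joint_upper(a, b, rho) -
          (1 - stats::pnorm(a)) * (1 - stats::pnorm(b))
      }
    }
    tot
  }
  f <- function(rho) cov_model(rho) - cov_obs
  lo <- -0.998; hi <- 0.998
  if (f(lo) > 0) return(-0.999)
  if (f(hi) < 0) return(0.999)
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Read a generator specification from YAML or JSON
#'
#' The file mirrors [generator_spec()]: keys `n`, `corr` (list of rows),
#' `var_defs`, `log_hazards`, `baseline_rate`, `censor_rate`.
#'
#' @param path File path.
#' @return A `generator_spec`.
#' @export
read_generator_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  corr <- do.call(rbind, lapply(raw$corr, as.numeric))
  generator_spec(n = raw$n, corr = corr, var_defs = raw$var_defs,
                 log_hazards = as.numeric(raw$log_hazards),
                 baseline_rate = raw$baseline_rate %||% 0.1,
                 censor_rate = raw$censor_rate %||% 0)
}
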