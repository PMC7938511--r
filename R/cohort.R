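#' Variable schema for a survival cohort
#'
#' A schema describes every column of a cohort table: its measurement kind
#' (`continuous`, `binary` or `ordinal`), its analytic role (`exposure`,
#' `adjustment`, `baseline_adjustment`, `time`, `event`, `weight`, `stratum`
#' or `cluster`), whether it is assumed free of measurement error, and, for
#' ordinal variables, the ordered level labels.
#'
#' Schemas are stored on disk as a YAML (or JSON) mapping from column name to
#' a list with entries `kind`, `role`, `error_free` and optionally `levels`.
#' Exactly one variable must carry each of the roles `exposure`, `time` and
#' `event`; the roles `weight`, `stratum` and `cluster` may appear at most
#' once.
#'
#' @param path Path to a YAML or JSON schema file.
#' @return A `voe_schema` object: a list of per-variable specifications, each
#'   with fields `name`, `kind`, `role`, `error_free` and `levels`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) {
    stop("schema file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_schema(raw)
}

#' Build a schema from a named list
#'
#' @param x Named list mapping column names to lists with `kind`, `role`,
#'   `error_free` and (ordinal only) `levels`.
#' @return A validated `voe_schema` object.
#' @export
as_schema <- function(x) {
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("schema must be a named mapping of column specifications", call. = FALSE)
  }
  kinds <- c("continuous", "binary", "ordinal")
  roles <- c("exposure", "adjustment", "baseline_adjustment", "time", "event",
             "weight", "stratum", "cluster")
  schema <- lapply(names(x), function(nm) {
    v <- x[[nm]]
    kind <- v$kind %||% "continuous"
    role <- v$role %||% "adjustment"
    if (!kind %in% kinds) {
      stop("unknown kind '", kind, "' for variable '", nm, "'", call. = FALSE)
    }
    if (!role %in% roles) {
      stop("unknown role '", role, "' for variable '", nm, "'", call. = FALSE)
    }
    levels <- v$levels
    if (kind == "ordinal") {
      if (is.null(levels) || length(levels) < 3) {
        stop("ordinal variable '", nm, "' needs >= 3 ordered levels",
             call. = FALSE)
      }
    } else if (!is.null(levels)) {
      stop("levels are only meaningful for ordinal variables ('", nm, "')",
           call. = FALSE)
    }
    list(name = nm, kind = kind, role = role,
         error_free = isTRUE(v$error_free), levels = levels)
  })
  names(schema) <- names(x)
  class(schema) <- "voe_schema"
  validate_schema(schema)
  schema
}

validate_schema <- function(schema) {
  roles <- vapply(schema, `[[`, "", "role")
  for (r in c("exposure", "time", "event")) {
    if (sum(roles == r) != 1L) {
      stop("schema must contain exactly one variable with role '", r,
           "' (found ", sum(roles == r), ")", call. = FALSE)
    }
  }
  for (r in c("weight", "stratum", "cluster")) {
    if (sum(roles == r) > 1L) {
      stop("schema role '", r, "' may appear at most once", call. = FALSE)
    }
  }
  invisible(schema)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

schema_names_by_role <- function(schema, role) {
  nms <- vapply(schema, `[[`, "", "name")
  nms[vapply(schema, `[[`, "", "role") %in% role]
}

#' @export
print.voe_schema <- function(x, ...) {
  cat("<voe_schema> ", length(x), " variables\n", sep = "")
  for (v in x) {
    cat(sprintf("  %-20s %-10s %-20s%s\n", v$name, v$kind, v$role,
                if (v$error_free) " [error-free]" else ""))
  }
  invisible(x)
}

#' Load a cohort table with its schema
#'
#' Reads a rectangular CSV of survival data, validates it against the schema,
#' drops incomplete rows (complete-case over all schema columns, with the
#' number of dropped rows reported via a message), recodes ordinal labels to
#' integer scores `1..L`, and optionally standardizes a continuous exposure
#' to mean 0 and unit standard deviation so that hazard ratios are per
#' standard deviation of the exposure.
#'
#' @param table_path Path to a CSV file with a header row covering all schema
#'   names.
#' @param schema Path to a schema file, or a `voe_schema` object.
#' @param standardize_exposure If `TRUE` (default) and the exposure is
#'   continuous, it is standardized at load time.
#' @return A `voe_cohort`: a list with elements `data` (data.frame), `schema`,
#'   `n`, `n_dropped` and `design` (names of weight/stratum/cluster columns,
#'   when present).
#' @export
load_cohort <- function(table_path, schema, standardize_exposure = TRUE) {
  if (!inherits(schema, "voe_schema")) schema <- read_schema(schema)
  df <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing schema columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, names(schema), drop = FALSE]
  new_cohort(df, schema, standardize_exposure = standardize_exposure)
}

#' Assemble a cohort from an in-memory data frame
#'
#' @param data Data frame whose columns cover the schema.
#' @param schema A `voe_schema`.
#' @param standardize_exposure Standardize a continuous exposure at load.
#' @return A `voe_cohort`.
#' @export
new_cohort <- function(data, schema, standardize_exposure = TRUE) {
  stopifnot(inherits(schema, "voe_schema"))
  df <- as.data.frame(data)[, names(schema), drop = FALSE]

  # ordinal labels -> integer scores 1..L before completeness check
  for (v in schema) {
    if (v$kind == "ordinal" && !is.numeric(df[[v$name]])) {
      idx <- match(as.character(df[[v$name]]), as.character(v$levels))
      if (anyNA(idx) && !anyNA(df[[v$name]])) {
        stop("ordinal variable '", v$name,
             "' has values outside its declared levels", call. = FALSE)
      }
      df[[v$name]] <- idx
    }
  }

  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message("load_cohort: dropped ", n_dropped, " incomplete row(s)")
  }
  df <- df[complete, , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0L) stop("cohort has no complete rows", call. = FALSE)

  time_var <- schema_names_by_role(schema, "time")
  event_var <- schema_names_by_role(schema, "event")
  if (any(df[[time_var]] < 0)) {
    stop("time variable '", time_var, "' has negative values", call. = FALSE)
  }
  if (!all(df[[event_var]] %in% c(0, 1))) {
    stop("event variable '", event_var, "' must take values in {0, 1}",
         call. = FALSE)
  }
  for (v in schema) {
    if (v$kind == "binary" && !all(df[[v$name]] %in% c(0, 1))) {
      stop("binary variable '", v$name, "' must take values in {0, 1}",
           call. = FALSE)
    }
    if (v$kind == "ordinal") {
      L <- length(v$levels)
      if (!all(df[[v$name]] %in% seq_len(L))) {
        stop("ordinal variable '", v$name, "' has scores outside 1..", L,
             call. = FALSE)
      }
    }
  }
  w <- schema_names_by_role(schema, "weight")
  if (length(w) && any(df[[w]] <= 0)) {
    stop("weights must be strictly positive", call. = FALSE)
  }

  cohort <- structure(
    list(
      data = df,
      schema = schema,
      n = nrow(df),
      n_dropped = n_dropped,
      design = list(
        weight = if (length(w)) w else NULL,
        stratum = {
          s <- schema_names_by_role(schema, "stratum")
          if (length(s)) s else NULL
        },
        cluster = {
          cl <- schema_names_by_role(schema, "cluster")
          if (length(cl)) cl else NULL
        }
      )
    ),
    class = "voe_cohort"
  )

  exp_var <- schema_names_by_role(schema, "exposure")
  if (standardize_exposure && schema[[exp_var]]$kind == "continuous") {
    cohort <- standardize_continuous(cohort, exp_var)
  }
  cohort
}

#' @export
print.voe_cohort <- function(x, ...) {
  cat("<voe_cohort> n = ", x$n, ", ", length(x$schema), " variables",
      if (x$n_dropped > 0) paste0(" (", x$n_dropped, " rows dropped)"),
      "\n", sep = "")
  invisible(x)
}

#' Standardize continuous cohort variables
#'
#' Centers and scales the named continuous columns to sample mean 0 and
#' sample standard deviation 1, leaving every other column untouched. Applied
#' to the exposure this puts hazard ratios on a per-standard-deviation scale,
#' which keeps them comparable across vibration analyses.
#'
#' @param cohort A `voe_cohort`.
#' @param names Character vector of continuous variable names.
#' @return The cohort with the named columns standardized.
#' @export
standardize_continuous <- function(cohort, names) {
  stopifnot(inherits(cohort, "voe_cohort"))
  for (nm in names) {
    v <- cohort$schema[[nm]]
    if (is.null(v)) stop("unknown variable '", nm, "'", call. = FALSE)
    if (v$kind != "continuous") {
      stop("variable '", nm, "' is not continuous", call. = FALSE)
    }
    x <- cohort$data[[nm]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("variable '", nm, "' has zero variance and cannot be standardized",
           call. = FALSE)
    }
    cohort$data[[nm]] <- (x - mean(x)) / s
  }
  cohort
}

#' Write a vibration result to disk
#'
#' Writes a long-format CSV with one row per fitted effect estimate
#' (provenance, log hazard ratio, hazard ratio, standard error, P-value and
#' convergence flag) plus a JSON file with the summary statistics, the run
#' settings and the seed, so that a run is fully reconstructible.
#'
#' @param result A `voe_result` from one of the vibration engines.
#' @param out_dir Output directory (created if absent).
#' @param alpha,pct_lo,pct_hi Passed to [summarize_vibration()].
#' @return Invisibly, the paths of the written files.
#' @export
write_results <- function(result, out_dir, alpha = 0.05,
                          pct_lo = 1, pct_hi = 99) {
  stopifnot(inherits(result, "voe_result"))
  if (nrow(result$estimates) == 0L) {
    stop("result contains no estimates", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, "estimates.csv")
  json_path <- file.path(out_dir, "summary.json")

  est <- result$estimates
  est$provenance_type <- result$vibration_type
  cols <- c("provenance_type", "provenance_id", "log_hr", "hr", "se",
            "p_value", "converged")
  utils::write.csv(est[, cols], csv_path, row.names = FALSE)

  smry <- summarize_vibration(result, alpha = alpha,
                              pct_lo = pct_lo, pct_hi = pct_hi)
  payload <- c(unclass(smry),
               list(vibration_type = result$vibration_type,
                    scenario = result$scenario,
                    seed = result$seed,
                    settings = result$settings))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(estimates = csv_path, summary = json_path))
}

#' Read back a written vibration result
#'
#' @param out_dir Directory previously written by [write_results()].
#' @return A list with `estimates` (data.frame) and `summary` (list).
#' @export
read_results <- function(out_dir) {
  list(
    estimates = utils::read.csv(file.path(out_dir, "estimates.csv"),
                                stringsAsFactors = FALSE),
    summary = jsonlite::read_json(file.path(out_dir, "summary.json"),
                                  simplifyVector = TRUE)
  )
}
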