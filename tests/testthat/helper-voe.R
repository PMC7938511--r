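# fixtures are built in code: a tiny cohort CSV + schema on disk, and small
# generator specs for the engines

toy_schema_list <- function() {
  list(
    time = list(kind = "continuous", role = "time", error_free = TRUE),
    event = list(kind = "binary", role = "event", error_free = TRUE),
    exposure = list(kind = "continuous", role = "exposure"),
    age = list(kind = "continuous", role = "baseline_adjustment",
               error_free = TRUE),
    smoker = list(kind = "binary", role = "adjustment"),
    education = list(kind = "ordinal", role = "adjustment",
                     levels = c("low", "mid", "high"))
  )
}

write_toy_cohort <- function(dir = NULL, na_in_row = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("toycohort")
    dir.create(dir)
  }
  df <- data.frame(
    time = c(1.2, 3.4, 0.5, 2.2, 4.1, 1.7),
    event = c(1, 0, 1, 1, 0, 1),
    exposure = c(0.3, -1.2, 0.8, 1.5, -0.4, 0.1),
    age = c(45, 60, 52, 70, 38, 55),
    smoker = c(1, 0, 0, 1, 0, 1),
    education = c("low", "mid", "high", "mid", "low", "high")
  )
  if (!is.null(na_in_row)) df$age[na_in_row] <- NA
  csv <- file.path(dir, "cohort.csv")
  sch <- file.path(dir, "schema.yaml")
  utils::write.csv(df, csv, row.names = FALSE)
  yaml::write_yaml(toy_schema_list(), sch)
  list(csv = csv, schema = sch, df = df)
}

# small all-purpose generator spec: exposure + a few adjustments,
# exchangeable-ish latent correlation, exponential times
quick_gspec <- function(n = 1000,
                        betas = c(0.3, 0.4, -0.2, 0.2),
                        kinds = NULL,
                        rho = 0.3,
                        baseline_rate = 0.1,
                        censor_rate = 0.1) {
  p <- length(betas)
  if (is.null(kinds)) kinds <- rep("continuous", p)
  corr <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  var_defs <- lapply(seq_len(p), function(i) {
    v <- list(name = if (i == 1) "exposure" else paste0("adj", i - 1),
              kind = kinds[i],
              role = if (i == 1) "exposure" else "adjustment")
    if (kinds[i] == "binary") v$thresholds <- 0
    if (kinds[i] == "ordinal") v$thresholds <- c(-0.7, 0.7)
    v
  })
  generator_spec(n = n, corr = corr, var_defs = var_defs,
                 log_hazards = betas, baseline_rate = baseline_rate,
                 censor_rate = censor_rate)
}

fixture_gspec <- function() {
  read_generator_spec(system.file("extdata", "synthetic_nhanes_like.yaml",
                                  package = "voe"))
}

fake_estimates <- function(log_hr, p_value, converged = TRUE) {
  data.frame(provenance_id = seq_along(log_hr), log_hr = log_hr,
             hr = exp(log_hr), se = 0.1, p_value = p_value,
             converged = converged)
}
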