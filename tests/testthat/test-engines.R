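test_that("model vibration fits every adjustment set deterministically", {
  set.seed(31)
  gs <- quick_gspec(n = 600, betas = c(0.3, 0.2, -0.2, 0.1))
  co <- generate_cohort(gs)
  r1 <- model_vibration(co)
  expect_s3_class(r1, "voe_result")
  expect_equal(nrow(r1$estimates), 8)
  expect_equal(r1$settings$k, 3)
  # no randomness involved: re-running is bit-identical
  r2 <- model_vibration(co)
  expect_identical(r1$estimates, r2$estimates)
})

test_that("an empty optional set reduces to the baseline-only fit", {
  set.seed(32)
  gs <- quick_gspec(n = 600, betas = c(0.3, 0.2, -0.2, 0.1))
  co <- generate_cohort(gs)
  r <- model_vibration(co, optional_vars = character(),
                       baseline_vars = c("adj1", "adj2", "adj3"))
  expect_equal(nrow(r$estimates), 1)
  ref <- fit_cox_effect(co, favourite_model(co))
  expect_equal(r$estimates$log_hr, ref$log_hr)
})

test_that("sampling vibration draws subsets of size floor(fraction * n)", {
  set.seed(33)
  gs <- quick_gspec(n = 2000, betas = c(0.3, 0.2, -0.2, 0.1))
  co <- generate_cohort(gs)
  expect_equal(voe:::subset_cohort(co, 1:123)$n, 123)

  r <- sampling_vibration(co, B = 50, seed = 9)
  expect_equal(nrow(r$estimates), 50)
  expect_equal(r$settings$subset_size, 1000)   # floor(0.5 * 2000)
  expect_equal(sort(r$estimates$provenance_id), 1:50)
  expect_equal(anyDuplicated(r$estimates$provenance_id), 0L)
  expect_true(r$reference$converged)

  # reproducible under the same master seed
  r2 <- sampling_vibration(co, B = 50, seed = 9)
  expect_identical(r$estimates, r2$estimates)
})

test_that("near-full subsamples vibrate less than half-samples", {
  set.seed(34)
  gs <- quick_gspec(n = 4000, betas = c(0.3, 0.2, -0.2, 0.1))
  co <- generate_cohort(gs)
  half <- sampling_vibration(co, B = 60, fraction = 0.5, seed = 5)
  full <- sampling_vibration(co, B = 60, fraction = 0.999, seed = 5)
  expect_lt(sd(full$estimates$log_hr), sd(half$estimates$log_hr) / 2)
})

test_that("a no-error draw reproduces the reference fit exactly", {
  set.seed(35)
  gs <- fixture_gspec()
  co <- generate_cohort(gs, n = 800)
  r0 <- me_ranges(rho = c(1, 1), sensitivity = c(1, 1),
                  specificity = c(1, 1))
  r <- measurement_vibration(co, ranges = r0, B = 10, seed = 4)
  expect_equal(nrow(r$estimates), 10)
  expect_true(all(r$estimates$log_hr == r$reference$log_hr))
  expect_true(all(r$estimates$se == r$reference$se))
})

test_that("measurement vibration is reproducible and tags its draws", {
  set.seed(36)
  gs <- quick_gspec(n = 700, betas = c(0.4, 0.2, -0.2, 0.1))
  co <- generate_cohort(gs)
  a <- measurement_vibration(co, B = 5, seed = 11)
  b <- measurement_vibration(co, B = 5, seed = 11)
  expect_identical(a$estimates, b$estimates)
  expect_true(all(a$estimates$rho >= 0.73 & a$estimates$rho <= 0.9))
  expect_equal(a$scenario, "both")
  expect_equal(anyDuplicated(a$estimates$provenance_id), 0L)
})

test_that("exposure-only error attenuates a true positive effect on average", {
  set.seed(37)
  gs <- quick_gspec(n = 4000, betas = c(0.5, 0.3, -0.2, 0.2),
                    censor_rate = 0)
  co <- generate_cohort(gs)
  r <- measurement_vibration(co, scenario = "exposure_only", B = 40,
                             seed = 13)
  ref_hr <- r$reference$hr
  med_hr <- median(r$estimates$hr[r$estimates$converged])
  expect_gt(ref_hr, 1)
  expect_lt(abs(log(med_hr)), abs(log(ref_hr)))  # closer to the null
})

test_that("wider misclassification ranges widen the estimate spread", {
  set.seed(38)
  gs <- quick_gspec(n = 3000, betas = c(0.5, 0.3, -0.2),
                    kinds = c("binary", "continuous", "continuous"),
                    censor_rate = 0)
  co <- generate_cohort(gs)
  narrow <- me_ranges(rho = c(0.95, 0.99), sensitivity = c(0.97, 0.99),
                      specificity = c(0.97, 0.99))
  wide <- me_ranges()
  rn <- measurement_vibration(co, scenario = "exposure_only",
                              ranges = narrow, B = 40, seed = 21)
  rw <- measurement_vibration(co, scenario = "exposure_only",
                              ranges = wide, B = 40, seed = 21)
  expect_lt(IQR(rn$estimates$log_hr), IQR(rw$estimates$log_hr))
  # near-perfect measurement stays tight around the reference
  expect_lt(max(abs(rn$estimates$log_hr - rn$reference$log_hr)),
            0.25 * abs(rn$reference$log_hr))
})

test_that("the sample-size sweep summarizes per size and engine", {
  set.seed(39)
  gs <- quick_gspec(n = 500, betas = c(0.4, 0.25, -0.2))
  one <- vibration_over_sample_sizes(gs, sizes = 600, engines = "model",
                                     B = 10, seed = 2)
  expect_equal(nrow(one), 1)
  expect_equal(one$vibration_type, "model")
  expect_equal(one$n, 600)

  tab <- vibration_over_sample_sizes(gs, sizes = c(500, 5000),
                                     engines = "sampling", B = 200,
                                     seed = 2)
  expect_equal(nrow(tab), 2)
  expect_lt(tab$rhr[tab$n == 5000], tab$rhr[tab$n == 500])

  tab2 <- vibration_over_sample_sizes(gs, sizes = c(500, 5000),
                                      engines = "sampling", B = 200,
                                      seed = 2)
  expect_identical(tab, tab2)

  expect_error(vibration_over_sample_sizes(gs, sizes = c(5000, 500)),
               "increasing")
})
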