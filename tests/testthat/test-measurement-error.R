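test_that("error variance follows the closed form Var(X)/rho^2 - Var(X)", {
  expect_equal(variance_of_error(1.0, 0.8), 0.5625)
  expect_equal(variance_of_error(4.0, 0.5), 12.0)
  expect_equal(variance_of_error(3.7, 1.0), 0.0)
  expect_error(variance_of_error(1, 0), "rho")
  expect_error(variance_of_error(1, 1.2), "rho")
  expect_error(variance_of_error(-1, 0.5), "var_x")

  # strictly decreasing in rho, linear in var_x
  rhos <- seq(0.1, 1, by = 0.1)
  v <- vapply(rhos, function(r) variance_of_error(2, r), 0)
  expect_true(all(diff(v) < 0))
  expect_equal(variance_of_error(6, 0.8), 3 * variance_of_error(2, 0.8))
})

test_that("classical error hits the target correlation and variance", {
  set.seed(101)
  x <- rnorm(200000)
  expect_identical(add_classical_error(x, 1), x)

  z <- add_classical_error(x, 0.9)
  expect_equal(cor(x, z), 0.9, tolerance = 0.005)
  expect_equal(var(z), var(x) / 0.81, tolerance = 0.02 * var(x) / 0.81)

  expect_error(add_classical_error(rep(2, 10), 0.9), "zero sample variance")
})

test_that("mean empirical correlation is unbiased across replicates", {
  set.seed(202)
  for (rho in c(0.73, 0.8, 0.9)) {
    cors <- replicate(100, {
      x <- rnorm(10000)
      cor(x, add_classical_error(x, rho))
    })
    se <- sd(cors) / sqrt(length(cors))
    expect_lt(abs(mean(cors) - rho), 2 * se + 1e-4)
  }
})

test_that("classical error attenuates a regression slope by rho^2", {
  set.seed(303)
  n <- 200000
  x <- rnorm(n)
  y <- 1.0 * x + rnorm(n)
  z <- add_classical_error(x, 0.8)
  slope <- unname(coef(lm(y ~ z))[2])
  expect_equal(slope, 0.64, tolerance = 0.05 * 0.64)
})

test_that("binary misclassification matches sensitivity and specificity", {
  x <- rbinom(1000, 1, 0.4)
  expect_identical(misclassify_binary(x, 1, 1), x)
  expect_error(misclassify_binary(c(0, 1, 2), 0.9, 0.9), "binary")
  expect_error(misclassify_binary(x, 0, 0.9), "sensitivity and specificity")

  set.seed(404)
  ones <- rep(1, 100000)
  expect_equal(mean(misclassify_binary(ones, 0.85, 1)), 0.85,
               tolerance = 0.01)
  zeros <- rep(0, 100000)
  expect_equal(mean(misclassify_binary(zeros, 1, 0.73)), 0.27,
               tolerance = 0.01)
})

test_that("1 -> 1 transitions behave as a binomial count", {
  set.seed(505)
  x <- rep(c(1, 0), c(5000, 5000))
  z <- misclassify_binary(x, 0.7, 0.9)
  kept <- sum(z[x == 1])
  # 4 sd band around Binomial(5000, 0.7)
  expect_lt(abs(kept - 5000 * 0.7), 4 * sqrt(5000 * 0.7 * 0.3))
  # zeros flip at rate 1 - specificity, independent of sensitivity
  expect_lt(abs(mean(z[x == 0]) - 0.1), 4 * sqrt(0.1 * 0.9 / 5000))
})

test_that("ordinal perturbation preserves marginals and degrades rank order", {
  set.seed(606)
  x <- sample(1:4, 200000, replace = TRUE)
  expect_identical(perturb_ordinal(x, 1), x)

  z <- perturb_ordinal(x, 0.8)
  f_in <- tabulate(x, 4) / length(x)
  f_out <- tabulate(z, 4) / length(z)
  expect_true(all(abs(f_in - f_out) < 0.02))

  sp <- vapply(c(1, 0.8, 0.6), function(r) {
    cor(x, perturb_ordinal(x, r), method = "spearman")
  }, 0)
  expect_true(all(diff(sp) < 0))

  expect_error(perturb_ordinal(c(1, 2, 1, 2), 0.8, n_levels = 2),
               ">= 3 levels")
  expect_error(perturb_ordinal(c(1, 1, 3, 3), 0.8, n_levels = 3),
               "observed at least once")
})

test_that("parameter draws are uniform on their ranges", {
  r_deg <- me_ranges(rho = c(0.8, 0.8), sensitivity = c(0.7, 0.7),
                     specificity = c(0.9, 0.9))
  d <- draw_me_params(r_deg)
  expect_equal(d$rho, 0.8)
  expect_equal(d$sensitivity, 0.7)
  expect_equal(d$specificity, 0.9)

  set.seed(707)
  r <- me_ranges()
  draws <- replicate(10000, draw_me_params(r), simplify = FALSE)
  rhos <- vapply(draws, `[[`, 0, "rho")
  sens <- vapply(draws, `[[`, 0, "sensitivity")
  spec <- vapply(draws, `[[`, 0, "specificity")
  expect_true(all(rhos >= 0.73 & rhos <= 0.9))
  expect_true(all(sens >= 0.56 & sens <= 0.85))
  expect_true(all(spec >= 0.73 & spec <= 0.98))
  expect_equal(mean(rhos), 0.815, tolerance = 0.005)

  expect_error(me_ranges(rho = c(0.9, 0.8)), "lower bound exceeds upper")
  expect_error(me_ranges(sensitivity = c(0, 0.9)), "\\(0, 1\\]")
})

test_that("cohort corruption touches only the targeted error-prone columns", {
  set.seed(808)
  gs <- quick_gspec(n = 400, betas = c(0.3, 0.2, 0.2, -0.1),
                    kinds = c("continuous", "binary", "ordinal",
                              "continuous"))
  co <- generate_cohort(gs)
  draw <- structure(list(rho = 0.8, sensitivity = 0.7, specificity = 0.9),
                    class = "me_draw")

  only_exp <- corrupt_cohort(co, draw, "exposure_only")
  for (nm in c("adj1", "adj2", "adj3", "time", "event")) {
    expect_identical(only_exp$data[[nm]], co$data[[nm]])
  }
  expect_false(identical(only_exp$data$exposure, co$data$exposure))

  only_adj <- corrupt_cohort(co, draw, "adjustment_only")
  expect_identical(only_adj$data$exposure, co$data$exposure)
  expect_false(identical(only_adj$data$adj1, co$data$adj1))

  no_err <- structure(list(rho = 1, sensitivity = 1, specificity = 1),
                      class = "me_draw")
  expect_identical(corrupt_cohort(co, no_err, "both")$data, co$data)

  expect_error(corrupt_cohort(co, draw, "everything"), "arg")
})

test_that("error-free variables are never corrupted", {
  set.seed(909)
  gs <- fixture_gspec()
  co <- generate_cohort(gs, n = 500)
  draw <- structure(list(rho = 0.75, sensitivity = 0.6, specificity = 0.8),
                    class = "me_draw")
  z <- corrupt_cohort(co, draw, "both")
  for (nm in c("age", "sex", "race_ethnicity")) {
    expect_identical(z$data[[nm]], co$data[[nm]])
  }
  expect_false(identical(z$data$bmi, co$data$bmi))
})
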