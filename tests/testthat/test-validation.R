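test_that("leave-one-out matches an exhaustive hand-rolled oracle", {
  d <- data.frame(compound_id = letters[1:5],
                  x1 = c(1, 2, 3, 4, 6),
                  pIC50_obs = c(2.2, 2.8, 4.1, 4.4, 6.5))
  cv <- loo_q2(d, function(dd) fit_mlr(dd, terms = "x1"))

  oracle <- numeric(5)
  for (i in 1:5) {
    beta <- normal_equations(matrix(d$x1[-i]), d$pIC50_obs[-i])
    oracle[i] <- beta[1] + beta[2] * d$x1[i]
  }
  expect_equal(unname(cv$predictions), oracle, tolerance = 1e-10)
  press <- sum((d$pIC50_obs - oracle)^2)
  expect_equal(cv$q2, 1 - press / sum((d$pIC50_obs - mean(d$pIC50_obs))^2))
  expect_equal(cv$mse_cv, press / 5)
  expect_named(cv$predictions, d$compound_id)
})

test_that("an oracle factory returning the truth gives Q2 = 1", {
  d <- generate_dataset(synthetic_config(noise_sd = 0, seed = 5))
  truth <- attr(d, "truth")
  oracle_model <- mlr_model(truth$intercept, truth$coefficients)
  cv <- loo_q2(d, function(dd) oracle_model)
  expect_equal(cv$q2, 1, tolerance = 1e-10)
})

test_that("a factory that ignores held-out-ness reproduces plain R2", {
  d <- generate_dataset(synthetic_config(n_compounds = 12, noise_sd = 0,
                                         seed = 8, test_fraction = 0))
  fit_all <- fit_mlr(d)
  cv <- loo_q2(d, function(dd) fit_all)
  expect_equal(cv$q2, fit_all$stats$r2, tolerance = 1e-10)
})

test_that("LOO input contracts are enforced", {
  expect_error(loo_q2(toy_line(2), fit_mlr), "at least 3")
  collinear <- data.frame(x1 = c(1, 1, 1, 2), x2 = c(2, 2, 2, 4),
                          pIC50_obs = 1:4)
  expect_error(loo_q2(collinear, function(d) fit_mlr(d, terms = c("x1", "x2"))),
               "held-out")
})

test_that("Golbraikh-Tropsha metrics equal their defining sums", {
  set.seed(42)
  y <- rnorm(10, 7, 0.5)
  yh <- y + rnorm(10, 0, 0.3)
  gt <- golbraikh_tropsha(y, yh)

  k <- sum(y * yh) / sum(y^2)
  kp <- sum(y * yh) / sum(yh^2)
  expect_equal(gt$r2, cor(y, yh)^2)
  expect_equal(gt$k, k)
  expect_equal(gt$k_prime, kp)
  expect_equal(gt$r0_sq, 1 - sum((yh - k * y)^2) / sum((yh - mean(yh))^2))
  expect_equal(gt$r0p_sq, 1 - sum((y - kp * yh)^2) / sum((y - mean(y))^2))
  # internal consistency of the stored report
  expect_identical(gt$delta_r0, abs(gt$r0_sq - gt$r0p_sq))
  expect_identical(gt$ratio1, (gt$r2 - gt$r0_sq) / gt$r2)
  expect_identical(gt$ratio2, (gt$r2 - gt$r0p_sq) / gt$r2)
})

test_that("perfect predictions pass every external-validation criterion", {
  y <- c(6.2, 6.9, 7.4, 7.9)
  gt <- golbraikh_tropsha(y, y)
  expect_equal(gt$r2, 1)
  expect_equal(gt$r0_sq, 1)
  expect_equal(gt$r0p_sq, 1)
  expect_equal(gt$k, 1)
  expect_equal(gt$k_prime, 1)
  expect_equal(gt$delta_r0, 0)
  expect_true(gt$verdicts$overall)
})

test_that("slope conventions lock to the study's printed values", {
  gt <- golbraikh_tropsha(study$test_pairs$pIC50_obs,
                          study$test_pairs$pIC50_pred_mlr)
  # k = 1.006...: prints as 1.00 under truncation; k' rounds to 0.99
  expect_equal(gt$k, 1.0065, tolerance = 1e-4)
  expect_equal(trunc(gt$k * 100) / 100, 1.00)
  expect_equal(round(gt$k_prime, 2), 0.99)
})

test_that("degenerate external-validation input is rejected", {
  expect_error(golbraikh_tropsha(c(1, 2), c(1, 2)), "at least 3")
  expect_error(golbraikh_tropsha(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("rmse and mse honor their denominator conventions", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  obs <- c(1, 2, 4); pred <- c(1.5, 1.5, 3)
  expect_equal(mse(obs, pred, dof = 3), (0.25 + 0.25 + 1) / 3)
  expect_equal(mse(obs, pred, dof = 1), 1.5)
  expect_equal(rmse(obs, pred), sqrt(0.5))
  # the study's training residual column at the reported denominator
  expect_lt(abs(mse(study_train$pIC50_obs, study_train$pIC50_pred_mlr,
                    dof = 18) - 0.020), 0.001)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(mse(1, 1, dof = 0), "positive")
})
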