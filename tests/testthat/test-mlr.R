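test_that("OLS coefficients match an explicit normal-equations solve", {
  toy <- toy_two_descriptor()
  fit <- fit_mlr(toy, terms = c("x1", "x2"))
  beta <- normal_equations(as.matrix(toy[, c("x1", "x2")]), toy$pIC50_obs)
  expect_equal(unname(c(fit$intercept, fit$coefficients)), unname(beta),
               tolerance = 1e-10)
})

test_that("noiseless linear data is interpolated exactly", {
  fit <- fit_mlr(toy_line(), terms = "x1")
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["x1"]), 3, tolerance = 1e-10)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-12)
})

test_that("training refit reproduces the tabulated linear predictions", {
  fit <- fit_mlr(study_train)
  expect_lt(max(abs(predict_mlr(fit, study_train) - study_train$pIC50_pred_mlr)),
            0.05)
  expect_lt(max(abs(predict_mlr(fit, study_test) - study_test$pIC50_pred_mlr)),
            0.05)
})

test_that("F statistic is consistent with R2", {
  fit <- fit_mlr(study_train)
  s <- fit$stats
  expect_equal(s$f_statistic,
               (s$r2 / s$p) / ((1 - s$r2) / (s$n - s$p - 1)),
               tolerance = 1e-6)
  # and with the lm summary's own F
  expect_equal(s$f_statistic, unname(summary(fit$fit)$fstatistic[1]),
               tolerance = 1e-8)
})

test_that("residuals are orthogonal to the design columns", {
  for (seed in 1:5) {
    d <- generate_dataset(synthetic_config(seed = seed))
    fit <- fit_mlr(d)
    res <- d$pIC50_obs - predict_mlr(fit, d)
    X <- cbind(1, as.matrix(d[, qsar_terms()]))
    scale <- sqrt(colSums(X^2)) * sqrt(sum(res^2))
    expect_lt(max(abs(drop(t(X) %*% res)) / scale), 1e-8)
  }
})

test_that("reported model reproduces the candidate predictions", {
  m <- reported_mlr_model()
  pred <- predict_mlr(m, study$candidates)
  expect_equal(round(pred[study$candidates$compound_id == "M5"], 2), 9.58)
  expect_equal(round(pred[study$candidates$compound_id == "M4"], 2), 9.42)
  # zero descriptor vector returns the intercept
  zero <- as.data.frame(as.list(setNames(rep(0, 6), qsar_terms())))
  expect_equal(predict_mlr(m, zero), m$intercept)
})

test_that("contribution scores are standardized coefficients with the right signs", {
  fit <- fit_mlr(study_train)
  scores <- contribution_coefficients(fit, study_train)
  expect_true(all(scores[c("S", "MP", "eta")] > 0))
  expect_true(all(scores[c("Tor", "NRB", "repul")] < 0))
  expect_equal(sign(scores), sign(fit$coefficients))

  # hand-checked on a 2-descriptor toy: score = coefficient * sd(descriptor)
  toy <- toy_two_descriptor()
  tfit <- fit_mlr(toy, terms = c("x1", "x2"))
  expect_equal(unname(contribution_coefficients(tfit, toy)),
               unname(tfit$coefficients * c(sd(toy$x1), sd(toy$x2))))

  # all-zero coefficients give all-zero scores
  null_model <- mlr_model(0, setNames(rep(0, 2), c("x1", "x2")))
  expect_equal(unname(contribution_coefficients(null_model, toy)), c(0, 0))
  # zero-variance descriptor is degenerate
  toy$x2 <- 1
  expect_error(contribution_coefficients(tfit, toy), "zero-variance")
})

test_that("degenerate designs are rejected with clear errors", {
  toy <- toy_two_descriptor()
  toy$x2 <- 2 * toy$x1
  expect_error(fit_mlr(toy, terms = c("x1", "x2")), "collinear")
  expect_error(fit_mlr(toy_line(2), terms = "x1"), "too few")
  expect_error(predict_mlr(reported_mlr_model(), toy), "descriptor")
})

test_that("models serialize to JSON and back losslessly", {
  fit <- fit_mlr(study_train)
  parsed <- jsonlite::fromJSON(model_json(fit))
  expect_equal(parsed$intercept, fit$intercept)
  expect_equal(unlist(parsed$coefficients), fit$coefficients)
  expect_equal(parsed$stats$r2, fit$stats$r2)
})
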