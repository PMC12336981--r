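test_that("candidate predictions carry improvement and domain flags", {
  out <- predict_candidates(reported_mlr_model(), study$candidates,
                            study$modeling)
  expect_s3_class(out, "candidate_predictions")
  expect_equal(round(out$predicted_pIC50, 2), study$candidates$pIC50_pred)
  # improvement baseline is the best observed modeling activity (8.06)
  expect_equal(out$improvement_vs_best,
               out$predicted_pIC50 - max(study$modeling$pIC50_obs))
  expect_true(all(out$improvement_vs_best > 0))

  # a candidate identical to a training compound predicts identically
  fit <- fit_mlr(study_train)
  clone <- study_train[3, ]
  clone$compound_id <- "clone"
  out2 <- predict_candidates(fit, clone, study$modeling)
  expect_equal(out2$predicted_pIC50,
               unname(predict_mlr(fit, study_train[3, ])))

  out3 <- predict_candidates(reported_mlr_model(), study$candidates)
  expect_true(all(is.na(out3$improvement_vs_best)))
})

test_that("the designed candidates satisfy every drug-likeness rule", {
  v <- apply_druglikeness_rules(study$candidate_properties)
  expect_equal(v$lipinski_violations, rep(0L, 5))
  expect_true(all(v$lipinski & v$veber & v$egan & v$muegge & v$overall))
  # agrees with the tabulated verdicts
  expect_equal(v$lipinski, study$candidate_properties$lipinski == "Yes")
  expect_equal(v$muegge, study$candidate_properties$muegge == "Yes")
})

test_that("rule thresholds toggle individually", {
  base <- data.frame(TPSA = 115.55, n_rotatable = 6, MW = 473.55,
                     LogP = 3.98, n_HBA = 9, n_HBD = 2)
  expect_true(apply_druglikeness_rules(base)$overall)

  # TPSA just over the Veber bound fails Veber but not Lipinski
  tpsa141 <- transform(base, TPSA = 141)
  v <- apply_druglikeness_rules(tpsa141)
  expect_false(v$veber)
  expect_true(v$lipinski)

  # every Lipinski bound exceeded: four violations, overall fail
  worst <- data.frame(TPSA = 115, n_rotatable = 6, MW = 600, LogP = 6,
                      n_HBA = 11, n_HBD = 6)
  w <- apply_druglikeness_rules(worst)
  expect_equal(w$lipinski_violations, 4L)
  expect_false(w$lipinski)
  expect_false(w$overall)

  # a single Lipinski violation is still a pass (rule-of-five allowance)
  one <- transform(base, MW = 510)
  expect_equal(apply_druglikeness_rules(one)$lipinski_violations, 1L)
  expect_true(apply_druglikeness_rules(one)$lipinski)
})

test_that("worsening any property never turns a fail into a pass", {
  base <- data.frame(TPSA = 115.55, n_rotatable = 6, MW = 473.55,
                     LogP = 3.98, n_HBA = 9, n_HBD = 2)
  worsen <- list(TPSA = 30, n_rotatable = 4, MW = 80, LogP = 1.5,
                 n_HBA = 3, n_HBD = 2)
  rulesets <- c("lipinski", "veber", "egan", "muegge")
  prev <- apply_druglikeness_rules(base)
  row <- base
  for (step in 1:4) {
    for (prop in names(worsen)) row[[prop]] <- row[[prop]] + worsen[[prop]]
    cur <- apply_druglikeness_rules(row)
    for (r in rulesets) expect_true(cur[[r]] <= prev[[r]])
    expect_gte(cur$lipinski_violations, prev$lipinski_violations)
    prev <- cur
  }
})

test_that("missing properties are rejected", {
  expect_error(apply_druglikeness_rules(data.frame(TPSA = 100, MW = 400)),
               "lacks")
})
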