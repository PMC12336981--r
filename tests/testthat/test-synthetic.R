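test_that("generation is deterministic and respects the count contract", {
  cfg <- synthetic_config(seed = 17)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))

  d50 <- generate_dataset(synthetic_config(n_compounds = 50,
                                           test_fraction = 0.2, seed = 1))
  expect_equal(sum(d50$split == "train"), 40)
  expect_equal(sum(d50$split == "test"), 10)
})

test_that("descriptors respect their ranges and integer constraints", {
  d <- generate_dataset(synthetic_config(n_compounds = 200, seed = 9))
  cfg <- synthetic_config()
  for (t in qsar_terms()) {
    r <- cfg$term_ranges[[t]]
    expect_true(all(d[[t]] >= r[1] & d[[t]] <= r[2]), label = t)
  }
  expect_true(all(d$NRB == round(d$NRB)))
  expect_setequal(unique(d$NRB), 6:11)
})

test_that("zero-noise data yields exact coefficient recovery", {
  cfg <- synthetic_config(noise_sd = 0, seed = 4)
  fit <- fit_mlr(generate_dataset(cfg))
  expect_equal(fit$coefficients, cfg$true_coefficients, tolerance = 1e-8)
  expect_equal(fit$intercept, cfg$true_intercept, tolerance = 1e-8)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-10)

  rec <- recovery_experiment(synthetic_config(noise_sd = 0, seed = 30), 3)
  expect_lt(max(abs(rec$bias)), 1e-8 * max(abs(c(1, cfg$true_coefficients))))
  expect_lt(max(rec$rmse / pmax(abs(c(1, cfg$true_coefficients)), 1e-3)), 1e-6)
})

test_that("refit R2 concentrates at the analytic signal-to-total ratio", {
  # population R2 = V / (V + noise^2) with V the linear signal variance
  # under the independent uniform (and discrete-uniform NRB) marginals
  cfg <- synthetic_config()
  V <- 0
  for (t in names(cfg$term_ranges)) {
    r <- cfg$term_ranges[[t]]
    v <- if (t %in% cfg$integer_terms) {
      k <- floor(r[2]) - ceiling(r[1]) + 1
      (k^2 - 1) / 12
    } else (r[2] - r[1])^2 / 12
    V <- V + cfg$true_coefficients[[t]]^2 * v
  }
  expected_r2 <- V / (V + cfg$noise_sd^2)

  r2s <- vapply(1:100, function(s) {
    d <- generate_dataset(synthetic_config(seed = s))
    fit_mlr(d[d$split == "train", ])$stats$r2
  }, numeric(1))
  expect_equal(mean(r2s), expected_r2, tolerance = 0.02)
  expect_true(all(r2s > expected_r2 - 0.05 & r2s <= 1))
})

test_that("cross-validated Q2 sits below training R2 on noisy data", {
  cfg <- synthetic_config(n_compounds = 25, test_fraction = 0, seed = 100)
  rec <- recovery_experiment(cfg, 100)
  expect_lt(rec$mean_q2, rec$mean_r2)
  expect_equal(nrow(rec$estimates), 100)
})

test_that("doubling the noise scales every coefficient RMSE up", {
  cfg1 <- synthetic_config(n_compounds = 25, test_fraction = 0, seed = 500)
  cfg2 <- cfg1
  cfg2$noise_sd <- 2 * cfg1$noise_sd
  r1 <- recovery_experiment(cfg1, 30)
  r2 <- recovery_experiment(cfg2, 30)
  expect_true(all(r2$rmse > r1$rmse))
})

test_that("degenerate configurations are rejected", {
  expect_error(synthetic_config(term_ranges = list(S = c(2, 1)),
                                true_coefficients = c(S = 1)),
               "degenerate")
  expect_error(synthetic_config(true_coefficients = c(bogus = 1)),
               "same descriptors")
  expect_error(synthetic_config(noise_sd = -1))
})

test_that("synthetic datasets round-trip through CSV plus truth JSON", {
  csv <- withr::local_tempfile(fileext = ".csv")
  truth_json <- withr::local_tempfile(fileext = ".json")
  d <- generate_dataset(synthetic_config(seed = 23))
  write_synthetic_dataset(d, csv, truth_json)
  back <- read_compound_csv(csv)
  expect_equal(back$pIC50_obs, d$pIC50_obs)
  truth <- jsonlite::read_json(truth_json, simplifyVector = TRUE)
  expect_equal(truth$noise_sd, 0.13)
  expect_equal(unlist(truth$coefficients),
               attr(d, "truth")$coefficients)
})
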