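test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 60, seed = 5)
  a <- generate_registry(cfg)
  b <- generate_registry(cfg)
  expect_identical(a, b)
  c2 <- generate_registry(sim_config(n_patients = 60, seed = 6))
  expect_false(identical(a$ground_truth, c2$ground_truth))
})

test_that("trial-arm generation is deterministic and respects bounds", {
  a <- generate_trial_arm("ranibizumab_monthly", 301, seed = 3)
  b <- generate_trial_arm("ranibizumab_monthly", 301, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a), 301)
  expect_true(all(a$baseline_letters >= 23 & a$baseline_letters <= 82))
  expect_true(all(a$year1_letters >= 0 & a$year1_letters <= 100))
  expect_true(all(a$n_injections >= 1))
  expect_error(generate_trial_arm("ranibizumab_monthly", 0), "positive")
})

test_that("generated marginals track the configuration", {
  cfg <- sim_config(n_patients = 800, seed = 21,
                    violation_fractions = c())
  sim <- generate_registry(cfg)
  gt <- sim$ground_truth
  pats <- sim$registry$patients
  # 2-SE tolerances (binomial / normal sampling error at n = 800)
  expect_lt(abs(mean(pats$gender == "F") - 0.63), 2 * sqrt(0.63 * 0.37 / 800))
  # closed-form truncated-normal mean (letters are drawn truncated to the
  # eligible chart range [25, 80], which pulls the latent mean 60 down)
  a <- (25 - 60) / 13; b <- (80 - 60) / 13
  mtrunc <- 60 + 13 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  # 0.35 slack for quantization to the ~5-letter chart grid
  expect_lt(abs(mean(gt$true_baseline_letters) - mtrunc),
            2.5 * 13 / sqrt(800) + 0.35)
  expect_lt(abs(mean(gt$arm == "ranibizumab") - 0.36),
            2 * sqrt(0.36 * 0.64 / 800))
  # every recorded acuity sits on a chart line
  key <- paste(sim$registry$va$snellen_num, sim$registry$va$snellen_den)
  expect_true(all(key %in% paste(cfg$chart$snellen_num,
                                 cfg$chart$snellen_den)))
})

test_that("trial injection counts recover the configured mean (CLT)", {
  tr <- generate_trial_arm("ranibizumab_monthly", 5000,
                           outcomes = list(injection_mean = 11.7), seed = 9)
  expect_lt(abs(mean(tr$n_injections) - 11.7), 0.1)
})

test_that("seeded violation mix approximates the configured fractions", {
  vf <- c(cadence = 0.10, glaucoma = 0.05)
  sim <- generate_registry(sim_config(n_patients = 600, seed = 13,
                                      violation_fractions = vf))
  tab <- table(sim$ground_truth$seeded_violation)
  expect_lt(abs(tab[["cadence"]] / 600 - 0.10), 2 * sqrt(0.1 * 0.9 / 600))
  expect_lt(abs(tab[["glaucoma"]] / 600 - 0.05), 2 * sqrt(0.05 * 0.95 / 600))
  expect_false("dr_dme" %in% names(tab))
})

test_that("infeasible or malformed configurations are rejected", {
  expect_error(sim_config(violation_fractions = c(cadence = 0.7,
                                                  glaucoma = 0.5)),
               "sum")
  expect_error(sim_config(violation_fractions = c(bogus = 0.1)), "unknown")
  expect_error(sim_config(n_patients = 0))
  expect_error(sim_config(arm_probs = c(bevacizumab = 0.9,
                                        ranibizumab = 0.9)))
})

test_that("fixture bundles round-trip through disk", {
  sim <- generate_registry(sim_config(n_patients = 25, seed = 2))
  trial <- generate_trial_arm("bevacizumab_monthly", 30, seed = 2)
  dir <- withr::local_tempdir()
  write_fixture_bundle(dir, sim$registry, trial, sim$ground_truth)
  back <- load_registry(dir)
  for (tb in names(trialemulate:::registry_schema())) {
    expect_equal(back[[tb]], sim$registry[[tb]], ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  trial_back <- load_trial(file.path(dir, "trial.csv"))
  expect_equal(trial_back, trial, ignore_attr = TRUE)
  expect_error(write_fixture_bundle(file.path(dir, "nope"), sim$registry),
               "does not exist")
})
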