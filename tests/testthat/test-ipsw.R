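test_that("the IRLS fit matches the GLM oracle on random fixtures", {
  set.seed(42)
  for (k in 1:10) {
    n <- sample(80:300, 1)
    x <- cbind(age = rnorm(n, 80, 7), female = rbinom(n, 1, 0.6),
               baseline_letters = rnorm(n, 60, 13))
    beta <- c(-1, 0.02, 0.4, -0.01)
    y <- rbinom(n, 1, plogis(cbind(1, x) %*% beta))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    fit <- fit_logistic(x, y)
    oracle <- glm(y ~ x, family = binomial)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$coefficients - unname(coef(oracle)))), 1e-6)
    expect_lt(abs(fit$log_likelihood - as.numeric(logLik(oracle))), 1e-8)
  }
})

test_that("a balanced binary design gives zero coefficients", {
  x <- matrix(rep(c(0, 1), each = 4), ncol = 1)
  y <- c(0, 0, 1, 1, 0, 0, 1, 1)  # 2/4 positive in each stratum
  fit <- fit_logistic(x, y)
  expect_lt(max(abs(fit$coefficients)), 1e-8)
})

test_that("null covariates give near-zero slopes (oracle simulation)", {
  set.seed(7)
  n <- 2000
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.4)
  fit <- fit_logistic(x, y)
  se <- sqrt(diag(vcov(glm(y ~ x, family = binomial))))
  expect_lt(abs(fit$coefficients[["a"]]), 2 * se[2])
  expect_lt(abs(fit$coefficients[["b"]]), 2 * se[3])
})

test_that("separation is flagged and weights are refused", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(x, y)
  expect_false(fit$converged)
  eyes <- data.frame(patient_id = letters[1:3], laterality = "OD",
                     age_at_index = 70, gender = "F", baseline_letters = 60)
  expect_error(att_weights(fit, eyes), "converge")
  expect_error(fit_logistic(matrix(1, 4, 1), c(0, 0, 1, 1)),
               "rank-deficient")
  expect_error(fit_logistic(matrix(rnorm(4), 4, 1), c(0, 0, 0, 0)),
               "each label")
})

test_that("identical covariate distributions give unit weights", {
  tr <- data.frame(age = rep(c(70, 80), 20), gender = "F",
                   baseline_letters = rep(c(55, 65), each = 20))
  ey <- data.frame(patient_id = sprintf("e%02d", 1:40), laterality = "OD",
                   age_at_index = rep(c(70, 80), 20), gender = "F",
                   baseline_letters = rep(c(55, 65), each = 20))
  ws <- att_weights(fit_propensity(tr, ey), ey)
  expect_equal(unname(ws$weights), rep(1, 40), tolerance = 1e-6)
})

test_that("the two-stratum toy example gives closed-form 3 and 1/3", {
  # stratum A: 30 trial / 10 registry; stratum B: 10 trial / 30 registry
  tr <- data.frame(age = c(rep(70, 30), rep(80, 10)), gender = "F",
                   baseline_letters = 60)
  ey <- data.frame(patient_id = sprintf("e%02d", 1:40), laterality = "OD",
                   age_at_index = c(rep(70, 10), rep(80, 30)), gender = "F",
                   baseline_letters = 60)
  ws <- att_weights(fit_propensity(tr, ey), ey)
  # odds are 3 in stratum A and 1/3 in stratum B; their weighted sum is
  # already 40, so normalization leaves them untouched
  expect_equal(unname(ws$weights[1:10]), rep(3, 10), tolerance = 1e-6)
  expect_equal(unname(ws$weights[11:40]), rep(1 / 3, 30), tolerance = 1e-6)
  expect_equal(sum(ws$weights), 40, tolerance = 1e-9)
})

test_that("weighted mean/SD follow the frequency-weight convention", {
  x <- c(2, 5, 9, 1)
  expect_equal(weighted_mean_sd(x, rep(1, 4)),
               c(mean = mean(x), sd = sd(x)))
  expect_equal(weighted_mean_sd(c(1, 3), c(1, 2))[["mean"]], 7 / 3)
  # frequency semantics: weight 2 == the value appearing twice
  expect_equal(weighted_mean_sd(c(1, 3), c(1, 2))[["sd"]],
               sd(c(1, 3, 3)))
  expect_error(weighted_mean_sd(x, c(1, 1, 0, 1)), "positive")
})

test_that("smd and effective_n match hand arithmetic", {
  expect_equal(smd(rep(c(1, 2), 10), rep(c(1, 2), 10)), 0)
  a <- rnorm(500, 1, 1); b <- rnorm(500, 0, 1)
  expect_equal(smd(a, b), (mean(a) - mean(b)) /
                 sqrt((sd(a)^2 + sd(b)^2) / 2))
  expect_warning(s <- smd(rep(1, 5), rep(1, 5)), "undefined")
  expect_true(is.nan(s))
  expect_equal(effective_n(rep(2, 10)), 10)
  expect_equal(effective_n(c(1, 1, 2)), 16 / 6)
  expect_error(effective_n(numeric(0)), "empty")
})

test_that("weighting moves shifted registry covariates toward the trial", {
  set.seed(11)
  for (k in 1:3) {
    n <- 400
    tr <- data.frame(age = pmin(round(rnorm(n, 79, 7)), 95),
                     gender = ifelse(runif(n) < 0.6, "F", "M"),
                     baseline_letters = round(rnorm(n, 60, 13)))
    ey <- data.frame(patient_id = sprintf("e%04d", 1:n), laterality = "OD",
                     age_at_index = pmin(round(rnorm(n, 83, 7)), 95),
                     gender = ifelse(runif(n) < 0.68, "F", "M"),
                     baseline_letters = round(rnorm(n, 55, 13)))
    ws <- att_weights(fit_propensity(tr, ey), ey)
    bal <- balance_report(tr, ey, ws)
    expect_true(all(abs(bal$smd_after) < abs(bal$smd_before)))
    expect_equal(sum(ws$weights), n, tolerance = 1e-9)
    expect_true(all(ws$weights > 0))
    expect_lte(attr(bal, "effective_n"), n)
  }
})

test_that("capped propensity values are counted, not silent", {
  tr <- data.frame(age = rep(90, 50), gender = "F",
                   baseline_letters = rep(80, 50))
  ey <- data.frame(patient_id = sprintf("e%02d", 1:52), laterality = "OD",
                   age_at_index = c(rep(90, 2), rep(55, 50)), gender = "F",
                   baseline_letters = c(rep(80, 2), rep(30, 50)))
  fit <- fit_propensity(tr, ey)
  if (fit$converged) {
    res <- withCallingHandlers(
      att_weights(fit, ey, p_max = 0.6),
      warning = function(w) {
        expect_match(conditionMessage(w), "capped")
        invokeRestart("muffleWarning")
      })
    expect_gt(res$n_capped, 0)
  } else {
    succeed("separated design refused upstream")
  }
})
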