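#' Inverse propensity score weighting
#'
#' A logistic regression of trial membership (monthly trial arm = 1,
#' registry prn arm = 0) on age, gender, and baseline acuity yields each
#' registry eye's probability p of trial membership; the ATT odds weight
#' p / (1 - p) reweights the registry arm toward the trial population.
#' Weights are rescaled to sum to the registry arm size so weighted
#' subgroup tallies are fractional counts directly comparable to cohort N.
#' The published description does not state the weight formula or
#' normalization; this ATT-odds interpretation (reweight the real-world arm
#' to resemble the trial arm it emulates) is the package's documented
#' reading.
#'
#' @name ipsw
NULL

#' Maximum-likelihood logistic regression (IRLS)
#'
#' Self-contained Newton/iteratively-reweighted-least-squares fit; written
#' in-package so the estimator under test is independent of the general
#' GLM machinery used as the oracle in the test suite.
#'
#' @param x Design matrix (no intercept column; one is added).
#' @param y Binary 0/1 response.
#' @param tol Convergence: maximum absolute coefficient change (1e-10).
#' @param max_iter Iteration cap (100).
#' @return List of class `propensity_fit`: `coefficients` (named, with
#'   `(Intercept)` first), `fitted`, `converged`, `log_likelihood`,
#'   `n_iterations`, `separated`.
#' @export
fit_logistic <- function(x, y, tol = 1e-10, max_iter = 100) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("need at least one observation of each label", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank-deficient (constant or collinear column)",
         call. = FALSE)
  }
  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    fit <- tryCatch(
      qr.solve(qr(X * sqrt(w)), z * sqrt(w)),
      error = function(e) NULL)
    if (is.null(fit)) break
    delta <- max(abs(fit - beta))
    beta <- fit
    if (delta <= tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  # quasi-complete separation: fitted probabilities at the boundary
  separated <- any(p > 1 - 1e-8 & y == 1) && any(p < 1e-8 & y == 0) ||
    any(pmin(p, 1 - p) < 1e-10)
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 fitted = p, converged = converged && !separated,
                 log_likelihood = ll, n_iterations = iter,
                 separated = separated),
            class = "propensity_fit")
}

#' Fit the trial-membership propensity model
#'
#' Covariates: age in years, an indicator for the top-coded age category
#' (>= `topcode_age`; deidentified registries report all such ages as one
#' value, so a purely linear age term misfits the resulting point mass and
#' leaves that subgroup imbalanced), a female indicator, and baseline
#' letters. Constant or collinear columns are dropped (pivoted QR) before
#' fitting, so degenerate designs - e.g. a single-gender cohort - fit on
#' the remaining covariates.
#'
#' @param trial Trial roster data.frame (`age`, `gender`,
#'   `baseline_letters`).
#' @param eyes Registry cohort data.frame (`age_at_index`, `gender`,
#'   `baseline_letters`).
#' @param topcode_age Top-coded age category bound (default 90).
#' @return A `propensity_fit` with trial membership as the response;
#'   `dropped` lists covariate columns removed as constant/collinear.
#' @export
fit_propensity <- function(trial, eyes, topcode_age = 90) {
  x <- rbind(
    data.frame(age = trial$age,
               age_top = as.numeric(trial$age >= topcode_age),
               female = as.numeric(trial$gender == "F"),
               baseline_letters = trial$baseline_letters),
    data.frame(age = eyes$age_at_index,
               age_top = as.numeric(eyes$age_at_index >= topcode_age),
               female = as.numeric(eyes$gender == "F"),
               baseline_letters = eyes$baseline_letters)
  )
  x <- as.matrix(x)
  y <- c(rep(1, nrow(trial)), rep(0, nrow(eyes)))
  q <- qr(cbind(1, x))
  keep <- sort(setdiff(q$pivot[seq_len(q$rank)], 1L)) - 1L
  dropped <- setdiff(colnames(x), colnames(x)[keep])
  fit <- fit_logistic(x[, keep, drop = FALSE], y)
  fit$dropped <- dropped
  fit$n_trial <- nrow(trial)
  fit$n_registry <- nrow(eyes)
  fit
}

#' ATT odds weights for the registry arm
#'
#' Raw weight p / (1 - p), where p is the predicted probability of trial
#' membership; predicted probabilities above `p_max` are capped (the count
#' of capped eyes is reported, never silent). Weights are rescaled so their
#' sum equals the registry arm size.
#'
#' @param fit A converged `propensity_fit` from [fit_propensity()].
#' @param eyes The registry cohort the model was fitted with (order must
#'   match).
#' @param p_max Cap on predicted probability (default 0.999).
#' @return List of class `weight_set`: `weights` (named by eye key),
#'   `n_capped`, `normalization` (= number of eyes).
#' @export
att_weights <- function(fit, eyes, p_max = 0.999) {
  if (!inherits(fit, "propensity_fit")) stop("fit must be a propensity_fit",
                                             call. = FALSE)
  if (!isTRUE(fit$converged)) {
    stop("propensity model did not converge (possible separation); ",
         "weights refused", call. = FALSE)
  }
  n <- nrow(eyes)
  p <- fit$fitted[seq(fit$n_trial + 1, fit$n_trial + n)]
  n_capped <- sum(p > p_max)
  if (n_capped > 0) {
    warning(sprintf("%d propensity value(s) capped at %.3f", n_capped,
                    p_max), call. = FALSE)
    p <- pmin(p, p_max)
  }
  raw <- p / (1 - p)
  w <- raw * n / sum(raw)
  structure(list(weights = setNames(w, eye_key(eyes$patient_id,
                                               eyes$laterality)),
                 n_capped = n_capped, normalization = n),
            class = "weight_set")
}

#' Weighted mean and standard deviation
#'
#' Frequency-weight convention: SD uses denominator (sum of weights - 1),
#' so uniform unit weights reproduce the ordinary sample SD.
#'
#' @param values Numeric vector.
#' @param weights Positive weights (sum > 1 for the SD).
#' @return Named numeric: `mean`, `sd`.
#' @export
weighted_mean_sd <- function(values, weights) {
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  stopifnot(length(values) == length(weights))
  sw <- sum(weights)
  m <- sum(weights * values) / sw
  s <- if (sw > 1) sqrt(sum(weights * (values - m)^2) / (sw - 1)) else NA_real_
  c(mean = m, sd = s)
}

#' Standardized mean difference
#'
#' (mean_a - mean_b) / pooled SD, the usual scale-free balance diagnostic;
#' group b may be weighted. Returns `NaN` (flagged degenerate) when the
#' pooled SD is zero.
#'
#' @param a,b Numeric vectors.
#' @param weights_b Optional positive weights for `b`.
#' @return Numeric SMD.
#' @export
smd <- function(a, b, weights_b = NULL) {
  ma <- mean(a); sa <- stats::sd(a)
  if (is.null(weights_b)) {
    mb <- mean(b); sb <- stats::sd(b)
  } else {
    ms <- weighted_mean_sd(b, weights_b)
    mb <- ms["mean"]; sb <- ms["sd"]
  }
  pooled <- sqrt((sa^2 + sb^2) / 2)
  if (!is.finite(pooled) || pooled == 0) {
    warning("zero pooled SD: SMD undefined", call. = FALSE)
    return(NaN)
  }
  unname((ma - mb) / pooled)
}

#' Effective sample size of a weighted sample
#'
#' Kish's (sum w)^2 / sum(w^2): n for uniform weights, approaching 1 when a
#' single weight dominates.
#'
#' @param weights Positive weights.
#' @return Numeric.
#' @export
effective_n <- function(weights) {
  if (length(weights) == 0) stop("empty weight set", call. = FALSE)
  sum(weights)^2 / sum(weights^2)
}

#' Covariate balance before and after weighting
#'
#' @param trial Trial roster.
#' @param eyes Registry cohort.
#' @param weight_set A `weight_set` from [att_weights()].
#' @return data.frame: `covariate`, `smd_before`, `smd_after`, plus the
#'   effective sample size as attribute `effective_n`.
#' @export
balance_report <- function(trial, eyes, weight_set) {
  w <- weight_set$weights
  covs <- list(
    age = list(a = trial$age, b = eyes$age_at_index),
    female = list(a = as.numeric(trial$gender == "F"),
                  b = as.numeric(eyes$gender == "F")),
    baseline_letters = list(a = trial$baseline_letters,
                            b = eyes$baseline_letters)
  )
  out <- data.frame(
    covariate = names(covs),
    smd_before = vapply(covs, function(cc) smd(cc$a, cc$b), numeric(1)),
    smd_after = vapply(covs, function(cc) smd(cc$a, cc$b, weights_b = w),
                       numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "effective_n") <- effective_n(w)
  out
}
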