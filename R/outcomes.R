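#' Per-arm clinical outcome summaries
#'
#' One-year acuity change, 15-letter responder proportions, injection
#' counts, annual drug cost (unit cost x mean injections), and
#' endophthalmitis incidence, with an optional weighted path for IPSW arms.
#' Acuity-change summaries are computed over eyes with both baseline and
#' one-year measurements (`n_va`), reported separately from the arm size.
#'
#' @name outcomes
NULL

#' Drug cost schedule
#'
#' @param costs Named unit costs per dose in USD (defaults: ranibizumab
#'   2000, bevacizumab 50).
#' @return Named numeric vector of class `cost_schedule`.
#' @export
cost_schedule <- function(costs = c(ranibizumab = 2000, bevacizumab = 50)) {
  stopifnot(all(costs >= 0), !is.null(names(costs)))
  structure(costs, class = "cost_schedule")
}

#' One-year acuity change in letters
#'
#' @param baseline,year1 Integer letter scores.
#' @return `year1 - baseline` (NA if either is missing).
#' @export
va_change <- function(baseline, year1) year1 - baseline

#' 15-letter responder flags
#'
#' @param change Letter change (vectorized).
#' @return data.frame with logical `gain15` (change >= +15) and `loss15`
#'   (change <= -15); boundaries inclusive, mutually exclusive.
#' @export
responder_flags <- function(change) {
  data.frame(gain15 = change >= 15, loss15 = change <= -15)
}

#' Annual drug cost per patient
#'
#' @param mean_injections Mean injections over the year (full precision;
#'   rounding for display happens only at the report layer).
#' @param drug Drug name present in the schedule.
#' @param schedule A [cost_schedule()].
#' @return Cost in USD, rounded to the cent.
#' @examples
#' drug_cost(11.7, "ranibizumab")  # 23400
#' drug_cost(11.9, "bevacizumab")  # 595
#' @export
drug_cost <- function(mean_injections, drug, schedule = cost_schedule()) {
  stopifnot(mean_injections >= 0)
  if (!drug %in% names(schedule)) {
    stop("unknown drug: ", drug, call. = FALSE)
  }
  # cents internally: unit costs are whole dollars, so the product in cents
  # is exact for means with limited precision
  round(mean_injections * unclass(schedule)[[drug]] * 100) / 100
}

#' Endophthalmitis incidence
#'
#' @param flags Logical vector (or weights-weighted via `weights`).
#' @param weights Optional positive weights.
#' @return Named numeric: `count`, `percent` (100 * count / n, rounded to
#'   2 decimals).
#' @examples
#' ae_incidence(c(rep(FALSE, 282), TRUE, TRUE))  # 2 of 284 -> 0.70%
#' @export
ae_incidence <- function(flags, weights = NULL) {
  if (length(flags) == 0) stop("empty arm", call. = FALSE)
  if (is.null(weights)) {
    c(count = sum(flags), percent = round(100 * mean(flags), 2))
  } else {
    cnt <- sum(weights[flags])
    c(count = cnt, percent = round(100 * cnt / sum(weights), 2))
  }
}

#' Summarize an arm's outcomes
#'
#' @param arm_label Label for the output row.
#' @param drug Drug for the cost line.
#' @param baseline,year1 Letter scores per eye (year1 may contain NA).
#' @param n_injections Injection counts per eye.
#' @param endophthalmitis Logical flags per eye.
#' @param weights Optional positive weights (IPSW path); uniform weights
#'   reproduce the unweighted summary exactly.
#' @param schedule A [cost_schedule()].
#' @return One-row data.frame of class `arm_summary`: `arm`, `n`, `n_va`,
#'   `mean_change_letters`, `sd_change_letters`, `pct_gain15`, `pct_loss15`,
#'   `mean_injections`, `cost_per_patient`, `endophthalmitis_n`,
#'   `endophthalmitis_pct`.
#' @export
summarize_arm <- function(arm_label, drug, baseline, year1, n_injections,
                          endophthalmitis, weights = NULL,
                          schedule = cost_schedule()) {
  n <- length(baseline)
  if (n == 0) stop("empty arm", call. = FALSE)
  stopifnot(length(year1) == n, length(n_injections) == n,
            length(endophthalmitis) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)

  chg <- va_change(baseline, year1)
  has_va <- !is.na(chg)
  ms <- weighted_mean_sd(chg[has_va], weights[has_va])
  fl <- responder_flags(chg[has_va])
  wva <- weights[has_va]
  inj <- weighted_mean_sd(n_injections, weights)
  ae <- ae_incidence(endophthalmitis,
                     weights = if (all(weights == 1)) NULL else weights)
  out <- data.frame(
    arm = arm_label,
    n = sum(weights),
    n_va = sum(wva),
    mean_change_letters = unname(ms["mean"]),
    sd_change_letters = unname(ms["sd"]),
    pct_gain15 = 100 * sum(wva[fl$gain15]) / sum(wva),
    pct_loss15 = 100 * sum(wva[fl$loss15]) / sum(wva),
    mean_injections = unname(inj["mean"]),
    cost_per_patient = drug_cost(unname(inj["mean"]), drug, schedule),
    endophthalmitis_n = unname(ae["count"]),
    endophthalmitis_pct = unname(ae["percent"]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("arm_summary", class(out))
  out
}

#' Summarize an eligible-eye cohort (or matched subset)
#'
#' Convenience wrapper over [summarize_arm()] for the cohort data.frame
#' produced by [run_attrition()].
#'
#' @param eyes Cohort data.frame.
#' @param arm_label Output label (default the drug).
#' @param weights Optional `weight_set` or numeric weights aligned to
#'   `eyes`.
#' @param schedule A [cost_schedule()].
#' @export
summarize_cohort <- function(eyes, arm_label = NULL, weights = NULL,
                             schedule = cost_schedule()) {
  drug <- unique(eyes$drug)
  stopifnot(length(drug) == 1)
  if (inherits(weights, "weight_set")) {
    weights <- unname(weights$weights[eye_key(eyes$patient_id,
                                              eyes$laterality)])
  }
  summarize_arm(arm_label %||% drug, drug, eyes$baseline_letters,
                eyes$year1_letters, eyes$n_injections_year1,
                eyes$endophthalmitis, weights = weights,
                schedule = schedule)
}

#' Summarize a trial roster arm
#'
#' @param trial Trial roster data.frame (one arm).
#' @param drug Drug for costing (inferred from the arm label when absent).
#' @param schedule A [cost_schedule()].
#' @export
summarize_trial_arm <- function(trial, drug = NULL,
                                schedule = cost_schedule()) {
  arm <- unique(trial$arm)
  stopifnot(length(arm) == 1)
  if (is.null(drug)) {
    drug <- if (grepl("ranibizumab", arm)) "ranibizumab" else "bevacizumab"
  }
  summarize_arm(arm, drug, trial$baseline_letters, trial$year1_letters,
                trial$n_injections, trial$endophthalmitis,
                schedule = schedule)
}
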