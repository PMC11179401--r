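#' Visual acuity: Snellen fractions and approximated ETDRS letters
#'
#' Registry visual acuity is recorded as Snellen chart lines (e.g. 20/40).
#' For analysis these are converted to an approximated ETDRS letter score
#' with the standard chart conversion
#' \deqn{letters = 85 + 50 \log_{10}(\mathrm{Snellen\ fraction})}
#' rounded to the nearest letter (half away from zero) and clamped to
#' \[0, 100\]. 20/20 maps to 85 letters and 20/200 to 35 letters.
#'
#' @name vision
NULL

#' Standard Snellen chart used for synthesis and nearest-line lookup
#'
#' @param denominators Snellen denominators at a 20-foot test distance,
#'   ordered from best to worst line. The default spans 20/20 to 20/400.
#' @param numerator Test distance in feet, conventionally 20.
#' @return A data.frame with columns `snellen_num`, `snellen_den`, `letters`.
#' @examples
#' standard_chart()
#' @export
standard_chart <- function(denominators = c(20, 25, 32, 40, 50, 63, 80, 100,
                                            125, 160, 200, 250, 320, 400),
                           numerator = 20) {
  stopifnot(length(denominators) >= 1, all(denominators > 0), numerator > 0)
  data.frame(
    snellen_num = numerator,
    snellen_den = denominators,
    letters = snellen_to_letters(numerator, denominators)
  )
}

#' Extended chart with better-than-20/20 lines
#'
#' Real Snellen charts carry lines above 20/20 (20/16, 20/12.5, 20/10,
#' i.e. 90/95/100 letters). The synthetic generator measures follow-up
#' acuity on this chart so that eyes gaining vision are not artificially
#' censored at 85 letters; eligibility bounds are applied separately.
#'
#' @inheritParams standard_chart
#' @return A data.frame as in [standard_chart()].
#' @export
extended_chart <- function(numerator = 20) {
  standard_chart(denominators = c(10, 12.5, 16, 20, 25, 32, 40, 50, 63, 80,
                                  100, 125, 160, 200, 250, 320, 400),
                 numerator = numerator)
}

#' Round half away from zero
#'
#' `base::round()` rounds half to even, which would silently move chart
#' lines (e.g. 20/25 = 80.15 is safe, but half-valued scores are not).
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a Snellen acuity to approximated ETDRS letters
#'
#' @param numerator Test distance in feet (conventionally 20); vectorized.
#' @param denominator Letter-size distance in feet; vectorized.
#' @return Integer letter score(s), `85 + 50 * log10(num/den)` rounded half
#'   away from zero and clamped to \[0, 100\].
#' @examples
#' snellen_to_letters(20, 20)   # 85
#' snellen_to_letters(20, 200)  # 35
#' @export
snellen_to_letters <- function(numerator, denominator) {
  if (any(!is.finite(numerator)) || any(!is.finite(denominator)) ||
      any(numerator <= 0) || any(denominator <= 0)) {
    stop("invalid Snellen acuity: numerator and denominator must be positive",
         call. = FALSE)
  }
  raw <- 85 + 50 * log10(numerator / denominator)
  as.integer(pmin(100, pmax(0, round_half_away(raw))))
}

#' Nearest chart line for a letter score
#'
#' Used by the synthetic generator to emit chart-valued acuities. Ties are
#' broken toward the better (higher-letters) line.
#'
#' @param letters Integer letter score(s) in \[0, 100\]; vectorized.
#' @param chart A chart data.frame from [standard_chart()].
#' @return A data.frame (one row per input) with `snellen_num`,
#'   `snellen_den`, `letters` of the chosen line.
#' @export
letters_to_nearest_snellen <- function(letters, chart = standard_chart()) {
  if (is.null(chart) || nrow(chart) == 0) {
    stop("chart must be a non-empty data.frame", call. = FALSE)
  }
  idx <- vapply(letters, function(l) {
    d <- abs(chart$letters - l)
    cand <- which(d == min(d))
    cand[which.max(chart$letters[cand])]
  }, integer(1))
  chart[idx, , drop = FALSE]
}

#' Best-documented letter score for an eye on a calendar day
#'
#' Registry encounters can record several Snellen measurements on the same
#' day; the best (maximum converted letters) one is the documented acuity.
#'
#' @param va_events data.frame with columns `patient_id`, `laterality`,
#'   `date` (Date), `snellen_num`, `snellen_den`.
#' @param patient_id,laterality Eye identifier.
#' @param date Calendar day (Date).
#' @return Integer letter score, or `NA_integer_` if no measurement.
#' @export
best_documented_letters <- function(va_events, patient_id, laterality, date) {
  sel <- va_events$patient_id == patient_id &
    va_events$laterality == laterality &
    va_events$date == date
  if (!any(sel)) return(NA_integer_)
  max(snellen_to_letters(va_events$snellen_num[sel],
                         va_events$snellen_den[sel]))
}

#' Baseline acuity at the index date
#'
#' Prefers a measurement on the index day itself; failing that, the
#' best-documented score at the nearest earlier measurement date within
#' `lookback_days` (default 14, keeping baseline pre-treatment).
#'
#' @inheritParams best_documented_letters
#' @param index_date Date of the first anti-VEGF injection.
#' @param lookback_days Non-negative window for a pre-index fallback.
#' @return Integer letter score or `NA_integer_`.
#' @export
select_baseline_va <- function(va_events, patient_id, laterality, index_date,
                               lookback_days = 14) {
  stopifnot(lookback_days >= 0)
  eye <- va_events[va_events$patient_id == patient_id &
                     va_events$laterality == laterality, , drop = FALSE]
  on_index <- best_documented_letters(eye, patient_id, laterality, index_date)
  if (!is.na(on_index)) return(on_index)
  prior <- eye$date[eye$date < index_date &
                      eye$date >= index_date - lookback_days]
  if (length(prior) == 0) return(NA_integer_)
  best_documented_letters(eye, patient_id, laterality, max(prior))
}

#' One-year endpoint acuity
#'
#' The measurement date nearest to `index_date + target_offset` within
#' `window_days` on either side; ties between an earlier and a later
#' equidistant date go to the later one.
#'
#' @inheritParams select_baseline_va
#' @param target_offset Days from index to the nominal endpoint (365).
#' @param window_days Acceptance half-window around the target (default 56).
#' @return Integer letter score or `NA_integer_`.
#' @export
select_year1_va <- function(va_events, patient_id, laterality, index_date,
                            target_offset = 365, window_days = 56) {
  stopifnot(window_days >= 0)
  eye <- va_events[va_events$patient_id == patient_id &
                     va_events$laterality == laterality, , drop = FALSE]
  target <- index_date + target_offset
  dates <- unique(eye$date[abs(as.numeric(eye$date - target)) <= window_days])
  if (length(dates) == 0) return(NA_integer_)
  dist <- abs(as.numeric(dates - target))
  cand <- dates[dist == min(dist)]
  best_documented_letters(eye, patient_id, laterality, max(cand))
}
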