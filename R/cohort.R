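#' Eligibility and attrition engine
#'
#' Applies the trial's non-imaging inclusion/exclusion criteria and the prn
#' treatment-pattern requirements to a registry, row by row in a fixed
#' order, and reports cumulative patient/eye counts (an attrition table)
#' plus the final per-drug eligible cohorts.
#'
#' Interval conventions (the source tables state none): lookbacks are
#' half-open `(index - N, index]`; the treatment-naive lookback excludes the
#' index injection itself, `[index - 365, index)`; follow-up is closed
#' `[index, index + 365]`.
#'
#' @name cohort
NULL

#' Criterion configuration
#'
#' @param naive_lookback_days Days before index with no anti-VEGF injection.
#' @param dx_lookback_days Window for dated exclusion diagnoses.
#' @param min_age Minimum age at index.
#' @param min_preindex_days Required pre-index record history.
#' @param va_bounds Snellen-fraction eligibility bounds, inclusive
#'   (default 20/320 to 20/25); applied to the baseline measurement's
#'   fraction, not to converted letters, to avoid rounding artifacts.
#' @param baseline_lookback_days Pre-index fallback window for baseline VA.
#' @param cadence_max_gap_days Maximum allowed gap between retina visits.
#' @param cadence_min_gap_days Optional strict lower bound on visit gaps
#'   (NULL = no minimum; real visits can be closer than 4 weeks).
#' @param cadence_first_visit_max_day Latest allowed first retina visit.
#' @param cadence_last_visit_min_day Earliest allowed last retina visit
#'   (323 = 365 - 42, i.e. coverage through the year).
#' @param followup_days Follow-up horizon after index.
#' @param surgery_washout_days Pre-index intraocular-surgery washout.
#' @param iop_threshold_mmHg,iop_min_readings Uncontrolled-glaucoma rule:
#'   at least `iop_min_readings` readings at or above the threshold in the
#'   year before index.
#' @param year1_window_days Half-window for the 1-year endpoint acuity.
#' @param ae_attribution_days Post-injection window for endophthalmitis.
#' @param anti_vegf_drugs Drug names counted as anti-VEGF.
#' @param study_drugs The two admissible study regimens.
#' @return List of class `criterion_config`.
#' @export
criterion_config <- function(naive_lookback_days = 365,
                             dx_lookback_days = 365,
                             min_age = 50,
                             min_preindex_days = 365,
                             va_bounds = c(20 / 320, 20 / 25),
                             baseline_lookback_days = 14,
                             cadence_max_gap_days = 42,
                             cadence_min_gap_days = NULL,
                             cadence_first_visit_max_day = 42,
                             cadence_last_visit_min_day = 323,
                             followup_days = 365,
                             surgery_washout_days = 60,
                             iop_threshold_mmHg = 25,
                             iop_min_readings = 2,
                             year1_window_days = 56,
                             ae_attribution_days = 42,
                             anti_vegf_drugs = c("bevacizumab", "ranibizumab",
                                                 "aflibercept",
                                                 "other_anti_vegf"),
                             study_drugs = c("bevacizumab", "ranibizumab")) {
  cfg <- as.list(environment())
  stopifnot(cfg$naive_lookback_days >= 0, cfg$dx_lookback_days >= 0,
            cfg$min_preindex_days >= 0, cfg$followup_days >= 0,
            cfg$surgery_washout_days >= 0,
            cfg$va_bounds[1] <= cfg$va_bounds[2],
            cfg$iop_min_readings >= 1)
  class(cfg) <- "criterion_config"
  cfg
}

eye_key <- function(patient_id, laterality) paste(patient_id, laterality)

# study-eye anti-VEGF injections, any drug
.eye_injections <- function(registry, patient_id, laterality, config) {
  inj <- registry$injections
  inj[inj$patient_id == patient_id & inj$laterality == laterality &
        inj$drug %in% config$anti_vegf_drugs, , drop = FALSE]
}

#' Index date: first anti-VEGF injection inside the enrollment window
#'
#' @param registry A registry object (see [load_registry()]).
#' @param patient_id,laterality Eye identifier.
#' @param window Length-2 Date vector (inclusive bounds).
#' @param config A [criterion_config()].
#' @return Date, or `NA` if the eye has no in-window anti-VEGF injection.
#' @export
find_index <- function(registry, patient_id, laterality, window,
                       config = criterion_config()) {
  inj <- .eye_injections(registry, patient_id, laterality, config)
  d <- inj$date[inj$date >= window[1] & inj$date <= window[2]]
  if (length(d) == 0) return(as_date(NA_real_))
  min(d)
}

#' Treatment-naive check
#'
#' TRUE iff the eye has no anti-VEGF injection in `[index - lookback,
#' index)`.
#'
#' @inheritParams find_index
#' @param index Index date.
#' @param lookback Days (default 365).
#' @export
is_treatment_naive <- function(registry, patient_id, laterality, index,
                               lookback = 365,
                               config = criterion_config()) {
  inj <- .eye_injections(registry, patient_id, laterality, config)
  !any(inj$date < index & inj$date >= index - lookback)
}

#' Single-agent regimen check
#'
#' @inheritParams is_treatment_naive
#' @param followup Follow-up horizon in days.
#' @return The unique study drug if every study-eye injection in
#'   `[index, index + followup]` is that one drug and it is bevacizumab or
#'   ranibizumab; `NA_character_` otherwise.
#' @export
meets_regimen <- function(registry, patient_id, laterality, index,
                          followup = 365, config = criterion_config()) {
  inj <- .eye_injections(registry, patient_id, laterality, config)
  drugs <- unique(inj$drug[inj$date >= index & inj$date <= index + followup])
  if (length(drugs) == 1 && drugs %in% config$study_drugs) drugs
  else NA_character_
}

retina_visit_days <- function(registry, patient_id, index, followup) {
  enc <- registry$encounters
  d <- enc$date[enc$patient_id == patient_id &
                  enc$provider_type == "retina" &
                  enc$date >= index & enc$date <= index + followup]
  sort(unique(as.numeric(d - index)))
}

#' Visit-cadence check: a retina encounter every 4-6 weeks for a year
#'
#' Enforced as: first retina visit within `cadence_first_visit_max_day` of
#' index, every consecutive gap at most `cadence_max_gap_days`, and the last
#' visit on/after day `cadence_last_visit_min_day`. Set
#' `cadence_min_gap_days = 28` in the config for the strict 4-week reading.
#'
#' @inheritParams is_treatment_naive
#' @export
meets_cadence <- function(registry, patient_id, index,
                          config = criterion_config()) {
  days <- retina_visit_days(registry, patient_id, index,
                            config$followup_days)
  if (length(days) == 0) return(FALSE)
  gaps <- diff(days)
  ok <- days[1] <= config$cadence_first_visit_max_day &&
    all(gaps <= config$cadence_max_gap_days) &&
    max(days) >= config$cadence_last_visit_min_day
  if (ok && !is.null(config$cadence_min_gap_days)) {
    ok <- all(gaps >= config$cadence_min_gap_days)
  }
  ok
}

#' prn marker: at least one retina visit day without a study-eye injection
#'
#' @inheritParams meets_regimen
#' @export
has_prn_marker <- function(registry, patient_id, laterality, index,
                           followup = 365, config = criterion_config()) {
  days <- retina_visit_days(registry, patient_id, index, followup)
  if (length(days) == 0) return(FALSE)
  inj <- .eye_injections(registry, patient_id, laterality, config)
  inj_days <- as.numeric(
    inj$date[inj$date >= index & inj$date <= index + followup] - index)
  length(setdiff(days, inj_days)) > 0
}

# diagnoses for one eye; laterality NA on a row means patient-level (both
# eyes)
.eye_dx <- function(registry, patient_id, laterality) {
  dx <- registry$diagnoses
  dx[dx$patient_id == patient_id &
       (is.na(dx$laterality) | dx$laterality == laterality), , drop = FALSE]
}

#' Exclusion criteria, in attrition-table order
#'
#' Dated ocular comorbidities (diabetic retinopathy / diabetic macular
#' edema, vitreous hemorrhage, subfoveal fibrosis / geographic atrophy,
#' CNV of other cause, other acuity-compromising disease) are looked up in
#' `(index - dx_lookback_days, index]`; "history of" rules (rhegmatogenous
#' retinal detachment / macular hole, pars plana vitrectomy, prior
#' PDT/anti-VEGF treatment) apply to any pre-index date. CNV of other cause
#' applies to either eye.
#'
#' @inheritParams is_treatment_naive
#' @return list with `pass` (logical) and `first_failed` (criterion key or
#'   `NA`), plus `flags`, a named logical vector over the exclusion keys
#'   (TRUE = passes).
#' @export
passes_exclusions <- function(registry, patient_id, laterality, index,
                              config = criterion_config()) {
  dx <- .eye_dx(registry, patient_id, laterality)
  dx_any <- registry$diagnoses[registry$diagnoses$patient_id == patient_id, ,
                               drop = FALSE]
  pr <- registry$procedures
  pr <- pr[pr$patient_id == patient_id & pr$laterality == laterality, ,
           drop = FALSE]
  iop <- registry$iop
  iop <- iop[iop$patient_id == patient_id & iop$laterality == laterality, ,
             drop = FALSE]
  inj <- .eye_injections(registry, patient_id, laterality, config)
  fellow <- if (laterality == "OD") "OS" else "OD"
  finj <- registry$injections
  finj <- finj[finj$patient_id == patient_id & finj$laterality == fellow &
                 finj$drug %in% config$anti_vegf_drugs, , drop = FALSE]

  in_lookback <- function(dates) {
    any(dates > index - config$dx_lookback_days & dates <= index)
  }
  dx_in_lookback <- function(cat) {
    in_lookback(dx$date[dx$code_category == cat])
  }
  surgery_cats <- c("cataract_surgery", "pars_plana_vitrectomy",
                    "other_intraocular_surgery")

  flags <- c(
    dr_dme = !dx_in_lookback("dr_dme"),
    vitreous_hemorrhage = !dx_in_lookback("vitreous_hemorrhage"),
    rrd_macular_hole = !any(dx$code_category == "rrd_macular_hole" &
                              dx$date <= index),
    ppv = !any(pr$category == "pars_plana_vitrectomy" & pr$date <= index),
    recent_surgery = !any(pr$category %in% surgery_cats &
                            pr$date > index - config$surgery_washout_days &
                            pr$date <= index),
    glaucoma = sum(iop$mmHg >= config$iop_threshold_mmHg &
                     iop$date > index - 365 & iop$date <= index) <
      config$iop_min_readings,
    prior_treatment = !(any(inj$date < index) |
                          any(pr$category == "pdt" & pr$date <= index)),
    fibrosis_ga = !dx_in_lookback("subfoveal_fibrosis_ga"),
    cnv_other = !in_lookback(
      dx_any$date[dx_any$code_category == "cnv_other_cause"]),
    other_va_compromise = !dx_in_lookback("other_va_compromising"),
    fellow_eye_antivegf = !any(finj$date >= index &
                                 finj$date <= index + config$followup_days)
  )
  first_failed <- if (all(flags)) NA_character_ else names(flags)[!flags][1]
  list(pass = all(flags), first_failed = first_failed, flags = flags)
}

#' Study-eye selection when both eyes qualify
#'
#' The eye with the earlier index date is kept; a same-day tie goes to the
#' right eye (OD), a documented convention.
#'
#' @param eyes data.frame with columns `laterality` and `index_date`
#'   (one patient's candidate eyes).
#' @return The selected row.
#' @export
select_study_eye <- function(eyes) {
  stopifnot(nrow(eyes) >= 1)
  ord <- order(eyes$index_date, match(eyes$laterality, c("OD", "OS")))
  eyes[ord[1], , drop = FALSE]
}

# one small registry per patient; every rule only reads one patient's rows
split_registry_by_patient <- function(registry) {
  tabs <- c("encounters", "injections", "diagnoses", "procedures", "va",
            "iop")
  ids <- registry$patients$patient_id
  parts <- lapply(tabs, function(tb) {
    df <- registry[[tb]]
    split(df, factor(df$patient_id, levels = ids))
  })
  names(parts) <- tabs
  out <- lapply(seq_along(ids), function(k) {
    sub <- lapply(parts, function(pp) pp[[k]])
    sub$patients <- registry$patients
    sub
  })
  names(out) <- ids
  out
}

patient_first_event_date <- function(registry, patient_id) {
  dates <- c(
    registry$encounters$date[registry$encounters$patient_id == patient_id],
    registry$injections$date[registry$injections$patient_id == patient_id],
    registry$diagnoses$date[registry$diagnoses$patient_id == patient_id],
    registry$procedures$date[registry$procedures$patient_id == patient_id],
    registry$va$date[registry$va$patient_id == patient_id],
    registry$iop$date[registry$iop$patient_id == patient_id]
  )
  if (length(dates) == 0) as_date(NA_real_) else min(dates)
}

# best-documented baseline measurement (row of va table) on the baseline day
baseline_va_event <- function(registry, patient_id, laterality, index,
                              config) {
  va <- registry$va
  va <- va[va$patient_id == patient_id & va$laterality == laterality, ,
           drop = FALSE]
  day <- if (any(va$date == index)) {
    index
  } else {
    prior <- va$date[va$date < index &
                       va$date >= index - config$baseline_lookback_days]
    if (length(prior) == 0) return(NULL)
    max(prior)
  }
  rows <- va[va$date == day, , drop = FALSE]
  letters <- snellen_to_letters(rows$snellen_num, rows$snellen_den)
  rows[which.max(letters), , drop = FALSE]
}

#' Run the full attrition cascade
#'
#' Evaluates every criterion for every candidate eye (an eye with at least
#' one in-window study-drug injection), then applies them cumulatively in
#' table order. Study-eye deduplication (one eye per patient, earlier index
#' wins) is folded into the fellow-eye exclusion row. Baseline and one-year
#' letter scores are attached to the surviving eyes via the acuity module.
#'
#' @param registry A registry object.
#' @param config A [criterion_config()].
#' @param window Enrollment window (defaults to the registry's injection
#'   date range).
#' @return List with `cohorts` (data.frame of eligible eyes: `patient_id`,
#'   `laterality`, `index_date`, `drug`, `age_at_index`, `gender`,
#'   `baseline_letters`, `year1_letters`, `n_injections_year1`,
#'   `endophthalmitis`), `attrition` (data.frame: `criterion`, `label`,
#'   `patients`, `eyes`, `pct_eyes`), and `verdicts` (per candidate eye,
#'   one logical `pass_*` column per criterion).
#' @export
run_attrition <- function(registry, config = criterion_config(),
                          window = NULL) {
  validate_registry(registry)
  inj <- registry$injections
  if (is.null(window)) {
    sd_inj <- inj[inj$drug %in% config$study_drugs, , drop = FALSE]
    window <- c(min(sd_inj$date), max(sd_inj$date))
  }
  cand <- unique(inj[inj$drug %in% config$study_drugs &
                       inj$date >= window[1] & inj$date <= window[2],
                     c("patient_id", "laterality")])
  rownames(cand) <- NULL
  n0 <- nrow(cand)
  if (n0 == 0) stop("no candidate eyes in the enrollment window",
                    call. = FALSE)
  crits <- attrition_criteria()
  pats <- registry$patients
  pat_row <- match(cand$patient_id, pats$patient_id)

  # per-patient sub-registries: every eligibility rule is patient-local, so
  # scanning the full event tables once per eye would be quadratic
  subregistries <- split_registry_by_patient(registry)

  verdict <- matrix(NA, nrow = n0, ncol = length(crits),
                    dimnames = list(NULL, crits))
  index_date <- as_date(rep(NA_real_, n0))
  drug <- character(n0)
  age <- integer(n0)
  baseline <- integer(n0)
  year1 <- integer(n0)
  n_inj <- integer(n0)
  endo <- logical(n0)

  for (i in seq_len(n0)) {
    pid <- cand$patient_id[i]; latr <- cand$laterality[i]
    reg_p <- subregistries[[pid]]
    idx <- find_index(reg_p, pid, latr, window, config)
    index_date[i] <- idx

    dxe <- .eye_dx(reg_p, pid, latr)
    verdict[i, "namd_dx"] <- any(
      dxe$code_category == "namd" &
        dxe$date > idx - config$dx_lookback_days & dxe$date <= idx)

    first_ev <- patient_first_event_date(reg_p, pid)
    a <- pats$age_at_first_record[pat_row[i]] +
      floor(as.numeric(idx - first_ev) / 365.25)
    age[i] <- as.integer(min(a, 90))  # deidentification top-code
    verdict[i, "age_min"] <- age[i] >= config$min_age

    verdict[i, "naive"] <- is_treatment_naive(
      reg_p, pid, latr, idx, config$naive_lookback_days, config)
    verdict[i, "preindex_history"] <-
      as.numeric(idx - first_ev) >= config$min_preindex_days

    bev <- baseline_va_event(reg_p, pid, latr, idx, config)
    if (is.null(bev)) {
      verdict[i, "va_range"] <- FALSE
      baseline[i] <- NA_integer_
    } else {
      frac <- bev$snellen_num / bev$snellen_den
      verdict[i, "va_range"] <- frac >= config$va_bounds[1] - 1e-12 &
        frac <= config$va_bounds[2] + 1e-12
      baseline[i] <- snellen_to_letters(bev$snellen_num, bev$snellen_den)
    }

    verdict[i, "cadence"] <- meets_cadence(reg_p, pid, idx, config)
    dr <- meets_regimen(reg_p, pid, latr, idx, config$followup_days,
                        config)
    verdict[i, "regimen"] <- !is.na(dr)
    drug[i] <- if (is.na(dr)) NA_character_ else dr

    ex <- passes_exclusions(reg_p, pid, latr, idx, config)
    verdict[i, names(ex$flags)] <- ex$flags
    verdict[i, "prn_marker"] <- has_prn_marker(
      reg_p, pid, latr, idx, config$followup_days, config)

    year1[i] <- select_year1_va(reg_p$va, pid, latr, idx,
                                target_offset = config$followup_days,
                                window_days = config$year1_window_days)
    eyeinj <- .eye_injections(reg_p, pid, latr, config)
    fu_inj <- eyeinj$date[eyeinj$date >= idx &
                            eyeinj$date <= idx + config$followup_days]
    n_inj[i] <- length(fu_inj)
    endo_dx <- dxe[dxe$code_category == "endophthalmitis", , drop = FALSE]
    endo[i] <- any(vapply(fu_inj, function(d) {
      any(endo_dx$date > d & endo_dx$date <= d + config$ae_attribution_days)
    }, logical(1)))
  }

  # cumulative cascade in table order
  alive <- rep(TRUE, n0)
  rows <- list(data.frame(criterion = "initial",
                          label = attrition_labels()["initial"],
                          patients = length(unique(cand$patient_id)),
                          eyes = n0, stringsAsFactors = FALSE))
  for (cr in crits) {
    alive <- alive & verdict[, cr]
    if (cr == "fellow_eye_antivegf") {
      # one study eye per patient: earlier index date, OD on ties
      keep <- rep(FALSE, n0)
      for (pid in unique(cand$patient_id[alive])) {
        sel <- which(alive & cand$patient_id == pid)
        sub <- data.frame(i = sel, laterality = cand$laterality[sel],
                          index_date = index_date[sel])
        keep[select_study_eye(sub)$i] <- TRUE
      }
      alive <- keep
    }
    rows[[length(rows) + 1]] <- data.frame(
      criterion = cr, label = attrition_labels()[cr],
      patients = length(unique(cand$patient_id[alive])),
      eyes = sum(alive), stringsAsFactors = FALSE)
  }
  attrition <- do.call(rbind, rows)
  attrition$pct_eyes <- round(100 * attrition$eyes / n0, 1)
  rownames(attrition) <- NULL

  cohorts <- data.frame(
    patient_id = cand$patient_id[alive],
    laterality = cand$laterality[alive],
    index_date = index_date[alive],
    drug = drug[alive],
    age_at_index = age[alive],
    gender = pats$gender[pat_row[alive]],
    baseline_letters = baseline[alive],
    year1_letters = year1[alive],
    n_injections_year1 = n_inj[alive],
    endophthalmitis = endo[alive],
    stringsAsFactors = FALSE
  )
  rownames(cohorts) <- NULL
  verdicts <- cbind(cand,
                    as.data.frame(verdict) |>
                      setNames(paste0("pass_", crits)))
  list(cohorts = cohorts, attrition = attrition, verdicts = verdicts)
}

attrition_labels <- function() {
  c(initial = "Injection of bevacizumab or ranibizumab in study window",
    namd_dx = "Documentation of nAMD within 1 year preindex",
    age_min = "Age of >=50 years at the time of index injection",
    naive = "No anti-VEGF injections received up to 365 days preindex",
    preindex_history = ">=1 year of preindex data",
    va_range = "Visual acuity between 20/25 and 20/320 in the study eye",
    cadence = "Visit every 4-6 weeks for 365 days by a retina specialist",
    regimen = "Treatment with only bevacizumab or ranibizumab for 365 days",
    dr_dme = "Diabetic retinopathy or diabetic macular edema, study eye",
    vitreous_hemorrhage = "Vitreous hemorrhage in the study eye",
    rrd_macular_hole =
      "History of rhegmatogenous retinal detachment or macular hole",
    ppv = "History of pars plana vitrectomy in the study eye",
    recent_surgery = "Intraocular surgery in the study eye within 2 months",
    glaucoma = "Uncontrolled glaucoma in the study eye (IOP >=25 mmHg x2)",
    prior_treatment = "Previous PDT or anti-VEGF treatment in the study eye",
    fibrosis_ga = "Subfoveal fibrosis or geographic atrophy, study eye",
    cnv_other = "CNV in either eye due to other causes",
    other_va_compromise = "Other ocular disease compromising acuity",
    fellow_eye_antivegf =
      "Anti-VEGF treatment in the fellow eye during follow-up",
    prn_marker = ">=1 retina specialist visit without an anti-VEGF injection")
}
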