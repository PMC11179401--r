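#' Synthetic registry and trial-roster generation
#'
#' The generator produces a longitudinal ophthalmology registry (seven event
#' tables keyed by patient/eye) plus a monthly-dosed trial roster with the
#' statistical structure the emulation pipeline assumes: elderly nAMD
#' patients (age ~81, top-coded at 90), ~63% female, chart-valued Snellen
#' acuities with baseline ~60 letters (SD 13) inside 20/25-20/320, per-arm
#' one-year acuity-change distributions, as-needed (prn) injection schedules
#' riding on a 4-6 week retina visit cadence, and configurable fractions of
#' eyes seeded to violate each eligibility criterion. A ground-truth
#' manifest records, per eye, the seeded violation and per-criterion pass
#' flags so the attrition engine can be audited record-for-record.
#'
#' @name synthetic_data
NULL

#' Canonical eligibility criterion keys, in attrition order
#'
#' One key per attrition row after the initial cohort row. The generator's
#' `violation_fractions` and the attrition engine share this vocabulary.
#'
#' @return Character vector of criterion keys.
#' @export
attrition_criteria <- function() {
  c("namd_dx", "age_min", "naive", "preindex_history", "va_range",
    "cadence", "regimen", "dr_dme", "vitreous_hemorrhage",
    "rrd_macular_hole", "ppv", "recent_surgery", "glaucoma",
    "prior_treatment", "fibrosis_ga", "cnv_other", "other_va_compromise",
    "fellow_eye_antivegf", "prn_marker")
}

#' Simulation configuration
#'
#' Defaults emulate the marginals of the real-world cohorts: index dates in
#' October 2015 - December 2019, age mean 81 (SD 8, truncated at 50,
#' top-coded at 90), 63% female, baseline acuity 60 +/- 13 letters restricted
#' to chart lines in 20/25-20/320, arm split ~64/36
#' bevacizumab/ranibizumab, one-year letter change +2.1 +/- 16 (bevacizumab)
#' and +2.8 +/- 15 (ranibizumab), injection counts near 7.7 and 9.0, and
#' retina visits every 28-42 days.
#'
#' @param n_patients Number of patients (one study eye each).
#' @param date_start,date_end Index-date window (ISO dates).
#' @param age_mean,age_sd Age at index, truncated to `[50, 97]` then
#'   top-coded at 90 (deidentification convention).
#' @param female_fraction Probability of gender "F".
#' @param race_probs Named probabilities over `white`, `other`, `unknown`.
#' @param baseline_letters_mean,baseline_letters_sd Baseline acuity before
#'   quantization to the chart, truncated to `[25, 80]` letters.
#' @param age_va_correlation Latent normal correlation between age and
#'   baseline letters (default 0, i.e. independent).
#' @param arm_probs Named probabilities over `bevacizumab`, `ranibizumab`.
#' @param va_change_mean,va_change_sd Named per-arm one-year letter change.
#' @param injection_count_mean,injection_count_sd Named per-arm injection
#'   counts, capped so at least one visit carries no injection.
#' @param visit_gap_days Integer range (length 2) of days between retina
#'   visits.
#' @param history_days_range Days of pre-index record history.
#' @param violation_fractions Named fractions (keys from
#'   [attrition_criteria()]) of eyes seeded to fail that criterion; must sum
#'   to at most 1. Unnamed criteria default to 0.
#' @param endophthalmitis_rate Per-eye probability of post-injection
#'   endophthalmitis in the registry.
#' @param chart Measurement chart for follow-up acuities (default
#'   [extended_chart()], which carries better-than-20/20 lines so gains are
#'   not ceiling-censored).
#' @param seed Master seed; all randomness flows from it through named
#'   substreams.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1200,
                       date_start = "2015-10-01",
                       date_end = "2019-12-31",
                       age_mean = 81, age_sd = 8,
                       female_fraction = 0.63,
                       race_probs = c(white = 0.905, other = 0.030,
                                      unknown = 0.065),
                       baseline_letters_mean = 60,
                       baseline_letters_sd = 13,
                       age_va_correlation = 0,
                       arm_probs = c(bevacizumab = 0.64,
                                     ranibizumab = 0.36),
                       va_change_mean = c(bevacizumab = 2.1,
                                          ranibizumab = 2.8),
                       va_change_sd = c(bevacizumab = 16,
                                        ranibizumab = 15),
                       injection_count_mean = c(bevacizumab = 7.7,
                                                ranibizumab = 9.0),
                       injection_count_sd = c(bevacizumab = 3.6,
                                              ranibizumab = 3.4),
                       visit_gap_days = c(28L, 42L),
                       history_days_range = c(400L, 1500L),
                       violation_fractions = default_violation_fractions(),
                       endophthalmitis_rate = 0.001,
                       chart = extended_chart(),
                       seed = 1L) {
  vf <- setNames(rep(0, length(attrition_criteria())), attrition_criteria())
  if (length(violation_fractions)) {
    bad <- setdiff(names(violation_fractions), names(vf))
    if (length(bad)) {
      stop("unknown violation criteria: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    vf[names(violation_fractions)] <- violation_fractions
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    date_start = as.Date(date_start), date_end = as.Date(date_end),
    age_mean = age_mean, age_sd = age_sd,
    female_fraction = female_fraction, race_probs = race_probs,
    baseline_letters_mean = baseline_letters_mean,
    baseline_letters_sd = baseline_letters_sd,
    age_va_correlation = age_va_correlation,
    arm_probs = arm_probs,
    va_change_mean = va_change_mean, va_change_sd = va_change_sd,
    injection_count_mean = injection_count_mean,
    injection_count_sd = injection_count_sd,
    visit_gap_days = as.integer(visit_gap_days),
    history_days_range = as.integer(history_days_range),
    violation_fractions = vf,
    endophthalmitis_rate = endophthalmitis_rate,
    chart = chart,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default seeded-violation mix: 2% of eyes per criterion
#' @return Named numeric vector over [attrition_criteria()].
#' @export
default_violation_fractions <- function() {
  setNames(rep(0.02, length(attrition_criteria())), attrition_criteria())
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients > 0,
            cfg$date_start < cfg$date_end,
            cfg$age_sd > 0, cfg$baseline_letters_sd > 0,
            cfg$female_fraction >= 0, cfg$female_fraction <= 1,
            abs(sum(cfg$race_probs) - 1) < 1e-8,
            abs(sum(cfg$arm_probs) - 1) < 1e-8,
            all(cfg$visit_gap_days >= 1),
            cfg$visit_gap_days[1] <= cfg$visit_gap_days[2],
            all(cfg$violation_fractions >= 0),
            all(cfg$violation_fractions <= 1),
            cfg$endophthalmitis_rate >= 0, cfg$endophthalmitis_rate <= 1,
            abs(cfg$age_va_correlation) <= 1)
  if (sum(cfg$violation_fractions) > 1) {
    stop("violation_fractions sum to more than 1; no eligible eye can exist",
         call. = FALSE)
  }
  invisible(cfg)
}

# Chart lines whose Snellen fraction lies in the eligibility range
# [20/320, 20/25]; baseline acuities are drawn on these lines.
eligible_chart_lines <- function(chart) {
  frac <- chart$snellen_num / chart$snellen_den
  chart[frac >= 20 / 320 - 1e-12 & frac <= 20 / 25 + 1e-12, , drop = FALSE]
}

#' Generate a synthetic registry with ground truth
#'
#' Eyes are eligible by construction; a configurable fraction per criterion
#' is then minimally mutated so that it fails exactly that criterion (the
#' sole exception: a seeded pre-index injection inside the naive lookback
#' necessarily also constitutes prior anti-VEGF treatment, and the ground
#' truth records both failures). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `registry` (class `registry`: data.frames `patients`,
#'   `encounters`, `injections`, `diagnoses`, `procedures`, `va`, `iop`) and
#'   `ground_truth` (one row per eye with seeded violation, per-criterion
#'   pass flags, true baseline/year-1 letters, injection count).
#' @export
generate_registry <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- config$n_patients
  crits <- attrition_criteria()

  ids <- make_ids("pt", n)
  gender <- with_substream(config$seed, "gender", {
    ifelse(runif(n) < config$female_fraction, "F", "M")
  })
  race <- with_substream(config$seed, "race", {
    sample(names(config$race_probs), n, replace = TRUE,
           prob = config$race_probs)
  })
  lat <- with_substream(config$seed, "laterality", {
    sample(c("OD", "OS"), n, replace = TRUE)
  })
  arm <- with_substream(config$seed, "arm", {
    sample(names(config$arm_probs), n, replace = TRUE,
           prob = config$arm_probs)
  })
  viol <- with_substream(config$seed, "violation", {
    p <- config$violation_fractions
    sample(c(names(p), "none"), n, replace = TRUE,
           prob = c(p, 1 - sum(p)))
  })
  # Latent bivariate normal for (age, baseline letters); joint rejection
  # keeps both truncations renormalized rather than piling mass at bounds.
  agava <- with_substream(config$seed, "age_va", {
    rho <- config$age_va_correlation
    age <- numeric(n); va <- numeric(n)
    need <- seq_len(n)
    while (length(need) > 0) {
      z1 <- rnorm(length(need)); z2 <- rnorm(length(need))
      a <- config$age_mean + config$age_sd * z1
      v <- config$baseline_letters_mean +
        config$baseline_letters_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
      ok <- a >= 50 & a <= 97 & v >= 25 & v <= 80
      age[need[ok]] <- a[ok]; va[need[ok]] <- v[ok]
      need <- need[!ok]
    }
    list(age = pmin(floor(age), 90), va = va)
  })
  age_at_index <- agava$age
  age_at_index[viol == "age_min"] <- with_substream(config$seed, "age_viol", {
    k <- sum(viol == "age_min")
    sample(35:49, k, replace = TRUE)
  })

  window_days <- as.integer(config$date_end - config$date_start)
  index_off <- with_substream(config$seed, "index_date", {
    off <- sample.int(window_days + 1L, n, replace = TRUE) - 1L
    # non-naive seeding needs the prior injection to fall before the
    # window start while staying inside the 365-day lookback
    off[viol == "naive"] <- sample.int(180L, sum(viol == "naive"),
                                       replace = TRUE)
    off
  })
  index_date <- config$date_start + index_off
  history_days <- with_substream(config$seed, "history", {
    h <- sample(seq(config$history_days_range[1],
                    config$history_days_range[2]), n, replace = TRUE)
    h[viol == "preindex_history"] <- 100L
    h
  })

  elig_lines <- eligible_chart_lines(config$chart)
  base_line_idx <- vapply(agava$va, function(v) {
    d <- abs(elig_lines$letters - v)
    cand <- which(d == min(d))
    cand[which.max(elig_lines$letters[cand])]
  }, integer(1))
  baseline_letters <- elig_lines$letters[base_line_idx]
  baseline_den <- elig_lines$snellen_den[base_line_idx]
  # out-of-range seeding: baseline measured at 20/20 (85 letters)
  baseline_letters[viol == "va_range"] <- 85L
  baseline_den[viol == "va_range"] <- 20

  change <- with_substream(config$seed, "va_change", {
    rnorm(n, config$va_change_mean[arm], config$va_change_sd[arm])
  })
  inj_target <- with_substream(config$seed, "inj_count", {
    round(rnorm(n, config$injection_count_mean[arm],
                config$injection_count_sd[arm]))
  })
  endo <- with_substream(config$seed, "endophthalmitis", {
    runif(n) < config$endophthalmitis_rate
  })

  # per-eye event assembly (substreamed so field additions do not reshuffle)
  eye_seed <- substream_seed(config$seed, "eyes")
  acc <- list(encounters = list(), injections = list(), diagnoses = list(),
              procedures = list(), va = list(), iop = list())
  gt_rows <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed((eye_seed + i * 7919L) %% 2147483647L)
    e <- build_eye_events(
      id = ids[i], lat = lat[i], index = index_date[i],
      drug = arm[i], viol = viol[i],
      baseline_letters = baseline_letters[i], baseline_den = baseline_den[i],
      change = change[i], inj_target = inj_target[i],
      history_days = history_days[i], endo = endo[i],
      config = config
    )
    for (tb in names(acc)) acc[[tb]][[i]] <- e[[tb]]
    pass <- setNames(rep(TRUE, length(crits)), crits)
    if (viol[i] != "none") pass[viol[i]] <- FALSE
    if (viol[i] == "naive") pass["prior_treatment"] <- FALSE
    gt_rows[[i]] <- data.frame(
      patient_id = ids[i], laterality = lat[i],
      arm = arm[i], seeded_violation = viol[i],
      eligible = viol[i] == "none",
      true_baseline_letters = e$true_baseline,
      true_year1_letters = e$true_year1,
      true_change = e$true_year1 - e$true_baseline,
      n_injections = e$n_injections,
      endophthalmitis = e$endophthalmitis,
      as.list(pass) |> setNames(paste0("pass_", crits)),
      stringsAsFactors = FALSE
    )
  }

  empty_tables <- list(
    encounters = data.frame(patient_id = character(), date = as_date(numeric()),
                            provider_type = character()),
    injections = data.frame(patient_id = character(), laterality = character(),
                            date = as_date(numeric()), drug = character()),
    diagnoses = data.frame(patient_id = character(), laterality = character(),
                           date = as_date(numeric()),
                           code_category = character()),
    procedures = data.frame(patient_id = character(), laterality = character(),
                            date = as_date(numeric()), category = character()),
    va = data.frame(patient_id = character(), laterality = character(),
                    date = as_date(numeric()), snellen_num = numeric(),
                    snellen_den = numeric()),
    iop = data.frame(patient_id = character(), laterality = character(),
                     date = as_date(numeric()), mmHg = numeric())
  )
  bind <- function(lst) {
    do.call(rbind, lst[!vapply(lst, is.null, logical(1))])
  }
  patients <- data.frame(
    patient_id = ids,
    age_at_first_record = as.integer(
      age_at_index - floor(history_days / 365.25)),
    gender = gender, race = race, stringsAsFactors = FALSE
  )
  tables <- lapply(names(empty_tables), function(tb) {
    bind(acc[[tb]]) %||% empty_tables[[tb]]
  })
  names(tables) <- names(empty_tables)
  registry <- structure(c(list(patients = patients), tables),
                        class = "registry")
  for (tb in c("encounters", "injections", "diagnoses", "procedures",
               "va", "iop")) {
    rownames(registry[[tb]]) <- NULL
  }
  list(registry = registry, ground_truth = do.call(rbind, gt_rows))
}

# One eye's event records. Events are first laid out eligible-by-
# construction, then the seeded violation is injected as a minimal edit.
build_eye_events <- function(id, lat, index, drug, viol, baseline_letters,
                             baseline_den, change, inj_target, history_days,
                             endo, config) {
  fellow <- if (lat == "OD") "OS" else "OD"
  gaps <- sample(seq(config$visit_gap_days[1], config$visit_gap_days[2]),
                 20, replace = TRUE)
  days <- c(0L, cumsum(gaps))
  days <- days[days <= 365L]

  n_inj <- max(1L, min(length(days) - 1L, inj_target))
  inj_days <- c(0L, sort(sample(days[-1], n_inj - 1L)))
  inj_drug <- rep(drug, n_inj)

  if (viol == "regimen") {
    k <- max(2L, ceiling(n_inj / 2))
    if (n_inj == 1L) { # need a second, off-protocol injection
      inj_days <- c(inj_days, days[2]); inj_drug <- c(inj_drug, drug)
      n_inj <- 2L; k <- 2L
    }
    inj_drug[k] <- "aflibercept"
  }
  if (viol == "prn_marker") {
    inj_days <- days
    inj_drug <- rep(drug, length(days))
    n_inj <- length(days)
  }
  if (viol == "cadence") {
    drop <- days > 140L & days < 235L  # leaves a >42-day gap mid-year
    days <- days[!drop]
    keep <- inj_days %in% days
    inj_days <- inj_days[keep]; inj_drug <- inj_drug[keep]
    n_inj <- length(inj_days)
    if (all(days %in% inj_days) && n_inj > 1L) { # keep the prn marker
      inj_drug <- inj_drug[-n_inj]; inj_days <- inj_days[-n_inj]
      n_inj <- n_inj - 1L
    }
  }

  # acuity trajectory: chart-valued at every visit; the final visit is the
  # noiseless chart rendering of baseline + change
  true_year1 <- letters_to_nearest_snellen(
    max(0, min(100, baseline_letters + change)), config$chart)$letters
  va_days <- days
  va_num <- numeric(length(va_days)); va_den <- numeric(length(va_days))
  for (j in seq_along(va_days)) {
    d <- va_days[j]
    if (d == 0L) {
      va_num[j] <- 20; va_den[j] <- baseline_den
    } else if (d == max(days)) {
      line <- letters_to_nearest_snellen(true_year1, config$chart)
      va_num[j] <- line$snellen_num; va_den[j] <- line$snellen_den
    } else {
      tgt <- baseline_letters + change * d / 365 + rnorm(1, 0, 3)
      line <- letters_to_nearest_snellen(max(0, min(100, tgt)), config$chart)
      va_num[j] <- line$snellen_num; va_den[j] <- line$snellen_den
    }
  }

  enc <- data.frame(
    patient_id = id,
    date = c(index - history_days, index + days),
    provider_type = c("general_ophthalmology", rep("retina", length(days))),
    stringsAsFactors = FALSE
  )
  inj <- data.frame(
    patient_id = id, laterality = lat, date = index + inj_days,
    drug = inj_drug, stringsAsFactors = FALSE
  )
  dx <- data.frame(
    patient_id = id, laterality = lat,
    date = index - sample(0:300, 1), code_category = "namd",
    stringsAsFactors = FALSE
  )
  proc <- NULL
  iop_n <- sample(1:2, 1)
  iop <- data.frame(
    patient_id = id, laterality = lat,
    date = index - sample(30:300, iop_n),
    mmHg = round(rnorm_trunc(iop_n, 16, 3, upper = 24)),
    stringsAsFactors = FALSE
  )

  add_dx <- function(cat, offset) {
    rbind(dx, data.frame(patient_id = id, laterality = lat,
                         date = index - offset, code_category = cat,
                         stringsAsFactors = FALSE))
  }
  if (viol == "namd_dx") dx$date <- index - sample(400:900, 1)
  if (viol == "dr_dme") dx <- add_dx("dr_dme", sample(0:300, 1))
  if (viol == "vitreous_hemorrhage")
    dx <- add_dx("vitreous_hemorrhage", sample(0:300, 1))
  if (viol == "rrd_macular_hole")
    dx <- add_dx("rrd_macular_hole", sample(100:800, 1))
  if (viol == "fibrosis_ga")
    dx <- add_dx("subfoveal_fibrosis_ga", sample(0:300, 1))
  if (viol == "cnv_other")
    dx <- add_dx("cnv_other_cause", sample(0:300, 1))
  if (viol == "other_va_compromise")
    dx <- add_dx("other_va_compromising", sample(0:300, 1))
  if (viol == "ppv") {
    proc <- data.frame(patient_id = id, laterality = lat,
                       date = index - sample(100:800, 1),
                       category = "pars_plana_vitrectomy",
                       stringsAsFactors = FALSE)
  }
  if (viol == "recent_surgery") {
    proc <- data.frame(patient_id = id, laterality = lat,
                       date = index - sample(1:59, 1),
                       category = "cataract_surgery",
                       stringsAsFactors = FALSE)
  }
  if (viol == "prior_treatment") {
    proc <- data.frame(patient_id = id, laterality = lat,
                       date = index - sample(400:900, 1),
                       category = "pdt", stringsAsFactors = FALSE)
  }
  if (viol == "glaucoma") {
    iop <- rbind(iop, data.frame(
      patient_id = id, laterality = lat,
      date = index - sample(30:300, 2), mmHg = sample(25:32, 2,
                                                      replace = TRUE),
      stringsAsFactors = FALSE))
  }
  if (viol == "naive") {
    prior_date <- config$date_start - sample(30:180, 1)
    stopifnot(index - prior_date <= 365)
    inj <- rbind(data.frame(patient_id = id, laterality = lat,
                            date = prior_date, drug = drug,
                            stringsAsFactors = FALSE), inj)
    enc <- rbind(enc, data.frame(patient_id = id, date = prior_date,
                                 provider_type = "retina",
                                 stringsAsFactors = FALSE))
  }
  if (viol == "fellow_eye_antivegf") {
    inj <- rbind(inj, data.frame(patient_id = id, laterality = fellow,
                                 date = index + sample(30:300, 1),
                                 drug = drug, stringsAsFactors = FALSE))
  }
  endo_flag <- FALSE
  if (endo && viol %in% c("none")) {
    post_inj <- inj$date[inj$laterality == lat & inj$date >= index]
    hit <- sample(post_inj, 1)
    dx <- rbind(dx, data.frame(patient_id = id, laterality = lat,
                               date = hit + sample(3:20, 1),
                               code_category = "endophthalmitis",
                               stringsAsFactors = FALSE))
    endo_flag <- TRUE
  }

  n_study_inj <- sum(inj$laterality == lat & inj$date >= index &
                       inj$date <= index + 365)
  list(encounters = enc, injections = inj, diagnoses = dx,
       procedures = proc,
       va = data.frame(patient_id = id, laterality = lat,
                       date = index + va_days, snellen_num = va_num,
                       snellen_den = va_den, stringsAsFactors = FALSE),
       iop = iop,
       true_baseline = baseline_letters, true_year1 = true_year1,
       n_injections = n_study_inj, endophthalmitis = endo_flag)
}

#' Generate a synthetic monthly trial arm roster
#'
#' Covariates and outcomes are drawn to match configured marginals; the
#' built-in defaults reflect the published monthly arms (n = 301
#' ranibizumab, n = 286 bevacizumab; age ~79.2/79.9, 60.8%/62.9% female,
#' baseline 60.1 letters, one-year gain ~8.5/8.0 letters, ~11.7/11.9
#' injections).
#'
#' @param arm_name Label, e.g. `"ranibizumab_monthly"`.
#' @param n Number of participants (> 0).
#' @param covariates List overriding `age_mean`, `age_sd`, `female_fraction`,
#'   `baseline_letters_mean`, `baseline_letters_sd`, `baseline_range`.
#' @param outcomes List overriding `va_change_mean`, `va_change_sd`,
#'   `injection_mean`, `injection_sd`, `endophthalmitis_rate`.
#' @param seed Integer seed.
#' @return data.frame with one row per participant: `participant_id`, `arm`,
#'   `age`, `gender`, `baseline_letters`, `year1_letters`, `n_injections`,
#'   `endophthalmitis`.
#' @export
generate_trial_arm <- function(arm_name, n,
                               covariates = list(), outcomes = list(),
                               seed = 1L) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  def <- trial_arm_defaults(arm_name)
  cv <- utils::modifyList(def$covariates, covariates)
  oc <- utils::modifyList(def$outcomes, outcomes)
  prefix <- paste0("trial_", arm_name, "_")
  age <- with_substream(seed, paste0(prefix, "age"), {
    pmin(floor(rnorm_trunc(n, cv$age_mean, cv$age_sd, 50, 97)), 90)
  })
  gender <- with_substream(seed, paste0(prefix, "gender"), {
    ifelse(runif(n) < cv$female_fraction, "F", "M")
  })
  baseline <- with_substream(seed, paste0(prefix, "baseline"), {
    as.integer(round(rnorm_trunc(n, cv$baseline_letters_mean,
                                 cv$baseline_letters_sd,
                                 cv$baseline_range[1],
                                 cv$baseline_range[2])))
  })
  change <- with_substream(seed, paste0(prefix, "change"), {
    round(rnorm(n, oc$va_change_mean, oc$va_change_sd))
  })
  n_inj <- with_substream(seed, paste0(prefix, "inj"), {
    as.integer(pmax(1, round(rnorm(n, oc$injection_mean, oc$injection_sd))))
  })
  endo <- with_substream(seed, paste0(prefix, "endo"), {
    runif(n) < oc$endophthalmitis_rate
  })
  data.frame(
    participant_id = make_ids(paste0(substr(arm_name, 1, 3), "_"), n),
    arm = arm_name, age = as.integer(age), gender = gender,
    baseline_letters = baseline,
    year1_letters = as.integer(pmax(0, pmin(100, baseline + change))),
    n_injections = n_inj, endophthalmitis = endo,
    stringsAsFactors = FALSE
  )
}

# Published monthly-arm marginals used as generator defaults.
trial_arm_defaults <- function(arm_name) {
  drug <- if (grepl("ranibizumab", arm_name)) "ranibizumab" else "bevacizumab"
  if (drug == "ranibizumab") {
    list(covariates = list(age_mean = 79.16, age_sd = 7.24,
                           female_fraction = 0.608,
                           baseline_letters_mean = 60.11,
                           baseline_letters_sd = 14.26,
                           baseline_range = c(23, 82)),
         outcomes = list(va_change_mean = 8.5, va_change_sd = 14.1,
                         injection_mean = 11.7, injection_sd = 1.5,
                         endophthalmitis_rate = 2 / 284))
  } else {
    list(covariates = list(age_mean = 79.90, age_sd = 6.99,
                           female_fraction = 0.629,
                           baseline_letters_mean = 60.16,
                           baseline_letters_sd = 13.12,
                           baseline_range = c(23, 82)),
         outcomes = list(va_change_mean = 8.0, va_change_sd = 15.8,
                         injection_mean = 11.9, injection_sd = 1.2,
                         endophthalmitis_rate = 4 / 265))
  }
}
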