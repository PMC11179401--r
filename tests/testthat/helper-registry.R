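# Hand-built toy registry: five eyes, all on a 35-day visit schedule with
# injections at the first k visits, an nAMD diagnosis 30 days pre-index,
# 400 days of pre-index history, and acuity 20/40 at every visit. Scenario
# mutations (non-naive, broken cadence, fellow-eye treatment) are applied
# on top. The enrollment window is 2017-01-01 .. 2018-12-31.

toy_window <- function() as.Date(c("2017-01-01", "2018-12-31"))

toy_eye <- function(id, lat = "OD", index = as.Date("2017-02-01"),
                    drug = "bevacizumab", n_inj = 8, age = 75) {
  days <- seq(0, 350, by = 35)
  inj_days <- days[seq_len(n_inj)]
  list(
    patient = data.frame(patient_id = id,
                         age_at_first_record = age - 1, gender = "F",
                         race = "white", stringsAsFactors = FALSE),
    encounters = data.frame(
      patient_id = id, date = c(index - 400, index + days),
      provider_type = c("general_ophthalmology",
                        rep("retina", length(days))),
      stringsAsFactors = FALSE),
    injections = data.frame(patient_id = id, laterality = lat,
                            date = index + inj_days, drug = drug,
                            stringsAsFactors = FALSE),
    diagnoses = data.frame(patient_id = id, laterality = lat,
                           date = index - 30, code_category = "namd",
                           stringsAsFactors = FALSE),
    procedures = data.frame(patient_id = character(),
                            laterality = character(),
                            date = as.Date(character()),
                            category = character(),
                            stringsAsFactors = FALSE),
    va = data.frame(patient_id = id, laterality = lat, date = index + days,
                    snellen_num = 20, snellen_den = 40,
                    stringsAsFactors = FALSE),
    iop = data.frame(patient_id = id, laterality = lat, date = index - 60,
                     mmHg = 15, stringsAsFactors = FALSE)
  )
}

bind_eyes <- function(eyes) {
  tabs <- c("encounters", "injections", "diagnoses", "procedures", "va",
            "iop")
  out <- lapply(tabs, function(tb) {
    do.call(rbind, lapply(eyes, `[[`, tb))
  })
  names(out) <- tabs
  out$patients <- do.call(rbind, lapply(eyes, `[[`, "patient"))
  structure(out[c("patients", tabs)], class = "registry")
}

# 1 non-naive, 1 cadence-fail, 1 fellow-eye-treated, 2 clean -> 2 survive
toy_registry <- function() {
  e1 <- toy_eye("tp1")                               # clean
  e2 <- toy_eye("tp2", lat = "OS", drug = "ranibizumab")  # clean
  e3 <- toy_eye("tp3")                               # non-naive
  e3$injections <- rbind(
    data.frame(patient_id = "tp3", laterality = "OD",
               date = as.Date("2016-12-01"), drug = "bevacizumab",
               stringsAsFactors = FALSE),
    e3$injections)
  e4 <- toy_eye("tp4")                               # cadence gap > 42 d
  gap <- e4$encounters$provider_type == "retina" &
    e4$encounters$date > as.Date("2017-02-01") + 100 &
    e4$encounters$date < as.Date("2017-02-01") + 215
  e4$encounters <- e4$encounters[!gap, ]
  e4$injections <- e4$injections[e4$injections$date %in%
                                   e4$encounters$date, ]
  e5 <- toy_eye("tp5")                               # fellow eye treated
  e5$injections <- rbind(
    e5$injections,
    data.frame(patient_id = "tp5", laterality = "OS",
               date = as.Date("2017-02-01") + 60, drug = "bevacizumab",
               stringsAsFactors = FALSE))
  bind_eyes(list(e1, e2, e3, e4, e5))
}
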