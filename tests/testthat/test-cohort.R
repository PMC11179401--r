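test_that("find_index returns the first in-window injection, inclusive", {
  reg <- toy_registry()
  win <- toy_window()
  expect_equal(find_index(reg, "tp1", "OD", win), as.Date("2017-02-01"))
  # window start boundary is inclusive
  expect_equal(find_index(reg, "tp1", "OD",
                          c(as.Date("2017-02-01"), win[2])),
               as.Date("2017-02-01"))
  # only pre-window injections -> absent
  expect_true(is.na(find_index(reg, "tp3", "OD",
                               c(as.Date("2019-06-01"), win[2]))))
})

test_that("treatment-naive lookback is (index - 365, index)", {
  reg <- toy_registry()
  idx <- as.Date("2017-02-01")
  expect_false(is_treatment_naive(reg, "tp3", "OD", idx))  # prior at -62 d
  expect_true(is_treatment_naive(reg, "tp1", "OD", idx))
  # a prior injection more than 365 days back does not break naivety
  reg2 <- toy_registry()
  reg2$injections <- rbind(reg2$injections,
                           data.frame(patient_id = "tp1", laterality = "OD",
                                      date = idx - 400,
                                      drug = "bevacizumab"))
  expect_true(is_treatment_naive(reg2, "tp1", "OD", idx))
})

test_that("regimen requires a single study drug for the whole year", {
  reg <- toy_registry()
  idx <- as.Date("2017-02-01")
  expect_equal(meets_regimen(reg, "tp1", "OD", idx), "bevacizumab")
  expect_equal(meets_regimen(reg, "tp2", "OS", idx), "ranibizumab")
  reg$injections$drug[reg$injections$patient_id == "tp1"][4] <- "aflibercept"
  expect_true(is.na(meets_regimen(reg, "tp1", "OD", idx)))
})

test_that("cadence requires gaps <= 42 days with year-long coverage", {
  reg <- toy_registry()
  idx <- as.Date("2017-02-01")
  expect_true(meets_cadence(reg, "tp1", idx))   # every 35 days to day 350
  expect_false(meets_cadence(reg, "tp4", idx))  # seeded 175-day gap
  expect_false(meets_cadence(reg, "absent", idx))
  # strict lower bound flag: 35-day gaps pass at 28, fail at 36
  expect_true(meets_cadence(reg, "tp1", idx,
                            criterion_config(cadence_min_gap_days = 28)))
  expect_false(meets_cadence(reg, "tp1", idx,
                             criterion_config(cadence_min_gap_days = 36)))
})

test_that("prn marker is a day-level join of encounters and injections", {
  reg <- toy_registry()
  idx <- as.Date("2017-02-01")
  expect_true(has_prn_marker(reg, "tp1", "OD", idx))  # 11 visits, 8 inj
  # inject on every visit day -> no marker
  reg2 <- toy_registry()
  days <- seq(0, 350, by = 35)
  reg2$injections <- rbind(
    reg2$injections[reg2$injections$patient_id != "tp1", ],
    data.frame(patient_id = "tp1", laterality = "OD", date = idx + days,
               drug = "bevacizumab"))
  expect_false(has_prn_marker(reg2, "tp1", "OD", idx))
})

test_that("exclusion rules match the documented windows", {
  reg <- toy_registry()
  idx <- as.Date("2017-02-01")
  base <- passes_exclusions(reg, "tp1", "OD", idx)
  expect_true(base$pass)
  expect_true(is.na(base$first_failed))

  # uncontrolled glaucoma needs >= 2 readings >= 25 mmHg in the prior year
  reg2 <- toy_registry()
  reg2$iop <- rbind(reg2$iop,
                    data.frame(patient_id = "tp1", laterality = "OD",
                               date = idx - c(30, 60), mmHg = c(26, 27)))
  ex <- passes_exclusions(reg2, "tp1", "OD", idx)
  expect_false(ex$flags[["glaucoma"]])
  expect_equal(ex$first_failed, "glaucoma")

  reg3 <- toy_registry()
  reg3$iop$mmHg[reg3$iop$patient_id == "tp1"] <- 30  # single reading
  expect_true(passes_exclusions(reg3, "tp1", "OD", idx)$flags[["glaucoma"]])

  # cataract surgery 30 days pre-index fails, 90 days pre-index passes
  reg4 <- toy_registry()
  reg4$procedures <- data.frame(patient_id = "tp1", laterality = "OD",
                                date = idx - 30,
                                category = "cataract_surgery")
  expect_false(passes_exclusions(reg4, "tp1", "OD",
                                 idx)$flags[["recent_surgery"]])
  reg4$procedures$date <- idx - 90
  expect_true(passes_exclusions(reg4, "tp1", "OD",
                                idx)$flags[["recent_surgery"]])

  # fellow-eye anti-VEGF during follow-up
  expect_false(passes_exclusions(reg, "tp5", "OD",
                                 idx)$flags[["fellow_eye_antivegf"]])
})

test_that("study-eye selection prefers earlier index, then OD", {
  eyes <- data.frame(laterality = c("OD", "OS"),
                     index_date = as.Date(c("2017-04-10", "2017-02-20")))
  expect_equal(select_study_eye(eyes)$laterality, "OS")
  eyes$index_date <- as.Date("2017-02-20")
  expect_equal(select_study_eye(eyes)$laterality, "OD")
  expect_equal(select_study_eye(eyes[2, ])$laterality, "OS")
})

test_that("toy registry attrition drops eyes at the expected rows", {
  att <- run_attrition(toy_registry(), window = toy_window())
  tab <- att$attrition
  drops <- setNames(-diff(tab$eyes), tab$criterion[-1])
  # 6 candidates: 5 study eyes + tp5's treated fellow eye (no nAMD dx)
  expect_equal(tab$eyes[tab$criterion == "initial"], 6)
  expect_equal(unname(drops["namd_dx"]), 1)   # the fellow-eye candidate
  expect_equal(unname(drops["naive"]), 1)     # tp3
  expect_equal(unname(drops["cadence"]), 1)   # tp4
  expect_equal(unname(drops["fellow_eye_antivegf"]), 1)  # tp5
  expect_equal(sum(drops), 4)
  expect_setequal(att$cohorts$patient_id, c("tp1", "tp2"))
  # eligible eyes carry outcomes from the acuity module
  expect_equal(att$cohorts$baseline_letters, c(70L, 70L))
  expect_equal(att$cohorts$year1_letters, c(70L, 70L))
  expect_equal(att$cohorts$n_injections_year1, c(8L, 8L))
})

test_that("attrition counts are monotone and match the verdict matrix", {
  sim <- generate_registry(sim_config(n_patients = 250, seed = 31))
  att <- run_attrition(sim$registry,
                       window = as.Date(c("2015-10-01", "2019-12-31")))
  expect_true(all(diff(att$attrition$eyes) <= 0))
  expect_true(all(diff(att$attrition$patients) <= 0))
  expect_equal(att$attrition$pct_eyes,
               round(100 * att$attrition$eyes / att$attrition$eyes[1], 1))
  # final cohort = eyes passing every criterion (set-intersection property;
  # the fixed row order only shapes per-row drops, never the survivors)
  pass_cols <- paste0("pass_", attrition_criteria())
  all_pass <- rowSums(!att$verdicts[pass_cols]) == 0
  expect_equal(sum(all_pass), nrow(att$cohorts))
  expect_equal(anyDuplicated(att$cohorts$patient_id), 0)
})

test_that("engine verdicts equal ground-truth flags per criterion", {
  sim <- generate_registry(sim_config(n_patients = 400, seed = 77))
  att <- run_attrition(sim$registry,
                       window = as.Date(c("2015-10-01", "2019-12-31")))
  v <- att$verdicts
  gt <- sim$ground_truth
  m <- match(paste(gt$patient_id, gt$laterality),
             paste(v$patient_id, v$laterality))
  expect_false(anyNA(m))
  for (cr in attrition_criteria()) {
    expect_equal(v[[paste0("pass_", cr)]][m], gt[[paste0("pass_", cr)]],
                 info = cr)
  }
})

test_that("registry schema violations are reported with table and row", {
  reg <- toy_registry()
  reg$injections$drug[3] <- "ibuprofen"
  expect_error(run_attrition(reg, window = toy_window()),
               "unknown drug 'ibuprofen' at row 3")
})
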