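test_that("snellen_to_letters reproduces the conversion formula", {
  # 85 + 50*log10(fraction), rounded half away from zero
  expect_identical(snellen_to_letters(20, 20), 85L)
  expect_identical(snellen_to_letters(20, 200), 35L)   # 85 - 50 exactly
  expect_identical(snellen_to_letters(20, 40), 70L)    # 69.948 -> 70
  expect_identical(snellen_to_letters(20, 25), 80L)    # 80.15 -> 80
  expect_identical(snellen_to_letters(20, c(20, 200, 40, 25)),
                   c(85L, 35L, 70L, 80L))
  # clamped to [0, 100]
  expect_identical(snellen_to_letters(20, 20000), 0L)
  expect_identical(snellen_to_letters(20, 9), 100L)
})

test_that("invalid Snellen fractions are rejected", {
  expect_error(snellen_to_letters(0, 20), "invalid")
  expect_error(snellen_to_letters(20, -5), "invalid")
  expect_error(snellen_to_letters(20, NA), "invalid")
})

test_that("conversion is strictly increasing over chart lines", {
  ch <- standard_chart()
  frac_order <- order(ch$snellen_num / ch$snellen_den)
  expect_true(all(diff(ch$letters[frac_order]) > 0))
  expect_true(all(ch$letters >= 0 & ch$letters <= 100))
})

test_that("letters_to_nearest_snellen inverts the conversion on the chart", {
  for (ch in list(standard_chart(), extended_chart())) {
    back <- letters_to_nearest_snellen(ch$letters, ch)
    expect_equal(back$snellen_den, ch$snellen_den)
  }
  # off-chart value: 72 is closer to 20/40 (70) than to 20/32 (75)
  expect_equal(letters_to_nearest_snellen(72)$snellen_den, 40)
  expect_equal(letters_to_nearest_snellen(85)$snellen_den, 20)
  expect_equal(letters_to_nearest_snellen(35)$snellen_den, 200)
  # ties break toward the better line: 77.5 between 75 and 80 -> 80 (20/25)
  expect_equal(letters_to_nearest_snellen(77.5)$snellen_den, 25)
  expect_error(letters_to_nearest_snellen(60, standard_chart()[0, ]),
               "non-empty")
})

test_that("best_documented_letters takes the day maximum", {
  ev <- data.frame(patient_id = "p1", laterality = "OD",
                   date = as.Date("2020-01-01"),
                   snellen_num = 20, snellen_den = c(40, 80))
  expect_identical(best_documented_letters(ev, "p1", "OD",
                                           as.Date("2020-01-01")), 70L)
  expect_identical(best_documented_letters(ev, "p1", "OS",
                                           as.Date("2020-01-01")),
                   NA_integer_)
  expect_identical(
    best_documented_letters(ev[1, ], "p1", "OD", as.Date("2020-01-01")),
    snellen_to_letters(20, 40))
})

test_that("baseline VA prefers the index day, then the nearest prior day", {
  idx <- as.Date("2020-06-01")
  ev <- data.frame(patient_id = "p1", laterality = "OD",
                   date = idx - c(0, 10, 20),
                   snellen_num = 20, snellen_den = c(40, 80, 25))
  expect_identical(select_baseline_va(ev, "p1", "OD", idx), 70L)
  # no measurement on index day: nearest prior within 14 days wins
  expect_identical(select_baseline_va(ev[-1, ], "p1", "OD", idx), 55L)
  # nothing within the window
  expect_identical(select_baseline_va(ev[3, , drop = FALSE], "p1", "OD",
                                      idx), NA_integer_)
})

test_that("one-year endpoint picks the nearest date, later on ties", {
  idx <- as.Date("2020-01-01")
  ev <- function(offsets, dens) {
    data.frame(patient_id = "p1", laterality = "OD", date = idx + offsets,
               snellen_num = 20, snellen_den = dens)
  }
  expect_identical(select_year1_va(ev(365, 40), "p1", "OD", idx), 70L)
  # day 390 (distance 25) beats day 330 (distance 35)
  expect_identical(select_year1_va(ev(c(330, 390), c(40, 80)), "p1", "OD",
                                   idx), 55L)
  # equidistant 337/393: the later date wins
  expect_identical(select_year1_va(ev(c(337, 393), c(40, 80)), "p1", "OD",
                                   idx), 55L)
  expect_identical(select_year1_va(ev(500, 40), "p1", "OD", idx),
                   NA_integer_)
})

test_that("converted scores are integers in [0, 100] for random fractions", {
  set.seed(101)
  den <- runif(500, 10, 2000)
  out <- snellen_to_letters(rep(20, 500), den)
  expect_true(all(out >= 0 & out <= 100))
  expect_type(out, "integer")
})
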