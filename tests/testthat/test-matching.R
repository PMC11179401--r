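mk_p <- function(id, gender, age, letters) {
  data.frame(participant_id = id, age = age, gender = gender,
             baseline_letters = letters, stringsAsFactors = FALSE)
}
mk_e <- function(id, gender, age, letters) {
  data.frame(patient_id = id, laterality = "OD", age_at_index = age,
             gender = gender, baseline_letters = letters,
             stringsAsFactors = FALSE)
}

test_that("compatibility implements the calipers and the age top-code", {
  expect_true(compatible(mk_p("A", "F", 75, 60), mk_e("x", "F", 73, 62)))
  expect_false(compatible(mk_p("A", "M", 70, 60), mk_e("x", "F", 70, 60)))
  expect_false(compatible(mk_p("A", "F", 75, 60), mk_e("x", "F", 81, 60)))
  expect_false(compatible(mk_p("A", "F", 75, 60), mk_e("x", "F", 75, 66)))
  # a >= 90 participant only matches >= 90 eyes, even within 5 years
  expect_false(compatible(mk_p("A", "F", 92, 60), mk_e("x", "F", 85, 60)))
  expect_true(compatible(mk_p("A", "F", 92, 60), mk_e("x", "F", 90, 60)))
  expect_error(compatible(mk_p("A", "F", NA, 60), mk_e("x", "F", 85, 60)),
               "missing covariate")
})

test_that("max-cardinality beats greedy on the crossing instance", {
  p <- rbind(mk_p("A", "F", 75, 60), mk_p("B", "F", 79, 60))
  e <- rbind(mk_e("x", "F", 76, 60), mk_e("y", "F", 71, 60))
  ms <- match_max_cardinality(p, e)
  expect_equal(nrow(ms$pairs), 2)
  expect_equal(ms$pairs$patient_id[ms$pairs$participant_id == "A"], "y")
  expect_equal(ms$pairs$patient_id[ms$pairs$participant_id == "B"], "x")
  # greedy in id order grabs x for A (closer age) and strands B
  mg <- match_greedy(p, e)
  expect_equal(nrow(mg$pairs), 1)
  expect_equal(mg$unmatched, "B")
})

test_that("degenerate pools are handled", {
  p <- mk_p("A", "F", 75, 60)
  empty_e <- mk_e("x", "F", 75, 60)[0, ]
  ms <- match_max_cardinality(p, empty_e)
  expect_equal(nrow(ms$pairs), 0)
  expect_equal(ms$unmatched, "A")
  # identity pool: everyone matches at zero distance
  p3 <- rbind(mk_p("A", "F", 75, 60), mk_p("B", "M", 80, 50),
              mk_p("C", "F", 91, 70))
  e3 <- rbind(mk_e("x", "F", 75, 60), mk_e("y", "M", 80, 50),
              mk_e("z", "F", 91, 70))
  ms3 <- match_max_cardinality(p3, e3)
  expect_equal(nrow(ms3$pairs), 3)
  expect_equal(sum(ms3$pairs$age_diff), 0)
  expect_equal(sum(ms3$pairs$letter_diff), 0)
})

test_that("solver equals the exhaustive optimum on random instances", {
  set.seed(1234)
  for (k in 1:200) {
    inst <- random_match_instance(sample(1:8, 1), sample(1:8, 1))
    ms <- match_max_cardinality(inst$participants, inst$eyes)
    opt <- brute_max_matching(adjacency_of(inst))
    expect_equal(nrow(ms$pairs), opt)
    mg <- match_greedy(inst$participants, inst$eyes)
    expect_lte(nrow(mg$pairs), nrow(ms$pairs))
  }
})

test_that("matching size is invariant to input permutation", {
  set.seed(99)
  inst <- random_match_instance(12, 15)
  base <- nrow(match_max_cardinality(inst$participants, inst$eyes)$pairs)
  for (k in 1:5) {
    pp <- inst$participants[sample(nrow(inst$participants)), ]
    ee <- inst$eyes[sample(nrow(inst$eyes)), ]
    expect_equal(nrow(match_max_cardinality(pp, ee)$pairs), base)
  }
})

test_that("validation rejects invalid match sets", {
  p <- rbind(mk_p("A", "F", 75, 60), mk_p("B", "F", 79, 60))
  e <- rbind(mk_e("x", "F", 76, 60), mk_e("y", "M", 71, 60))
  bad <- structure(list(pairs = data.frame(
    participant_id = c("A", "B"), patient_id = c("x", "x"),
    laterality = "OD", age_diff = 1, letter_diff = 0),
    unmatched = character()), class = "match_set")
  expect_error(validate_match_set(bad, p, e), "reuses")
  bad2 <- structure(list(pairs = data.frame(
    participant_id = "A", patient_id = "y", laterality = "OD",
    age_diff = 4, letter_diff = 0), unmatched = "B"),
    class = "match_set")
  expect_error(validate_match_set(bad2, p, e), "incompatible")
})

test_that("match_rate rounds to integer percent", {
  expect_identical(match_rate(281, 286), 98L)
  expect_identical(match_rate(261, 301), 87L)
  expect_identical(match_rate(0, 10), 0L)
  expect_error(match_rate(5, 0), "positive")
})
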