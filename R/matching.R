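#' 1:1 caliper matching of trial participants to registry eyes
#'
#' A trial participant and a registry eye are compatible when gender is
#' equal, ages are within 5 years (with ages >= 90 treated as one top-coded
#' category: a >= 90 participant matches only >= 90 eyes), and baseline
#' acuity is within 5 letters. Matching is 1:1 without replacement. The
#' default solver maximizes the number of matched pairs over the
#' compatibility graph (the published quantity is the match *rate*); a
#' greedy closest-candidate matcher is provided as a sensitivity baseline
#' and is never larger.
#'
#' @name matching
NULL

#' Matching rules (calipers)
#'
#' @param age_caliper_years Maximum age difference in years.
#' @param va_caliper_letters Maximum baseline-acuity difference in letters.
#' @param topcode_age Ages at/above this value form a single category.
#' @param gender_exact Require equal gender.
#' @return List of class `match_rules`.
#' @export
match_rules <- function(age_caliper_years = 5, va_caliper_letters = 5,
                        topcode_age = 90, gender_exact = TRUE) {
  stopifnot(age_caliper_years >= 0, va_caliper_letters >= 0)
  structure(list(age_caliper_years = age_caliper_years,
                 va_caliper_letters = va_caliper_letters,
                 topcode_age = topcode_age, gender_exact = gender_exact),
            class = "match_rules")
}

# vectorized compatibility over paired covariate vectors
compatible_vec <- function(age_a, gender_a, letters_a,
                           age_b, gender_b, letters_b,
                           rules = match_rules()) {
  if (any(is.na(age_a)) || any(is.na(age_b)) || any(is.na(gender_a)) ||
      any(is.na(gender_b)) || any(is.na(letters_a)) || any(is.na(letters_b))) {
    stop("missing covariate in matching input", call. = FALSE)
  }
  top_a <- age_a >= rules$topcode_age
  top_b <- age_b >= rules$topcode_age
  age_ok <- (top_a & top_b) |
    (!top_a & !top_b & abs(age_a - age_b) <= rules$age_caliper_years)
  va_ok <- abs(letters_a - letters_b) <= rules$va_caliper_letters
  g_ok <- if (rules$gender_exact) gender_a == gender_b else TRUE
  age_ok & va_ok & g_ok
}

#' Are a participant and an eye compatible under the matching rules?
#'
#' @param participant One-row data.frame with `age`, `gender`,
#'   `baseline_letters`.
#' @param eye One-row data.frame with `age_at_index`, `gender`,
#'   `baseline_letters`.
#' @param rules A [match_rules()].
#' @return Logical.
#' @export
compatible <- function(participant, eye, rules = match_rules()) {
  compatible_vec(participant$age, participant$gender,
                 participant$baseline_letters,
                 eye$age_at_index, eye$gender, eye$baseline_letters, rules)
}

match_inputs <- function(participants, eyes) {
  participants <- participants[order(participants$participant_id), ,
                               drop = FALSE]
  eyes <- eyes[order(eyes$patient_id, eyes$laterality), , drop = FALSE]
  rownames(participants) <- rownames(eyes) <- NULL
  list(participants = participants, eyes = eyes)
}

# edge cost encoding the tie-break: letter difference dominates, then age
# difference, then (epsilon) the eye's position in id order
match_cost_matrix <- function(participants, eyes, rules) {
  np <- nrow(participants); ne <- nrow(eyes)
  if (np == 0 || ne == 0) return(matrix(numeric(0), np, ne))
  ldiff <- abs(outer(participants$baseline_letters, eyes$baseline_letters,
                     "-"))
  adiff <- abs(outer(participants$age, eyes$age_at_index, "-"))
  comp <- outer(seq_len(np), seq_len(ne), function(i, j) {
    compatible_vec(participants$age[i], participants$gender[i],
                   participants$baseline_letters[i],
                   eyes$age_at_index[j], eyes$gender[j],
                   eyes$baseline_letters[j], rules)
  })
  c1 <- rules$age_caliper_years * max(np, ne) + 1
  eps <- 1 / ((np + 1) * (ne + 1))
  cost <- ldiff * c1 + adiff +
    matrix(seq_len(ne), np, ne, byrow = TRUE) * eps
  cost[!comp] <- Inf
  cost
}

new_match_set <- function(pairs, unmatched, algorithm) {
  structure(list(pairs = pairs, unmatched = unmatched,
                 algorithm = algorithm), class = "match_set")
}

assemble_pairs <- function(participants, eyes, assign) {
  hit <- which(assign > 0)
  pairs <- data.frame(
    participant_id = participants$participant_id[hit],
    patient_id = eyes$patient_id[assign[hit]],
    laterality = eyes$laterality[assign[hit]],
    age_diff = abs(participants$age[hit] -
                     eyes$age_at_index[assign[hit]]),
    letter_diff = abs(participants$baseline_letters[hit] -
                        eyes$baseline_letters[assign[hit]]),
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  pairs
}

#' Maximum-cardinality 1:1 matching
#'
#' Solves for the largest possible set of compatible (participant, eye)
#' pairs via successive shortest augmenting paths on a cost that ranks ties
#' by total letter difference, then total age difference, then eye id
#' order; participants are processed in id order, making the result
#' deterministic. The returned matching is validated (all pairs compatible,
#' no vertex reused) before it is returned.
#'
#' @param participants Trial roster data.frame (`participant_id`, `age`,
#'   `gender`, `baseline_letters`).
#' @param eyes Eligible-eye data.frame (`patient_id`, `laterality`,
#'   `age_at_index`, `gender`, `baseline_letters`).
#' @param rules A [match_rules()].
#' @return A `match_set`: `pairs` (data.frame `participant_id`,
#'   `patient_id`, `laterality`, `age_diff`, `letter_diff`) and `unmatched`
#'   (participant ids).
#' @export
match_max_cardinality <- function(participants, eyes,
                                  rules = match_rules()) {
  mi <- match_inputs(participants, eyes)
  cost <- match_cost_matrix(mi$participants, mi$eyes, rules)
  assign <- if (length(cost)) ssp_match(cost) else
    integer(nrow(mi$participants))
  pairs <- assemble_pairs(mi$participants, mi$eyes, assign)
  out <- new_match_set(
    pairs,
    unmatched = mi$participants$participant_id[assign == 0],
    algorithm = "maxcard")
  validate_match_set(out, mi$participants, mi$eyes, rules)
  out
}

#' Greedy closest-candidate matching
#'
#' Sequentially assigns each participant (in `order`, default id order) the
#' compatible unmatched eye with the smallest letter difference, breaking
#' ties by age difference then eye id. Kept as a sensitivity baseline:
#' its size never exceeds the maximum-cardinality size.
#'
#' @inheritParams match_max_cardinality
#' @param order Optional integer permutation of participants.
#' @return A `match_set`.
#' @export
match_greedy <- function(participants, eyes, rules = match_rules(),
                         order = NULL) {
  mi <- match_inputs(participants, eyes)
  participants <- mi$participants; eyes <- mi$eyes
  if (is.null(order)) order <- seq_len(nrow(participants))
  taken <- rep(FALSE, nrow(eyes))
  assign <- integer(nrow(participants))
  for (i in order) {
    ok <- which(!taken & compatible_vec(
      participants$age[i], participants$gender[i],
      participants$baseline_letters[i],
      eyes$age_at_index, eyes$gender, eyes$baseline_letters, rules))
    if (length(ok) == 0) next
    ld <- abs(participants$baseline_letters[i] -
                eyes$baseline_letters[ok])
    ad <- abs(participants$age[i] - eyes$age_at_index[ok])
    pick <- ok[order(ld, ad, ok)][1]
    taken[pick] <- TRUE
    assign[i] <- pick
  }
  out <- new_match_set(assemble_pairs(participants, eyes, assign),
                       unmatched = participants$participant_id[assign == 0],
                       algorithm = "greedy")
  validate_match_set(out, participants, eyes, rules)
  out
}

#' Validate a match set against the rules
#'
#' Errors if any pair violates the calipers or any participant/eye is used
#' more than once.
#'
#' @param match_set A `match_set`.
#' @inheritParams match_max_cardinality
#' @return The match set, invisibly.
#' @export
validate_match_set <- function(match_set, participants, eyes,
                               rules = match_rules()) {
  p <- match_set$pairs
  if (nrow(p) == 0) return(invisible(match_set))
  if (anyDuplicated(p$participant_id) ||
      anyDuplicated(eye_key(p$patient_id, p$laterality))) {
    stop("matching reuses a vertex", call. = FALSE)
  }
  pi <- match(p$participant_id, participants$participant_id)
  ei <- match(eye_key(p$patient_id, p$laterality),
              eye_key(eyes$patient_id, eyes$laterality))
  ok <- compatible_vec(participants$age[pi], participants$gender[pi],
                       participants$baseline_letters[pi],
                       eyes$age_at_index[ei], eyes$gender[ei],
                       eyes$baseline_letters[ei], rules)
  if (!all(ok)) stop("matching contains an incompatible pair",
                     call. = FALSE)
  invisible(match_set)
}

#' Match rate as an integer percentage
#'
#' @param match_set A `match_set` (or a pair count).
#' @param n_participants Arm size (> 0).
#' @return `100 * pairs / n_participants`, rounded to the nearest integer.
#' @examples
#' match_rate(281, 286)  # 98
#' match_rate(261, 301)  # 87
#' @export
match_rate <- function(match_set, n_participants) {
  if (n_participants <= 0) stop("n_participants must be positive",
                                call. = FALSE)
  n_pairs <- if (inherits(match_set, "match_set")) nrow(match_set$pairs)
  else match_set
  as.integer(round_half_away(100 * n_pairs / n_participants))
}
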