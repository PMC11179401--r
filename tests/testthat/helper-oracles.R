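# Independent oracles used across tests.

# Exhaustive maximum-cardinality bipartite matching by bitmask dynamic
# programming over the right-hand side (feasible up to ~10 columns).
# Completely independent of the augmenting-path solver under test.
brute_max_matching <- function(adj) {
  np <- nrow(adj); ne <- ncol(adj)
  if (np == 0 || ne == 0) return(0L)
  stopifnot(ne <= 12)
  best <- rep(0L, 2^ne)
  for (i in seq_len(np)) {
    new <- best
    for (j in which(adj[i, ])) {
      bit <- bitwShiftL(1L, j - 1L)
      pos <- which(bitwAnd(seq_len(2^ne) - 1L, bit) > 0L)
      new[pos] <- pmax(new[pos], best[pos - bit] + 1L)
    }
    best <- new
  }
  max(best)
}

# random caliper-matching instance on the covariate scales the pipeline uses
random_match_instance <- function(np, ne) {
  list(
    participants = data.frame(
      participant_id = sprintf("p%02d", seq_len(np)),
      age = sample(60:95, np, replace = TRUE),
      gender = sample(c("F", "M"), np, replace = TRUE),
      baseline_letters = sample(30:80, np, replace = TRUE),
      stringsAsFactors = FALSE),
    eyes = data.frame(
      patient_id = sprintf("e%02d", seq_len(ne)),
      laterality = "OD",
      age_at_index = sample(60:95, ne, replace = TRUE),
      gender = sample(c("F", "M"), ne, replace = TRUE),
      baseline_letters = sample(30:80, ne, replace = TRUE),
      stringsAsFactors = FALSE)
  )
}

adjacency_of <- function(inst, rules = match_rules()) {
  np <- nrow(inst$participants); ne <- nrow(inst$eyes)
  outer(seq_len(np), seq_len(ne), function(i, j) {
    trialemulate:::compatible_vec(
      inst$participants$age[i], inst$participants$gender[i],
      inst$participants$baseline_letters[i],
      inst$eyes$age_at_index[j], inst$eyes$gender[j],
      inst$eyes$baseline_letters[j], rules)
  })
}
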