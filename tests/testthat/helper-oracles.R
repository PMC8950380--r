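# Independent oracles and fixture builders shared across test files.

# Step-function curve evaluation (internal helper, re-exported for tests).
surv_at <- synsurv:::surv_at

# Minimal survival records: followup + exitus only.
surv_records <- function(followup, died) {
  data.frame(followup = as.integer(followup),
             exitus = factor(ifelse(died, "died", "survived"),
                             levels = c("died", "survived")))
}

# Brute-force product-limit oracle: sequential per-year risk-set loop,
# deliberately naive and independent of the package's vectorized code.
km_oracle <- function(followup, died, horizon) {
  s <- numeric(horizon + 1L); s[1L] <- 1
  cur <- 1
  for (t in seq_len(horizon)) {
    at_risk <- sum(followup >= t)
    events <- sum(followup == t & died)
    if (at_risk > 0L) cur <- cur * (1 - events / at_risk)
    s[t + 1L] <- cur
  }
  s
}

# Oracle for the censoring distribution: censorings are events, and the
# year's deaths leave the risk set before the censorings are counted.
censoring_oracle <- function(followup, died, horizon) {
  s <- numeric(horizon + 1L); s[1L] <- 1
  cur <- 1
  for (t in seq_len(horizon)) {
    at_risk <- sum(followup >= t) - sum(followup == t & died)
    events <- sum(followup == t & !died)
    if (at_risk > 0L) cur <- cur * (1 - events / at_risk)
    s[t + 1L] <- cur
  }
  s
}

# All multiset cohorts of n records, each record one of the 8 types
# (time 1..4) x (died, survived). Returns a list of count vectors
# (length 8, indexed time-major: type = (time-1)*2 + died+1).
enumerate_count_vectors <- function(n_max) {
  out <- list()
  rec <- function(prefix, remaining, slots) {
    if (slots == 1L) { out[[length(out) + 1L]] <<- c(prefix, remaining); return() }
    for (k in 0:remaining) rec(c(prefix, k), remaining - k, slots - 1L)
  }
  for (n in seq_len(n_max)) rec(integer(0), n, 8L)
  out
}

counts_to_records <- function(counts) {
  time <- rep(rep(1:4, each = 2L), counts)
  died <- rep(rep(c(TRUE, FALSE), 4L), counts)
  list(followup = time, died = died)
}

# A small canonical cohort fixture with known values, used by several
# module tests.
toy_cohort <- function() {
  as.data.frame(list(
    id = sprintf("T%02d", 1:8),
    age_dx = c(40L, 45L, 52L, 58L, 61L, 70L, 48L, 66L),
    age_group = synsurv::age_group_of(c(40, 45, 52, 58, 61, 70, 48, 66)),
    stage = factor(c("I", "II", "III", "I", "II", "III", "I", "II"),
                   levels = c("I", "II", "III")),
    her2 = factor(c("pos", "neg", "neg", "neg", "pos", "neg", "neg", "pos"),
                  levels = c("pos", "neg")),
    adherence = factor(c("yes", "no", "yes", "yes", NA, "no", "yes", "yes"),
                       levels = c("yes", "no")),
    followup = c(10L, 5L, 2L, 10L, 7L, 1L, 10L, 9L),
    exitus = factor(c("survived", "died", "died", "survived", "survived",
                      "died", "survived", "died"),
                    levels = c("died", "survived")),
    year_dx = c(2005L, 2006L, 2007L, 2008L, 2009L, 2005L, 2007L, 2008L)))
}

# The published 9x4 integrated-Brier-score matrix (strata = age group
# within stage, columns GMk1, GMTest, GMAIC, GMBIC) used as a printed
# input for the selection-logic acceptance test.
published_ibs_matrix <- function() {
  m <- matrix(c(
    0.0149, 0.0146, 0.0142, 0.0143,   # Stage I,  <=49
    0.0432, 0.0433, 0.0433, 0.0433,   # Stage I,  50-59
    0.0471, 0.0485, 0.0482, 0.0482,   # Stage I,  60-74
    0.0484, 0.0486, 0.0485, 0.0485,   # Stage II, <=49
    0.0703, 0.0707, 0.0706, 0.0706,   # Stage II, 50-59
    0.0943, 0.0986, 0.0982, 0.0984,   # Stage II, 60-74
    0.1183, 0.1188, 0.1185, 0.1185,   # Stage III,<=49
    0.1437, 0.1431, 0.1427, 0.1426,   # Stage III,50-59
    0.1722, 0.2020, 0.1960, 0.1965),  # Stage III,60-74
    nrow = 9L, byrow = TRUE,
    dimnames = list(
      c("I|<=49", "I|50-59", "I|60-74", "II|<=49", "II|50-59",
        "II|60-74", "III|<=49", "III|50-59", "III|60-74"),
      c("GMK1", "GMTEST", "GMAIC", "GMBIC")))
  m
}

# All-pairs edge list (the saturated graph) over a variable set.
complete_edges_for_test <- function(vars) {
  t(utils::combn(sort(vars), 2L))
}

# Build a hazard_series object directly (for indicator unit tests).
make_series <- function(O, E, Y) {
  structure(list(T = seq_along(O), O = O, E = E, Y = Y,
                 lambda_O = O / Y, lambda_P = E / Y),
            class = "hazard_series")
}

# Write a cohort data.frame to a temp CSV in the canonical dialect.
write_temp_cohort <- function(cohort) {
  f <- tempfile(fileext = ".csv")
  synsurv::write_cohort(cohort, f)
  f
}
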