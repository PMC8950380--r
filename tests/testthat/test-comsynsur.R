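# comsynsur: product-limit estimators, censored Brier score, IBS,
# partitioning, scoring and selection.

test_that("km_estimate matches hand-computed product limits", {
  all_cens <- surv_records(rep(10L, 5L), rep(FALSE, 5L))
  expect_true(all(km_estimate(all_cens)$surv == 1))

  four <- surv_records(c(2L, 5L, 3L, 10L), c(TRUE, TRUE, FALSE, FALSE))
  s <- km_estimate(four)
  expect_equal(surv_at(s, 2), 0.75)              # 3/4
  expect_equal(surv_at(s, 5), 0.375)             # 3/4 * 1/2
  expect_equal(km_estimate(surv_records(c(1L, 1L), c(TRUE, TRUE)))$surv[2L],
               0)
  expect_error(km_estimate(four[0L, ]), "empty")
})

test_that("censoring_km uses the deaths-first tie convention", {
  four <- surv_records(c(2L, 5L, 3L, 10L), c(TRUE, TRUE, FALSE, FALSE))
  g <- censoring_km(four)
  expect_equal(surv_at(g, 3), 2 / 3)             # risk set excludes death
  no_cens <- surv_records(c(3L, 4L), c(TRUE, TRUE))
  expect_true(all(censoring_km(no_cens)$surv == 1))
  expect_equal(censoring_km(surv_records(c(1L, 1L),
                                         c(FALSE, FALSE)))$surv[2L], 0)
  # tied death and censoring in the same year: death leaves first
  tied <- surv_records(c(2L, 2L, 5L), c(TRUE, FALSE, FALSE))
  expect_equal(surv_at(censoring_km(tied), 2), 1 - 1 / 2)
})

test_that("exhaustive small-cohort equivalence with the brute-force
          oracle (n <= 5 here; full n <= 8 in the acceptance suite)", {
  for (counts in enumerate_count_vectors(5L)) {
    r <- counts_to_records(counts)
    rec <- surv_records(r$followup, r$died)
    expect_equal(km_estimate(rec, horizon = 4L)$surv,
                 km_oracle(r$followup, r$died, 4L))
    expect_equal(censoring_km(rec, horizon = 4L)$surv,
                 censoring_oracle(r$followup, r$died, 4L))
  }
})

test_that("censored Brier score evaluates the weighted formula", {
  # perfect prediction, nobody censored or dead before t
  alive <- surv_records(rep(10L, 4L), rep(FALSE, 4L))
  perfect <- structure(list(time = 0:10, surv = rep(1, 11),
                            type = "event"), class = "surv_curve")
  expect_equal(brier_censored(alive, perfect, 5), 0)

  # everyone dead before t with S-hat = 0
  dead <- surv_records(rep(1L, 3L), rep(TRUE, 3L))
  zero <- structure(list(time = 0:10, surv = c(1, rep(0, 10)),
                         type = "event"), class = "surv_curve")
  expect_equal(brier_censored(dead, zero, 5), 0)

  # three uncensored subjects, S-hat(2) = 0.8, G == 1:
  # (0.64 + 0.04 + 0.04) / 3 = 0.24
  three <- surv_records(c(1L, 4L, 4L), c(TRUE, FALSE, FALSE))
  s08 <- structure(list(time = 0:10, surv = c(1, rep(0.8, 10)),
                        type = "event"), class = "surv_curve")
  expect_equal(brier_censored(three, s08, 2), 0.24)
  # the printed-variant weighting agrees here because G == 1
  expect_equal(brier_censored(three, s08, 2, weighting = "printed"), 0.24)
})

test_that("IBS integrates the Brier curve with uniform weight", {
  # integration rule in isolation: constant and linear integrands
  expect_equal(synsurv:::trapz_mean(rep(0.3, 11L)), 0.3)
  expect_equal(synsurv:::trapz_mean(seq(0, 1, length.out = 11L)), 0.5)

  # fine-grid oracle on the 3-subject fixture with constant S-hat = 0.8:
  # trapezoid of the annual-knot linear interpolation
  three <- surv_records(c(1L, 4L, 4L), c(TRUE, FALSE, FALSE))
  s08 <- structure(list(time = 0:10, surv = c(1, rep(0.8, 10)),
                        type = "event"), class = "surv_curve")
  G <- censoring_km(three, horizon = 10L)
  bs <- vapply(0:10, function(t) brier_censored(three, s08, t, G = G), 0)
  fine_t <- seq(0, 10, by = 1 / 512)
  fine <- stats::approx(0:10, bs, xout = fine_t)$y
  oracle <- sum((fine[-1L] + fine[-length(fine)]) / 2) * (1 / 512) / 10
  expect_equal(ibs(three, s08), oracle, tolerance = 1e-9)

  # duplication invariance: IBS is an average
  six <- three[rep(1:3, 2L), ]
  expect_equal(ibs(six, s08), ibs(three, s08), tolerance = 1e-12)

  expect_gte(ibs(three, s08), 0)
  expect_lte(ibs(three, s08), 1)
})

test_that("partition produces A x S ordered subsets and flags empties", {
  cfg <- registry_config(n_patients = 300L, seed = 14L)
  co <- generate_cohort(cfg)
  parts <- partition_cohort(co)
  expect_length(parts, 9L)
  expect_equal(names(parts)[1:3], c("<=49|I", "<=49|II", "<=49|III"))
  expect_equal(sum(vapply(parts, nrow, 0L)), nrow(co))

  expect_length(partition_cohort(data.frame(g = factor("a"),
                                            h = factor("b")),
                                 by = c("g", "h")), 1L)

  no3 <- co[co$stage != "III", ]
  p3 <- partition_cohort(no3)
  expect_setequal(attr(p3, "empty"),
                  c("<=49|III", "50-59|III", "60-74|III"))
})

test_that("score matrix shape, range, selection and merging", {
  cfg <- registry_config(n_patients = 2500L, seed = 33L,
                         p_missing_adherence = 0)
  co <- generate_cohort(cfg)
  # candidates: the cohort itself, plus distorted variants
  worse1 <- co; worse1$exitus <- factor("died", levels = c("died", "survived"))
  worse2 <- co; worse2$followup <- pmax(1L, co$followup - 5L)
  synds <- list(self = co, allval = worse1, shifted = worse2)
  sm <- score_matrix(co, synds)
  expect_equal(dim(sm$scores), c(9L, 3L))
  ok <- !is.na(sm$scores)
  expect_true(all(sm$scores[ok] >= 0 & sm$scores[ok] <= 1))
  # the cohort's own KM prediction is minimal (or tied) in every stratum
  expect_true(all(sm$scores[, 1L] <= apply(sm$scores, 1L, min) + 1e-12))
  expect_true(all(sm$selection == 1L))

  merged <- select_and_merge(sm, synds)
  expect_equal(nrow(merged), nrow(co))
  expect_true(all(merged$.model == "self"))
  expect_true(all(table(merged$.stratum) ==
                    table(paste(co$age_group, co$stage, sep = "|"))))

  # single-candidate selection is trivially that candidate
  sm1 <- score_matrix(co, list(only = worse2))
  expect_true(all(sm1$selection == 1L))

  # all-equal scores: tie-break to the first dataset in label order
  smt <- score_matrix(co, list(A = co, B = co, C = co))
  expect_true(all(smt$selection == 1L))
})

test_that("empty synthetic strata are never selectable; empty cohort
          strata are skipped in the merge", {
  cfg <- registry_config(n_patients = 2000L, seed = 41L,
                         p_missing_adherence = 0)
  co <- generate_cohort(cfg)
  gap <- co[co$stage != "III", ]         # candidate missing stage III
  sm <- score_matrix(co, list(gap = gap, full = co))
  iii <- grepl("\\|III$", rownames(sm$scores))
  expect_true(all(is.na(sm$scores[iii, "gap"])))
  expect_true(all(sm$selection[iii] == 2L))

  co_no3 <- co[co$stage != "III", ]
  sm2 <- score_matrix(co_no3, list(full = co))
  merged <- select_and_merge(sm2, list(full = co))
  expect_false(any(grepl("\\|III$", merged$.stratum)))
  expect_setequal(attr(merged, "skipped_strata"),
                  c("<=49|III", "50-59|III", "60-74|III"))

  # a non-empty stratum with no valid candidate is an error
  sm3 <- score_matrix(co, list(gap = gap))
  expect_error(select_and_merge(sm3, list(gap = gap)), "no valid score")
})
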