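# gm_engine: contingency tables, IPF fitting, stepwise search,
# imputation and junction-tree simulation.

# direct (non-IPF) saturated / independence log-likelihoods, written
# from the definition, as oracles for the penalized-search tests
loglik_saturated <- function(counts) {
  n <- sum(counts); p <- counts / n
  sum(counts[counts > 0] * log(p[counts > 0]))
}
loglik_independence <- function(counts) {
  n <- sum(counts)
  ll <- 0
  for (d in seq_along(dim(counts))) {
    m <- apply(counts, d, sum)
    ll <- ll + sum(m[m > 0] * log(m[m > 0] / n))
  }
  ll
}

# expand a count array into a data.frame of records
records_from_counts <- function(counts, levels) {
  grid <- expand.grid(levels, stringsAsFactors = TRUE)
  grid[rep(seq_len(nrow(grid)), as.vector(counts)), , drop = FALSE]
}

test_that("build_table cross-tabulates exactly", {
  df <- data.frame(adherence = factor(c("yes", "yes", "no", "yes"),
                                      levels = c("yes", "no")))
  tab <- build_table(df, "adherence")
  expect_equal(as.vector(tab$counts), c(3L, 1L))

  cfg <- registry_config(n_patients = 400L, seed = 2L,
                         p_missing_adherence = 0)
  co <- generate_cohort(cfg)
  tab6 <- build_table(co, c("age_group", "stage", "her2", "adherence",
                            "followup", "exitus"))
  expect_equal(prod(dim(tab6$counts)), 720L)
  expect_equal(sum(tab6$counts), 400L)

  co$adherence[1L] <- NA
  expect_error(build_table(co, c("stage", "adherence")), "missing")
  expect_error(build_table(co[0L, ], "stage"), "empty")
})

test_that("saturated and independence fits are exact", {
  lv <- list(x = c("a", "b"), y = c("a", "b"))
  counts <- array(c(30L, 10L, 10L, 30L), dim = c(2L, 2L), dimnames = lv)
  df <- records_from_counts(counts, lv)
  tab <- build_table(df, c("x", "y"))

  sat <- fit_decomposable(tab, list(c("x", "y")))
  expect_equal(as.vector(sat$p), as.vector(counts) / 80, tolerance = 1e-12)
  expect_equal(sat$loglik, loglik_saturated(counts), tolerance = 1e-10)
  expect_equal(sat$z, 3)

  ind <- fit_decomposable(tab, NULL)
  expect_equal(ind$p[1L, 1L], 0.25, tolerance = 1e-10)  # 0.5 * 0.5
  expect_equal(ind$loglik, loglik_independence(counts), tolerance = 1e-10)
  expect_equal(ind$z, 2)

  balanced <- array(rep(10L, 4L), dim = c(2L, 2L), dimnames = lv)
  tabb <- build_table(records_from_counts(balanced, lv), c("x", "y"))
  indb <- fit_decomposable(tabb, NULL)
  expect_true(all(abs(indb$p - 0.25) < 1e-10))
})

test_that("non-decomposable graphs are rejected", {
  df <- data.frame(a = factor(c("0", "1")), b = factor(c("0", "1")),
                   c = factor(c("0", "1")), d = factor(c("0", "1")))
  tab <- build_table(df, c("a", "b", "c", "d"))
  four_cycle <- list(c("a", "b"), c("b", "c"), c("c", "d"), c("a", "d"))
  expect_error(fit_decomposable(tab, four_cycle), "decomposable")
})

test_that("IPF reproduces observed clique marginals and the closed-form
          decomposable factorization", {
  set.seed(7)
  cfg <- registry_config(n_patients = 800L, seed = 44L,
                         p_missing_adherence = 0)
  co <- generate_cohort(cfg)
  tab <- build_table(co, c("age_group", "stage", "her2", "adherence"))
  edges <- list(c("age_group", "stage"), c("stage", "her2"),
                c("age_group", "adherence"))
  m <- fit_decomposable(tab, edges)
  expect_equal(sum(m$p), 1, tolerance = 1e-10)

  obs <- tab$counts / tab$n
  for (cq in m$cliques) {
    ix <- match(cq, tab$vars)
    expect_equal(apply(m$p, ix, sum), apply(obs, ix, sum),
                 tolerance = 1e-8)
  }
  # closed form: prod of clique marginals / prod of separator marginals
  marg <- function(vars) {
    ix <- match(vars, tab$vars)
    mm <- apply(obs, ix, sum)
    perm <- c(ix, setdiff(seq_along(dim(obs)), ix))
    full <- array(mm, dim = dim(obs)[perm])
    aperm(full, order(perm))
  }
  closed <- Reduce(`*`, lapply(m$cliques, marg))
  seps <- m$separators[m$parents != 0L]
  seps <- seps[lengths(seps) > 0L]
  for (s in seps) {
    d <- marg(s)
    r <- closed / d
    r[!is.finite(r)] <- 0
    closed <- r
  }
  expect_equal(as.vector(m$p), as.vector(closed), tolerance = 1e-8)
})

test_that("deviance is nonnegative and zero for the saturated model", {
  cfg <- registry_config(n_patients = 600L, seed = 8L,
                         p_missing_adherence = 0)
  co <- generate_cohort(cfg)
  tab <- build_table(co, c("age_group", "stage", "her2"))
  sat <- fit_decomposable(tab, complete_edges_for_test(tab$vars))
  expect_equal(2 * (loglik_saturated(tab$counts) - sat$loglik), 0,
               tolerance = 1e-8)
  for (edges in list(NULL, list(c("age_group", "stage")),
                     list(c("stage", "her2"), c("age_group", "stage")))) {
    sub <- fit_decomposable(tab, edges)
    expect_gte(2 * (sat$loglik - sub$loglik), -1e-8)
  }
})

test_that("stepwise search finds independence and keeps real edges", {
  # two independent balanced binary variables, n = 10,000
  lv <- list(x = c("a", "b"), y = c("a", "b"))
  counts <- array(rep(2500L, 4L), dim = c(2L, 2L), dimnames = lv)
  tab <- build_table(records_from_counts(counts, lv), c("x", "y"))
  # oracle: H from the penalized-likelihood definition, fitted values
  # computed directly from counts (not through the package fit)
  H_sat <- -2 * loglik_saturated(counts) + 2 * 3
  H_emp <- -2 * loglik_independence(counts) + 2 * 2
  expect_lt(H_emp, H_sat)
  got <- stepwise_select(tab, k = 2)
  expect_equal(nrow(got$edges), 0L)

  # perfectly correlated pair: edge retained under all four criteria
  counts2 <- array(c(500L, 0L, 0L, 500L), dim = c(2L, 2L), dimnames = lv)
  tab2 <- build_table(records_from_counts(counts2, lv), c("x", "y"))
  for (m in list(stepwise_select(tab2, k = 1),
                 stepwise_select(tab2, k = 2),
                 stepwise_select(tab2, k = log(1000)),
                 stepwise_select(tab2, alpha = 0.05)))
    expect_equal(nrow(m$edges), 1L)

  # degenerate penalties
  expect_equal(nrow(stepwise_select(tab2, k = 0)$edges), 1L)
  expect_equal(nrow(stepwise_select(tab2, k = Inf)$edges), 0L)
  expect_error(stepwise_select(tab2), "exactly one")
  expect_error(stepwise_select(tab2, k = 1, alpha = 0.05), "exactly one")
})

test_that("edge count is monotone non-increasing in the penalty", {
  cfg <- registry_config(n_patients = 1500L, seed = 17L,
                         p_missing_adherence = 0)
  co <- generate_cohort(cfg)
  tab <- build_table(co, c("age_group", "stage", "her2", "adherence",
                           "exitus"))
  sizes <- vapply(c(0, 1, 2, log(tab$n), 50, Inf), function(k)
    nrow(stepwise_select(tab, k = k)$edges), 0L)
  expect_true(all(diff(sizes) <= 0L))
  expect_equal(sizes[1L], choose(5L, 2L))   # k = 0: saturated
  expect_equal(sizes[length(sizes)], 0L)    # k = Inf: empty
})

test_that("fit_four_models labels and degenerate cases", {
  lv <- list(x = c("a", "b"), y = c("a", "b"), z = c("a", "b"))
  # x = y perfectly, z independent: all four criteria keep exactly x~y
  n_half <- 500L
  df <- data.frame(
    x = factor(rep(c("a", "b"), each = n_half), levels = lv$x),
    y = factor(rep(c("a", "b"), each = n_half), levels = lv$y),
    z = factor(rep(c("a", "b"), n_half), levels = lv$z))
  tab <- build_table(df, c("x", "y", "z"))
  ms <- fit_four_models(tab)
  expect_named(ms, c("GMK1", "GMTEST", "GMAIC", "GMBIC"))
  for (m in ms) expect_equal(m$edges, matrix(c("x", "y"), 1L, 2L))
  expect_identical(ms$GMAIC$edges, ms$GMBIC$edges)

  # independence data: all four graphs empty
  counts <- array(rep(625L, 8L), dim = c(2L, 2L, 2L), dimnames = lv)
  tabi <- build_table(records_from_counts(counts, lv), c("x", "y", "z"))
  for (m in fit_four_models(tabi)) expect_equal(nrow(m$edges), 0L)

  # n = 1: log(1) = 0 penalty, saturated behavior for GMBIC
  tab1 <- build_table(df[1L, ], c("x", "y", "z"))
  expect_equal(nrow(stepwise_select(tab1, k = log(1))$edges), 3L)
})

test_that("impute_missing draws from the fitted conditional", {
  cfg <- registry_config(n_patients = 500L, seed = 23L,
                         p_missing_adherence = 0)
  co <- generate_cohort(cfg)
  tab <- build_table(co, c("stage", "adherence"))
  m <- fit_decomposable(tab, list(c("stage", "adherence")))

  # no missing values: unchanged
  out <- impute_missing(co, m, "adherence", seed = 1L)
  expect_identical(out$adherence, co$adherence)

  # degenerate conditional: P(yes | stage) = 1 forces yes
  co2 <- co
  co2$adherence <- factor("yes", levels = c("yes", "no"))
  m2 <- fit_decomposable(build_table(co2, c("stage", "adherence")),
                         list(c("stage", "adherence")))
  co2$adherence[1:20] <- NA
  out2 <- impute_missing(co2, m2, "adherence", seed = 4L)
  expect_true(all(out2$adherence[1:20] == "yes"))

  # large-sample frequency matches the conditional probability
  n_miss <- 10000L
  base <- data.frame(
    stage = factor("I", levels = c("I", "II", "III")),
    adherence = factor(rep(c("yes", "no"), c(7L, 3L)),
                       levels = c("yes", "no")))
  mod <- fit_decomposable(build_table(base, c("stage", "adherence")),
                          list(c("stage", "adherence")))
  tofill <- data.frame(
    stage = factor("I", levels = c("I", "II", "III")),
    adherence = factor(rep(NA_character_, n_miss),
                       levels = c("yes", "no")))
  filled <- impute_missing(tofill, mod, "adherence", seed = 9L)
  se <- sqrt(0.7 * 0.3 / n_miss)
  expect_lt(abs(mean(filled$adherence == "yes") - 0.7), 4 * se)
})

test_that("junction-tree simulation reproduces the fitted joint", {
  expect_equal(nrow(simulate_syn(
    fit_decomposable(build_table(
      data.frame(x = factor(c("a", "b"))), "x"), NULL), 0L)), 0L)

  # point mass: all records identical
  dfp <- data.frame(x = factor(rep("a", 5L), levels = c("a", "b")),
                    y = factor(rep("b", 5L), levels = c("a", "b")))
  mp <- fit_decomposable(build_table(dfp, c("x", "y")),
                         list(c("x", "y")))
  sp <- simulate_syn(mp, 50L, seed = 3L)
  expect_true(all(sp$x == "a" & sp$y == "b"))
  expect_error(simulate_syn(mp, -1L), ">= 0")

  # closure: simulate -> tabulate -> saturated refit recovers the
  # generating probabilities within multinomial error
  cfg <- registry_config(n_patients = 2000L, seed = 5L,
                         p_missing_adherence = 0)
  co <- generate_cohort(cfg)
  tab <- build_table(co, c("age_group", "stage", "her2"))
  gen <- stepwise_select(tab, k = 2)
  n_sim <- 50000L
  syn <- simulate_syn(gen, n_sim, seed = 12L)
  refit <- fit_decomposable(build_table(syn, c("age_group", "stage",
                                               "her2")),
                            complete_edges_for_test(gen$vars))
  err <- abs(refit$p - gen$p)
  bound <- 4 * sqrt(gen$p * (1 - gen$p) / n_sim) + 1e-9
  expect_true(all(err <= bound))

  # determinism
  expect_identical(simulate_syn(gen, 1000L, seed = 8L),
                   simulate_syn(gen, 1000L, seed = 8L))
})

test_that("graph models serialize and reload", {
  cfg <- registry_config(n_patients = 300L, seed = 6L,
                         p_missing_adherence = 0)
  co <- generate_cohort(cfg)
  tab <- build_table(co, c("age_group", "stage", "exitus"))
  m <- stepwise_select(tab, k = 2)
  m$criterion <- "GMAIC"
  f <- tempfile(fileext = ".json")
  write_graph_model(m, f)
  m2 <- read_graph_model(f)
  expect_equal(m2$edges, m$edges)
  expect_equal(as.vector(m2$p), as.vector(m$p), tolerance = 1e-12)
  expect_equal(m2$loglik, m$loglik, tolerance = 1e-12)
  expect_identical(simulate_syn(m2, 200L, seed = 1L)$stage,
                   simulate_syn(m, 200L, seed = 1L)$stage)
})
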