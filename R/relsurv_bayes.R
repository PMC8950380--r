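# Bayesian relative-survival modeling on the annual grid.
#
# From a cohort and a general-population life table, build per-year
# counts: O(T) observed deaths, Y(T) persons entering interval T, and
# E(T) expected deaths (population rates applied to the at-risk
# person-time, half an interval for subjects exiting within the year,
# Ederer-II style). The observed hazard is smoothed with a first-order
# autoregressive Poisson model,
#   O(T) ~ Poisson(mu_T), log(mu_T) = log(Y(T)) + delta_T,
#   delta_1 ~ N(0, 1/0.001), delta_T ~ N(delta_{T-1}, 1/0.001),
# i.e. a Gaussian random walk with precision 0.001 (variance 1000) in
# the WinBUGS parameterization. Survival indicators (relative survival,
# conditional relative survival, excess mortality, crude probabilities
# of death) are computed per posterior draw and summarized as the
# median with a 95% credible interval.

#' Observed, expected and at-risk series by follow-up year
#'
#' For T = 1..`horizon`: `Y(T)` = subjects with follow-up >= T (entering
#' interval T), `O(T)` = deaths in interval T, and `E(T)` = sum over
#' subjects at risk of the population annual hazard at their attained
#' age (`age_dx + T - 1`) and calendar year (`year_dx + T - 1`), with a
#' half-interval contribution for subjects exiting (death or censoring)
#' within T. Survivors whose follow-up ends exactly at the
#' administrative horizon are under observation for the whole final
#' interval and contribute a full interval.
#'
#' @param cohort cohort data.frame (needs `age_dx`, `year_dx`,
#'   `followup`, `exitus`).
#' @param lifetable a `life_table`.
#' @param horizon last follow-up year (default 10).
#' @return object of class `hazard_series`: `T`, `O`, `E`, `Y` and the
#'   crude rates `lambda_O = O/Y`, `lambda_P = E/Y`.
#' @export
hazard_series <- function(cohort, lifetable, horizon = 10L) {
  stopifnot(inherits(lifetable, "life_table"))
  tt <- seq_len(horizon)
  O <- E <- numeric(horizon); Y <- integer(horizon)
  for (t in tt) {
    at_risk <- cohort$followup >= t
    Y[t] <- sum(at_risk)
    O[t] <- sum(at_risk & cohort$followup == t & cohort$exitus == "died")
    if (Y[t] > 0L) {
      idx <- which(at_risk)
      rate <- lifetable_rate(lifetable, cohort$age_dx[idx] + t - 1L,
                             cohort$year_dx[idx] + t - 1L)
      exits_within <- cohort$followup[idx] == t &
        !(cohort$exitus[idx] == "survived" & t == horizon)
      frac <- ifelse(exits_within, 0.5, 1)
      E[t] <- sum(rate * frac)
    }
  }
  structure(list(T = tt, O = O, E = E, Y = Y,
                 lambda_O = ifelse(Y > 0, O / Y, NA_real_),
                 lambda_P = ifelse(Y > 0, E / Y, NA_real_)),
            class = "hazard_series")
}

#' @export
print.hazard_series <- function(x, ...) {
  print(data.frame(T = x$T, O = x$O, E = round(x$E, 2), Y = x$Y,
                   lambda_O = round(x$lambda_O, 5),
                   lambda_P = round(x$lambda_P, 5)))
  invisible(x)
}

# Split-chain potential scale reduction (Rhat) for one parameter;
# draws is an iterations x chains matrix.
split_rhat <- function(draws) {
  n <- nrow(draws) %/% 2L
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2L, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the AR(1) Poisson hazard model
#'
#' Samples the posterior of the log-hazard offsets
#' \eqn{\delta_{1..T}} (so \eqn{\mu_T = Y(T) e^{\delta_T}}) by adaptive
#' random-walk Metropolis-within-Gibbs. Split-chain
#' \eqn{\hat R} and effective sample sizes are computed for every
#' \eqn{\delta_T}; a warning is raised if any \eqn{\hat R > 1.05} or
#' any ESS < 400, and the diagnostics travel with the fit either way.
#'
#' @param series a `hazard_series` with `Y(T) > 0` for every T.
#' @param n_draws post-warmup draws per chain (default 5000).
#' @param n_warmup warmup iterations per chain (default 5000).
#' @param chains number of chains (default 4).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param prior_var prior variance of the random-walk increments
#'   (default 1000, i.e. precision 0.001).
#' @return object of class `ar1_fit`: `delta` (all post-warmup draws,
#'   iterations x T), `series`, `diagnostics` (per-T `rhat`, `ess`),
#'   `converged`.
#' @export
fit_ar1_poisson <- function(series, n_draws = 5000L, n_warmup = 5000L,
                            chains = 4L, seed = 1L, prior_var = 1000) {
  stopifnot(inherits(series, "hazard_series"))
  if (any(series$Y <= 0L))
    stop("Y(T) must be positive for every modeled interval")
  Tn <- length(series$T)
  per_chain <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    per_chain[[ch]] <- ar1_poisson_chain(series$O, series$Y,
                                         as.integer(n_draws),
                                         as.integer(n_warmup), prior_var)
  }
  rhat <- vapply(seq_len(Tn), function(t)
    split_rhat(vapply(per_chain, function(m) m[, t],
                      numeric(n_draws))), 0)
  ess <- vapply(seq_len(Tn), function(t)
    sum(vapply(per_chain, function(m)
      unname(coda::effectiveSize(m[, t])), 0)), 0)
  converged <- all(rhat < 1.05) && all(ess > 400)
  if (!converged)
    warning("MCMC diagnostics outside targets (max Rhat = ",
            round(max(rhat), 3), ", min ESS = ", round(min(ess)),
            "); increase draws/warmup")
  structure(list(delta = do.call(rbind, per_chain), series = series,
                 chains = chains, n_draws = n_draws, n_warmup = n_warmup,
                 diagnostics = data.frame(T = series$T, rhat = rhat,
                                          ess = ess),
                 converged = converged),
            class = "ar1_fit")
}

#' @export
print.ar1_fit <- function(x, ...) {
  cat("AR(1) Poisson hazard fit:", x$chains, "chains x", x$n_draws,
      "draws", if (!x$converged) "(NOT CONVERGED)", "\n")
  print(x$diagnostics)
  invisible(x)
}

#' Posterior survival indicators
#'
#' Per posterior draw, with annual hazards
#' \eqn{\lambda_O(T) = e^{\delta_T}} and fixed
#' \eqn{\lambda_P(T) = E(T)/Y(T)}:
#' observed survival \eqn{OS(T) = e^{-\sum_{u \le T} \lambda_O(u)}},
#' expected survival \eqn{ES(T)} likewise from \eqn{\lambda_P}, relative
#' survival \eqn{RS = OS/ES}, five-year conditional relative survival
#' \eqn{CRS(T) = RS(T+5)/RS(T)} for \eqn{T = 0..5} (with
#' \eqn{RS(0) = 1}), excess mortality \eqn{EM = 1 - CRS}, and crude
#' probabilities of death from cancer and from other causes
#' \deqn{PCa(T) = \sum_{u \le T} \bar{OS}(u)\,\lambda_X(u), \quad
#'       POC(T) = \sum_{u \le T} \bar{OS}(u)\,\lambda_P(u),}
#' where \eqn{\lambda_X = \lambda_O - \lambda_P} and
#' \eqn{\bar{OS}(u) = OS(u-1)(1 - e^{-\lambda_O(u)})/\lambda_O(u)} is
#' the within-interval average of OS under a constant interval hazard
#' (its \eqn{\lambda_O \to 0} limit is \eqn{OS(u-1)}). This quadrature
#' makes \eqn{PCa(T) + POC(T) = 1 - OS(T)} an exact identity per draw.
#' Summaries are the posterior median and 2.5/97.5 percentiles.
#'
#' @param fit an `ar1_fit` (or a draws matrix, iterations x T).
#' @param series the `hazard_series` (taken from `fit` if absent).
#' @return object of class `posterior_indicators`: `summary` (long
#'   data.frame `indicator, T, median, lo95, hi95`, proportions on
#'   `[0, 1]`) and `draws` (list of per-draw matrices, for identity
#'   checks).
#' @export
survival_indicators <- function(fit, series = NULL) {
  if (inherits(fit, "ar1_fit")) {
    series <- series %||% fit$series
    delta <- fit$delta
  } else delta <- as.matrix(fit)
  stopifnot(inherits(series, "hazard_series"))
  Tn <- length(series$T)
  stopifnot(ncol(delta) == Tn)

  lam_O <- exp(delta)                        # draws x T
  lam_P <- matrix(series$E / series$Y, nrow(delta), Tn, byrow = TRUE)
  lam_X <- lam_O - lam_P
  cum_O <- t(apply(lam_O, 1L, cumsum))
  cum_P <- t(apply(lam_P, 1L, cumsum))
  OS <- exp(-cum_O); ES <- exp(-cum_P)
  RS <- OS / ES
  OS0 <- cbind(1, OS[, -Tn, drop = FALSE])   # OS(u-1)
  osbar <- ifelse(lam_O > 0, OS0 * (1 - exp(-lam_O)) / lam_O, OS0)
  PCa <- t(apply(osbar * lam_X, 1L, cumsum))
  POC <- t(apply(osbar * lam_P, 1L, cumsum))
  RS0 <- cbind(1, RS)                        # RS at T = 0..Tn
  if (Tn >= 5L) {
    # columns correspond to conditioning times T = 0..(Tn-5)
    CRS <- sapply(0:(Tn - 5L), function(T)
      RS0[, T + 5L + 1L] / RS0[, T + 1L])
    if (is.null(dim(CRS))) CRS <- matrix(CRS, nrow = 1L)
    EM <- 1 - CRS
  } else CRS <- EM <- NULL

  summarize <- function(mat, name, t_index) {
    q <- apply(mat, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
               names = FALSE)
    data.frame(indicator = name, T = t_index, median = q[1L, ],
               lo95 = q[2L, ], hi95 = q[3L, ])
  }
  tt <- series$T
  summ <- rbind(
    summarize(OS, "OS", tt), summarize(ES, "ES", tt),
    summarize(RS, "RS", tt),
    if (!is.null(CRS)) summarize(CRS, "CRS", 0:(Tn - 5L)),
    if (!is.null(EM)) summarize(EM, "EM", 0:(Tn - 5L)),
    summarize(PCa, "PCa", tt), summarize(POC, "POC", tt))
  rownames(summ) <- NULL
  structure(list(summary = summ,
                 draws = list(OS = OS, ES = ES, RS = RS, CRS = CRS,
                              EM = EM, PCa = PCa, POC = POC,
                              lambda_O = lam_O, lambda_P = lam_P,
                              lambda_X = lam_X)),
            class = "posterior_indicators")
}

#' @export
print.posterior_indicators <- function(x, digits = 3, ...) {
  s <- x$summary
  s[c("median", "lo95", "hi95")] <- round(s[c("median", "lo95", "hi95")],
                                          digits)
  print(s)
  invisible(x)
}

#' Difference between two group medians, in percentage points
#'
#' Reported contrasts (e.g. adherent minus nonadherent) are differences
#' of posterior medians on the percent scale, rounded to one decimal
#' with halves away from zero. Inputs may be bare numbers (already in
#' percent) or single rows of a `posterior_indicators` summary (same
#' `indicator` and `T` required; proportions are scaled to percent).
#'
#' @param a,b numeric medians in percent, or one-row summary
#'   data.frames.
#' @return `median(a) - median(b)` rounded to one decimal.
#' @export
group_difference <- function(a, b) {
  pick <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1L)
      list(v = 100 * x$median, lbl = paste(x$indicator, x$T))
    } else list(v = x, lbl = NA_character_)
  }
  pa <- pick(a); pb <- pick(b)
  if (!is.na(pa$lbl) && !is.na(pb$lbl) && pa$lbl != pb$lbl)
    stop("mismatched indicator labels: ", pa$lbl, " vs ", pb$lbl)
  round_half_away(pa$v - pb$v, 1L)
}
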