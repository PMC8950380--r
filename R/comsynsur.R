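# ComSynSurData: score synthetic datasets against the cohort with the
# integrated censored Brier score, stratum by stratum, and merge the
# winning subsets into a combined synthetic cohort.
#
# All survival estimation here is on the discrete annual grid t = 0..10:
# follow-up is recorded in whole years, so the Kaplan-Meier estimators
# are simple product-limit computations with the convention that at tied
# times deaths precede censorings in the risk-set bookkeeping.

#' Kaplan-Meier survival curve on the annual grid
#'
#' Product-limit estimator with deaths as events, evaluated at
#' t = 0, 1, ..., `horizon`. At a tied time deaths are removed from the
#' risk set before censorings (the standard convention).
#'
#' @param records data.frame with `followup` (integer years) and
#'   `exitus` (`died`/`survived`).
#' @param horizon last grid time (default 10).
#' @return object of class `surv_curve`: `time`, `surv`, `n_risk`,
#'   `n_event`, `type = "event"`.
#' @export
km_estimate <- function(records, horizon = 10L) {
  if (nrow(records) == 0L) stop("empty subset")
  tt <- seq_len(horizon)
  n_risk  <- vapply(tt, function(t) sum(records$followup >= t), 0L)
  n_event <- vapply(tt, function(t)
    sum(records$followup == t & records$exitus == "died"), 0L)
  frac <- ifelse(n_risk > 0L, 1 - n_event / n_risk, 1)
  structure(list(time = c(0L, tt), surv = c(1, cumprod(frac)),
                 n_risk = n_risk, n_event = n_event, type = "event"),
            class = "surv_curve")
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Reverse Kaplan-Meier: censorings are the events. At a tied time the
#' deaths leave the risk set first, so the censoring factor at t is
#' \eqn{1 - c_t / (Y_t - d_t)}.
#'
#' @inheritParams km_estimate
#' @return a `surv_curve` with `type = "censoring"`.
#' @export
censoring_km <- function(records, horizon = 10L) {
  if (nrow(records) == 0L) stop("empty subset")
  tt <- seq_len(horizon)
  n_risk <- vapply(tt, function(t) sum(records$followup >= t), 0L)
  d <- vapply(tt, function(t)
    sum(records$followup == t & records$exitus == "died"), 0L)
  cns <- vapply(tt, function(t)
    sum(records$followup == t & records$exitus == "survived"), 0L)
  risk <- n_risk - d
  frac <- ifelse(risk > 0L, 1 - cns / risk, 1)
  structure(list(time = c(0L, tt), surv = c(1, cumprod(frac)),
                 n_risk = risk, n_event = cns, type = "censoring"),
            class = "surv_curve")
}

#' @export
print.surv_curve <- function(x, ...) {
  cat("Product-limit curve (", x$type, "), t = 0..",
      max(x$time), "\n", sep = "")
  print(stats::setNames(round(x$surv, 4), x$time))
  invisible(x)
}

# Step-function evaluation of a surv_curve at (possibly vector) times;
# curve value holds from its last grid point onward.
surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  idx[idx < 1L] <- 1L
  curve$surv[pmin(idx, length(curve$surv))]
}

# G(t) with the floor rule: values below `floor` are replaced by the
# curve's value at the last time where it was still >= floor, keeping
# inverse-probability weights finite in heavily censored tails.
g_at <- function(G, t, floor = 1e-8) {
  ok <- G$surv >= floor
  if (!any(ok)) stop("censoring distribution entirely below floor")
  last_ok <- max(which(ok))
  v <- surv_at(G, t)
  v[v < floor] <- G$surv[last_ok]
  v
}

#' Censored Brier score at a time point
#'
#' Inverse-probability-of-censoring weighted squared error between the
#' survival status at `t` and a predicted survival probability
#' \eqn{\hat S(t)}. Subjects dead by `t` contribute
#' \eqn{\hat S(t)^2 / \hat G(t_i^-)}; subjects still under follow-up
#' after `t` contribute \eqn{(1-\hat S(t))^2 / \hat G(t)}; subjects
#' censored exactly at `t` are known alive at `t` and contribute
#' \eqn{(1-\hat S(t))^2 / \hat G(t^-)} (this keeps the score proper at
#' the administrative horizon, where \eqn{\hat G(t) = 0}); subjects
#' censored strictly before `t` contribute 0. `weighting = "printed"` instead divides
#' both terms by \eqn{\hat G(t)} (a variant kept for sensitivity
#' checks). Weights with \eqn{\hat G} below `g_floor` are truncated at
#' the last time \eqn{\hat G} was above it.
#'
#' @param records cohort subset (with `followup`, `exitus`).
#' @param predicted a `surv_curve` giving \eqn{\hat S}.
#' @param t evaluation time (years).
#' @param G optional censoring curve; defaults to
#'   [censoring_km()] of `records`.
#' @param weighting `"standard"` (default) or `"printed"`.
#' @param g_floor truncation floor for \eqn{\hat G} (default 1e-8).
#' @return nonnegative scalar score.
#' @export
brier_censored <- function(records, predicted, t, G = NULL,
                           weighting = c("standard", "printed"),
                           g_floor = 1e-8) {
  weighting <- match.arg(weighting)
  if (nrow(records) == 0L) stop("empty subset")
  if (is.null(G)) G <- censoring_km(records, horizon = max(predicted$time))
  s_t <- surv_at(predicted, t)
  died <- records$exitus == "died"
  ti <- records$followup
  contrib <- numeric(nrow(records))
  dead_by_t <- died & ti <= t
  at_risk   <- ti > t
  cens_at_t <- !died & ti == t           # alive at t, censored at t
  if (weighting == "standard") {
    w_dead <- g_at(G, ti[dead_by_t] - 1L, g_floor)  # G(t_i^-)
    contrib[dead_by_t] <- s_t^2 / w_dead
    contrib[at_risk] <- (1 - s_t)^2 / g_at(G, t, g_floor)
    contrib[cens_at_t] <- (1 - s_t)^2 / g_at(G, t - 1L, g_floor)
  } else {
    gt <- g_at(G, t, g_floor)
    contrib[dead_by_t] <- s_t^2 / gt
    contrib[at_risk | cens_at_t] <- (1 - s_t)^2 / gt
  }
  mean(contrib)
}

#' Integrated Brier score up to a horizon
#'
#' Time-averaged censored Brier score,
#' \eqn{\mathrm{IBS}(t^*) = \frac{1}{t^*}\int_0^{t^*} BS(t)\,dt},
#' computed by the trapezoidal rule on the annual grid 0..`t_star`
#' (equivalently, Stieltjes integration against the uniform weight
#' \eqn{W(t) = t/t^*}).
#'
#' @inheritParams brier_censored
#' @param t_star integration horizon (default 10 years).
#' @return score in `[0, 1]`.
#' @export
ibs <- function(records, predicted, t_star = 10L, G = NULL,
                weighting = c("standard", "printed"), g_floor = 1e-8) {
  weighting <- match.arg(weighting)
  if (is.null(G)) G <- censoring_km(records, horizon = max(predicted$time))
  grid <- 0:t_star
  bs <- vapply(grid, function(t)
    brier_censored(records, predicted, t, G = G, weighting = weighting,
                   g_floor = g_floor), 0)
  trapz_mean(bs)
}

# Mean of a function tabulated on a unit-spaced grid, trapezoidal rule:
# the uniform-weight Stieltjes integral (1/t*) int_0^{t*} f dt.
trapz_mean <- function(f) {
  sum((f[-1L] + f[-length(f)]) / 2) / (length(f) - 1L)
}

#' Partition a cohort into age-by-stratum subsets
#'
#' Splits into `L = A x S` disjoint, exhaustive subsets with a fixed
#' ordering: the first grouping variable is the outer loop (age group by
#' default), the second the inner one. Empty subsets are allowed but
#' flagged in the `empty` attribute.
#'
#' @param cohort data.frame with the grouping factors.
#' @param by length-2 character vector of grouping variables
#'   (default `c("age_group", "stage")`).
#' @return named list of `L` data.frames, names `outer|inner`; attribute
#'   `empty` marks strata with no records.
#' @export
partition_cohort <- function(cohort, by = c("age_group", "stage")) {
  stopifnot(length(by) == 2L, all(by %in% names(cohort)))
  lv1 <- canonical_levels(by[1L], cohort[[by[1L]]])
  lv2 <- canonical_levels(by[2L], cohort[[by[2L]]])
  out <- list()
  for (a in lv1) for (s in lv2) {
    sel <- cohort[[by[1L]]] == a & cohort[[by[2L]]] == s
    out[[paste(a, s, sep = "|")]] <- cohort[sel, , drop = FALSE]
  }
  attr(out, "empty") <- names(out)[vapply(out, nrow, 0L) == 0L]
  out
}

#' Score every synthetic dataset against every cohort stratum
#'
#' Entry (l, m) is the integrated Brier score of cohort stratum `l`
#' against the Kaplan-Meier curve predicted from synthetic dataset `m`'s
#' matching stratum (one curve per stratum, applied to every subject of
#' the cohort stratum). Strata that are empty in a synthetic dataset get
#' `NA` (never selectable); strata empty in the cohort give an `NA` row
#' and are flagged.
#'
#' @param cohort the observed cohort.
#' @param synds named list of synthetic datasets (in selection-priority
#'   order; ties in later selection break toward earlier names).
#' @param t_star integration horizon (default 10).
#' @param by grouping variables, as in [partition_cohort()].
#' @return object of class `score_matrix`: `scores` (L x M matrix),
#'   `selection` (see [ibs_selection()]), `empty_cohort_strata`.
#' @export
score_matrix <- function(cohort, synds, t_star = 10L,
                         by = c("age_group", "stage")) {
  stopifnot(is.list(synds), length(synds) >= 1L)
  if (is.null(names(synds)))
    names(synds) <- paste0("SynD", seq_along(synds))
  parts_obs <- partition_cohort(cohort, by)
  parts_syn <- lapply(synds, partition_cohort, by = by)
  L <- length(parts_obs); M <- length(synds)
  scores <- matrix(NA_real_, L, M,
                   dimnames = list(names(parts_obs), names(synds)))
  for (l in seq_len(L)) {
    obs <- parts_obs[[l]]
    if (nrow(obs) == 0L) next
    G <- censoring_km(obs, horizon = t_star)
    for (m in seq_len(M)) {
      syn <- parts_syn[[m]][[l]]
      if (nrow(syn) == 0L) next
      pred <- km_estimate(syn, horizon = t_star)
      scores[l, m] <- ibs(obs, pred, t_star = t_star, G = G)
    }
  }
  structure(list(scores = scores,
                 selection = ibs_selection(scores),
                 empty_cohort_strata = attr(parts_obs, "empty")),
            class = "score_matrix")
}

#' Row-wise argmin selection over an IBS matrix
#'
#' For each stratum (row) returns the index of the dataset (column) with
#' the smallest integrated Brier score; ties break toward the first
#' column, rows with no valid entry give `NA`.
#'
#' @param scores numeric matrix (strata x datasets), or a
#'   `score_matrix`.
#' @return named integer vector of selected column indices.
#' @export
ibs_selection <- function(scores) {
  if (inherits(scores, "score_matrix")) scores <- scores$scores
  sel <- apply(scores, 1L, function(r)
    if (all(is.na(r))) NA_integer_ else which.min(r))
  stats::setNames(as.integer(sel), rownames(scores))
}

#' @export
print.score_matrix <- function(x, ...) {
  m <- cbind(as.data.frame(round(x$scores, 4)),
             selected = colnames(x$scores)[x$selection])
  print(m)
  invisible(x)
}

#' Merge the per-stratum winning synthetic subsets
#'
#' Takes, for each stratum, the synthetic dataset selected by the IBS
#' argmin and concatenates the matching subsets into one combined
#' synthetic cohort, with provenance columns `.stratum` and `.model`.
#' Strata empty in the cohort are skipped (and reported via the
#' `skipped_strata` attribute); a non-empty stratum with no valid score
#' is an error.
#'
#' @param scores a `score_matrix` from [score_matrix()].
#' @param synds the same named list of synthetic datasets scored.
#' @param by grouping variables used for the partition.
#' @return combined data.frame; attribute `provenance` maps stratum to
#'   selected model.
#' @export
select_and_merge <- function(scores, synds, by = c("age_group", "stage")) {
  stopifnot(inherits(scores, "score_matrix"))
  parts_syn <- lapply(synds, partition_cohort, by = by)
  sel <- scores$selection
  pieces <- list(); prov <- character(0)
  for (l in seq_along(sel)) {
    stratum <- names(sel)[l]
    if (stratum %in% scores$empty_cohort_strata) next
    if (is.na(sel[l]))
      stop("stratum ", stratum, " has no valid score entry")
    model <- names(synds)[sel[l]]
    piece <- parts_syn[[sel[l]]][[stratum]]
    piece$.stratum <- stratum
    piece$.model <- model
    pieces[[stratum]] <- piece
    prov[stratum] <- model
  }
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  attr(out, "provenance") <- prov
  attr(out, "skipped_strata") <- scores$empty_cohort_strata
  out
}
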