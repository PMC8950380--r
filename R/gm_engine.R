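# Decomposable log-linear graphical models over categorical cohort data.
#
# The model class is restricted to decomposable (chordal) undirected
# graphs so that the maximum-likelihood fit is the fixed point of
# iterative proportional fitting (reached exactly, cliques visited in
# running-intersection order) and so that synthetic records can be drawn
# directly by forward sampling over the junction tree. The hierarchical
# log-linear expansion log p(cell) = alpha + main effects + interactions
# is encoded implicitly by the graph's clique structure: an interaction
# term is present iff its variables form a clique.
#
# Model search is backward stepwise edge elimination from the saturated
# model under the penalized likelihood H(j, k) = -2 logL(j) + k z(j),
# with z(j) the model dimension, or under per-edge likelihood-ratio
# tests (GMTEST). Four standard criteria are exposed: k = 1 (GMK1),
# k = 2 (GMAIC), k = log N (GMBIC), and the test at alpha = 0.05.

MODEL_LABELS <- c("GMK1", "GMTEST", "GMAIC", "GMBIC")

# Canonical level sets for registry variables; other variables fall back
# to their factor levels (or sorted unique values for character columns).
canonical_levels <- function(name, values) {
  known <- list(age_group = AGE_GROUP_LEVELS, stage = STAGE_LEVELS,
                her2 = HER2_LEVELS, adherence = ADHERENCE_LEVELS,
                followup = as.character(1:FOLLOWUP_MAX),
                exitus = EXITUS_LEVELS)
  if (name %in% names(known)) return(known[[name]])
  if (is.factor(values)) return(levels(values))
  sort(unique(as.character(values)))
}

#' Cross-tabulate a cohort into a contingency table
#'
#' Exact cross-tabulation of the listed categorical variables; the cell
#' array's dimension order follows the variable list. Records with a
#' missing value in any listed variable are an error — graphical models
#' are fitted on complete cases only.
#'
#' @param cohort data.frame of categorical columns (cohort or any
#'   fixture with factor/character columns).
#' @param variables character vector of column names to tabulate.
#' @return object of class `contingency_table`: `counts` (array),
#'   `vars`, `levels`, `n`.
#' @export
build_table <- function(cohort, variables) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  miss <- setdiff(variables, names(cohort))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  facs <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (anyNA(x)) stop("missing value in variable '", v,
                       "'; fit on complete cases")
    lv <- canonical_levels(v, x)
    x <- factor(as.character(x), levels = lv)
    if (anyNA(x)) stop("value outside canonical levels in '", v, "'")
    x
  })
  names(facs) <- variables
  counts <- table(facs)
  structure(list(counts = unclass(counts), vars = variables,
                 levels = lapply(facs, levels), n = nrow(cohort)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table:", length(x$vars), "variables,",
      prod(lengths(x$levels)), "cells, N =", x$n, "\n")
  invisible(x)
}

# ---- graph plumbing --------------------------------------------------

# Normalize an edge set to a 2-column character matrix, each row sorted,
# rows ordered lexicographically. `edges` may be a matrix, a list of
# pairs, or NULL/empty for the empty graph.
normalize_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0L)
    return(matrix(character(0), 0L, 2L))
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.character(edges), ncol = 2L)
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

complete_edges <- function(vars) {
  if (length(vars) < 2L) return(matrix(character(0), 0L, 2L))
  normalize_edges(t(utils::combn(sort(vars), 2L)))
}

as_igraph <- function(vars, edges) {
  g <- igraph::make_empty_graph(n = length(vars), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vars)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  g
}

is_decomposable <- function(vars, edges) {
  igraph::is_chordal(as_igraph(vars, edges))$chordal
}

# Junction tree of a chordal graph: maximal cliques ordered so each
# clique's intersection with its predecessors lies in one earlier clique
# (running intersection), with parent links and separators. Deterministic:
# cliques sorted lexicographically, maximum-weight spanning tree by
# Kruskal with lexicographic tie-break.
junction_tree <- function(vars, edges) {
  g <- as_igraph(vars, edges)
  cl <- lapply(igraph::max_cliques(g), function(v) sort(names(v)))
  cl <- cl[order(vapply(cl, paste, "", collapse = "\r"))]
  k <- length(cl)
  if (k == 1L)
    return(list(cliques = cl, parents = 0L,
                separators = list(character(0)), order = 1L))
  pairs <- t(utils::combn(k, 2L))
  w <- apply(pairs, 1L, function(ij)
    length(intersect(cl[[ij[1L]]], cl[[ij[2L]]])))
  ord <- order(-w, pairs[, 1L], pairs[, 2L])
  comp <- seq_len(k)                       # union-find (path-halving-free)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  tree_adj <- vector("list", k)
  taken <- 0L
  for (e in ord) {
    i <- pairs[e, 1L]; j <- pairs[e, 2L]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      comp[ri] <- rj
      tree_adj[[i]] <- c(tree_adj[[i]], j)
      tree_adj[[j]] <- c(tree_adj[[j]], i)
      taken <- taken + 1L
      if (taken == k - 1L) break
    }
  }
  # BFS from clique 1 for a sampling order; separator = overlap with parent.
  parents <- integer(k); order_out <- integer(k)
  seen <- logical(k); queue <- 1L; seen[1L] <- TRUE; pos <- 0L
  while (length(queue)) {
    node <- queue[1L]; queue <- queue[-1L]
    pos <- pos + 1L; order_out[pos] <- node
    nb <- sort(tree_adj[[node]])
    for (m in nb) if (!seen[m]) {
      seen[m] <- TRUE; parents[m] <- node; queue <- c(queue, m)
    }
  }
  separators <- lapply(seq_len(k), function(i)
    if (parents[i] == 0L) character(0)
    else intersect(cl[[i]], cl[[parents[i]]]))
  list(cliques = cl, parents = parents, separators = separators,
       order = order_out)
}

# Model dimension z(j): free parameters of the decomposable model =
# sum over cliques of the clique table size, minus the table size of
# every non-root separator (with multiplicity; an empty separator
# between components counts 1), minus 1 for the sum-to-one constraint.
model_dim <- function(jt, levels) {
  size <- function(vs) if (length(vs) == 0L) 1 else
    prod(lengths(levels[vs]))
  seps <- jt$separators[jt$parents != 0L]
  sum(vapply(jt$cliques, size, 0)) - sum(vapply(seps, size, 0)) - 1
}

# Marginal of an array over a subset of its dimensions, kept as an array
# in the order of `idx`.
marginalize <- function(p, idx) {
  if (length(idx) == 0L) return(sum(p))
  apply(p, idx, sum)
}

# ---- fitting ---------------------------------------------------------

#' Fit a decomposable log-linear model by iterative proportional fitting
#'
#' Scales a uniform start to match every observed clique marginal,
#' cycling over the junction tree's cliques until the fitted joint
#' changes by less than `tol` (visited in running-intersection order,
#' one cycle suffices on decomposable models; further cycles only
#' confirm convergence). Zero observed clique marginals propagate as
#' structural zeros.
#'
#' @param table a `contingency_table` from [build_table()].
#' @param edges edge set of a decomposable undirected graph over the
#'   table's variables (2-column matrix or list of pairs; `NULL` = empty
#'   graph).
#' @param tol IPF convergence tolerance on the joint (default 1e-10).
#' @return object of class `graph_model`: fitted joint `p`, `loglik`,
#'   model dimension `z`, junction tree (`cliques`, `separators`,
#'   `parents`, `order`), `edges`, `vars`, `levels`, `n`.
#' @export
fit_decomposable <- function(table, edges = NULL, tol = 1e-10) {
  stopifnot(inherits(table, "contingency_table"))
  edges <- normalize_edges(edges)
  if (!all(edges %in% table$vars))
    stop("edge endpoints must be table variables")
  if (!is_decomposable(table$vars, edges))
    stop("graph is not decomposable (triangulated); ",
         "triangulate or reject the candidate")
  jt <- junction_tree(table$vars, edges)
  dims <- unname(lengths(table$levels))
  obs <- table$counts / table$n

  p <- array(1 / prod(dims), dim = dims, dimnames = table$levels)
  clique_idx <- lapply(jt$cliques, function(cq) match(cq, table$vars))
  obs_marg <- lapply(clique_idx, function(ix) marginalize(obs, ix))
  visit <- jt$order
  repeat {
    p_old <- p
    for (ci in visit) {
      ix <- clique_idx[[ci]]
      cur <- marginalize(p, ix)
      ratio <- obs_marg[[ci]] / cur
      ratio[!is.finite(ratio)] <- 0      # 0/0: structural zero
      # expand ratio over the full array along dims ix
      perm <- c(ix, setdiff(seq_along(dims), ix))
      full <- array(ratio, dim = dims[perm])
      full <- aperm(full, order(perm))
      p <- p * full
    }
    if (max(abs(p - p_old)) < tol) break
  }

  pos <- table$counts > 0
  loglik <- sum(table$counts[pos] * log(p[pos]))
  z <- model_dim(jt, table$levels)
  structure(list(vars = table$vars, levels = table$levels,
                 edges = edges, cliques = jt$cliques,
                 separators = jt$separators, parents = jt$parents,
                 order = jt$order, p = p, loglik = loglik, z = z,
                 n = table$n, k = NA_real_, criterion = NA_character_),
            class = "graph_model")
}

#' @export
print.graph_model <- function(x, ...) {
  cat("Decomposable graphical model",
      if (!is.na(x$criterion)) paste0("[", x$criterion, "]"), "\n")
  cat("  variables:", paste(x$vars, collapse = ", "), "\n")
  cat("  edges:", nrow(x$edges), " cliques:", length(x$cliques),
      " z:", x$z, " logL:", format(x$loglik), "\n")
  invisible(x)
}

#' Backward stepwise edge elimination
#'
#' Starting from the complete (saturated) graph, repeatedly considers
#' every edge whose deletion keeps the graph decomposable. In penalty
#' mode the edge whose deletion most decreases
#' \eqn{H(j,k) = -2\log L(j) + k\,z(j)} is removed, stopping when no
#' deletion decreases H. In test mode the deletion whose deviance
#' increase is least significant against a chi-square with df equal to
#' the dimension drop is removed, stopping when every remaining deletion
#' is significant at `alpha`. Ties break on the lexicographically
#' smallest edge.
#'
#' @param table a `contingency_table`.
#' @param k penalty factor (use `k = 2` for AIC, `log(N)` for BIC);
#'   exactly one of `k`/`alpha` must be given.
#' @param alpha significance level for test mode.
#' @return the selected `graph_model`, with `k`/`criterion` recorded.
#' @export
stepwise_select <- function(table, k = NULL, alpha = NULL) {
  if (is.null(k) == is.null(alpha))
    stop("give exactly one of 'k' (penalty) or 'alpha' (test)")
  vars <- table$vars
  edges <- complete_edges(vars)
  current <- fit_decomposable(table, edges)
  repeat {
    if (nrow(current$edges) == 0L) break
    cand <- vector("list", nrow(current$edges))
    for (i in seq_len(nrow(current$edges))) {
      reduced <- current$edges[-i, , drop = FALSE]
      if (!is_decomposable(vars, reduced)) next
      cand[[i]] <- fit_decomposable(table, reduced)
    }
    ok <- which(!vapply(cand, is.null, TRUE))
    if (length(ok) == 0L) break
    if (!is.null(k)) {
      # H(cand) - H(current), in difference form so k = Inf and k = 0
      # behave correctly (deviance increase vs penalty saved)
      dH <- vapply(ok, function(i)
        2 * (current$loglik - cand[[i]]$loglik) -
          k * (current$z - cand[[i]]$z), 0)
      best <- ok[which.min(dH)]           # ties: first in lexicographic
      if (min(dH) >= -1e-9) break
    } else {
      pvals <- vapply(ok, function(i) {
        dev <- 2 * (current$loglik - cand[[i]]$loglik)
        df <- current$z - cand[[i]]$z
        stats::pchisq(max(dev, 0), df = df, lower.tail = FALSE)
      }, 0)
      best <- ok[which.max(pvals)]        # ties: first in lexicographic
      if (max(pvals) < alpha) break
    }
    current <- cand[[best]]
  }
  current$k <- if (is.null(k)) NA_real_ else k
  current$alpha <- alpha
  current
}

#' Fit the four standard model-selection criteria
#'
#' Runs [stepwise_select()] under k = 1 (`GMK1`), the per-edge
#' likelihood-ratio test at `alpha` (`GMTEST`), k = 2 (`GMAIC`) and
#' k = log N (`GMBIC`). GMAIC and GMBIC may legitimately coincide.
#'
#' @param table a `contingency_table`.
#' @param alpha significance level for `GMTEST` (default 0.05).
#' @return named list of four `graph_model`s in the order
#'   `GMK1, GMTEST, GMAIC, GMBIC`.
#' @export
fit_four_models <- function(table, alpha = 0.05) {
  models <- list(
    GMK1   = stepwise_select(table, k = 1),
    GMTEST = stepwise_select(table, alpha = alpha),
    GMAIC  = stepwise_select(table, k = 2),
    GMBIC  = stepwise_select(table, k = log(table$n)))
  for (lbl in names(models)) models[[lbl]]$criterion <- lbl
  models
}

# ---- conditioning helpers -------------------------------------------

# Integer cell index (1-based) of each record's configuration over the
# given variables, using the model's level sets. NA if any value missing.
config_key <- function(df, vars, levels) {
  if (length(vars) == 0L) return(rep(1L, nrow(df)))
  key <- rep(1L, nrow(df)); mult <- 1L
  for (v in vars) {
    iv <- match(as.character(df[[v]]), levels[[v]])
    key <- key + (iv - 1L) * mult
    mult <- mult * length(levels[[v]])
  }
  key
}

#' Impute a missing categorical variable from a fitted model
#'
#' For each record with a missing target, draws the target from the
#' model's conditional distribution given the record's other model
#' variables (obtained from the fitted joint by normalization). Records
#' without missingness are untouched. If a record's covariate
#' combination has zero fitted probability the target's marginal is used
#' instead and the fallback is logged in the result's
#' `imputation_fallbacks` attribute.
#'
#' @param cohort data.frame containing all model variables; `target` may
#'   have NAs.
#' @param model a `graph_model` whose variables include `target`.
#' @param target variable to fill (default `"adherence"`).
#' @param seed integer seed.
#' @return the cohort with `target` filled; attributes
#'   `imputed_rows` (indices) and `imputation_fallbacks` (count).
#' @export
impute_missing <- function(cohort, model, target = "adherence", seed = 1L) {
  stopifnot(inherits(model, "graph_model"), target %in% model$vars)
  others <- setdiff(model$vars, target)
  rows <- which(is.na(cohort[[target]]))
  out <- cohort
  attr(out, "imputed_rows") <- rows
  attr(out, "imputation_fallbacks") <- 0L
  if (length(rows) == 0L) return(out)
  for (v in others)
    if (anyNA(cohort[[v]][rows]))
      stop("non-target variable '", v, "' has missing values")

  ti <- match(target, model$vars)
  oi <- match(others, model$vars)
  # conditional table: rows = configs of `others`, cols = target levels
  cond <- marginalize(model$p, c(oi, ti))
  n_other <- prod(lengths(model$levels[others]))
  cond <- matrix(cond, nrow = n_other)
  marg <- colSums(cond); marg <- marg / sum(marg)
  key <- config_key(cohort[rows, , drop = FALSE], others, model$levels)

  set.seed(seed)
  lv <- model$levels[[target]]
  filled <- character(length(rows))
  fallbacks <- 0L
  for (kk in unique(key)) {
    sel <- which(key == kk)
    pr <- cond[kk, ]
    if (sum(pr) <= 0) { pr <- marg; fallbacks <- fallbacks + length(sel) }
    filled[sel] <- lv[sample.int(length(lv), length(sel),
                                 replace = TRUE, prob = pr)]
  }
  x <- as.character(out[[target]])
  x[rows] <- filled
  out[[target]] <- factor(x, levels = canonical_levels(target, out[[target]]))
  attr(out, "imputation_fallbacks") <- fallbacks
  if (fallbacks > 0L)
    message("impute_missing: marginal fallback used for ", fallbacks,
            " record(s) with zero-probability covariate pattern")
  out
}

#' Simulate synthetic records by junction-tree forward sampling
#'
#' Draws `n` records from the fitted joint: the root clique's
#' configuration from its marginal, then each clique in junction-tree
#' order conditional on its separator (already sampled) configuration.
#' Zero-probability separator configurations cannot be reached by
#' construction. If a reference `cohort` is supplied, exact age at
#' diagnosis and calendar year are re-sampled within each record's age
#' group from the cohort's empirical within-group (age, year)
#' distribution, so the synthetic records can be pushed through the
#' life-table machinery.
#'
#' @param model a `graph_model`.
#' @param n number of records (>= 0).
#' @param seed integer seed.
#' @param cohort optional cohort for within-age-group (age_dx, year_dx)
#'   resampling (requires `age_group` among the model variables).
#' @return data.frame of `n` sampled records over the model variables
#'   (factors); plus `id`, `age_dx`, `year_dx` columns when `cohort` is
#'   given.
#' @export
simulate_syn <- function(model, n, seed = 1L, cohort = NULL) {
  stopifnot(inherits(model, "graph_model"))
  if (n < 0) stop("n must be >= 0")
  levels <- model$levels
  out <- lapply(model$vars, function(v)
    factor(character(n), levels = levels[[v]]))
  names(out) <- model$vars
  out <- as.data.frame(out)
  if (n == 0L) {
    if ("followup" %in% names(out)) out$followup <- integer(0)
    if (!is.null(cohort)) { out$id <- character(0)
      out$age_dx <- integer(0); out$year_dx <- integer(0) }
    return(out)
  }

  set.seed(seed)
  assigned <- character(0)
  for (ci in model$order) {
    cq <- model$cliques[[ci]]
    res <- setdiff(cq, assigned)           # variables still to sample
    if (length(res) == 0L) next
    given <- intersect(cq, assigned)       # superset of the separator
    idx_all <- match(c(given, res), model$vars)
    marg <- marginalize(model$p, idx_all)
    n_g <- prod(lengths(levels[given])); if (length(given) == 0L) n_g <- 1L
    n_r <- prod(lengths(levels[res]))
    marg <- matrix(marg, nrow = n_g)       # rows: given-configs
    key <- config_key(out, given, levels)
    draw <- integer(n)
    for (kk in unique(key)) {
      sel <- which(key == kk)
      pr <- marg[kk, ]
      if (sum(pr) <= 0) pr <- colSums(marg)   # unreachable; safety net
      draw[sel] <- sample.int(n_r, length(sel), replace = TRUE, prob = pr)
    }
    # decode the flat residual-config index into the res variables
    rem <- draw - 1L
    for (v in res) {
      lv <- length(levels[[v]])
      out[[v]] <- factor(levels[[v]][(rem %% lv) + 1L],
                         levels = levels[[v]])
      rem <- rem %/% lv
    }
    assigned <- c(assigned, res)
  }

  if ("followup" %in% names(out))        # back to integer years
    out$followup <- as.integer(as.character(out$followup))

  if (!is.null(cohort)) {
    stopifnot("age_group" %in% model$vars)
    out$id <- sprintf("S%07d", seq_len(n))
    out$age_dx <- integer(n); out$year_dx <- integer(n)
    for (ag in levels(out$age_group)) {
      src <- which(cohort$age_group == ag)
      dst <- which(out$age_group == ag)
      if (length(dst) == 0L) next
      if (length(src) == 0L)
        stop("cohort has no records in age group ", ag,
             " to resample ages from")
      pick <- src[sample.int(length(src), length(dst), replace = TRUE)]
      out$age_dx[dst] <- cohort$age_dx[pick]
      out$year_dx[dst] <- cohort$year_dx[pick]
    }
  }
  out
}
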