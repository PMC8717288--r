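# Canonical correspondence analysis (CCA) from first principles: chi-square
# standardized community matrix, row-weighted projection onto the span of the
# environmental predictors, permutation pseudo-F tests, backward elimination
# and per-variable variance shares.

# Design matrix from an environment table: numeric columns as-is, character/
# factor columns expanded to treatment contrasts (topography reference level
# "flat", so a 4-level factor contributes 3 df). Returns the matrix without
# intercept plus the term assignment of each column.
build_design <- function(env, terms) {
  stopifnot(all(terms %in% names(env)))
  df <- env[, terms, drop = FALSE]
  for (v in terms) {
    if (is.character(df[[v]]) || is.factor(df[[v]])) {
      levs <- unique(as.character(df[[v]]))
      ref <- if ("flat" %in% levs) "flat" else levs[1]
      df[[v]] <- factor(df[[v]], levels = c(ref, setdiff(sort(levs), ref)))
    }
  }
  mm <- stats::model.matrix(stats::reformulate(terms), df)
  assign <- attr(mm, "assign")
  list(X = mm[, assign != 0, drop = FALSE], assign = assign[assign != 0],
       labels = terms)
}

# Orthonormal basis (site space, weighted metric) of the centered constraints.
constraint_basis <- function(X, r) {
  if (is.null(X) || ncol(X) == 0) return(matrix(0, length(r), 0))
  Xc <- sweep(X, 2, colSums(X * r))
  Xw <- Xc * sqrt(r)
  sv <- svd(Xw)
  rank <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-9)
  sv$u[, seq_len(rank), drop = FALSE]
}

# Core decomposition given the standardized matrix Q and a constraint basis.
project_inertia <- function(Q, U) {
  if (ncol(U) == 0) return(list(Qhat = Q * 0, ci = 0))
  Qhat <- U %*% crossprod(U, Q)
  list(Qhat = Qhat, ci = sum(Qhat^2))
}

#' Canonical correspondence analysis of an abundance table
#'
#' Correspondence analysis of the site x species table `Y`, constrained to
#' the span of the environmental predictors. With `P = Y / sum(Y)`, row and
#' column masses `r`, `c`, the chi-square standardized matrix is
#' `Q = (P - r c') / sqrt(r c')`; its total sum of squares is the total
#' inertia of the correspondence analysis. The constrained part is the
#' row-weighted projection of `Q` onto the span of the (weighted-centered)
#' predictors; singular values of the projection give the constrained axes,
#' and the residual gives the unconstrained axes. Constrained plus residual
#' inertia equals the total by construction.
#'
#' Rows with zero abundance sum and all-zero species columns are dropped
#' (counts recorded in the result). Collinear predictors trigger a rank
#' warning; the projection then uses the least-norm span.
#'
#' @param Y site x species abundance matrix (non-negative; rownames = site
#'   ids).
#' @param env environment table, one row per site, aligned to `Y` by a
#'   `subplot_id` column when `Y` has rownames, otherwise by position.
#' @param terms predictor column names in `env`; character/factor columns are
#'   expanded to indicator contrasts (reference level `"flat"` for
#'   topography).
#' @return object of class `cca_fit` with eigenvalues (`eig_constrained`,
#'   `eig_unconstrained`), `total_inertia`, `constrained_inertia`,
#'   `proportion_constrained`, site scores (linear-combination and weighted-
#'   average), species scores (scaled by the singular values, "scaling 2"),
#'   biplot scores of the predictors, and the internal pieces reused by
#'   [anova_cca], [backward_select] and [variance_decomposition].
#' @export
fit_cca <- function(Y, env,
                    terms = c("slope_pct", "dist_water_m", "altitude_m",
                              "topography")) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("negative abundances")
  if (sum(Y) <= 0) stop("empty abundance table")
  if (!is.null(rownames(Y)) && "subplot_id" %in% names(env)) {
    idx <- match(rownames(Y), env$subplot_id)
    if (anyNA(idx)) stop("site(s) of Y missing from the environment table")
    env <- env[idx, , drop = FALSE]
  }
  if (nrow(env) != nrow(Y)) stop("Y and env have different numbers of sites")
  keep_r <- rowSums(Y) > 0
  keep_c <- colSums(Y) > 0
  dropped_rows <- sum(!keep_r); dropped_cols <- sum(!keep_c)
  Y <- Y[keep_r, keep_c, drop = FALSE]
  env <- env[keep_r, , drop = FALSE]
  des <- build_design(env, terms)
  X <- des$X
  n <- nrow(Y); m <- ncol(Y)
  tot <- sum(Y); P <- Y / tot
  r <- rowSums(P); cc <- colSums(P)
  E <- r %o% cc
  Q <- (P - E) / sqrt(E)
  total <- sum(Q^2)
  U <- constraint_basis(X, r)
  if (ncol(U) < ncol(X))
    warning("collinear predictors: constraint rank ", ncol(U),
            " < ", ncol(X), " columns; least-norm projection used")
  pr <- project_inertia(Q, U)
  svq <- svd(pr$Qhat)
  tol <- max(svq$d[1], .Machine$double.eps) * 1e-8
  kc <- seq_len(sum(svq$d > tol))
  eig_c <- svq$d[kc]^2
  svr <- svd(Q - pr$Qhat)
  ku <- seq_len(sum(svr$d > max(svr$d[1], .Machine$double.eps) * 1e-8))
  eig_u <- svr$d[ku]^2
  ax <- if (length(kc)) paste0("CCA", seq_along(kc)) else character(0)
  site_lc <- sweep(svq$u[, kc, drop = FALSE], 1, sqrt(r), "/")
  site_wa <- sweep(Q %*% svq$v[, kc, drop = FALSE], 1, sqrt(r), "/")
  species <- sweep(sweep(svq$v[, kc, drop = FALSE], 1, sqrt(cc), "/"),
                   2, svq$d[kc], "*")
  dimnames(site_lc) <- list(rownames(Y), ax)
  dimnames(site_wa) <- list(rownames(Y), ax)
  dimnames(species) <- list(colnames(Y), ax)
  # weighted correlations of predictors with the constrained site axes
  Xc <- sweep(X, 2, colSums(X * r))
  num <- crossprod(Xc * r, site_lc)
  sdx <- sqrt(colSums(r * Xc^2))
  sda <- sqrt(colSums(r * site_lc^2))
  biplot <- num / (sdx %o% sda)
  structure(
    list(eig_constrained = eig_c, eig_unconstrained = eig_u,
         total_inertia = total, constrained_inertia = pr$ci,
         unconstrained_inertia = total - pr$ci,
         proportion_constrained = pr$ci / total,
         site_scores = site_lc, site_scores_wa = site_wa,
         species_scores = species, biplot_scores = biplot,
         terms = terms, assign = des$assign, X = X, r = r, c = cc, Q = Q,
         U = U, rank = ncol(U), n = n, m = m,
         dropped_rows = dropped_rows, dropped_cols = dropped_cols),
    class = "cca_fit")
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf(
    paste0("CCA: %d sites x %d species, %d constraint df\n",
           "  total inertia %.4f, constrained %.4f (%.2f%%)\n"),
    x$n, x$m, x$rank, x$total_inertia, x$constrained_inertia,
    100 * x$proportion_constrained))
  cat("  constrained eigenvalues:",
      paste(signif(x$eig_constrained, 4), collapse = ", "), "\n")
  invisible(x)
}

# refit the projection for a subset of terms on a (possibly permuted) Q
inertia_for_terms <- function(fit, terms, Q = fit$Q) {
  keep <- fit$assign %in% match(terms, fit$terms)
  U <- constraint_basis(fit$X[, keep, drop = FALSE], fit$r)
  project_inertia(Q, U)
}

#' Permutation tests for a CCA fit
#'
#' Pseudo-F statistics with permutation p-values
#' (`p = (1 + exceedances) / (1 + n_perm)`).
#'
#' * `scope = "model"`: overall test,
#'   `F = (CI/q) / (RI/(n-1-q))` with `CI`/`RI` the constrained/residual
#'   inertia and `q` the constraint rank; rows of the predictor matrix are
#'   permuted.
#' * `scope = "margin"`: each term is tested by the inertia it adds to the
#'   model holding all other terms, with rows of the reduced-model residual
#'   of `Q` permuted (reduced-model residual permutation).
#' * `scope = "axes"`: sequential tests of the constrained axes,
#'   `F_k = lambda_k / (RI/(n-1-q))`, against the same permutations as the
#'   model test.
#'
#' @param fit a [fit_cca] result.
#' @param n_perm number of permutations (999 emulates the reference
#'   protocol; < 99 triggers a warning).
#' @param seed integer seed.
#' @param scope `"model"`, `"margin"` or `"axes"`.
#' @return data frame with one row per tested unit: `term`, `df`,
#'   `chi_square` (inertia), `pseudo_F`, `p_perm`.
#' @export
anova_cca <- function(fit, n_perm = 999, seed = NULL,
                      scope = c("model", "margin", "axes")) {
  scope <- match.arg(scope)
  if (n_perm < 99) warning("n_perm < 99: p-values are coarse")
  n <- fit$n; q <- fit$rank
  ri <- fit$unconstrained_inertia
  df_res <- n - 1 - q
  stopifnot(df_res > 0)
  if (scope == "model" || scope == "axes") {
    F_obs <- if (scope == "model") (fit$constrained_inertia / q) / (ri / df_res)
      else fit$eig_constrained / (ri / df_res)
    perm_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        idx <- sample.int(n)
        U <- constraint_basis(fit$X[idx, , drop = FALSE], fit$r)
        pr <- project_inertia(fit$Q, U)
        ri_s <- fit$total_inertia - pr$ci
        if (scope == "model") (pr$ci / q) / (ri_s / df_res)
        else {
          d <- svd(pr$Qhat, nu = 0, nv = 0)$d
          lam <- d[seq_along(fit$eig_constrained)]^2
          lam / (ri_s / df_res)
        }
      }, numeric(if (scope == "model") 1L else length(fit$eig_constrained)))
    })
    perm_stats <- matrix(perm_stats, ncol = n_perm)
    p <- (1 + rowSums(perm_stats >= F_obs)) / (1 + n_perm)
    lab <- if (scope == "model") "Model" else
      paste0("CCA", seq_along(fit$eig_constrained))
    chi <- if (scope == "model") fit$constrained_inertia else fit$eig_constrained
    dfs <- if (scope == "model") q else rep(1L, length(F_obs))
    return(data.frame(term = lab, df = dfs, chi_square = chi,
                      pseudo_F = F_obs, p_perm = p, stringsAsFactors = FALSE))
  }
  # marginal tests
  out <- lapply(fit$terms, function(t) {
    red_terms <- setdiff(fit$terms, t)
    red <- inertia_for_terms(fit, red_terms)
    df_t <- sum(fit$assign == match(t, fit$terms))
    marg <- fit$constrained_inertia - red$ci
    F_obs <- (marg / df_t) / (ri / df_res)
    R <- fit$Q - red$Qhat
    Ured <- constraint_basis(
      fit$X[, fit$assign %in% match(red_terms, fit$terms), drop = FALSE],
      fit$r)
    exceed <- with_seed(if (is.null(seed)) NULL else
      sub_seed(seed, "margin", t), {
        sum(vapply(seq_len(n_perm), function(k) {
          Qs <- red$Qhat + R[sample.int(n), , drop = FALSE]
          ci_full <- project_inertia(Qs, fit$U)$ci
          ci_red <- project_inertia(Qs, Ured)$ci
          ri_s <- sum(Qs^2) - ci_full
          ((ci_full - ci_red) / df_t) / (ri_s / df_res) >= F_obs
        }, logical(1)))
      })
    data.frame(term = t, df = df_t, chi_square = marg, pseudo_F = F_obs,
               p_perm = (1 + exceed) / (1 + n_perm), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# AIC analog for a constrained ordination: deviance-style
# n * log(residual inertia / n) + 2 * (1 + rank of constraints)
cca_aic <- function(fit) {
  fit$n * log(fit$unconstrained_inertia / fit$n) + 2 * (1 + fit$rank)
}

#' Backward elimination of environmental terms by an information criterion
#'
#' Starting from the full model, repeatedly drops the term whose removal most
#' decreases the criterion `n * ln(RI/n) + 2 (1 + q)` (residual inertia `RI`,
#' constraint rank `q`) until no removal improves it. May return the
#' intercept-only model (no terms). The elimination trace is exposed so the
#' selection path can be audited.
#'
#' @inheritParams fit_cca
#' @return list with `terms` (retained), `fit` (the reduced [fit_cca], or
#'   `NULL` when no term survives) and `trace` (data frame of each step's
#'   criterion).
#' @export
backward_select <- function(Y, env,
                            terms = c("slope_pct", "dist_water_m",
                                      "altitude_m", "topography")) {
  stopifnot(length(terms) >= 1)
  current <- terms
  fit <- fit_cca(Y, env, current)
  trace <- data.frame(step = 0L, dropped = NA_character_,
                      n_terms = length(current), aic = cca_aic(fit),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (!length(current)) break
    cand <- vapply(current, function(t) {
      rest <- setdiff(current, t)
      if (!length(rest)) {
        # intercept-only: residual inertia = total inertia, q = 0
        fit$n * log(fit$total_inertia / fit$n) + 2
      } else cca_aic(fit_cca(Y, env, rest))
    }, numeric(1))
    best <- which.min(cand)
    if (cand[best] >= utils::tail(trace$aic, 1)) break
    step <- step + 1L
    dropped <- current[best]
    current <- setdiff(current, dropped)
    fit <- if (length(current)) fit_cca(Y, env, current) else NULL
    trace <- rbind(trace, data.frame(
      step = step, dropped = dropped, n_terms = length(current),
      aic = cand[best], stringsAsFactors = FALSE))
    if (!length(current)) break
  }
  list(terms = current, fit = fit, trace = trace)
}

#' Per-variable shares of the constrained inertia
#'
#' For each term of a fitted model, the marginal chi-square (inertia the term
#' adds to the model holding all others) and its share of the constrained
#' inertia, both raw and normalized to sum to 100% (with correlated
#' predictors the raw marginal shares need not sum to 100).
#'
#' @param fit a [fit_cca] result.
#' @return data frame `term`, `df`, `chi_square`, `share_raw_pct`,
#'   `share_norm_pct`.
#' @export
variance_decomposition <- function(fit) {
  marg <- vapply(fit$terms, function(t) {
    fit$constrained_inertia - inertia_for_terms(fit, setdiff(fit$terms, t))$ci
  }, numeric(1))
  dfs <- vapply(fit$terms, function(t)
    sum(fit$assign == match(t, fit$terms)), numeric(1))
  data.frame(
    term = fit$terms, df = as.integer(dfs), chi_square = marg,
    share_raw_pct = 100 * marg / fit$constrained_inertia,
    share_norm_pct = if (sum(marg) > 0) 100 * marg / sum(marg) else 0 * marg,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' CCA with and without a focal species
#'
#' Fits the same constrained ordination on the full abundance table and on
#' the table with the focal species' column removed (rows that become empty
#' are re-dropped), and reports how much of the community variation the
#' environment explains in each case. Comparing the two shows how strongly a
#' single environment-affine reference species drives the constrained
#' proportion.
#'
#' @inheritParams fit_cca
#' @param focal species (column) code to remove.
#' @return list with `fit_with`, `fit_without`, `proportion_with`,
#'   `proportion_without`, `delta` (with minus without).
#' @export
compare_with_without <- function(Y, env, focal,
                                 terms = c("slope_pct", "dist_water_m",
                                           "altitude_m", "topography")) {
  Y <- as.matrix(Y)
  if (!focal %in% colnames(Y)) stop("focal species not in the table: ", focal)
  f1 <- fit_cca(Y, env, terms)
  f0 <- fit_cca(Y[, setdiff(colnames(Y), focal), drop = FALSE], env, terms)
  list(fit_with = f1, fit_without = f0,
       proportion_with = f1$proportion_constrained,
       proportion_without = f0$proportion_constrained,
       delta = f1$proportion_constrained - f0$proportion_constrained)
}
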