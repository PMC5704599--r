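#' Collinearity prefilter for explanatory variables
#'
#' Computes all pairwise Pearson correlations and greedily resolves every
#' pair with `|r| >= r_threshold` by keeping the higher-priority member
#' (priority defaults to column order). The full correlation matrix and the
#' flagged pairs are reported alongside the reduced table.
#'
#' @param X Samples x variables numeric data.frame or matrix.
#' @param r_threshold Absolute Pearson correlation threshold (default 0.85).
#' @param keep_priority Character vector of variable names in decreasing
#'   priority; unlisted variables rank below listed ones in column order.
#' @return List with `X` (reduced table), `removed`, `correlations` (full
#'   matrix), and `flagged_pairs` (data.frame var_a, var_b, r).
#' @export
collinearity_prefilter <- function(X, r_threshold = 0.85,
                                   keep_priority = colnames(X)) {
  X <- as.data.frame(X)
  stopifnot(all(vapply(X, is.numeric, logical(1))))
  vars <- colnames(X)
  R <- stats::cor(as.matrix(X))
  prio <- match(vars, keep_priority)
  prio[is.na(prio)] <- length(keep_priority) + match(vars, vars)[is.na(prio)]
  flagged <- NULL
  for (i in seq_along(vars)) for (j in seq_along(vars)) if (j > i) {
    if (is.finite(R[i, j]) && abs(R[i, j]) >= r_threshold)
      flagged <- rbind(flagged, data.frame(var_a = vars[i], var_b = vars[j],
                                           r = R[i, j], stringsAsFactors = FALSE))
  }
  removed <- character(0)
  if (!is.null(flagged)) {
    ## greedy: walk flagged pairs by descending |r|, drop the lower-priority
    ## member of any pair whose both members still survive
    ord <- order(-abs(flagged$r))
    for (k in ord) {
      a <- flagged$var_a[k]; b <- flagged$var_b[k]
      if (a %in% removed || b %in% removed) next
      drop <- if (prio[match(a, vars)] <= prio[match(b, vars)]) b else a
      removed <- c(removed, drop)
    }
  }
  list(X = X[, setdiff(vars, removed), drop = FALSE], removed = removed,
       correlations = R, flagged_pairs = flagged)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing variable j on the remaining
#' variables; an exactly collinear variable is reported as `Inf`.
#'
#' @param X Samples x variables numeric table.
#' @return Named numeric vector of VIFs (all 1 for orthogonal columns).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) return(stats::setNames(rep(1, p), colnames(X)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, colnames(X))
}

## shared CAP machinery: PCoA scores with non-negative eigenvalues
pcoa_scores <- function(D) {
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  S <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), sum(keep))
  rownames(S) <- rownames(as.matrix(D))
  S
}

constrained_ss <- function(S, Xc) {
  q <- qr(Xc)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  sum((crossprod(Q, S))^2)
}

#' Constrained analysis of principal coordinates (CAP / db-RDA)
#'
#' Classical PCoA of the distance matrix (Gower centering, axes with
#' non-negative eigenvalues retained) followed by a least-squares projection
#' of the axis scores onto the column space of the centered explanatory
#' table. Constrained inertia is the sum of squares of the projected scores;
#' `F = (SS_constrained / q) / (SS_residual / (n - q - 1))` with `q` the rank
#' of the centered predictors.
#'
#' @param D Distance matrix.
#' @param X Samples x variables numeric table (rows aligned with `D`).
#' @param allow_aliased Keep exactly collinear columns instead of erroring
#'   (their marginal contribution is then zero; default FALSE).
#' @return A `cap_fit` list: `variation_explained`, `F`, `constrained_inertia`,
#'   `total_inertia`, `rank`, `scores` (constrained axis scores), `S` (PCoA
#'   scores), `Xc` (centered predictors).
#' @export
cap_fit <- function(D, X, allow_aliased = FALSE) {
  X <- as.matrix(X)
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(nrow(X) == n)
  if (n <= ncol(X) + 1) stop("need n > number of variables + 1")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  q <- qr(Xc)
  if (q$rank < ncol(Xc) && !allow_aliased) {
    dep <- colnames(Xc)[q$pivot[(q$rank + 1):ncol(Xc)]]
    stop("rank-deficient explanatory table; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  S <- pcoa_scores(D)
  ss_tot <- sum(S^2)
  ss_con <- constrained_ss(S, Xc)
  qr_rank <- q$rank
  Fv <- (ss_con / qr_rank) / ((ss_tot - ss_con) / (n - qr_rank - 1))
  Q <- qr.Q(q)[, seq_len(qr_rank), drop = FALSE]
  fitted <- Q %*% crossprod(Q, S)
  sv <- svd(fitted)
  k <- sum(sv$d > max(sv$d) * 1e-10)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(S)
  structure(list(variation_explained = ss_con / ss_tot, F = Fv,
                 constrained_inertia = ss_con, total_inertia = ss_tot,
                 rank = qr_rank, scores = scores, S = S, Xc = Xc,
                 n = n), class = "cap_fit")
}

#' @export
print.cap_fit <- function(x, ...) {
  cat(sprintf("cap_fit: variation explained = %.1f%% (F = %.3f, q = %d, n = %d)\n",
              100 * x$variation_explained, x$F, x$rank, x$n))
  invisible(x)
}

#' Permutation tests for a CAP model
#'
#' The overall test permutes the rows of the explanatory table and
#' recomputes the model F; each marginal test measures the drop in
#' constrained sum of squares when one term is removed, given all others,
#' under the same permutation scheme. P-values follow the plus-one rule, or
#' exhaustive enumeration of row permutations when `exhaustive = TRUE`
#' (`n <= 8`).
#'
#' @param fit A `cap_fit`.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @param marginal Also test each term's marginal effect.
#' @param exhaustive Enumerate all row permutations.
#' @return List with `overall` (F, P) and `marginal` (data.frame term, Df,
#'   F, P), plus `n_perm`.
#' @export
cap_permutation_tests <- function(fit, n_perm = 999, seed = 1L,
                                  marginal = TRUE, exhaustive = FALSE) {
  stopifnot(inherits(fit, "cap_fit"))
  S <- fit$S; Xc <- fit$Xc
  n <- fit$n; q <- fit$rank
  ss_tot <- fit$total_inertia
  vars <- colnames(Xc)

  stats_for <- function(p) {
    Xp <- Xc[p, , drop = FALSE]
    ss_con <- constrained_ss(S, Xp)
    Fov <- (ss_con / q) / ((ss_tot - ss_con) / (n - q - 1))
    Fm <- NULL
    if (marginal && length(vars) > 1) {
      Fm <- vapply(vars, function(v) {
        ss_red <- constrained_ss(S, Xp[, setdiff(vars, v), drop = FALSE])
        (ss_con - ss_red) / ((ss_tot - ss_con) / (n - q - 1))
      }, numeric(1))
    } else if (marginal) {
      Fm <- stats::setNames(Fov, vars)
    }
    c(Fov, Fm)
  }
  obs <- stats_for(seq_len(n))
  as_rows <- function(m) if (is.matrix(m)) t(m) else matrix(m, ncol = 1)
  if (exhaustive) {
    P <- all_permutations(n)
    mat <- as_rows(apply(P, 1, stats_for))
    pv <- colMeans(sweep(mat, 2, obs - 1e-12, ">="))
  } else {
    mat <- withr_seed(seed, as_rows(replicate(n_perm, stats_for(sample.int(n)))))
    pv <- (colSums(sweep(mat, 2, obs - 1e-12, ">=")) + 1) / (n_perm + 1)
  }
  marg <- NULL
  if (marginal)
    marg <- data.frame(term = vars, Df = 1L, F = unname(obs[-1]),
                       P = unname(pv[-1]), stringsAsFactors = FALSE)
  list(overall = list(F = unname(obs[1]), P = unname(pv[1])),
       marginal = marg,
       n_perm = if (exhaustive) factorial(n) else n_perm)
}

#' Backward selection of explanatory variables in a CAP model
#'
#' Repeatedly drops the variable with the largest marginal permutation
#' P-value while that P exceeds `alpha_drop`, refitting after each drop.
#' Stops when all remaining marginal P-values are at or below the threshold
#' or a single variable remains. Deterministic given `seed`.
#'
#' @param D Distance matrix.
#' @param X Samples x variables numeric table.
#' @param alpha_drop Removal threshold on the marginal P (default 0.10).
#' @param n_perm Permutations per marginal test.
#' @param seed Seed.
#' @return List with `selected` (variable names), `X` (reduced table),
#'   `trace` (one row per elimination round), `final_fit`, `final_tests`.
#' @export
backward_select <- function(D, X, alpha_drop = 0.10, n_perm = 199, seed = 1L) {
  X <- as.data.frame(X)
  trace <- NULL
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    fit <- cap_fit(D, X)
    tests <- cap_permutation_tests(fit, n_perm = n_perm,
                                   seed = seed + round_i, marginal = TRUE)
    m <- tests$marginal
    worst <- which.max(m$P)
    trace <- rbind(trace, data.frame(
      round = round_i, n_vars = ncol(X),
      worst_term = m$term[worst], worst_P = m$P[worst],
      dropped = m$P[worst] > alpha_drop && ncol(X) > 1,
      stringsAsFactors = FALSE))
    if (m$P[worst] > alpha_drop && ncol(X) > 1) {
      X <- X[, setdiff(colnames(X), m$term[worst]), drop = FALSE]
    } else break
    if (ncol(X) == 1) {
      ## report the last variable's own test, then stop
      fit <- cap_fit(D, X)
      tests <- cap_permutation_tests(fit, n_perm = n_perm,
                                     seed = seed + round_i + 1L)
      break
    }
  }
  list(selected = colnames(X), X = X, trace = trace, final_fit = fit,
       final_tests = tests)
}

#' Partial least squares regression responder screen
#'
#' NIPALS PLS2 with the explanatory table as predictors (standardized
#' internally) and the feature matrix as the multivariate response block
#' (features centered). For each response, the percentage of its variance
#' explained by the first component is
#' `100 * (1 - SS_resid_1 / SS_total)`; responders are the features above
#' `var_explained_threshold`. Leave-one-out cross-validated RMSEP per
#' component count is reported as a diagnostic.
#'
#' @param Y Feature x sample numeric matrix (normalized abundances).
#' @param X Samples x variables explanatory table.
#' @param n_components Number of components (default `min(n - 1, p)`).
#' @param var_explained_threshold Responder threshold in percent (default
#'   30).
#' @param cross_validate Run leave-one-out CV (default TRUE).
#' @param standardize Standardize predictor columns (default TRUE).
#' @return A `plsr_screen` list: `var_explained_comp1` (per feature, %),
#'   `responders`, `scores`, `loadings`, `weights`, `cv` (RMSEP per
#'   component count or NULL).
#' @export
plsr_screen <- function(Y, X, n_components = NULL,
                        var_explained_threshold = 30,
                        cross_validate = TRUE, standardize = TRUE) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(ncol(Y) == n)
  p <- ncol(X)
  if (is.null(n_components)) n_components <- min(n - 1L, p)
  if (n_components >= n) stop("fewer samples than components")

  fit_pls <- function(Xm, Ym, A) {
    ## Xm: n x p (already centered/scaled), Ym: n x m (centered)
    Ex <- Xm; Fy <- Ym
    Tm <- matrix(0, nrow(Xm), A)
    W <- matrix(0, ncol(Xm), A)
    Pm <- matrix(0, ncol(Xm), A)
    Cm <- matrix(0, ncol(Ym), A)
    for (a in seq_len(A)) {
      u <- Fy[, which.max(apply(Fy, 2, stats::var))]
      if (all(abs(u) < 1e-300)) break
      for (it in 1:500) {
        w <- crossprod(Ex, u); w <- w / sqrt(sum(w^2))
        tt <- Ex %*% w
        cc <- crossprod(Fy, tt) / sum(tt^2)
        u_new <- Fy %*% cc / sum(cc^2)
        if (sqrt(sum((u_new - u)^2)) < 1e-12 * sqrt(sum(u^2))) { u <- u_new; break }
        u <- u_new
      }
      pp <- crossprod(Ex, tt) / sum(tt^2)
      Ex <- Ex - tt %*% t(pp)
      Fy <- Fy - tt %*% t(cc)
      Tm[, a] <- tt; W[, a] <- w; Pm[, a] <- pp; Cm[, a] <- cc
    }
    list(T = Tm, W = W, P = Pm, C = Cm)
  }

  Xs <- scale(X, center = TRUE, scale = standardize)
  ym <- rowMeans(Y)
  Yc <- t(Y - ym)                      # n x m, centered responses
  m <- fit_pls(Xs, Yc, n_components)

  t1 <- m$T[, 1]
  fit1 <- t1 %*% t(m$C[, 1, drop = FALSE])
  ss_tot <- colSums(Yc^2)
  ss_res <- colSums((Yc - fit1)^2)
  ve1 <- ifelse(ss_tot > 0, 100 * (1 - ss_res / ss_tot), NA_real_)
  names(ve1) <- rownames(Y)

  cv <- NULL
  if (cross_validate) {
    press <- matrix(0, n, n_components)
    for (i in seq_len(n)) {
      Xtr <- X[-i, , drop = FALSE]
      ctr <- colMeans(Xtr)
      str_ <- if (standardize) apply(Xtr, 2, stats::sd) else rep(1, p)
      str_[str_ == 0] <- 1
      Xtr_s <- scale(Xtr, center = ctr, scale = str_)
      Ytr <- t(Y[, -i, drop = FALSE] - rowMeans(Y[, -i, drop = FALSE]))
      mi <- fit_pls(Xtr_s, Ytr, n_components)
      xte <- (X[i, ] - ctr) / str_
      yte <- Y[, i] - rowMeans(Y[, -i, drop = FALSE])
      ## accumulate prediction over components via deflation weights
      xres <- xte
      yhat <- rep(0, length(yte))
      for (a in seq_len(n_components)) {
        ta <- sum(xres * mi$W[, a])
        yhat <- yhat + ta * mi$C[, a]
        xres <- xres - ta * mi$P[, a]
        press[i, a] <- mean((yte - yhat)^2)
      }
    }
    cv <- data.frame(n_components = seq_len(n_components),
                     rmsep = sqrt(colMeans(press)))
  }
  structure(list(var_explained_comp1 = ve1,
                 responders = names(ve1)[!is.na(ve1) & ve1 > var_explained_threshold],
                 scores = m$T, loadings = m$P, weights = m$W,
                 y_loadings = m$C, cv = cv,
                 threshold = var_explained_threshold),
            class = "plsr_screen")
}

#' @export
print.plsr_screen <- function(x, ...) {
  cat("plsr_screen:", length(x$var_explained_comp1), "features,",
      length(x$responders), "responders (>", x$threshold,
      "% variance on component 1)\n")
  invisible(x)
}

#' Univariate regression screen of features on explanatory variables
#'
#' Ordinary least squares of each feature on each variable separately;
#' reports slope, t and two-sided P per (feature, variable) pair. Constant
#' features or variables yield `NA` with a reason.
#'
#' @param Y Feature x sample matrix.
#' @param X Samples x variables table.
#' @param features Subset of feature names to screen (default all rows).
#' @param alpha Significance level for the `significant` flag.
#' @return data.frame with `feature`, `variable`, `slope`, `t`, `P`,
#'   `significant`, `note`.
#' @export
univariate_screen <- function(Y, X, features = rownames(Y), alpha = 0.05) {
  Y <- as.matrix(Y)[features, , drop = FALSE]
  X <- as.matrix(X)
  n <- ncol(Y)
  stopifnot(nrow(X) == n, n > 2)
  rows <- vector("list", ncol(X))
  for (k in seq_len(ncol(X))) {
    v <- colnames(X)[k]
    x <- X[, v]
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    yc <- Y - rowMeans(Y)
    syy <- rowSums(yc^2)
    if (sxx == 0) {
      rows[[k]] <- data.frame(feature = rownames(Y), variable = v,
                              slope = NA_real_, t = NA_real_, P = NA_real_,
                              significant = FALSE, note = "constant predictor",
                              stringsAsFactors = FALSE)
      next
    }
    sxy <- as.vector(yc %*% xc)
    b <- sxy / sxx
    ss_res <- pmax(syy - b * sxy, 0)
    se <- sqrt(ss_res / (n - 2) / sxx)
    tv <- ifelse(se == 0, sign(b) * Inf, b / se)
    pv <- 2 * stats::pt(-abs(tv), df = n - 2)
    const <- syy == 0
    rows[[k]] <- data.frame(
      feature = rownames(Y), variable = v,
      slope = ifelse(const, 0, b),
      t = ifelse(const, NA_real_, tv),
      P = ifelse(const, NA_real_, pv),
      significant = !const & is.finite(pv) & pv < alpha,
      note = ifelse(const, "constant response", ""),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
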