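test_that("collinearity prefilter flags the strongly coupled diet covariates", {
  dt <- builtin_diet_table()
  X <- as.data.frame(t(dt[c("TDN", "ADF", "NDF", "Ca", "Fe", "Zn"), ]))
  res <- collinearity_prefilter(X, keep_priority = c("TDN", "Zn"))
  expect_equal(round(res$correlations["TDN", "ADF"], 2), -1.00)
  flagged <- paste(res$flagged_pairs$var_a, res$flagged_pairs$var_b)
  expect_true("TDN ADF" %in% flagged)
  expect_true("TDN" %in% colnames(res$X))
  expect_false("ADF" %in% colnames(res$X))     # lower priority than TDN
  # orthogonal columns: nothing removed
  set.seed(1)
  Xo <- data.frame(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1), c = rnorm(4))
  expect_equal(length(collinearity_prefilter(Xo)$removed), 0)
})

test_that("prefilter matches a brute-force greedy oracle on random tables", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 12
    base <- matrix(rnorm(n * 3), n)
    X <- data.frame(v1 = base[, 1], v2 = base[, 1] + rnorm(n, 0, 0.1),
                    v3 = base[, 2], v4 = base[, 2] * -1 + rnorm(n, 0, 0.2),
                    v5 = base[, 3], v6 = rnorm(n))
    got <- collinearity_prefilter(X, r_threshold = 0.85)
    ## oracle: same greedy walk, literal implementation
    R <- stats::cor(as.matrix(X))
    pairs <- NULL
    for (i in 1:5) for (j in (i + 1):6)
      if (abs(R[i, j]) >= 0.85)
        pairs <- rbind(pairs, data.frame(i = i, j = j, r = abs(R[i, j])))
    removed <- character(0)
    if (!is.null(pairs)) {
      pairs <- pairs[order(-pairs$r), ]
      for (k in seq_len(nrow(pairs))) {
        a <- colnames(X)[pairs$i[k]]; b <- colnames(X)[pairs$j[k]]
        if (a %in% removed || b %in% removed) next
        removed <- c(removed, b)   # column order is the default priority
      }
    }
    expect_setequal(got$removed, removed)
  }
})

test_that("prefilter correlations are invariant to per-diet row replication", {
  dt <- builtin_diet_table()
  X4 <- as.data.frame(t(dt[c("TDN", "ADF", "NDF", "Zn"), ]))
  X20 <- X4[rep(1:4, each = 5), ]
  expect_equal(collinearity_prefilter(X4)$correlations,
               collinearity_prefilter(X20)$correlations, tolerance = 1e-12)
})

test_that("vif matches closed forms and flags exact collinearity", {
  X <- data.frame(a = c(1, -1, 1, -1, 0), b = c(1, 1, -1, -1, 0),
                  c = c(0, 0, 0, 0, 1))
  v <- vif(scale(X, scale = FALSE))
  expect_equal(unname(v["a"]), 1, tolerance = 1e-8)
  Xd <- data.frame(a = rnorm(6), b = rnorm(6))
  Xd$c <- Xd$a
  expect_equal(unname(vif(Xd)["c"]), Inf)
  # 3-variable hand oracle
  set.seed(4)
  X3 <- data.frame(x = rnorm(10), y = rnorm(10))
  X3$z <- 0.8 * X3$x + rnorm(10, 0, 0.5)
  r2 <- summary(stats::lm(z ~ x + y, data = X3))$r.squared
  expect_equal(unname(vif(X3)["z"]), 1 / (1 - r2), tolerance = 1e-8)
})

test_that("cap_fit limits: saturated and orthogonal predictors", {
  set.seed(3)
  n <- 8
  # Euclidean distances from 3-d coordinates: predictors spanning those
  # coordinates explain everything
  coords <- matrix(rnorm(n * 3), n)
  D <- as.matrix(stats::dist(coords))
  colnames(D) <- rownames(D) <- sprintf("s%d", 1:n)
  fit <- cap_fit(D, coords)
  expect_equal(fit$variation_explained, 1, tolerance = 1e-8)
  # low-rank Euclidean input: a predictor orthogonal to the coordinate
  # space explains ~ nothing
  S <- rumivir:::pcoa_scores(D)
  x_orth <- stats::residuals(stats::lm(rnorm(n) ~ S))
  f0 <- cap_fit(D, cbind(v = x_orth))
  expect_lt(f0$variation_explained, 1e-8)
  # rank-deficient X errors with the offending column
  Xbad <- data.frame(a = rnorm(n), b = rnorm(n))
  Xbad$c <- Xbad$a + Xbad$b
  expect_error(cap_fit(D, Xbad), "rank-deficient")
})

test_that("cap_fit equals a redundancy-analysis oracle on Euclidean input", {
  set.seed(11)
  n <- 15
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b")))
  coords <- cbind(X %*% c(1, 2), X %*% c(-1, 0.5)) + matrix(rnorm(n * 2, 0, 0.4), n)
  D <- as.matrix(stats::dist(coords))
  fit <- cap_fit(D, X)
  ## RDA on the raw coordinates: projection of centered coordinates onto X
  Yc <- scale(coords, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  expect_equal(fit$variation_explained, sum((H %*% Yc)^2) / sum(Yc^2),
               tolerance = 1e-8)
})

test_that("cap_fit increases constrained inertia monotonically in variables", {
  set.seed(12)
  n <- 12
  Y <- matrix(rpois(25 * n, 8), 25, n, dimnames = list(NULL, sprintf("s%d", 1:n)))
  D <- bray_curtis(Y)
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  ss <- sapply(1:3, function(k) cap_fit(D, X[, 1:k, drop = FALSE])$constrained_inertia)
  expect_true(all(diff(ss) >= -1e-10))
  expect_true(all(sapply(1:3, function(k)
    cap_fit(D, X[, 1:k, drop = FALSE])$variation_explained) <= 1))
})

test_that("cap permutation tests: exhaustive enumeration and duplicate terms", {
  set.seed(13)
  n <- 6
  Y <- matrix(rpois(12 * n, 10), 12, n, dimnames = list(NULL, sprintf("s%d", 1:n)))
  D <- bray_curtis(Y)
  X <- cbind(v = rnorm(n))
  fit <- cap_fit(D, X)
  pe <- cap_permutation_tests(fit, exhaustive = TRUE)
  ## brute-force oracle over all row permutations
  S <- rumivir:::pcoa_scores(D)
  Xc <- scale(X, scale = FALSE)
  sstot <- sum(S^2)
  fof <- function(p) {
    Xp <- Xc[p, , drop = FALSE]
    ssc <- sum((Xp %*% solve(crossprod(Xp)) %*% crossprod(Xp, S))^2)
    ssc / ((sstot - ssc) / (n - 2))
  }
  perms <- rumivir:::all_permutations(n)
  Fall <- apply(perms, 1, fof)
  expect_equal(pe$overall$P, mean(Fall >= fof(seq_len(n)) - 1e-12))
  ## an exactly duplicated term has zero marginal F (no unique contribution)
  X2 <- cbind(a = rnorm(12), b = 0)
  X2[, "b"] <- X2[, "a"]
  Y2 <- matrix(rpois(20 * 12, 10), 20, 12, dimnames = list(NULL, sprintf("s%d", 1:12)))
  f2 <- cap_fit(bray_curtis(Y2), X2, allow_aliased = TRUE)
  m2 <- cap_permutation_tests(f2, n_perm = 49, seed = 1)
  expect_true(all(abs(m2$marginal$F) < 1e-8))
})

test_that("cap_permutation_tests agrees with vegan's marginal F", {
  skip_if_not_installed("vegan")
  set.seed(5)
  n <- 20
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  Y <- matrix(rpois(40 * n, 15), 40, n, dimnames = list(NULL, sprintf("s%d", 1:n)))
  D <- bray_curtis(Y)
  fit <- cap_fit(D, X)
  tests <- cap_permutation_tests(fit, n_perm = 99, seed = 2)
  cs <- vegan::capscale(stats::as.dist(D) ~ a + b + c, data = X)
  am <- stats::anova(cs, by = "margin", permutations = 99)
  expect_equal(tests$marginal$F, am$F[1:3], tolerance = 1e-8)
  ao <- stats::anova(cs, permutations = 99)
  expect_equal(tests$overall$F, ao$F[1], tolerance = 1e-8)
})

test_that("backward selection honours the drop rule and its limits", {
  set.seed(21)
  n <- 20
  driver <- rnorm(n)
  Y <- matrix(rpois(30 * n, exp(2 + outer(rnorm(30), driver))), 30, n,
              dimnames = list(NULL, sprintf("s%d", 1:n)))
  D <- bray_curtis(Y)
  X <- data.frame(driver = driver, noise1 = rnorm(n), noise2 = rnorm(n))
  sel <- backward_select(D, X, n_perm = 99, seed = 4)
  expect_true("driver" %in% sel$selected)
  # trace never drops a variable whose current marginal P <= alpha
  dropped_rows <- sel$trace[sel$trace$dropped, ]
  expect_true(all(dropped_rows$worst_P > 0.10))
  # alpha_drop = 1 is a no-op: permutation P never exceeds 1, so the
  # strict "P > alpha" rule removes nothing (documented degenerate limit)
  sel1 <- backward_select(D, X, alpha_drop = 1, n_perm = 19, seed = 1)
  expect_equal(length(sel1$selected), 3)
})

test_that("plsr_screen reduces to OLS with one predictor", {
  set.seed(30)
  x <- rnorm(14)
  y <- 3 * x + rnorm(14, 0, 0.3)
  sc <- plsr_screen(rbind(f = y), cbind(v = x), n_components = 1)
  expect_equal(unname(sc$var_explained_comp1["f"]),
               100 * summary(stats::lm(y ~ x))$r.squared, tolerance = 1e-8)
  # noiseless proportional response: exactly 100%
  sc2 <- plsr_screen(rbind(f = 2 * x), cbind(v = x), n_components = 1,
                     cross_validate = FALSE)
  expect_equal(unname(sc2$var_explained_comp1["f"]), 100)
  expect_equal(sc2$responders, "f")
  # permuted response explains ~ nothing on average
  r2s <- replicate(50, {
    yp <- sample(y)
    unname(plsr_screen(rbind(f = yp), cbind(v = x), n_components = 1,
                       cross_validate = FALSE)$var_explained_comp1)
  })
  expect_lt(mean(r2s), 25)
  expect_error(plsr_screen(rbind(f = y), cbind(v = x), n_components = 14),
               "fewer samples")
})

test_that("univariate screen matches the closed-form simple regression", {
  set.seed(31)
  n <- 10
  x <- rnorm(n)
  Y <- rbind(lin = x, noisy = 2 * x + rnorm(n), const = rep(1, n))
  colnames(Y) <- sprintf("s%d", 1:n)
  out <- univariate_screen(Y, cbind(v = x))
  lin <- out[out$feature == "lin", ]
  expect_equal(lin$slope, 1)
  expect_gt(lin$t, 1e6)   # numerically exact fit
  expect_lt(lin$P, 1e-10)
  noisy <- out[out$feature == "noisy", ]
  f <- summary(stats::lm(Y["noisy", ] ~ x))$coefficients
  expect_equal(noisy$slope, f[2, 1], tolerance = 1e-10)
  expect_equal(noisy$t, f[2, 3], tolerance = 1e-10)
  expect_equal(noisy$P, f[2, 4], tolerance = 1e-10)
  cst <- out[out$feature == "const", ]
  expect_equal(cst$slope, 0)
  expect_true(is.na(cst$P))
  expect_equal(cst$note, "constant response")
})
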