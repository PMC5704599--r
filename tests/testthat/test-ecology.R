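test_that("chao1 matches hand evaluation of both variants", {
  expect_equal(chao1(c(5, 1, 1, 2)), 4.5)
  expect_equal(chao1(c(5, 5, 3)), 3)                       # no singletons
  x <- c(1, 1, 1, 2, 2, 4)
  expect_equal(chao1(x, bias_corrected = FALSE), 6 + 9 / 4)
  expect_gte(chao1(x), sum(x > 0))
})

test_that("shannon follows the entropy closed forms", {
  expect_equal(shannon(c(1, 1)), 1)
  expect_equal(shannon(c(7)), 0)
  expect_equal(shannon(rep(3, 16)), 4)                     # uniform: log2 S
  expect_equal(shannon(c(1, 1), log_base = exp(1)), log(2))
})

test_that("rarefaction identities hold", {
  x <- c(a = 5, b = 3, c = 0, d = 2)
  expect_equal(rarefy_counts(x, 10, seed = 1), x)          # depth = total
  one <- rarefy_counts(x, 1, seed = 2)
  expect_equal(sum(one), 1)
  expect_equal(sum(one > 0), 1)
  expect_error(rarefy_counts(x, 11), "exceeds")
  for (s in 1:5) expect_equal(sum(rarefy_counts(x, 6, seed = s)), 6)
})

test_that("expected rarefied richness matches the hypergeometric closed form", {
  x <- c(50, 20, 5, 2, 1, 1, 0, 30)
  d <- 30
  N <- sum(x)
  closed <- sum(1 - choose(N - x, d) / choose(N, d))
  set.seed(4)
  emp <- mean(replicate(500, sum(rarefy_counts(x, d) > 0)))
  expect_lt(abs(emp - closed), 4 * sqrt(1.5 / 500) + 0.15) # Monte-Carlo slack
})

test_that("bray_curtis matches hand arithmetic and bounds", {
  m <- cbind(a = c(2, 2), b = c(1, 3), c = c(0, 5), d = c(4, 0))
  D <- bray_curtis(m)
  expect_equal(D["a", "b"], 0.25)
  expect_equal(D["c", "d"], 1)                             # disjoint supports
  expect_equal(diag(D), c(a = 0, b = 0, c = 0, d = 0))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
})

test_that("weighted UniFrac hand cases and star-tree closed form", {
  # two-leaf tree, branch lengths 1 and 1: disjoint samples at raw distance 2
  tr2 <- ape::read.tree(text = "(t1:1,t2:1);")
  tab <- matrix(c(10, 0, 0, 7), 2, 2, dimnames = list(c("t1", "t2"), c("A", "B")))
  D <- weighted_unifrac(tab, tr2)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "A"], 0)
  # star tree with equal branch lengths b: weighted L1 closed form
  set.seed(6)
  ntip <- 6
  star <- ape::stree(ntip, type = "star")
  star$edge.length <- rep(0.7, ntip)
  star$tip.label <- sprintf("t%d", 1:ntip)
  tab2 <- matrix(rpois(ntip * 2, 20) + 1, ntip, 2,
                 dimnames = list(star$tip.label, c("A", "B")))
  p <- sweep(tab2, 2, colSums(tab2), "/")
  expect_equal(weighted_unifrac(tab2, star)["A", "B"],
               0.7 * sum(abs(p[, 1] - p[, 2])))
  # normalized form of the two-leaf case is 1 (maximal separation)
  expect_equal(weighted_unifrac(tab, tr2, normalized = TRUE)["A", "B"], 1)
})

test_that("permanova partitions variance and matches perfect separation", {
  # two tight groups: factor explains everything
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- D[3, 4] <- D[4, 3] <- 0
  colnames(D) <- rownames(D) <- sprintf("s%d", 1:4)
  g <- data.frame(grp = c("a", "a", "b", "b"))
  pt <- permanova(D, g, terms = "grp", n_perm = 99, seed = 1)
  expect_equal(pt$R2[1], 1)
  expect_equal(pt$F[1], Inf)
  # R2 rows always sum to one
  set.seed(2)
  Y <- matrix(rpois(30 * 12, 10), 30, 12, dimnames = list(NULL, sprintf("s%d", 1:12)))
  g2 <- data.frame(x = rep(c("a", "b", "c"), 4), y = rep(c("u", "v"), 6))
  pt2 <- permanova(bray_curtis(Y), g2, terms = c("x", "y"), n_perm = 49, seed = 1)
  expect_equal(sum(pt2$R2[1:3]), 1)
  expect_true(all(pt2$P[1:2] > 0))
  # confounded model errors
  g3 <- data.frame(x = sprintf("lvl%d", 1:12))
  expect_error(permanova(bray_curtis(Y), g3, terms = "x"), "confounded")
})

test_that("permanova P equals exhaustive enumeration for small n", {
  for (seed in 1:5) {
    set.seed(seed)
    Y <- matrix(rpois(8 * 6, 15), 8, 6, dimnames = list(NULL, sprintf("s%d", 1:6)))
    D <- bray_curtis(Y)
    labels <- c("a", "a", "a", "b", "b", "b")
    pe <- permanova(D, data.frame(grp = labels), terms = "grp",
                    exhaustive = TRUE)
    perms <- rumivir:::all_permutations(6)
    Fobs <- oracle_permanova_F(D, labels)
    Fall <- apply(perms, 1, function(p) oracle_permanova_F(D, labels[p]))
    expect_equal(pe$P[1], mean(Fall >= Fobs - 1e-12))
  }
})

test_that("permanova agrees with vegan::adonis2 on sums of squares and F", {
  skip_if_not_installed("vegan")
  des <- default_design()
  set.seed(7)
  Y <- matrix(rpois(50 * 20, 30), 50, 20,
              dimnames = list(NULL, des$samples$sample_id))
  D <- bray_curtis(Y)
  pt <- permanova(D, des, n_perm = 99, seed = 3)
  df <- des$samples
  df$period <- factor(df$period)
  va <- vegan::adonis2(stats::as.dist(D) ~ steer + period + diet, data = df,
                       permutations = 99, by = "terms")
  expect_equal(pt$SumOfSqs[1:4], va$SumOfSqs[1:4], tolerance = 1e-10)
  expect_equal(pt$F[1:3], va$F[1:3], tolerance = 1e-10)
})

test_that("dispersion test: symmetry, degeneracy and the geometry oracle", {
  # mirror-image configurations disperse equally
  set.seed(10)
  a <- matrix(rnorm(16, sd = 2), 8)
  pts <- rbind(a, -a)
  D <- as.matrix(stats::dist(pts))
  colnames(D) <- rownames(D) <- sprintf("s%d", 1:16)
  dt <- dispersion_test(D, rep(c("x", "y"), each = 8))
  expect_equal(unname(dt$group_dispersions["x"]),
               unname(dt$group_dispersions["y"]), tolerance = 1e-6)
  expect_lt(dt$F, 1e-6)
  # identical points: zero dispersion
  D0 <- matrix(0, 4, 4, dimnames = list(sprintf("s%d", 1:4), sprintf("s%d", 1:4)))
  d0 <- dispersion_test(D0, c("g", "g", "h", "h"))
  expect_equal(as.numeric(d0$group_dispersions), c(0, 0))
  expect_equal(d0$P, 1)
  # Euclidean input: distances to spatial median match direct geometry
  set.seed(9)
  p2 <- matrix(rnorm(16 * 3), 16)
  D2 <- as.matrix(stats::dist(p2))
  colnames(D2) <- rownames(D2) <- sprintf("s%d", 1:16)
  g <- rep(c("x", "y"), each = 8)
  got <- dispersion_test(D2, g)$distances
  sm <- function(X) {
    m <- colMeans(X)
    for (i in 1:500) {
      dd <- sqrt(rowSums(sweep(X, 2, m)^2))
      w <- 1 / pmax(dd, 1e-8)
      m2 <- colSums(X * w) / sum(w)
      if (sqrt(sum((m2 - m)^2)) < 1e-8) return(m2)
      m <- m2
    }
    m
  }
  want <- numeric(16)
  for (gg in c("x", "y")) {
    i <- which(g == gg)
    m <- sm(p2[i, ])
    want[i] <- sqrt(rowSums(sweep(p2[i, ], 2, m)^2))
  }
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("intra-group contrast has the stated sign convention and oracle", {
  # intra-diet 0, intra-steer 1: grouping_a (steer) distances larger -> t > 0
  D <- matrix(1, 8, 8) - diag(8)
  colnames(D) <- rownames(D) <- sprintf("s%d", 1:8)
  diet <- rep(c("d1", "d2", "d3", "d4"), 2)
  steer <- rep(c("A", "B"), each = 4)
  for (dd in unique(diet)) {
    i <- which(diet == dd)
    D[i, i] <- 0
  }
  res <- intra_group_contrast(D, steer, diet)
  expect_gt(res$t, 0)
  expect_lt(res$P, 0.01)
  # all-equal distances: t = 0, P = 1
  De <- matrix(0.4, 6, 6) - 0.4 * diag(6)
  colnames(De) <- rownames(De) <- sprintf("s%d", 1:6)
  r0 <- intra_group_contrast(De, rep(c("a", "b"), 3), rep(c("u", "v"), each = 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$P, 1)
  # textbook Welch formula oracle on a toy matrix
  set.seed(5)
  Dt <- as.matrix(stats::dist(matrix(rnorm(12), 6)))
  colnames(Dt) <- rownames(Dt) <- sprintf("s%d", 1:6)
  ga <- c("p", "p", "p", "q", "q", "q")
  gb <- c("m", "n", "m", "n", "m", "n")
  res2 <- intra_group_contrast(Dt, ga, gb)
  wa <- c(Dt[1, 2], Dt[1, 3], Dt[2, 3], Dt[4, 5], Dt[4, 6], Dt[5, 6])
  wb <- c(Dt[1, 3], Dt[1, 5], Dt[3, 5], Dt[2, 4], Dt[2, 6], Dt[4, 6])
  tt <- (mean(wa) - mean(wb)) /
    sqrt(stats::var(wa) / 6 + stats::var(wb) / 6)
  expect_equal(res2$t, tt, tolerance = 1e-10)
})

test_that("alpha_anova: degenerate response, planted effect, orthogonality", {
  des <- default_design()
  # constant response: all F = 0
  r <- alpha_anova(rep(3.2, 20), des)
  expect_true(all(r$anova$F[1:3] == 0))
  expect_true(all(r$pairwise$t == 0))
  # planted diet shift far above noise is detected
  set.seed(2)
  shift <- ifelse(des$samples$diet == "55CS", 5, 0)
  y <- shift + rnorm(20, sd = 0.1)
  r2 <- alpha_anova(y, des)
  expect_lt(r2$anova$P[r2$anova$term == "diet"], 0.05)
  # balanced factors (Latin square): Type-I SS invariant to term order
  d4 <- make_crossover_design(4, 4, c("A", "B", "C", "D"), seed = 3,
                              diet_table = NULL)
  y4 <- rnorm(16)
  a1 <- alpha_anova(y4, d4, terms = c("steer", "period", "diet"))$anova
  a2 <- alpha_anova(y4, d4, terms = c("diet", "period", "steer"))$anova
  expect_equal(sort(a1$SumSq[1:3]),
               sort(a2$SumSq[1:3]), tolerance = 1e-8)
})
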