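#' Chao1 richness estimate
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where F1 and F2
#' are the singleton and doubleton counts; the classic form
#' `S_obs + F1^2 / (2 F2)` is available with `bias_corrected = FALSE` (it
#' falls back to the corrected form when F2 = 0).
#'
#' @param x Integer count vector for one sample.
#' @param bias_corrected Use the bias-corrected estimator (default).
#' @return Estimated richness (never below observed richness).
#' @export
#' @examples
#' chao1(c(5, 1, 1, 2))  # 4.5
chao1 <- function(x, bias_corrected = TRUE) {
  x <- x[x > 0]
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (bias_corrected || f2 == 0) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else s_obs + f1^2 / (2 * f2)
}

#' Shannon diversity index
#'
#' `-sum(p_i log_b p_i)` over nonzero proportions; base 2 by default.
#'
#' @param x Count (or proportion) vector for one sample.
#' @param log_base Logarithm base (2 default; use `exp(1)` for nats).
#' @return Shannon diversity.
#' @export
shannon <- function(x, log_base = 2) {
  p <- x[x > 0]
  p <- p / sum(p)
  -sum(p * log(p, base = log_base))
}

#' Rarefy one sample to a fixed depth
#'
#' Subsamples reads without replacement so the returned counts sum exactly
#' to `depth`.
#'
#' @param x Integer count vector.
#' @param depth Target depth; must not exceed `sum(x)`.
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return Integer vector of the same length and names as `x`.
#' @export
rarefy_counts <- function(x, depth, seed = NULL) {
  total <- sum(x)
  if (depth > total) stop("depth exceeds sample total")
  draw <- function() {
    picked <- sample.int(total, depth)
    breaks <- c(0, cumsum(x))
    tab <- tabulate(findInterval(picked, breaks, left.open = TRUE),
                    nbins = length(x))
    stats::setNames(as.integer(tab), names(x))
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Rarefaction curve of mean richness and diversity
#'
#' Repeatedly subsamples each sample (without replacement) to each depth and
#' averages the Chao1 and Shannon indices over repetitions. Samples shallower
#' than a depth are skipped with a warning.
#'
#' @param counts Feature x sample count matrix.
#' @param depths Numeric vector of depths.
#' @param reps Repetitions per depth.
#' @param seed Seed for the subsampling stream.
#' @return data.frame with `sample_id`, `depth`, `mean_chao1`,
#'   `mean_shannon`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 10, seed = 1L) {
  withr_seed(seed, {
    out <- NULL
    for (j in seq_len(ncol(counts))) {
      x <- counts[, j]
      for (d in depths) {
        if (d > sum(x)) {
          warning("sample ", colnames(counts)[j], " shallower than depth ",
                  d, "; skipped")
          next
        }
        c1 <- s <- numeric(reps)
        for (r in seq_len(reps)) {
          sub <- rarefy_counts(x, d)
          c1[r] <- chao1(sub)
          s[r] <- shannon(sub)
        }
        out <- rbind(out, data.frame(sample_id = colnames(counts)[j],
                                     depth = d, mean_chao1 = mean(c1),
                                     mean_shannon = mean(s),
                                     stringsAsFactors = FALSE))
      }
    }
    out
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` between sample columns; in `[0, 1]`
#' for non-negative input.
#'
#' @param mat Feature x sample matrix (counts or relative abundances).
#' @return Symmetric sample x sample distance matrix with zero diagonal.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(abs(mat[, i] - mat[, j]))
    den <- sum(mat[, i] + mat[, j])
    d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
  }
  d
}

#' Weighted UniFrac distance matrix
#'
#' For each branch of the phylogeny, computes the proportion of each
#' sample's reads descending from that branch; the raw weighted UniFrac
#' distance is `sum(branch_length * |p_A - p_B|)`. The normalized form
#' divides by the abundance-weighted tree depth
#' `sum_tips depth_tip * (p_A_tip + p_B_tip)` (root-to-tip path lengths), so
#' values fall in `[0, 1]`.
#'
#' @param otu_table Feature (tip) x sample count matrix; row names must be
#'   tree tip labels.
#' @param tree An `ape::phylo` tree covering all features.
#' @param normalized Divide by the abundance-weighted tree depth (default
#'   `FALSE`, the raw form).
#' @return Symmetric sample x sample distance matrix.
#' @export
weighted_unifrac <- function(otu_table, tree, normalized = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  otu_table <- as.matrix(otu_table)
  if (!all(rownames(otu_table) %in% tree$tip.label))
    stop("tree tips must cover all features")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  prop <- sweep(otu_table, 2, colSums(otu_table), "/")
  prop[is.nan(prop)] <- 0
  ## accumulate per-node descendant mass in postorder
  mass <- matrix(0, n_node, ncol(otu_table))
  idx <- match(tree$tip.label, rownames(otu_table))
  has <- !is.na(idx)
  mass[which(has), ] <- prop[idx[has], , drop = FALSE]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge)))
    mass[tr$edge[e, 1], ] <- mass[tr$edge[e, 1], ] + mass[tr$edge[e, 2], ]
  ## per-edge mass is the mass of the child node
  edge_mass <- mass[tr$edge[, 2], , drop = FALSE]
  bl <- tr$edge.length
  n <- ncol(otu_table)
  d <- matrix(0, n, n, dimnames = list(colnames(otu_table), colnames(otu_table)))
  depth <- if (normalized) ape::node.depth.edgelength(tree)[seq_len(n_tip)] else NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    raw <- sum(bl * abs(edge_mass[, i] - edge_mass[, j]))
    if (normalized) {
      dn <- sum(depth * (prop[tree$tip.label, i] + prop[tree$tip.label, j]))
      raw <- if (dn == 0) 0 else raw / dn
    }
    d[i, j] <- d[j, i] <- raw
  }
  d
}

validate_distance <- function(D) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < -1e-12)) stop("negative distances")
  D
}

gower_center <- function(D) {
  D <- validate_distance(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# all permutations of 1:n (n small)
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' Gower-centers the squared distances (`G = -1/2 J D^2 J`) and partitions
#' the total sum of squares sequentially (Type I) over the model terms in
#' the given order, via projections onto cumulative model spaces. Pseudo-F
#' per term uses the residual mean square; `R^2 = SS_term / SS_total`.
#' P-values come from freely permuting the rows of the design with the
#' plus-one rule `P = (#\{F* >= F\} + 1) / (n_perm + 1)`, or from exhaustive
#' enumeration of all `n!` row permutations when `exhaustive = TRUE`
#' (then `P = mean(F* >= F)`, the identity included).
#'
#' @param D Distance matrix (or `dist`).
#' @param design A `study_design` or a data.frame of factors, rows aligned
#'   with `D`.
#' @param terms Character vector of term names, in the order sums of squares
#'   are assigned.
#' @param n_perm Number of random permutations.
#' @param seed Seed for the permutation stream.
#' @param exhaustive Enumerate all permutations (requires `n <= 8`).
#' @return A `permanova_table` data.frame: one row per term plus `Residual`
#'   and `Total`, with columns `Df`, `SumOfSqs`, `R2`, `F`, `P`.
#' @export
permanova <- function(D, design, terms = c("steer", "period", "diet"),
                      n_perm = 999, seed = 1L, exhaustive = FALSE) {
  df <- if (inherits(design, "study_design")) design$samples else as.data.frame(design)
  D <- as.matrix(D)
  stopifnot(nrow(df) == nrow(D), all(terms %in% colnames(df)))
  for (t in terms) df[[t]] <- factor(df[[t]])
  n <- nrow(D)
  G <- gower_center(D)
  ss_total <- sum(diag(G))

  ## cumulative hat matrices
  hats <- vector("list", length(terms))
  ranks <- integer(length(terms))
  for (k in seq_along(terms)) {
    fm <- stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = "+")))
    X <- stats::model.matrix(fm, df)
    q <- qr(X)
    ranks[k] <- q$rank
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(Q)
  }
  df_terms <- diff(c(1L, ranks))
  if (any(df_terms == 0))
    stop("confounded terms (zero df): ",
         paste(terms[df_terms == 0], collapse = ", "))
  df_resid <- n - ranks[length(ranks)]
  if (df_resid <= 0)
    stop("confounded terms: model saturates the ", n, " samples (",
         paste(terms, collapse = " + "), ")")

  stat <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))  # tr(H G)
    ss_seq <- diff(c(0, tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    Fv <- (ss_seq / df_terms) / (ss_res / df_resid)
    if (ss_res / df_resid <= 1e-12 * max(1, abs(ss_total) / n))
      Fv <- ifelse(ss_seq > 1e-12, Inf, NaN)
    list(ss = ss_seq, ss_res = ss_res, F = Fv)
  }
  obs <- stat(G)

  perm_F <- function(p) stat(G[p, p])$F
  as_rows <- function(Fs) if (is.matrix(Fs)) t(Fs) else matrix(Fs, ncol = 1)
  if (exhaustive) {
    P <- all_permutations(n)
    Fs <- as_rows(apply(P, 1, perm_F))
    pval <- colMeans(sweep(Fs, 2, obs$F - 1e-12, ">="))
  } else {
    Fs <- withr_seed(seed, as_rows(replicate(n_perm, perm_F(sample.int(n)))))
    pval <- (colSums(sweep(Fs, 2, obs$F - 1e-12, ">=")) + 1) / (n_perm + 1)
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(df_terms, df_resid, n - 1L),
    SumOfSqs = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$F, NA, NA),
    P = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- if (exhaustive) factorial(n) else n_perm
  class(out) <- c("permanova_table", "data.frame")
  out
}

#' Homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by principal coordinates analysis (negative
#' eigenvalues kept on "imaginary" axes whose squared distances subtract),
#' locates each group's spatial median by iterative reweighting (Weiszfeld,
#' tolerance `tol`), and runs a one-way ANOVA on the member-to-median
#' distances.
#'
#' @param D Distance matrix.
#' @param grouping Factor of group labels, aligned with `D`.
#' @param tol Convergence tolerance for the spatial median.
#' @return List with `distances` (per sample), `group_dispersions` (means),
#'   `anova` (the ANOVA table), `F`, `P`.
#' @export
dispersion_test <- function(D, grouping, tol = 1e-8) {
  D <- validate_distance(D)
  grouping <- factor(grouping)
  stopifnot(length(grouping) == nrow(D))
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values)) * 1e-10
  lam <- e$values[keep]
  V <- e$vectors[, keep, drop = FALSE]
  pos <- lam > 0
  Xr <- V[, pos, drop = FALSE] %*% diag(sqrt(lam[pos]), sum(pos))
  Xi <- V[, !pos, drop = FALSE] %*% diag(sqrt(-lam[!pos]), sum(!pos))

  dist_to <- function(X, m) sqrt(rowSums(sweep(X, 2, m)^2))
  spatial_median <- function(X) {
    if (ncol(X) == 0) return(numeric(0))
    m <- colMeans(X)
    for (it in 1:500) {
      d <- dist_to(X, m)
      w <- 1 / pmax(d, tol)
      m_new <- colSums(X * w) / sum(w)
      if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
      m <- m_new
    }
    m
  }
  z <- numeric(nrow(D))
  for (g in levels(grouping)) {
    i <- which(grouping == g)
    mr <- spatial_median(Xr[i, , drop = FALSE])
    mi <- spatial_median(Xi[i, , drop = FALSE])
    dr2 <- if (length(mr)) rowSums(sweep(Xr[i, , drop = FALSE], 2, mr)^2) else 0
    di2 <- if (length(mi)) rowSums(sweep(Xi[i, , drop = FALSE], 2, mi)^2) else 0
    z[i] <- sqrt(pmax(0, dr2 - di2))
  }
  disp <- stats::setNames(as.numeric(tapply(z, grouping, mean)),
                          levels(grouping))
  if (stats::var(z) < 1e-14) {
    Fv <- 0; Pv <- 1
    an <- NULL
  } else {
    an <- stats::anova(stats::lm(z ~ grouping))
    Fv <- an$`F value`[1]; Pv <- an$`Pr(>F)`[1]
  }
  list(distances = z, group_dispersions = disp, anova = an, F = Fv, P = Pv)
}

#' Compare within-group distances between two groupings
#'
#' Collects all within-group pairwise distances under each grouping (for
#' example intra-steer versus intra-diet) and compares the two collections
#' with a two-sample t test. Positive t means grouping-a distances exceed
#' grouping-b distances.
#'
#' @param D Distance matrix.
#' @param grouping_a,grouping_b Factors aligned with `D`.
#' @param pooled Use the pooled-variance t test instead of Welch.
#' @return List with `t`, `P`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
intra_group_contrast <- function(D, grouping_a, grouping_b, pooled = FALSE) {
  D <- validate_distance(D)
  within <- function(g) {
    g <- factor(g)
    out <- numeric(0)
    for (lev in levels(g)) {
      i <- which(g == lev)
      if (length(i) > 1) {
        sub <- D[i, i]
        out <- c(out, sub[lower.tri(sub)])
      }
    }
    out
  }
  a <- within(grouping_a)
  b <- within(grouping_b)
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 within-group pairs per grouping")
  if (stats::sd(a) < 1e-14 && stats::sd(b) < 1e-14) {
    s <- sign(mean(a) - mean(b))
    tt <- list(statistic = c(t = if (s == 0) 0 else s * Inf),
               p.value = if (s == 0) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = pooled)
  }
  list(t = unname(tt$statistic), P = tt$p.value,
       mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b))
}

#' Main-effects ANOVA of an alpha-diversity metric with pairwise diet tests
#'
#' Fits the main-effects-only linear model `metric ~ steer + period + diet`
#' (the crossover design cannot support interactions) and reports the
#' sequential (Type I) ANOVA table in that order, plus unadjusted pairwise
#' t tests between diets.
#'
#' @param metric Numeric vector, one value per sample.
#' @param design `study_design` or data.frame with `steer`, `period`, `diet`.
#' @param terms Term order for the sequential table.
#' @param p_adjust Adjustment method for the pairwise tests (default
#'   `"none"`).
#' @return List with `anova` (data.frame: term, Df, SumSq, F, P) and
#'   `pairwise` (data.frame: diet_a, diet_b, t, P, P_adj).
#' @export
alpha_anova <- function(metric, design, terms = c("steer", "period", "diet"),
                        p_adjust = "none") {
  df <- if (inherits(design, "study_design")) design$samples else as.data.frame(design)
  stopifnot(length(metric) == nrow(df), all(terms %in% colnames(df)))
  for (t in terms) df[[t]] <- factor(df[[t]])
  df$.y <- metric
  fm <- stats::as.formula(paste(".y ~", paste(terms, collapse = "+")))
  fit <- stats::aov(fm, data = df)
  an <- summary(fit)[[1]]
  tab <- data.frame(term = trimws(rownames(an)), Df = an$Df,
                    SumSq = an$`Sum Sq`, F = an$`F value`, P = an$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  if (all(tab$SumSq[tab$term != "Residuals"] < 1e-20)) {
    tab$F[tab$term != "Residuals"] <- 0
    tab$P[tab$term != "Residuals"] <- 1
  }
  diets <- levels(df$diet)
  pw <- NULL
  for (i in seq_along(diets)) for (j in seq_along(diets)) if (j > i) {
    ya <- metric[df$diet == diets[i]]
    yb <- metric[df$diet == diets[j]]
    if (stats::sd(ya) < 1e-14 && stats::sd(yb) < 1e-14 && mean(ya) == mean(yb)) {
      tv <- 0; pv <- 1
    } else {
      tt <- stats::t.test(ya, yb)
      tv <- unname(tt$statistic); pv <- tt$p.value
    }
    pw <- rbind(pw, data.frame(diet_a = diets[i], diet_b = diets[j],
                               t = tv, P = pv, stringsAsFactors = FALSE))
  }
  if (!is.null(pw)) pw$P_adj <- stats::p.adjust(pw$P, method = p_adjust)
  list(anova = tab, pairwise = pw)
}
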