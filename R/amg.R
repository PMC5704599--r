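#' Default pathway rule for Class-I AMG classification
#'
#' KEGG orthologs mapping to pathways whose functions are commonly carried
#' by viral genomes (replication, repair, nucleotide and amino-acid
#' housekeeping) are excluded from the auxiliary metabolic gene (AMG) set,
#' unless the KO is additionally involved in carbon metabolism (ko01200),
#' nitrogen metabolism (ko00910) or the pentose phosphate pathway (ko00030),
#' which rescue it.
#'
#' @return List with `excluded` and `rescue` pathway id vectors (disjoint).
#' @export
default_pathway_rule <- function() {
  rule <- list(
    excluded = c("ko03440", "ko03430", "ko00970", "ko00230", "ko00240",
                 "ko03030", "ko00520", "ko01230", "ko03410", "ko00270",
                 "ko00330"),
    rescue = c("ko01200", "ko00910", "ko00030"))
  stopifnot(length(intersect(rule$excluded, rule$rescue)) == 0)
  rule
}

#' Classify Class-I auxiliary metabolic genes
#'
#' Keeps ORF annotations passing the homology thresholds (E-value at most
#' `max_evalue`, bit-score at least `min_bitscore`) on bona-fide viral
#' contigs strictly longer than `min_contig_length`, then classifies each KO:
#' Class I iff it maps to at least one KEGG metabolic pathway AND NOT
#' (it touches an excluded pathway while touching no rescue pathway).
#' Per-KO abundance is the sum of its surviving ORFs' counts; the number of
#' supporting contigs is reported. KOs absent from the pathway map are
#' listed as unmapped and excluded from classification.
#'
#' @param annotations data.frame with `orf_id`, `contig_id`,
#'   `contig_length`, `viral_bona_fide`, `ko`, `evalue`, `bitscore` and
#'   optionally `aa_length` (ORFs shorter than `min_orf_aa` amino acids are
#'   dropped at read time).
#' @param ko_pathways data.frame with `ko`, `pathway`, `metabolic`.
#' @param orf_counts Optional ORF x sample count matrix for per-KO
#'   abundances.
#' @param rule Pathway rule, as from [default_pathway_rule()].
#' @param min_contig_length Contig length gate in bp (strict, default 1500).
#' @param max_evalue,min_bitscore Homology thresholds.
#' @param min_orf_aa Minimum ORF length in amino acids.
#' @return List with `amg_table` (data.frame `ko`, `n_contigs`, `n_orfs`),
#'   `abundance` (KO x sample matrix or NULL), `unmapped` (KO ids), and
#'   `kept_orfs`.
#' @export
classify_class1 <- function(annotations, ko_pathways, orf_counts = NULL,
                            rule = default_pathway_rule(),
                            min_contig_length = 1500,
                            max_evalue = 1e-5, min_bitscore = 50,
                            min_orf_aa = 60) {
  stopifnot(all(c("orf_id", "contig_id", "contig_length", "viral_bona_fide",
                  "ko", "evalue", "bitscore") %in% colnames(annotations)),
            all(c("ko", "pathway", "metabolic") %in% colnames(ko_pathways)))
  ann <- annotations
  if ("aa_length" %in% colnames(ann)) ann <- ann[ann$aa_length >= min_orf_aa, ]
  ann <- ann[ann$evalue <= max_evalue & ann$bitscore >= min_bitscore &
               ann$viral_bona_fide & ann$contig_length > min_contig_length, ,
             drop = FALSE]
  unmapped <- sort(unique(setdiff(ann$ko, ko_pathways$ko)))
  ann <- ann[ann$ko %in% ko_pathways$ko, , drop = FALSE]

  path_sets <- split(ko_pathways$pathway, ko_pathways$ko)
  meta_sets <- split(ko_pathways$metabolic, ko_pathways$ko)
  kos <- sort(unique(ann$ko))
  is_class1 <- vapply(kos, function(k) {
    p <- path_sets[[k]]
    any(meta_sets[[k]]) &&
      !(length(intersect(p, rule$excluded)) > 0 &&
          length(intersect(p, rule$rescue)) == 0)
  }, logical(1))
  amg_kos <- kos[is_class1]
  keep <- ann[ann$ko %in% amg_kos, , drop = FALSE]
  tab <- if (length(amg_kos)) data.frame(
    ko = amg_kos,
    n_contigs = as.integer(tapply(keep$contig_id, keep$ko,
                                  function(z) length(unique(z)))[amg_kos]),
    n_orfs = as.integer(table(factor(keep$ko, levels = amg_kos))),
    stringsAsFactors = FALSE) else
      data.frame(ko = character(0), n_contigs = integer(0),
                 n_orfs = integer(0), stringsAsFactors = FALSE)
  ab <- NULL
  if (!is.null(orf_counts) && nrow(keep)) {
    missing <- setdiff(keep$orf_id, rownames(orf_counts))
    if (length(missing)) stop("input error: ORFs missing from count matrix")
    ab <- rowsum(orf_counts[keep$orf_id, , drop = FALSE], group = keep$ko)
    ab <- ab[amg_kos, , drop = FALSE]
  }
  list(amg_table = tab, abundance = ab, unmapped = unmapped, kept_orfs = keep)
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over features (with finite
#' geometric mean across samples) of the ratio of the feature's count to its
#' geometric mean. Computed from the full ORF matrix, not from the AMG
#' subset, for more stable normalization.
#'
#' @param orf_counts Feature x sample count matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(orf_counts) {
  m <- as.matrix(orf_counts)
  gm <- exp(rowMeans(log(m)))
  use <- is.finite(gm) & gm > 0
  if (!any(use)) stop("no feature has all-positive counts")
  sf <- apply(m[use, , drop = FALSE] / gm[use], 2, stats::median)
  stats::setNames(sf, colnames(m))
}

#' Negative-binomial Wald test for differential AMG abundance
#'
#' Tests each KO for a difference between two groups on size-factor
#' normalized counts. The dispersion is a per-KO method-of-moments estimate
#' (pooled within groups) moderated by taking the maximum of the KO's own
#' estimate, the across-KO median estimate, and a small floor -- sharing
#' information across features the way shrinkage-based tools do, without
#' reproducing their estimators. The Wald statistic on the log ratio of
#' group means (delta-method standard error) is referred to the standard
#' normal, and P-values are Benjamini-Hochberg adjusted.
#'
#' @param amg_counts KO x sample count matrix.
#' @param sf Per-sample size factors (from [size_factors()] on all ORFs).
#' @param groups Factor (two levels) aligned with the columns.
#' @param fdr FDR threshold for the `significant` flag.
#' @param pseudocount Added to group means before taking logs.
#' @return data.frame with `ko`, `base_mean`, `log2FC`, `stat`, `P`,
#'   `P_adj`, `significant`.
#' @export
diff_test <- function(amg_counts, sf, groups, fdr = 0.05, pseudocount = 0.5) {
  m <- as.matrix(amg_counts)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == ncol(m))
  n_g <- table(groups)
  if (any(n_g < 2)) stop("each group needs at least 2 samples")
  sf <- sf[colnames(m)]
  q <- sweep(m, 2, sf, "/")
  ia <- groups == levels(groups)[1]
  ib <- !ia
  zbar <- mean(1 / sf)                      # Poisson variance correction on the normalized scale
  mA <- rowMeans(q[, ia, drop = FALSE]); mB <- rowMeans(q[, ib, drop = FALSE])
  vA <- apply(q[, ia, drop = FALSE], 1, stats::var)
  vB <- apply(q[, ib, drop = FALSE], 1, stats::var)
  nA <- sum(ia); nB <- sum(ib)
  v_pool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  m_pool <- (nA * mA + nB * mB) / (nA + nB)
  a_own <- (v_pool - m_pool * zbar) / pmax(m_pool, pseudocount)^2
  a_med <- stats::median(a_own[is.finite(a_own)])
  alpha <- pmax(1e-8, a_own, if (is.finite(a_med)) a_med else 0)
  mAp <- mA + pseudocount; mBp <- mB + pseudocount
  se <- sqrt(zbar / (nA * mAp) + alpha / nA + zbar / (nB * mBp) + alpha / nB)
  stat <- (log(mBp) - log(mAp)) / se
  lfc <- (log(mBp) - log(mAp)) / log(2)
  P <- 2 * stats::pnorm(-abs(stat))
  P[vA == 0 & vB == 0 & mA == mB] <- 1
  padj <- stats::p.adjust(P, method = "BH")
  data.frame(ko = rownames(m), base_mean = m_pool, log2FC = lfc, stat = stat,
             P = P, P_adj = padj, significant = padj < fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Prevalence of single-sample AMGs
#'
#' Counts KOs with nonzero abundance in exactly one sample.
#'
#' @param amg_abundance KO x sample abundance matrix.
#' @return List with `n_amgs`, `n_single_sample`, `percentage` (via
#'   [summarize_fraction()]).
#' @export
singleton_prevalence <- function(amg_abundance) {
  m <- as.matrix(amg_abundance)
  n_present <- rowSums(m > 0)
  n_single <- sum(n_present == 1)
  list(n_amgs = nrow(m), n_single_sample = n_single,
       percentage = summarize_fraction(n_single, nrow(m)))
}
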