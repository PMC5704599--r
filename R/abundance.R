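#' Construct an abundance bundle
#'
#' Bundles a raw count matrix (features by samples) with per-sample library
#' sizes and optional per-feature lengths, the inputs of the CPM / CPKM
#' normalizations. Library sizes are the total sequenced reads per sample
#' (not the column sums of the feature matrix, which may cover only part of
#' the library).
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param lib_sizes Named numeric vector of per-sample library sizes; must
#'   cover all columns and be at least the column sums.
#' @param lengths Optional named numeric vector of feature lengths (bp).
#' @return An `abundance_bundle` (list with `counts`, `lib_sizes`, `lengths`,
#'   `normalized`, `normalization`).
#' @export
abundance_bundle <- function(counts, lib_sizes, lengths = NULL) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(names(lib_sizes))) names(lib_sizes) <- colnames(counts)
  if (!all(colnames(counts) %in% names(lib_sizes)))
    stop("lib_sizes must name every sample")
  lib_sizes <- lib_sizes[colnames(counts)]
  if (any(lib_sizes < colSums(counts) - 1e-8))
    stop("library size smaller than the column sum of counts")
  if (!is.null(lengths)) {
    if (is.null(names(lengths))) names(lengths) <- rownames(counts)
    if (!all(rownames(counts) %in% names(lengths)))
      stop("lengths must name every feature")
    lengths <- lengths[rownames(counts)]
    if (any(lengths <= 0)) stop("feature lengths must be positive")
  }
  structure(list(counts = counts, lib_sizes = lib_sizes, lengths = lengths,
                 normalized = NULL, normalization = NULL),
            class = "abundance_bundle")
}

#' @export
print.abundance_bundle <- function(x, ...) {
  cat("abundance_bundle:", nrow(x$counts), "features x", ncol(x$counts),
      "samples")
  if (!is.null(x$normalization)) cat(" |", x$normalization)
  cat("\n")
  invisible(x)
}

#' Sum contig counts into population counts
#'
#' Population abundance is the sum of its member contigs' read counts in
#' each sample.
#'
#' @param contig_counts Contig x sample count matrix.
#' @param populations A `viral_populations` object.
#' @param lib_sizes Per-sample library sizes (defaults to the full contig
#'   matrix column sums).
#' @return An `abundance_bundle` over populations, with lengths set to the
#'   cumulative population lengths.
#' @export
population_counts <- function(contig_counts, populations, lib_sizes = NULL) {
  stopifnot(inherits(populations, "viral_populations"))
  mem <- populations$members
  missing <- setdiff(mem$contig_id, rownames(contig_counts))
  if (length(missing))
    stop("input error: contigs missing from count matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sub <- contig_counts[mem$contig_id, , drop = FALSE]
  agg <- rowsum(sub, group = mem$population_id)
  agg <- agg[populations$populations$population_id, , drop = FALSE]
  if (is.null(lib_sizes)) lib_sizes <- colSums(contig_counts)
  lens <- stats::setNames(populations$populations$cumulative_length,
                          populations$populations$population_id)
  abundance_bundle(agg, lib_sizes, lens)
}

#' Length- and depth-normalized abundance (log2 CPKM)
#'
#' Computes `log2(count / (lib/1e6) / (length/1e3) + pseudocount)`: counts
#' per kilobase of feature per million library reads, then a pseudocount and
#' log2. Scaling a sample's counts and library size jointly leaves values
#' unchanged.
#'
#' @param bundle An `abundance_bundle` with feature lengths.
#' @param pseudocount Added on the CPKM scale before the log (default 1, so
#'   zero counts map to 0).
#' @return The bundle with `normalized` filled in and tag `"log2CPKM"`.
#' @export
normalize_log2cpkm <- function(bundle, pseudocount = 1.0) {
  stopifnot(inherits(bundle, "abundance_bundle"))
  if (is.null(bundle$lengths)) stop("lengths required for CPKM")
  if (any(bundle$lib_sizes == 0)) stop("zero library size")
  cpkm <- sweep(bundle$counts, 2, bundle$lib_sizes / 1e6, "/") /
    (bundle$lengths / 1e3)
  bundle$normalized <- log2(cpkm + pseudocount)
  bundle$normalization <- "log2CPKM"
  bundle
}

#' Depth-normalized abundance (log2 CPM)
#'
#' `log2(count / (lib/1e6) + pseudocount)`; as [normalize_log2cpkm()] without
#' the length division.
#'
#' @inheritParams normalize_log2cpkm
#' @return The bundle with `normalized` filled in and tag `"log2CPM"`.
#' @export
normalize_log2cpm <- function(bundle, pseudocount = 1.0) {
  stopifnot(inherits(bundle, "abundance_bundle"))
  if (any(bundle$lib_sizes == 0)) stop("zero library size")
  cpm <- sweep(bundle$counts, 2, bundle$lib_sizes / 1e6, "/")
  bundle$normalized <- log2(cpm + pseudocount)
  bundle$normalization <- "log2CPM"
  bundle
}

#' Per-sample relative abundance
#'
#' Divides raw counts by the total library size, the presence measure used
#' for protein clusters.
#'
#' @inheritParams normalize_log2cpkm
#' @return The bundle with `normalized` filled in and tag `"relative"`.
#' @export
normalize_relative <- function(bundle) {
  stopifnot(inherits(bundle, "abundance_bundle"))
  if (any(bundle$lib_sizes == 0)) stop("zero library size")
  bundle$normalized <- sweep(bundle$counts, 2, bundle$lib_sizes, "/")
  bundle$normalization <- "relative"
  bundle
}

#' Breadth of coverage per population
#'
#' Breadth is the fraction of a population's cumulative length covered by at
#' least one read: the sum of member-contig covered bases divided by the
#' cumulative length. This is the presence measure behind the core-virome
#' criterion.
#'
#' @param covered_bases Contig x sample matrix of covered base counts.
#' @param populations A `viral_populations` object.
#' @return Population x sample matrix of breadth fractions in `[0, 1]`.
#' @export
breadth <- function(covered_bases, populations) {
  stopifnot(inherits(populations, "viral_populations"))
  mem <- populations$members
  missing <- setdiff(mem$contig_id, rownames(covered_bases))
  if (length(missing)) stop("input error: contigs missing from covered_bases")
  sub <- covered_bases[mem$contig_id, , drop = FALSE]
  if (any(sub > mem$length_bp + 1e-8))
    stop("input error: covered bases exceed contig length")
  agg <- rowsum(sub, group = mem$population_id)
  agg <- agg[populations$populations$population_id, , drop = FALSE]
  b <- agg / populations$populations$cumulative_length
  stopifnot(all(b >= 0 & b <= 1 + 1e-12))
  pmin(b, 1)
}

#' Aggregate population abundance to viral families
#'
#' Family raw count is the sum of member-population counts; family length is
#' the sum of member cumulative lengths; the result is log2-CPKM normalized
#' on those totals. Unclassified populations are dropped.
#'
#' @param bundle Population-level `abundance_bundle` (raw counts, lengths).
#' @param populations A `viral_populations` object with taxonomy assigned.
#' @param pseudocount Passed to [normalize_log2cpkm()].
#' @return A family-level `abundance_bundle`, normalized.
#' @export
family_abundance <- function(bundle, populations, pseudocount = 1.0) {
  stopifnot(inherits(bundle, "abundance_bundle"),
            inherits(populations, "viral_populations"))
  p <- populations$populations
  p <- p[!is.na(p$family), , drop = FALSE]
  if (nrow(p) == 0) stop("no classified populations")
  cnt <- bundle$counts[p$population_id, , drop = FALSE]
  agg <- rowsum(cnt, group = p$family)
  lens <- tapply(p$cumulative_length, p$family, sum)[rownames(agg)]
  fb <- abundance_bundle(agg, bundle$lib_sizes, lens)
  normalize_log2cpkm(fb, pseudocount)
}

#' Fraction of each library recruited to features
#'
#' @param bundle An `abundance_bundle`.
#' @return List with `per_sample` (column sum / library size, in `[0, 1]`),
#'   `median` across samples, and `feature_stats` (per-feature max and mean
#'   percent of sample reads recruited, the core-table summary columns).
#' @export
reads_recruited <- function(bundle) {
  stopifnot(inherits(bundle, "abundance_bundle"))
  frac <- colSums(bundle$counts) / bundle$lib_sizes
  pct <- 100 * sweep(bundle$counts, 2, bundle$lib_sizes, "/")
  list(per_sample = frac, median = stats::median(frac),
       feature_stats = data.frame(
         feature_id = rownames(bundle$counts),
         max_pct_reads = apply(pct, 1, max),
         mean_pct_reads = rowMeans(pct),
         stringsAsFactors = FALSE))
}

#' Retention filter for protein clusters
#'
#' Keeps protein clusters (PCs) backed by two or more ORFs, or singleton PCs
#' detected in at least `min_samples` samples.
#'
#' @param pc_table data.frame with `pc_id`, `orf_count`, and one numeric
#'   abundance column per sample.
#' @param min_samples Minimum number of samples with nonzero abundance for a
#'   singleton PC (default 3).
#' @return The retained subset of `pc_table`.
#' @export
pc_filter <- function(pc_table, min_samples = 3) {
  stopifnot(all(c("pc_id", "orf_count") %in% colnames(pc_table)))
  ab <- as.matrix(pc_table[, setdiff(colnames(pc_table), c("pc_id", "orf_count")),
                           drop = FALSE])
  n_present <- rowSums(ab > 0)
  keep <- pc_table$orf_count >= 2 |
    (pc_table$orf_count == 1 & n_present >= min_samples)
  out <- pc_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage summary at one decimal place
#'
#' The convention used for all printed fraction summaries:
#' `round(100 * numerator / denominator, 1)`.
#'
#' @param numerator,denominator Counts.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' summarize_fraction(118, 2243)  # 5.3
summarize_fraction <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  round(100 * numerator / denominator, 1)
}
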