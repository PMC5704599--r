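#' Detect near-ubiquitous (core) viral populations
#'
#' A population is core when its breadth of coverage reaches
#' `presence_breadth_min` (default 15%) in at least
#' `ceiling(prevalence_min * n_samples)` samples (default 80% of samples;
#' "80% or more" is inclusive, so 4 of 5 samples qualifies). For each core
#' population the maximum and mean percentage of sample reads recruited are
#' reported.
#'
#' @param breadth_matrix Population x sample breadth matrix (from
#'   [breadth()]).
#' @param bundle Population-level `abundance_bundle` sharing rows/columns
#'   with `breadth_matrix`.
#' @param presence_breadth_min Breadth needed to call a population present
#'   in a sample (inclusive).
#' @param prevalence_min Fraction of samples the population must be present
#'   in (inclusive, via ceiling on the sample count).
#' @return data.frame with one row per core population: `population_id`,
#'   `n_present`, `max_pct_reads`, `mean_pct_reads`; the full presence count
#'   vector is attached as attribute `n_present_all`.
#' @export
detect_core <- function(breadth_matrix, bundle,
                        presence_breadth_min = 0.15, prevalence_min = 0.80) {
  if (length(breadth_matrix) == 0 || nrow(breadth_matrix) == 0)
    stop("empty breadth matrix")
  stopifnot(inherits(bundle, "abundance_bundle"),
            presence_breadth_min >= 0,  # values > 1 simply yield an empty core
            prevalence_min >= 0, prevalence_min <= 1)
  common <- intersect(rownames(breadth_matrix), rownames(bundle$counts))
  if (!setequal(rownames(breadth_matrix), rownames(bundle$counts)) ||
      !identical(colnames(breadth_matrix), colnames(bundle$counts)))
    stopifnot(length(common) > 0)
  b <- breadth_matrix[common, colnames(bundle$counts), drop = FALSE]
  n_samp <- ncol(b)
  ## tolerance guards float artifacts like 0.8 * 15 = 12.000000000000002
  need <- ceiling(prevalence_min * n_samp - 1e-9)
  n_present <- rowSums(b >= presence_breadth_min)
  core_ids <- rownames(b)[n_present >= need]
  pct <- 100 * sweep(bundle$counts[common, , drop = FALSE], 2,
                     bundle$lib_sizes, "/")
  out <- data.frame(
    population_id = core_ids,
    n_present = as.integer(n_present[core_ids]),
    max_pct_reads = if (length(core_ids)) apply(pct[core_ids, , drop = FALSE], 1, max) else numeric(0),
    mean_pct_reads = if (length(core_ids)) rowMeans(pct[core_ids, , drop = FALSE]) else numeric(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_present_all") <- n_present
  attr(out, "n_required") <- need
  out
}
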