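#' Retain viral contigs above a length threshold
#'
#' Keeps contigs that are flagged viral and strictly longer than
#' `min_length` base pairs. The result is independent of input order.
#'
#' @param catalog Contig catalog: data.frame with at least `contig_id`,
#'   `length_bp` and `viral_flag` columns.
#' @param min_length Length threshold in bp; contigs must be strictly longer.
#' @return The filtered catalog.
#' @export
filter_viral_contigs <- function(catalog, min_length = 1000) {
  validate_catalog(catalog)
  keep <- catalog$length_bp > min_length & catalog$viral_flag
  out <- catalog[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no contigs pass the viral/length filter")
  rownames(out) <- NULL
  out
}

validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog),
            all(c("contig_id", "length_bp", "viral_flag") %in% colnames(catalog)))
  if (anyDuplicated(catalog$contig_id)) stop("duplicate contig ids in catalog")
  if (any(catalog$length_bp <= 0)) stop("contig lengths must be positive")
  invisible(catalog)
}

# per-bin marker totals for a binning (data.frame contig_id, bin_id)
bin_marker_counts <- function(binning, catalog) {
  idx <- match(binning$contig_id, catalog$contig_id)
  if (anyNA(idx))
    stop("input error: binning references contigs absent from catalog: ",
         paste(utils::head(binning$contig_id[is.na(idx)], 5), collapse = ", "))
  data.frame(
    bin_id = names(tapply(catalog$terL_count[idx], binning$bin_id, sum)),
    terL = as.integer(tapply(catalog$terL_count[idx], binning$bin_id, sum)),
    scg = as.integer(tapply(catalog$scg_count[idx], binning$bin_id, sum)),
    stringsAsFactors = FALSE)
}

#' Choose the candidate binning with the fewest duplicate-terL bins
#'
#' Scores each candidate contig-to-bin assignment by the number of bins
#' containing two or more terminase large subunit (terL) genes and returns
#' the candidate minimising that score. Ties are broken by the larger count
#' of bins with exactly one terL, then by input order.
#'
#' @param candidate_binnings List of data.frames (`contig_id`, `bin_id`).
#' @param catalog Contig catalog with `terL_count` and `scg_count` columns.
#' @return List with `chosen` (the winning binning), `chosen_index`, and
#'   `scores` (per-candidate duplicate-terL bin counts and single-terL
#'   counts).
#' @export
score_binning <- function(candidate_binnings, catalog) {
  stopifnot(length(candidate_binnings) >= 1)
  validate_catalog(catalog)
  scores <- t(vapply(candidate_binnings, function(b) {
    m <- bin_marker_counts(b, catalog)
    c(multi_terL = sum(m$terL >= 2), single_terL = sum(m$terL == 1))
  }, numeric(2)))
  ord <- order(scores[, "multi_terL"], -scores[, "single_terL"],
               seq_len(nrow(scores)))
  i <- ord[1]
  list(chosen = candidate_binnings[[i]], chosen_index = i,
       scores = data.frame(candidate = seq_len(nrow(scores)),
                           multi_terL_bins = scores[, "multi_terL"],
                           single_terL_bins = scores[, "single_terL"]))
}

#' Curate bins into viral populations
#'
#' Applies the population-curation rules in order: (1) bins with two or more
#' terL genes are removed, and each of their member contigs at least
#' `rescue_min_length` bp long is rescued as a singleton population;
#' (2) bins containing a bacterial single-copy gene (SCG) are removed with no
#' rescue; (3) remaining bins become populations; (4) populations whose
#' cumulative length falls below `min_population_length` are dropped.
#' Rescued singletons are themselves subject to the SCG and single-terL
#' checks, since the intent of the rules is decontamination (see
#' `scg_on_rescued`). The result is deterministic and independent of the
#' order of contigs or bins in the input.
#'
#' @param binning data.frame (`contig_id`, `bin_id`) covering a subset of the
#'   catalog.
#' @param catalog Contig catalog with `terL_count` and `scg_count` columns.
#' @param rescue_min_length Minimum contig length (bp, inclusive) for rescue
#'   from a multi-terL bin.
#' @param min_population_length Minimum cumulative population length (bp,
#'   inclusive).
#' @param scg_on_rescued Re-check rescued contigs for SCGs (default TRUE).
#' @return A `viral_populations` object: list with `populations`
#'   (`population_id`, `cumulative_length`, `provenance`, `taxon`, `family`)
#'   and `members` (`population_id`, `contig_id`, `length_bp`).
#' @export
curate_bins <- function(binning, catalog, rescue_min_length = 10000,
                        min_population_length = 10000, scg_on_rescued = TRUE) {
  validate_catalog(catalog)
  idx <- match(binning$contig_id, catalog$contig_id)
  if (anyNA(idx))
    stop("input error: binning references contigs absent from catalog")
  ctg <- catalog[idx, , drop = FALSE]
  ctg$bin_id <- binning$bin_id
  m <- bin_marker_counts(binning, catalog)

  multi <- m$bin_id[m$terL >= 2]
  scg_bins <- m$bin_id[m$scg >= 1]

  ## rescues from multi-terL bins (rule 1)
  resc <- ctg[ctg$bin_id %in% multi & ctg$length_bp >= rescue_min_length, ,
              drop = FALSE]
  resc <- resc[resc$terL_count <= 1, , drop = FALSE]      # population invariant
  if (scg_on_rescued) resc <- resc[resc$scg_count == 0, , drop = FALSE]

  ## surviving whole bins (rules 1-2)
  keep_bins <- setdiff(m$bin_id, union(multi, scg_bins))
  kept <- ctg[ctg$bin_id %in% keep_bins, , drop = FALSE]

  members <- rbind(
    if (nrow(kept)) data.frame(group = kept$bin_id, contig_id = kept$contig_id,
                               length_bp = kept$length_bp,
                               provenance = "bin", stringsAsFactors = FALSE),
    if (nrow(resc)) data.frame(group = paste0("rescued:", resc$contig_id),
                               contig_id = resc$contig_id,
                               length_bp = resc$length_bp,
                               provenance = "rescued_contig",
                               stringsAsFactors = FALSE))
  if (is.null(members) || nrow(members) == 0) {
    return(new_viral_populations(
      data.frame(population_id = character(0), cumulative_length = integer(0),
                 provenance = character(0), taxon = character(0),
                 family = character(0), stringsAsFactors = FALSE),
      data.frame(population_id = character(0), contig_id = character(0),
                 length_bp = integer(0), stringsAsFactors = FALSE)))
  }
  cum <- tapply(members$length_bp, members$group, sum)
  prov <- tapply(members$provenance, members$group, `[`, 1)
  groups <- sort(names(cum))
  pops <- data.frame(population_id = groups,
                     cumulative_length = as.integer(cum[groups]),
                     provenance = as.character(prov[groups]),
                     taxon = NA_character_, family = NA_character_,
                     stringsAsFactors = FALSE)
  ## rule 4: cumulative length filter
  pops <- pops[pops$cumulative_length >= min_population_length, , drop = FALSE]
  members <- members[members$group %in% pops$population_id, , drop = FALSE]
  members <- members[order(members$group, members$contig_id), , drop = FALSE]
  out <- new_viral_populations(
    pops,
    data.frame(population_id = members$group, contig_id = members$contig_id,
               length_bp = members$length_bp, stringsAsFactors = FALSE))
  validate_populations(out, catalog)
  out
}

new_viral_populations <- function(populations, members) {
  rownames(populations) <- NULL
  rownames(members) <- NULL
  structure(list(populations = populations, members = members),
            class = "viral_populations")
}

#' Check the structural invariants of a curated population set
#'
#' Asserts that contig membership is a partition, cumulative lengths equal
#' member sums, every population has at most one terL and no SCGs (when a
#' catalog is supplied), and all cumulative lengths meet the floor recorded
#' in the object.
#'
#' @param ps A `viral_populations` object.
#' @param catalog Optional contig catalog for marker checks.
#' @param min_population_length Length floor to assert (bp).
#' @return `ps`, invisibly.
#' @export
validate_populations <- function(ps, catalog = NULL,
                                 min_population_length = 10000) {
  stopifnot(inherits(ps, "viral_populations"))
  if (anyDuplicated(ps$members$contig_id))
    stop("invariant violated: a contig belongs to two populations")
  cum <- tapply(ps$members$length_bp, ps$members$population_id, sum)
  if (nrow(ps$populations) &&
      !isTRUE(all.equal(as.integer(cum[ps$populations$population_id]),
                        ps$populations$cumulative_length)))
    stop("invariant violated: cumulative_length != sum of member lengths")
  if (any(ps$populations$cumulative_length < min_population_length))
    stop("invariant violated: population below the cumulative length floor")
  if (!is.null(catalog)) {
    idx <- match(ps$members$contig_id, catalog$contig_id)
    terL <- tapply(catalog$terL_count[idx], ps$members$population_id, sum)
    scg <- tapply(catalog$scg_count[idx], ps$members$population_id, sum)
    if (any(terL > 1)) stop("invariant violated: population with > 1 terL")
    if (any(scg > 0)) stop("invariant violated: population with bacterial SCG")
  }
  invisible(ps)
}

#' @export
print.viral_populations <- function(x, ...) {
  cat("viral_populations:", nrow(x$populations), "populations,",
      nrow(x$members), "member contigs\n")
  if (nrow(x$populations)) {
    cat("  provenance:", paste(names(table(x$populations$provenance)),
                               table(x$populations$provenance),
                               collapse = ", "), "\n")
    cat("  classified:", sum(!is.na(x$populations$taxon)), "\n")
  }
  invisible(x)
}

#' Assign taxonomy to populations from homology hits
#'
#' Discards hits failing the E-value or bit-score thresholds, keeps each
#' contig's best surviving hit (highest bit-score, then lowest E-value, then
#' lexicographic taxon id), and assigns to each population the taxonomy of
#' its longest contig that has a surviving hit (ties broken by contig id).
#' Populations with no surviving hit remain unclassified.
#'
#' @param ps A `viral_populations` object.
#' @param hits data.frame with `contig_id`, `ref_taxon`, `family`, `evalue`,
#'   `bitscore`.
#' @param max_evalue Maximum E-value (inclusive).
#' @param min_bitscore Minimum bit-score (inclusive).
#' @return `ps` with `taxon` and `family` filled in where classifiable.
#' @export
assign_taxonomy <- function(ps, hits, max_evalue = 1e-5, min_bitscore = 50) {
  stopifnot(inherits(ps, "viral_populations"))
  h <- hits[hits$evalue <= max_evalue & hits$bitscore >= min_bitscore, ,
            drop = FALSE]
  pops <- ps$populations
  pops$taxon <- NA_character_
  pops$family <- NA_character_
  if (nrow(h)) {
    h <- h[order(h$contig_id, -h$bitscore, h$evalue, h$ref_taxon), , drop = FALSE]
    best <- h[!duplicated(h$contig_id), , drop = FALSE]
    mem <- ps$members
    mem <- mem[mem$contig_id %in% best$contig_id, , drop = FALSE]
    if (nrow(mem)) {
      mem <- mem[order(mem$population_id, -mem$length_bp, mem$contig_id), ,
                 drop = FALSE]
      top <- mem[!duplicated(mem$population_id), , drop = FALSE]
      j <- match(top$contig_id, best$contig_id)
      k <- match(top$population_id, pops$population_id)
      pops$taxon[k] <- best$ref_taxon[j]
      pops$family[k] <- best$family[j]
    }
  }
  new_viral_populations(pops, ps$members)
}
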