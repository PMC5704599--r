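# Shared fixtures and independent oracles, built in code.

default_design <- function(seed = 1L) {
  make_crossover_design(5, 4, c("Corn", "27CDS", "40MDGS", "55CS"), seed = seed)
}

# small contig catalog with controllable markers
toy_catalog <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    contig_id = sprintf("c%02d", seq_len(n)),
    length_bp = sample(1500:30000, n),
    viral_flag = TRUE,
    terL_count = 0L,
    scg_count = 0L,
    bin_id = NA_character_,
    stringsAsFactors = FALSE)
}

# brute-force curation oracle: literal rule evaluation per bin
oracle_curate <- function(binning, catalog, rescue_min = 10000, min_pop = 10000,
                          scg_on_rescued = TRUE) {
  pops <- list()
  for (b in unique(binning$bin_id)) {
    ids <- binning$contig_id[binning$bin_id == b]
    rows <- catalog[match(ids, catalog$contig_id), ]
    if (sum(rows$terL_count) >= 2) {
      for (k in seq_len(nrow(rows))) {
        r <- rows[k, ]
        ok <- r$length_bp >= rescue_min && r$terL_count <= 1 &&
          (!scg_on_rescued || r$scg_count == 0)
        if (ok && r$length_bp >= min_pop)
          pops[[paste0("rescued:", r$contig_id)]] <- r$contig_id
      }
    } else if (sum(rows$scg_count) >= 1) {
      # dropped, no rescue
    } else if (sum(rows$length_bp) >= min_pop) {
      pops[[b]] <- sort(ids)
    }
  }
  pops[order(names(pops))]
}

members_as_list <- function(ps) {
  out <- split(ps$members$contig_id, ps$members$population_id)
  lapply(out[order(names(out))], sort)
}

# brute-force Class-I AMG set logic
oracle_class1 <- function(kos, path_sets, meta_sets, rule) {
  keep <- vapply(kos, function(k) {
    p <- path_sets[[k]]
    if (is.null(p)) return(FALSE)
    any(meta_sets[[k]]) &&
      !(any(p %in% rule$excluded) && !any(p %in% rule$rescue))
  }, logical(1))
  sort(kos[keep])
}

# direct sequential-SS PERMANOVA statistic for the enumeration oracle
oracle_permanova_F <- function(D, labels) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D^2 %*% J
  X <- stats::model.matrix(~ factor(labels))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ssc <- sum(H * G)
  sst <- sum(diag(G))
  dfh <- qr(X)$rank - 1
  (ssc / dfh) / ((sst - ssc) / (n - dfh - 1))
}
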