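#' Simulate a diet-crossover viral metagenome study with known truth
#'
#' Generates every tabular input the curation and abundance modules consume,
#' with ground truth attached, for a crossover feeding trial. Populations are
#' given 1--5 contigs (cumulative length at least 10 kbp, exactly one terL
#' marker, no bacterial single-copy genes); contaminant bins violate at least
#' one curation rule (two or more terL genes, or a bacterial SCG). Expected
#' log2 abundance of population p in sample j follows
#' `a_p + beta_p * (TDN_j - mean(TDN)) + u_{p,steer(j)} + eps_pj`, and
#' per-sample contig counts are drawn as a single multinomial of the sample's
#' library size over these log-normal intensities (so column sums equal the
#' drawn library sizes exactly). Covered-base counts follow the
#' Lander-Waterman saturation `breadth = 1 - exp(-depth)` scaled to contig
#' length. Planted core populations are abundant enough that their breadth
#' exceeds 15% in every sample; planted responders are kept at low depth so
#' they stay below the presence threshold in part of the gradient, and all
#' remaining background populations are structurally absent from enough
#' samples that only the planted core satisfies the core criterion.
#'
#' @param design A `study_design` whose diet table carries a `TDN` row.
#' @param n_populations Number of true (clean) viral populations.
#' @param n_core Number of planted near-ubiquitous populations.
#' @param n_responders Number of populations with a linear TDN response.
#' @param n_contaminant_bins Number of planted contaminant bins.
#' @param effect_size Total log2 abundance change of a responder across the
#'   observed TDN range (slope `beta_p = +/- effect_size / range(TDN)`).
#' @param libsize_range Integer range the per-sample library sizes are drawn
#'   from (uniform).
#' @param sigma_e Per-(population, sample) log2-normal noise SD.
#' @param sigma_u Per-(population, steer) random-intercept SD.
#' @param read_length Read length used to convert counts to depth for the
#'   coverage-breadth model.
#' @param n_decoys Number of decoy contigs (non-viral or sub-1-kbp) added to
#'   exercise the viral-contig filter.
#' @param seed Master seed; one derived stream per output table, so adding
#'   tables never perturbs existing ones.
#'
#' @return An object of class `virome_sim`: list with `catalog`, `binnings`
#'   (candidate contig-to-bin maps, first one the truth), `hits`, `counts`,
#'   `covered`, `lib_sizes`, `design`, and `truth` (population, bin and
#'   taxonomy ground truth plus the steer-effect matrix).
#' @export
simulate_viral_metagenome <- function(design,
                                      n_populations = 200L,
                                      n_core = 14L,
                                      n_responders = 30L,
                                      n_contaminant_bins = 20L,
                                      effect_size = 2,
                                      libsize_range = c(150000L, 400000L),
                                      sigma_e = 0.5,
                                      sigma_u = 0.3,
                                      read_length = 150L,
                                      n_decoys = 30L,
                                      seed = 1L) {
  validate_design(design)
  if (n_core + n_responders > n_populations)
    stop("parameter error: n_core + n_responders exceeds n_populations")
  if (effect_size < 0) stop("parameter error: effect_size must be >= 0")
  sm <- design$samples
  n_samp <- nrow(sm)
  tdn <- diet_covariate(design, "TDN", center = TRUE)
  tdn_range <- diff(range(diet_covariate(design, "TDN")))

  seeds <- derive_seeds(seed, 8L)

  ## --- population skeleton (contigs, lengths, markers) ------------------
  skel <- withr_seed(seeds[1], {
    pop_ids <- sprintf("vpop%04d", seq_len(n_populations))
    n_ctg <- sample(1:5, n_populations, replace = TRUE)
    pops <- data.frame(population_id = pop_ids, bin_id = sprintf("bin%04d", seq_len(n_populations)),
                       n_contigs = n_ctg, stringsAsFactors = FALSE)
    ctg <- do.call(rbind, lapply(seq_len(n_populations), function(i) {
      len <- pmax(1001, round(exp(rnorm(n_ctg[i], log(15000), 0.6))))
      if (sum(len) < 10500) len <- round(len * (10500 / sum(len)) + 1)
      terL <- integer(n_ctg[i]); terL[which.max(len)] <- 1L
      data.frame(contig_id = sprintf("%s_c%d", pops$population_id[i], seq_len(n_ctg[i])),
                 length_bp = len, viral_flag = TRUE, terL_count = terL,
                 scg_count = 0L, bin_id = pops$bin_id[i], stringsAsFactors = FALSE)
    }))
    list(pops = pops, ctg = ctg)
  })
  pops <- skel$pops
  pops$cumulative_length <- as.integer(tapply(skel$ctg$length_bp, skel$ctg$bin_id,
                                              sum)[pops$bin_id])

  ## --- contaminant bins -------------------------------------------------
  contam <- withr_seed(seeds[2], {
    if (n_contaminant_bins == 0) return(list(ctg = NULL, bins = NULL))
    bin_ids <- sprintf("bin%04d", n_populations + seq_len(n_contaminant_bins))
    kind <- rep(c("multi_terL", "scg"), length.out = n_contaminant_bins)
    ctg <- NULL
    bins <- data.frame(bin_id = bin_ids, kind = kind, stringsAsFactors = FALSE)
    for (i in seq_len(n_contaminant_bins)) {
      nc <- sample(2:4, 1)
      len <- pmax(1001, round(exp(rnorm(nc, log(6000), 0.9))))
      terL <- integer(nc); scg <- integer(nc)
      if (kind[i] == "multi_terL") terL[sample(nc, 2)] <- 1L else {
        scg[sample(nc, 1)] <- 1L
        terL[sample(nc, 1)] <- 1L
      }
      ctg <- rbind(ctg, data.frame(
        contig_id = sprintf("cont%02d_c%d", i, seq_len(nc)), length_bp = len,
        viral_flag = TRUE, terL_count = terL, scg_count = scg,
        bin_id = bin_ids[i], stringsAsFactors = FALSE))
    }
    list(ctg = ctg, bins = bins)
  })

  ## --- decoy contigs (fail the viral/length filter, unbinned) -----------
  decoys <- withr_seed(seeds[3], {
    if (n_decoys == 0) return(NULL)
    half <- n_decoys %/% 2
    data.frame(
      contig_id = sprintf("decoy%03d", seq_len(n_decoys)),
      length_bp = c(pmax(1500, round(exp(rnorm(half, log(8000), 0.8)))),
                    sample(300:1000, n_decoys - half, replace = TRUE)),
      viral_flag = c(rep(FALSE, half), rep(TRUE, n_decoys - half)),
      terL_count = 0L, scg_count = 0L, bin_id = NA_character_,
      stringsAsFactors = FALSE)
  })
  catalog <- rbind(skel$ctg, contam$ctg, decoys)

  ## --- planted truth: roles, baselines, slopes --------------------------
  truthbits <- withr_seed(seeds[4], {
    is_core <- seq_len(n_populations) <= n_core
    is_resp <- seq_len(n_populations) > n_core &
      seq_len(n_populations) <= n_core + n_responders
    beta <- numeric(n_populations)
    if (n_responders > 0 && tdn_range > 0)
      beta[is_resp] <- rep_len(c(1, -1), n_responders) * effect_size / tdn_range
    a <- rnorm(n_populations, 0.5, 1)
    a[is_core] <- rnorm(sum(is_core), 4, 0.3)
    a[is_resp] <- rnorm(sum(is_resp), 1.5, 0.3)
    u <- matrix(rnorm(n_populations * length(unique(sm$steer)), 0, sigma_u),
                n_populations, dimnames = list(pops$population_id, unique(sm$steer)))
    ## structural absences keep everything but the planted core out of the
    ## core set: background populations drop out of random samples;
    ## responders drop out of the diet(s) at the unfavourable end of their
    ## TDN gradient (below-detection at that end), which also encodes part
    ## of their diet response
    n_absent_min <- n_samp - ceiling(0.8 * n_samp - 1e-9) + 1L
    absent <- matrix(FALSE, n_populations, n_samp,
                     dimnames = list(pops$population_id, sm$sample_id))
    bg <- which(!is_core & !is_resp)
    for (i in bg) {
      k <- sample(n_absent_min:max(n_absent_min, round(n_samp / 2)), 1)
      absent[i, sample(n_samp, k)] <- TRUE
    }
    diet_order <- order(tapply(tdn, sm$diet, mean))       # ascending TDN
    diets_asc <- names(tapply(tdn, sm$diet, mean))[diet_order]
    for (i in which(is_resp)) {
      worst <- if (beta[i] > 0) diets_asc else rev(diets_asc)
      off <- character(0); k <- 1L
      while (sum(sm$diet %in% off) < n_absent_min && k <= length(worst)) {
        off <- c(off, worst[k]); k <- k + 1L
      }
      absent[i, sm$diet %in% off] <- TRUE
    }
    list(is_core = is_core, is_resp = is_resp, beta = beta, a = a, u = u,
         absent = absent, n_absent_min = n_absent_min)
  })

  ## --- counts: one multinomial per sample over contig intensities -------
  cnt <- withr_seed(seeds[5], {
    L <- as.integer(round(runif(n_samp, libsize_range[1], libsize_range[2])))
    names(L) <- sm$sample_id
    eps <- matrix(rnorm(n_populations * n_samp, 0, sigma_e), n_populations, n_samp)
    eta <- outer(truthbits$a, rep(1, n_samp)) +
      outer(truthbits$beta, tdn) +
      truthbits$u[, sm$steer, drop = FALSE] + eps
    wpop <- 2^eta
    wpop[truthbits$absent] <- 0
    rownames(wpop) <- pops$population_id

    ## contig weight = population weight x (contig length / cumulative length)
    w_ctg <- matrix(0, nrow(catalog), n_samp,
                    dimnames = list(catalog$contig_id, sm$sample_id))
    pop_of <- match(catalog$bin_id, pops$bin_id)
    in_pop <- !is.na(pop_of)
    frac <- catalog$length_bp / pops$cumulative_length[pop_of]
    w_ctg[in_pop, ] <- wpop[pop_of[in_pop], , drop = FALSE] *
      frac[in_pop] * pops$cumulative_length[pop_of[in_pop]]
    if (!is.null(contam$ctg)) {
      idx <- which(catalog$bin_id %in% contam$bins$bin_id)
      a_ct <- rnorm(length(idx), -1, 1)
      w_ctg[idx, ] <- catalog$length_bp[idx] * 2^a_ct
      ## contaminant contigs are patchy too, so rescued singletons are not core
      for (i in idx)
        w_ctg[i, sample(n_samp, truthbits$n_absent_min)] <- 0
    }
    if (!is.null(decoys)) {
      idx <- is.na(catalog$bin_id)
      w_ctg[idx, ] <- catalog$length_bp[idx] * 2^-6
    }
    counts <- sapply(seq_len(n_samp), function(j)
      rmultinom(1, L[j], prob = w_ctg[, j]))
    dimnames(counts) <- list(catalog$contig_id, sm$sample_id)
    list(counts = counts, L = L)
  })

  ## breadth = 1 - exp(-depth), deterministic given counts
  depth <- cnt$counts * read_length / catalog$length_bp
  covered <- round(catalog$length_bp * (1 - exp(-depth)))
  dimnames(covered) <- dimnames(cnt$counts)

  ## --- candidate binnings: truth first, then corrupted merges -----------
  binnings <- withr_seed(seeds[6], {
    truth_bin <- catalog[!is.na(catalog$bin_id), c("contig_id", "bin_id")]
    cands <- list(truth_bin)
    clean_bins <- pops$bin_id
    for (k in 1:2) {
      b <- truth_bin
      n_merge <- min(2 * k, length(clean_bins) %/% 2)
      if (n_merge > 0) {
        pairs <- matrix(sample(clean_bins, 2 * n_merge), ncol = 2)
        for (m in seq_len(n_merge))
          b$bin_id[b$bin_id == pairs[m, 2]] <- pairs[m, 1]
      }
      cands[[k + 1]] <- b
    }
    cands
  })

  ## --- homology hits with a planted taxonomy expectation ----------------
  fams <- c("Myoviridae", "Siphoviridae", "Podoviridae", "Mimiviridae")
  hits <- withr_seed(seeds[7], {
    n_hit <- max(1L, round(0.08 * n_populations))
    hit_pops <- sample(n_populations, n_hit)
    rows <- NULL
    expected <- data.frame(population_id = pops$population_id,
                           taxon = NA_character_, family = NA_character_,
                           stringsAsFactors = FALSE)
    for (i in hit_pops) {
      members <- skel$ctg[skel$ctg$bin_id == pops$bin_id[i], ]
      fam <- sample(fams, 1)
      tax <- sprintf("refvir_%s_%03d", substr(fam, 1, 3), i)
      longest <- members$contig_id[which.max(members$length_bp)]
      rows <- rbind(rows, data.frame(
        contig_id = longest, ref_taxon = tax, family = fam,
        evalue = 10^-runif(1, 10, 40), bitscore = runif(1, 80, 400),
        stringsAsFactors = FALSE))
      ## occasional disagreeing hit on a shorter member contig
      if (nrow(members) > 1 && runif(1) < 0.5) {
        other <- setdiff(members$contig_id, longest)[1]
        fam2 <- sample(setdiff(fams, fam), 1)
        rows <- rbind(rows, data.frame(
          contig_id = other, ref_taxon = sprintf("refvir_%s_alt%03d", substr(fam2, 1, 3), i),
          family = fam2, evalue = 10^-runif(1, 10, 40),
          bitscore = runif(1, 80, 400), stringsAsFactors = FALSE))
      }
      expected$taxon[i] <- tax
      expected$family[i] <- fam
    }
    ## sub-threshold hits that must be ignored
    junk_pops <- setdiff(seq_len(n_populations), hit_pops)[1:min(5, n_populations - n_hit)]
    for (i in junk_pops) {
      members <- skel$ctg[skel$ctg$bin_id == pops$bin_id[i], ]
      rows <- rbind(rows, data.frame(
        contig_id = members$contig_id[1], ref_taxon = sprintf("refvir_weak_%03d", i),
        family = sample(fams, 1), evalue = 1e-3, bitscore = runif(1, 20, 45),
        stringsAsFactors = FALSE))
    }
    list(table = rows, expected = expected)
  })

  ## rescued-contig truth for contaminant multi-terL bins
  rescued <- character(0)
  if (!is.null(contam$ctg)) {
    mt <- contam$bins$bin_id[contam$bins$kind == "multi_terL"]
    cc <- contam$ctg[contam$ctg$bin_id %in% mt, ]
    rescued <- cc$contig_id[cc$length_bp >= 10000 & cc$terL_count <= 1 & cc$scg_count == 0]
  }

  truth <- list(
    populations = data.frame(
      population_id = pops$population_id, bin_id = pops$bin_id,
      n_contigs = pops$n_contigs, cumulative_length = pops$cumulative_length,
      is_core = truthbits$is_core, is_responder = truthbits$is_resp,
      beta = truthbits$beta, baseline = truthbits$a,
      expected_taxon = hits$expected$taxon, expected_family = hits$expected$family,
      stringsAsFactors = FALSE),
    bins = contam$bins, rescued_contigs = rescued,
    steer_effects = truthbits$u, absent = truthbits$absent,
    params = list(effect_size = effect_size, sigma_e = sigma_e,
                  sigma_u = sigma_u, read_length = read_length, seed = seed))

  structure(list(catalog = catalog, binnings = binnings, hits = hits$table,
                 counts = cnt$counts, covered = covered, lib_sizes = cnt$L,
                 design = design, truth = truth, seed = seed),
            class = "virome_sim")
}

#' Simulate a 16S OTU community with a phylogeny and planted diet effects
#'
#' Draws a random bifurcating tree with exponential branch lengths and OTU
#' counts under the same log-normal multinomial model as
#' [simulate_viral_metagenome()] (log2 mean linear in centered TDN for
#' planted responders, plus per-(OTU, steer) random intercepts).
#'
#' @inheritParams simulate_viral_metagenome
#' @param n_otus Number of OTUs (at least 2).
#' @param libsize_range Range of per-sample sequencing depths.
#' @return A list with `counts` (OTUs x samples), `tree` (an `ape::phylo`),
#'   `lib_sizes`, `min_depth` and `truth`.
#' @export
simulate_otu_community <- function(design, n_otus = 150L, n_responders = 20L,
                                   effect_size = 2,
                                   libsize_range = c(21000L, 60000L),
                                   sigma_e = 0.6, sigma_u = 0.3, seed = 1L) {
  validate_design(design)
  if (n_otus < 2) stop("parameter error: need at least 2 OTUs")
  if (n_responders > n_otus) stop("parameter error: n_responders > n_otus")
  sm <- design$samples
  n_samp <- nrow(sm)
  tdn <- diet_covariate(design, "TDN", center = TRUE)
  tdn_range <- diff(range(diet_covariate(design, "TDN")))
  seeds <- derive_seeds(seed, 3L)

  tree <- withr_seed(seeds[1], {
    tr <- ape::rtree(n_otus, br = NULL)
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 10)
    tr$tip.label <- sprintf("otu%04d", seq_len(n_otus))
    tr
  })

  tb <- withr_seed(seeds[2], {
    is_resp <- seq_len(n_otus) <= n_responders
    beta <- numeric(n_otus)
    if (n_responders > 0 && tdn_range > 0)
      beta[is_resp] <- rep_len(c(1, -1), n_responders) * effect_size / tdn_range
    a <- rnorm(n_otus, 0, 1.2)
    u <- matrix(rnorm(n_otus * length(unique(sm$steer)), 0, sigma_u),
                n_otus, dimnames = list(tree$tip.label, unique(sm$steer)))
    list(is_resp = is_resp, beta = beta, a = a, u = u)
  })

  cnt <- withr_seed(seeds[3], {
    L <- as.integer(round(runif(n_samp, libsize_range[1], libsize_range[2])))
    names(L) <- sm$sample_id
    eps <- matrix(rnorm(n_otus * n_samp, 0, sigma_e), n_otus, n_samp)
    eta <- outer(tb$a, rep(1, n_samp)) + outer(tb$beta, tdn) +
      tb$u[, sm$steer, drop = FALSE] + eps
    counts <- sapply(seq_len(n_samp), function(j) rmultinom(1, L[j], prob = 2^eta[, j]))
    dimnames(counts) <- list(tree$tip.label, sm$sample_id)
    list(counts = counts, L = L)
  })

  list(counts = cnt$counts, tree = tree, lib_sizes = cnt$L,
       min_depth = min(colSums(cnt$counts)),
       truth = list(is_responder = tb$is_resp, beta = tb$beta, baseline = tb$a,
                    steer_effects = tb$u, seed = seed))
}

#' Built-in KEGG-orthology catalog for AMG simulations
#'
#' Assembles a synthetic KO-to-pathway map spanning the excluded
#' (virus-associated), rescue (carbon/nitrogen/pentose-phosphate) and neutral
#' pathway groups that the Class-I classifier distinguishes. Each pathway
#' carries a logical `metabolic` flag (KEGG metabolic-category membership).
#'
#' @param n_kos Number of KOs.
#' @param fraction_excluded Fraction of KOs given at least one excluded
#'   pathway.
#' @param rescue_fraction Among excluded-pathway KOs, the fraction also given
#'   a rescue pathway.
#' @param seed Seed.
#' @return data.frame with columns `ko`, `pathway`, `metabolic`.
#' @export
builtin_ko_catalog <- function(n_kos = 120L, fraction_excluded = 0.3,
                               rescue_fraction = 0.3, seed = 1L) {
  rule <- default_pathway_rule()
  excl_meta <- c(ko03440 = FALSE, ko03430 = FALSE, ko00970 = FALSE,
                 ko00230 = TRUE, ko00240 = TRUE, ko03030 = FALSE,
                 ko00520 = TRUE, ko01230 = TRUE, ko03410 = FALSE,
                 ko00270 = TRUE, ko00330 = TRUE)
  stopifnot(setequal(names(excl_meta), rule$excluded))
  neutral_meta <- c(ko00010 = TRUE, ko00500 = TRUE, ko00620 = TRUE,
                    ko00790 = TRUE, ko00920 = TRUE, ko00061 = TRUE,
                    ko03010 = FALSE, ko03070 = FALSE)
  rescue_meta <- c(ko01200 = TRUE, ko00910 = TRUE, ko00030 = TRUE)
  meta <- c(excl_meta, neutral_meta, rescue_meta)
  withr_seed(seed, {
    kos <- sprintf("K%05d", seq_len(n_kos))
    rows <- lapply(seq_len(n_kos), function(i) {
      p <- character(0)
      if (runif(1) < fraction_excluded) {
        p <- sample(names(excl_meta), 1)
        if (runif(1) < rescue_fraction) p <- c(p, sample(names(rescue_meta), 1))
      } else {
        pool <- if (runif(1) < 0.85) names(neutral_meta)[neutral_meta] else
          names(neutral_meta)[!neutral_meta]
        p <- sample(pool, min(length(pool), sample(1:2, 1)))
      }
      data.frame(ko = kos[i], pathway = p, metabolic = unname(meta[p]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate ORF annotations and abundances for AMG analysis
#'
#' Emulates the inputs of the Class-I AMG workflow: an ORF-to-KO annotation
#' table on (mostly) bona-fide viral contigs longer than 1.5 kbp, a KO-to-
#' pathway map, and an ORF-by-sample count matrix drawn from a negative
#' binomial null, optionally with planted fold changes between the two diets
#' present in `design`.
#'
#' @param design A `study_design` restricted to the samples of interest
#'   (typically two contrasting diets).
#' @param n_orfs Number of ORFs.
#' @param ko_catalog KO-to-pathway map as from [builtin_ko_catalog()];
#'   `NULL` builds the default catalog from a derived seed.
#' @param fraction_excluded,rescue_fraction Passed to [builtin_ko_catalog()]
#'   when `ko_catalog` is `NULL`.
#' @param n_deg Number of KOs given a planted fold change.
#' @param lfc log2 fold change planted on `n_deg` KOs (second diet level over
#'   first).
#' @param nb_dispersion Negative-binomial dispersion (`1/size`).
#' @param seed Master seed.
#' @return List with `orf_ko` (annotation table), `orf_counts`
#'   (ORFs x samples), `ko_pathways`, and `truth`.
#' @export
simulate_amg_inputs <- function(design, n_orfs = 600L, ko_catalog = NULL,
                                fraction_excluded = 0.3, rescue_fraction = 0.3,
                                n_deg = 0L, lfc = 0, nb_dispersion = 0.1,
                                seed = 1L) {
  validate_design(design)
  sm <- design$samples
  seeds <- derive_seeds(seed, 3L)
  if (is.null(ko_catalog))
    ko_catalog <- builtin_ko_catalog(fraction_excluded = fraction_excluded,
                                     rescue_fraction = rescue_fraction,
                                     seed = seeds[1])
  if (nrow(ko_catalog) == 0) stop("empty KO catalog")
  kos <- unique(ko_catalog$ko)

  ann <- withr_seed(seeds[2], {
    n_ctg <- max(2L, ceiling(n_orfs / 4))
    ctg_len <- pmax(500, round(exp(rnorm(n_ctg, log(3000), 0.6))))
    bona <- runif(n_ctg) < 0.9
    ctg_of <- sample(n_ctg, n_orfs, replace = TRUE)
    ko <- sample(kos, n_orfs, replace = TRUE)
    unknown <- runif(n_orfs) < 0.02
    ko[unknown] <- sprintf("K9%04d", sample(9999, sum(unknown), replace = TRUE))
    ev <- 10^-runif(n_orfs, 6, 40)
    ev[runif(n_orfs) < 0.05] <- 1e-3                 # sub-threshold hits
    bs <- runif(n_orfs, 60, 400)
    low_bs <- runif(n_orfs) < 0.05
    bs[low_bs] <- runif(sum(low_bs), 20, 49)
    aa <- pmax(30L, round(rnorm(n_orfs, 250, 80)))
    data.frame(orf_id = sprintf("orf%05d", seq_len(n_orfs)),
               contig_id = sprintf("dvctg%04d", ctg_of),
               contig_length = ctg_len[ctg_of],
               viral_bona_fide = bona[ctg_of], ko = ko,
               evalue = ev, bitscore = bs, aa_length = aa,
               stringsAsFactors = FALSE)
  })

  cnt <- withr_seed(seeds[3], {
    mu <- exp(rnorm(n_orfs, log(50), 1))
    sf <- runif(nrow(sm), 0.7, 1.4)
    diets <- sort(unique(sm$diet))
    deg_kos <- character(0)
    if (n_deg > 0) {
      if (length(diets) != 2) stop("planted fold changes need exactly two diets")
      deg_kos <- sample(kos, min(n_deg, length(kos)))
    }
    fc <- rep(1, n_orfs)
    counts <- sapply(seq_len(nrow(sm)), function(j) {
      m <- mu * sf[j]
      if (length(deg_kos) && sm$diet[j] == diets[2])
        m <- m * ifelse(ann$ko %in% deg_kos, 2^lfc, 1)
      stats::rnbinom(n_orfs, mu = m, size = 1 / nb_dispersion)
    })
    dimnames(counts) <- list(ann$orf_id, sm$sample_id)
    list(counts = counts, deg_kos = deg_kos, sf = sf)
  })

  list(orf_ko = ann, orf_counts = cnt$counts, ko_pathways = ko_catalog,
       truth = list(deg_kos = cnt$deg_kos, sample_factors = cnt$sf,
                    lfc = lfc, nb_dispersion = nb_dispersion, seed = seed))
}

#' Write a simulated study to tab-separated files
#'
#' Emits the plain-text interchange files consumed by the command-line
#' interface: `contigs.tsv`, `markers.tsv`, `counts.tsv`,
#' `covered_bases.tsv`, `hits.tsv`, `design.tsv`, `diet.tsv`, `truth.tsv`,
#' and one `bins_<k>.tsv` per candidate binning. All tables are
#' tab-separated with a single header line.
#'
#' @param sim A `virome_sim`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "virome_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(sim$catalog[, c("contig_id", "length_bp", "viral_flag", "bin_id")], "contigs.tsv")
  mk <- rbind(
    data.frame(contig_id = rep(sim$catalog$contig_id, sim$catalog$terL_count),
               marker_type = "terL", stringsAsFactors = FALSE),
    data.frame(contig_id = rep(sim$catalog$contig_id, sim$catalog$scg_count),
               marker_type = "bacterial_scg", stringsAsFactors = FALSE))
  wt(mk, "markers.tsv")
  wt(data.frame(feature_id = rownames(sim$counts), sim$counts, check.names = FALSE),
     "counts.tsv")
  wt(data.frame(feature_id = rownames(sim$covered), sim$covered, check.names = FALSE),
     "covered_bases.tsv")
  wt(sim$hits, "hits.tsv")
  for (k in seq_along(sim$binnings)) wt(sim$binnings[[k]], sprintf("bins_%d.tsv", k))
  des <- sim$design$samples
  des$lib_size <- sim$lib_sizes[des$sample_id]
  wt(des, "design.tsv")
  dt <- sim$design$diet_table
  wt(data.frame(covariate = rownames(dt), dt, check.names = FALSE), "diet.tsv")
  wt(sim$truth$populations, "truth.tsv")
  invisible(dir)
}
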