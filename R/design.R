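#' Build a row-column crossover feeding design
#'
#' Constructs the sample layout of a crossover feeding trial in which
#' `n_steers` animals are rotated through `length(diet_ids)` dietary
#' treatments over `n_periods` periods. Every steer receives one diet per
#' period and never repeats a diet, so rows (steers) are complete blocks;
#' when `n_steers == n_periods` the layout is a Latin square and diet
#' occurrence is also balanced across periods. The assignment is built from a
#' cyclic schedule whose row offsets and diet ordering are shuffled under
#' `seed`, so the same seed always yields the same design.
#'
#' @param n_steers Number of animals (rows). Must be at least `n_periods`.
#' @param n_periods Number of feeding periods (columns).
#' @param diet_ids Character vector of diet identifiers; one per period.
#' @param seed Integer seed controlling the shuffle of rows and diet order.
#' @param diet_table Optional data.frame of per-diet covariates
#'   (columns = diets). Defaults to [builtin_diet_table()] when `diet_ids`
#'   match its columns, otherwise `NULL`.
#'
#' @return An object of class `study_design`: a list with `samples`
#'   (data.frame with columns `sample_id`, `steer`, `period`, `diet`) and
#'   `diet_table` (covariates-by-diet data.frame or `NULL`).
#' @export
#' @examples
#' d <- make_crossover_design(5, 4, c("Corn", "27CDS", "40MDGS", "55CS"), seed = 1)
#' table(d$samples$diet)
make_crossover_design <- function(n_steers, n_periods, diet_ids, seed = 1L,
                                  diet_table = NULL) {
  if (n_steers < 1L || n_periods < 1L)
    stop("n_steers and n_periods must be positive")
  if (length(diet_ids) != n_periods)
    stop("design error: need exactly one diet per period (",
         length(diet_ids), " diets for ", n_periods, " periods)")
  if (n_periods > length(unique(diet_ids)))
    stop("design error: more periods than distinct diets")
  if (n_steers < n_periods)
    stop("design error: fewer steers than periods breaks row blocking")
  diet_ids <- as.character(diet_ids)

  withr_seed(seed, {
    diets <- sample(diet_ids)
    offsets <- sample(seq_len(n_periods)) - 1L    # one distinct offset per 'row class'
    rows <- lapply(seq_len(n_steers), function(i) {
      off <- offsets[((i - 1L) %% n_periods) + 1L]
      diets[((seq_len(n_periods) - 1L + off) %% n_periods) + 1L]
    })
    steer_ids <- sprintf("steer%02d", sample(seq_len(n_steers)))
    samples <- data.frame(
      sample_id = character(0), steer = character(0),
      period = integer(0), diet = character(0),
      stringsAsFactors = FALSE
    )
    for (i in seq_len(n_steers)) {
      samples <- rbind(samples, data.frame(
        sample_id = sprintf("%s_P%d", steer_ids[i], seq_len(n_periods)),
        steer = steer_ids[i],
        period = seq_len(n_periods),
        diet = rows[[i]],
        stringsAsFactors = FALSE
      ))
    }
    if (is.null(diet_table)) {
      bt <- builtin_diet_table()
      if (all(diet_ids %in% colnames(bt))) diet_table <- bt[, diet_ids, drop = FALSE]
    }
    out <- structure(list(samples = samples, diet_table = diet_table),
                     class = "study_design")
    validate_design(out)
    out
  })
}

#' Validate the invariants of a crossover design
#'
#' Checks that every (steer, period) pair maps to exactly one diet, that no
#' steer repeats a diet, and that diet covariates (when present) are finite
#' and non-negative.
#'
#' @param design A `study_design` object.
#' @return `design`, invisibly. Errors if an invariant is violated.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  s <- design$samples
  if (anyDuplicated(s[, c("steer", "period")]))
    stop("invalid design: a (steer, period) cell is assigned twice")
  rep_diet <- tapply(s$diet, s$steer, anyDuplicated)
  if (any(unlist(rep_diet) > 0))
    stop("invalid design: a steer repeats a diet")
  dt <- design$diet_table
  if (!is.null(dt)) {
    m <- as.matrix(dt)
    if (!all(is.finite(m)) || any(m < 0))
      stop("invalid design: diet covariates must be finite and non-negative")
    if (!all(unique(s$diet) %in% colnames(dt)))
      stop("invalid design: diets missing from diet_table")
  }
  invisible(design)
}

#' Composition of the four dietary treatments
#'
#' Returns the built-in diet composition table for the four treatments used
#' throughout the package (Corn, 27CDS, 40MDGS, 55CS): ingredient inclusions
#' and chemical composition expressed as percent dry matter, with trace
#' minerals in ppm. Rows are covariates, columns are diets. Total digestible
#' nutrients (`TDN`) is the dietary energy index that drives the simulated
#' abundance gradients.
#'
#' @return A data.frame of covariates (rows) by diets (columns).
#' @export
#' @examples
#' builtin_diet_table()["TDN", ]
builtin_diet_table <- function() {
  diets <- c("Corn", "27CDS", "40MDGS", "55CS")
  rows <- list(
    high_moisture_corn = c(51.25, 36.30, 28.50, 0),
    dry_rolled_corn    = c(36.25, 24.20, 19.00, 0),
    condensed_distillers_solubles = c(0, 27.00, 0, 0),
    modified_distillers_grains    = c(0, 0, 40.00, 40.00),
    silage     = c(0, 0, 0, 55.00),
    brome      = c(7.50, 7.50, 7.50, 0),
    supplement = c(5.00, 5.00, 5.00, 5.00),
    relative_feed_value = c(1100.14, 1378.78, 712.65, 252.00),
    TDN = c(81.43, 82.65, 78.50, 73.30),
    ADF = c(5.39, 4.91, 9.28, 15.25),
    NDF = c(11.22, 10.14, 19.25, 25.45),
    crude_protein = c(8.74, 12.16, 17.96, 17.17),
    nitrate_ppm = c(25.75, 25.75, 25.75, 19.00),
    Ca = c(0.08, 0.07, 0.09, 0.18),
    P  = c(0.34, 0.82, 0.60, 0.56),
    K  = c(0.63, 1.33, 0.97, 1.25),
    Mg = c(0.14, 0.31, 0.23, 0.25),
    Zn = c(24.90, 123.47, 38.51, 40.15),
    Fe = c(55.91, 92.93, 125.22, 197.25),
    Mn = c(10.84, 18.58, 16.32, 21.60),
    Cu = c(2.57, 4.16, 4.14, 6.52),
    S  = c(0.11, 0.23, 0.26, 0.26),
    Na = c(0.03, 0.17, 0.17, 0.13),
    Mo = c(0.24, 0.38, 0.51, 0.51)
  )
  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- diets
  out
}

#' Per-sample value of a diet covariate
#'
#' Looks up a covariate (for example `"TDN"`) in the design's diet table and
#' returns it in sample order, optionally centered on the across-sample mean.
#'
#' @param design A `study_design`.
#' @param covariate Row name in `design$diet_table`.
#' @param center Subtract the across-sample mean?
#' @return Named numeric vector, one value per sample.
#' @export
diet_covariate <- function(design, covariate = "TDN", center = FALSE) {
  stopifnot(inherits(design, "study_design"))
  dt <- design$diet_table
  if (is.null(dt) || !covariate %in% rownames(dt))
    stop("covariate '", covariate, "' not in diet_table")
  x <- as.numeric(dt[covariate, design$samples$diet])
  names(x) <- design$samples$sample_id
  if (center) x <- x - mean(x)
  x
}

#' Restrict a design to a deep-sequencing subset
#'
#' Selects up to `n_per_diet` samples from each of the named diets (the
#' deeply sequenced contrast of a study, typically the two diets at the
#' extremes of the energy gradient), preferring later periods.
#'
#' @param design A `study_design`.
#' @param diets Diets to keep.
#' @param n_per_diet Samples per diet.
#' @return A `study_design` containing only the selected samples.
#' @export
deep_subset <- function(design, diets = c("55CS", "27CDS"), n_per_diet = 3L) {
  stopifnot(inherits(design, "study_design"))
  s <- design$samples
  keep <- unlist(lapply(diets, function(dd) {
    i <- which(s$diet == dd)
    i[order(-s$period[i])][seq_len(min(n_per_diet, length(i)))]
  }))
  out <- design
  out$samples <- s[sort(keep), , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

#' @export
print.study_design <- function(x, ...) {
  s <- x$samples
  cat("study_design:", nrow(s), "samples |", length(unique(s$steer)),
      "steers x", length(unique(s$period)), "periods |",
      length(unique(s$diet)), "diets\n")
  if (!is.null(x$diet_table))
    cat("diet covariates:", nrow(x$diet_table), "\n")
  invisible(x)
}

# Run code under a temporary RNG state so callers' streams are untouched.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive independent sub-seeds (one pseudo-random stream per output table).
derive_seeds <- function(seed, n) {
  withr_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
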