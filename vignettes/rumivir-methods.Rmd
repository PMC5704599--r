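---
title: "Models and methods behind rumivir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rumivir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumivir)
```

rumivir analyses the response of rumen viral (and bacterial) communities to
dietary change in a crossover feeding trial, working entirely from
post-assembly tabular artifacts: contig tables, candidate genome binnings,
marker annotations, per-contig read and covered-base counts, homology hits,
KO annotations, OTU tables with a phylogeny, and the trial design. This
vignette explains the models, the tunable parameters, and the design
decisions taken where the methodology left genuine freedom.

## The study design

Five steers rotate through four diets over four 21-day periods in a
row-column crossover: every steer receives every diet exactly once, so diet
contrasts are balanced within animals. The four diets differ mainly in
energy: total digestible nutrients (TDN, an energy index built from
digestible fiber, protein, lipid and carbohydrate fractions) spans roughly
73--83% of dry matter across them. `make_crossover_design()` builds such a
layout from a cyclic schedule (a Latin square when steers = periods) and
`builtin_diet_table()` supplies the full diet composition (ingredients,
fiber fractions, minerals) used as explanatory covariates downstream.

## Viral population curation

Viral populations — the operational genome units of all abundance work —
are curated from binned contigs with four deterministic rules, applied in
this order:

1. bins carrying **two or more terL genes** (terminase large subunit, an
   expected single-copy phage marker) are removed; member contigs of at
   least 10 kbp are rescued as singleton populations;
2. bins containing a **bacterial single-copy gene** (SCG) are removed with
   no rescue — they indicate cellular contamination;
3. surviving bins become populations;
4. populations under **10 kbp cumulative length** are dropped.

Two points were genuinely open. First, whether rescued contigs are
re-checked for SCGs: we do (`scg_on_rescued = TRUE`, toggleable), because
the intent of the rules is decontamination; a rescued contig carrying an
SCG is exactly the contamination the rules target. Rescued contigs carrying
two terL copies on a single contig are likewise dropped, since the
population invariant (at most one terL) would otherwise be violated.
Second, both "longer than 10 kb" (rescue) and "greater than 10 kbp"
(population filter) are implemented as a single inclusive `>= 10000` bp
threshold for consistency. The contig-level viral filter is strict
(`> 1000` bp), matching "longer than 1 kbp".

Among candidate binnings, `score_binning()` selects the one minimising the
number of multi-terL bins (ties: more single-terL bins, then input order).
Taxonomy uses BLAST-style hits thresholded at E ≤ 1e-5 and bit-score ≥ 50;
within a population, the longest contig with a surviving hit decides
(best hit per contig = highest bit-score, then lowest E-value, then
lexicographic taxon id — the last two tie-breaks are our deterministic
choice, unspecified in the underlying methodology).

## Abundance, normalization and breadth

Population counts are sums of member-contig counts. Normalizations:

* `log2 CPKM` = `log2(count / (lib/1e6) / (length/1e3) + 1)` for
  length-heterogeneous features (populations, families);
* `log2 CPM` without the length division (OTUs, AMGs);
* relative abundance (count / library reads) for protein clusters.

The pseudocount convention is *add 1 on the CPM/CPKM scale, then log2*
(zero counts map to 0). The upstream toolchain's exact prior-count
arithmetic is not reproduced; all acceptance properties are
convention-independent, and the pseudocount is a parameter. Library size is
the *total* QC'd reads of a sample, not the feature-column sum.

Breadth of coverage — the presence measure — is the fraction of a
population's cumulative length covered by at least one read:
`sum(member covered bases) / cumulative length`. A population is **core**
when breadth ≥ 15% in at least `ceiling(0.80 × n_samples)` samples; both
thresholds are inclusive ("at least 15%", "80% or more"), and the ceiling
is guarded against floating-point artifacts (0.8 × 15 must require 12
samples, not 13).

## Diversity and permutation statistics

* **Chao1** is the bias-corrected `S + F1(F1−1)/(2(F2+1))` by default;
  **Shannon** uses log base 2. Both choices match common toolkit defaults
  and carry flags.
* **Rarefaction** subsamples without replacement; expected richness is
  validated against the hypergeometric closed form.
* **Bray-Curtis** and **weighted UniFrac** are implemented directly;
  UniFrac defaults to the *raw* (non-normalized) form, with
  `normalized = TRUE` dividing by the abundance-weighted tree depth. Both
  agree with independent reference implementations in the test suite.
* **PERMANOVA** Gower-centres squared distances and partitions the total
  sum of squares sequentially (Type I) in the given term order — R² values
  are order-dependent, and the original analysis did not state its order;
  we default to (steer, period, diet) and expose the order. All terms are
  treated as fixed with free row permutation, which is what the standard
  implementation does regardless of fixed/random labels. P-values use the
  plus-one rule and can be computed by exhaustive enumeration for n ≤ 8.
* **Dispersion homogeneity** embeds samples by PCoA, keeping
  negative-eigenvalue axes on "imaginary" coordinates whose squared
  distances subtract, finds group spatial medians by Weiszfeld iteration
  (tolerance 1e-8), and runs a one-way ANOVA on member-to-median distances.
* The **intra-steer vs intra-diet contrast** collects within-group pairwise
  distances under both groupings and compares them with a Welch t test
  (pooled-variance flag available); positive t means the first grouping's
  distances are larger.
* **Alpha-diversity ANOVA** is main-effects-only (the crossover cannot
  support interactions), sequential in (steer, period, diet), with
  unadjusted pairwise Welch t tests between diets (Holm adjustment
  available).

## Ecological drivers

The driver analysis chains: a Pearson collinearity prefilter (|r| ≥ 0.85
pairs resolved greedily in favour of the higher-priority variable),
constrained analysis of principal coordinates (CAP/db-RDA: PCoA scores with
non-negative eigenvalues, least-squares projection onto centred
predictors), permutation tests (overall and marginal-by-term, permuting
rows of the predictor table), backward selection (drop the worst marginal
P while it exceeds 0.10), variance inflation factors, and a PLSR responder
screen.

Decisions worth knowing:

* Negative-eigenvalue PCoA axes are discarded before constraint projection
  (Bray-Curtis is non-Euclidean); this is the simplest defensible
  convention and the constrained F statistics match the standard
  implementation exactly on shared inputs.
* Backward selection follows the strict rule "drop while P > 0.10". Since
  permutation P never exceeds 1, `alpha_drop = 1` removes nothing — the
  degenerate limit is a no-op, not a full strip-down.
* PLSR (NIPALS, predictors standardized internally because the covariates
  span percent units to ppm) treats the feature matrix as the multivariate
  response block. The responder statistic — per-response percent variance
  explained by component 1, `100(1 − SS_res,1/SS_tot)` — had to be pinned,
  since "variation explained in the first component" admits several
  definitions; the univariate-predictor case reduces exactly to OLS R².
  Responders exceed 30%.
* The univariate support screen is an ordinary per-(feature, variable)
  regression reporting slope, t and two-sided P, with explicit NA reasons
  for degenerate inputs.

## Class-I AMG classification and differential abundance

A KEGG ortholog found on a bona-fide viral contig longer than 1.5 kbp
(strict) with hit E ≤ 1e-5 and bit ≥ 50 is a Class-I auxiliary metabolic
gene iff it belongs to at least one KEGG *metabolic* pathway and is not
confined to the excluded list (recombination, repair, replication,
nucleotide/amino-acid housekeeping: ko03440, ko03430, ko00970, ko00230,
ko00240, ko03030, ko00520, ko01230, ko03410, ko00270, ko00330) without a
rescuing membership in carbon metabolism (ko01200), nitrogen metabolism
(ko00910) or the pentose phosphate pathway (ko00030). The
metabolic-category flag travels with the KO→pathway input table rather than
a bundled KEGG snapshot. ORFs under 60 amino acids are dropped at
table-read time.

Differential abundance between the two deeply sequenced diets uses
median-of-ratios size factors computed **from all ORFs** (not the AMG
subset — the one normalization detail the original analysis emphasises)
and a simplified negative-binomial Wald test: per-KO method-of-moments
dispersion, moderated by flooring at the across-KO median (information
sharing across features, in the spirit of shrinkage-based tools, without
reproducing their estimators), delta-method standard error on the log
ratio of group means, standard-normal reference, Benjamini-Hochberg
adjustment. Under a negative-binomial null (1000 KOs, 3 vs 3) this test
rejects at ≈ 4.7% for nominal 5%, and detects a planted 8-fold change at
μ = 200 in ≥ 90% of replicates at FDR 0.05.

## The synthetic world

The generator emulates the study's structure with known truth; its defaults
are stated once and are not calibrated to any measured outcome.

Counts follow a log-normal multinomial: population p in sample j has log2
intensity `a_p + β_p (TDN_j − mean TDN) + u_{p,steer(j)} + ε_pj` with
`ε ~ N(0, 0.5²)` and per-(population, steer) intercepts `u ~ N(0, 0.3²)`;
a single multinomial per sample (library sizes uniform on 150k--400k)
distributes reads over contigs proportionally to length × intensity, so
column sums equal library sizes exactly. Responder slopes are
`±effect_size / range(TDN)` with `effect_size = 2` log2 units across the
gradient — our choice of a "clearly detectable but not trivial" effect; the
underlying study reports no quantitative effect sizes. Covered bases follow
the Lander-Waterman expectation `breadth = 1 − exp(−depth)` scaled to
contig length. Contig lengths are log-normal (median 15 kbp, truncated
above 1 kbp), consistent with the 10.5--104 kbp core-population range the
field reports.

Presence structure is part of the stated world: planted core populations
(baseline log2 ≈ 4) are deep enough that breadth ≥ 15% everywhere;
responders (baseline ≈ 1.5) are structurally absent from the diet(s) at the
unfavourable end of their TDN gradient — below-detection at that end is
both ecologically sensible and guarantees they are not core; background
populations and contaminant contigs are absent from at least
`n − ceiling(0.8 n) + 1` random samples. Consequently the detected core
equals the planted core exactly, which is what the recovery suite asserts.
Slope-recovery checks regress on *present* samples, where the log-linear
model is correctly specified; across-all-samples regressions would mix the
presence process into the slope.

One derived pseudo-random stream per output table means adding a new table
never perturbs existing ones; the same master seed yields byte-identical
tables.

**What a green test does not establish.** The generator has no sequencing
error, no assembly artifacts, no chimeric bins beyond the planted marker
violations, no compositional load shifts beyond the planted effects, and
independent populations (no co-occurrence structure). Contaminant detection
at precision = recall = 1 reflects that the simulated marker annotations
are noiseless — real terL/SCG annotation is not. Null calibrations are run
under the fully exchangeable null (no diet *and* no steer effects): in a
balanced crossover, animal random intercepts cancel out of OLS diet
contrasts while inflating the naive residual, so the simple univariate
screen is *conservative* when animal effects exist, and free-permutation
PERMANOVA is only approximate under block structure. These are properties
of the methods themselves (as commonly applied in the field), not
implementation defects.

## Numerical conventions

Permutation P-values use `(#{F* ≥ F_obs} + 1)/(n_perm + 1)` (never zero);
exhaustive enumeration includes the identity. Ties in F comparisons use a
1e-12 slack. Perfect separation reports `F = Inf`. The Weiszfeld iteration
caps at 500 steps. Exact collinearity yields `VIF = Inf` and, in CAP, an
error naming the dependent columns (`allow_aliased = TRUE` keeps them, with
zero marginal contribution). Degenerate t tests (zero variance in both
groups) return t = 0, P = 1 when means agree and ±Inf, P = 0 otherwise.

## Known limitations

The PERMANOVA/CAP machinery treats all factors as fixed and permutes
freely; restricted permutation schemes for the row-column structure are out
of scope. The NB test's dispersion moderation is a floor, not an empirical
Bayes fit. PLSR cross-validation is plain leave-one-out RMSEP, reported as
a diagnostic only. The CLI covers simulate/curate/core; the statistical
operations are R-level API.
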