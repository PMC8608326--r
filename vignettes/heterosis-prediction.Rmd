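---
title: "Predicting hybrid heterosis from windowed parental genetic similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hybrid heterosis from windowed parental genetic similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hybrid breeding programs based on cytoplasmic male sterility (CMS) — such as
the *Ogura* system in rapeseed (*Brassica napus*) — must identify parental
combinations whose F1 shows strong heterosis: superiority of the hybrid over
its better parent (high-parent heterosis, HPH) or over the parental mean
(mid-parent heterosis, MPH). Field-testing every candidate cross is the
bottleneck; genomic selection (GS) replaces most of that testing with
predictions from parental genome sequences.

`pgsihet` implements a GS approach built around one idea: summarize the two
parental genomes of each candidate cross into a vector of *regional parental
genetic similarity indices* (PGSI), one per fixed-width genome window, and
predict heterosis from those window features. A window where the parents are
dissimilar is a window where the F1 will be heterozygous; windows whose
similarity consistently tracks heterosis across a training population of
crosses are called *h-QTLs*.

## The PGSI

For a cross between inbred parents P1 and P2, every SNP site where both
parents have a called (homozygous) genotype receives a mark:

* **2** — both parents carry the same nucleotide (regardless of whether it is
  the reference allele; identity takes precedence);
* **1** — one parent matches the reference, the other does not;
* **0** — the parents differ from each other and both differ from the
  reference (possible only at multiallelic sites).

The PGSI of a window is the accumulated mark divided by twice the number of
informative loci, so it lies in [0, 1]: identical parents score 1, a window
of all ref-hom/alt-hom contrasts scores 0.5. A description of the index as
"two times the accumulated marks divided by the locus count" also circulates;
that scaling has range [0, 4] and is available behind `literal = TRUE` for
auditability, but the normalized form is the default because it is the unique
scaling under which marks behave as shared-allele counts on the unit
interval. Sites with a missing call in either parent enter neither numerator
nor denominator. A window with no informative locus for a cross is scored 1
by default — among the called SNPs of the panel, no divergence was observed —
with a per-cell flag, and can instead be set missing (`empty = "missing"`);
the model layer mean-imputes missing feature cells.

Windows are fixed-width (100 kb, 500 kb, 1 Mb by convention), contiguous and
half-open `[start, end)` in 0-based coordinates, deliberately ignoring local
LD structure and gene content: LD-aware windows would require a per-cross LD
notion that is not well defined. Exports use BED conventions for intervals
and 1-based indices for h-QTL names.

## Phenotype integration and heterosis

Replicate-level phenotypes from multi-environment trials are integrated in
two steps: replicates are collapsed to genotype-by-environment means, then a
linear mixed model `y = 1*mu + Z*g + E*u + e` is fitted to the means with
genotype `g` fixed and environment `u` random, giving each genotype a best
linear unbiased estimate (BLUE) on the trait scale. The two variance
components are estimated by REML; the implementation profiles the ratio
`lambda = var(env)/var(resid)` on the environment-block compound-symmetry
structure and maximizes the restricted likelihood by Brent search on
`log(lambda)` in [-12, 12], which reduces to simple genotype means for
single-environment data. (The suite cross-checks the fixed-effect estimates
and variance components against `lme4` on unbalanced layouts.)

From the BLUEs, for each cross with parental values P1 and P2:

* `HPH = (F1 - max(P1, P2)) / max(P1, P2)`
* `MPH = (F1 - (P1 + P2)/2) / ((P1 + P2)/2)`

Values are kept as fractions internally and exported as rounded percentages.
The "high parent" is always the numerically larger parent; traits where
smaller values are agronomically better are not special-cased. Cells with a
non-positive denominator are set missing with a warning, since relative
heterosis is meaningless there.

## Prediction models

Six model flavors share the linear model
`y = X*beta + sum_k Z_k * gamma_k + e` with an intercept-only `X` by default:

* **GBLUP_A** — marker effects integrated out through the kinship
  `K = (1/m) * Z Z'` built from additive codes (1 = minor-allele homozygote,
  0 = heterozygote, -1 = major-allele homozygote; the minor allele is the
  rarer allele in the coded population, ties resolved to the alternate
  allele). `var(y) = K*phi^2 + I*sigma^2`; the ratio `phi^2/sigma^2` is
  estimated by REML via the eigendecomposition of K and Brent search over
  `log(lambda)` in [-6, 6] (tolerance 1e-8). A ratio at the boundary is
  reported, not an error — it is the legitimate answer for a trait with no
  (or overwhelming) genetic variance.
* **GBLUP_AD** — adds a dominance kinship built identically from a
  mean-centered heterozygosity indicator (het = 1, hom = 0). The two ratios
  are maximized by Nelder-Mead on the log scale (at most 500 iterations).
* **LASSO_SNP** — L1-penalized regression directly on a random subsample of
  the additive marker codes. Following the source protocol, the subsample is
  0.05% of markers (seeded), and the same subsample default applies when
  markers feed GBLUP; a flag allows the full marker set.
* **LASSO_100Kb / LASSO_500Kb / LASSO_1Mb** — L1-penalized regression on the
  PGSI matrix at the named window width.

All LASSO flavors standardize feature columns internally, choose the penalty
by seeded inner 10-fold cross-validation over a ~100-point logarithmic path
(`glmnet`), then *re-estimate* the selected variables by ordinary least
squares (a 1e-8 ridge on the normal equations guards near-collinearity; if
the selection reaches n-1 features, the largest-|coefficient| n/2 are kept,
with a message). Predictions use only the re-estimated coefficients.
Inbred-parent F1 genotypes are inferred from the parental calls (one allele
per parent), since hybrids are never sequenced in this design; heterozygous
calls in a nominal inbred are masked (or rejected in strict mode), and
multiallelic sites are reduced to reference plus the most frequent alternate.

## h-QTL extraction, naming and mapping

Every window selected by a window-feature LASSO model is an h-QTL; its
re-estimated coefficient is the effect criterion. The top and bottom 10% of
coefficients (ceiling counts, ties broken by larger magnitude then earlier
position) are flagged *high-impact*. Because the features are similarity
indices, a *negative* coefficient means dissimilarity favors heterosis; by
the field's display convention that is a **positive** effect label, and the
raw coefficient is always exported alongside the label to avoid ambiguity.
Records are named `Chr.<chrom>-<NN>` counting from the chromosome top
(zero-padded, growing past two digits when needed). Windows on unplaced
scaffolds are retained in tables but flagged unmappable and left out of BED
tracks. Per-chromosome *influence* is the sum of absolute window-heterosis
correlations, with A/C subgenome aggregates taken from the chromosome name
prefix; gene lookup intersects the half-open windows with the `gene` features
of a GFF3 annotation (`rtracklayer`/`GenomicRanges`).

## Predictability

Predictability is estimated by k-fold cross-validation (default k = 10)
replicated with fresh random partitions (default 100). Within a replicate
every hybrid is predicted exactly once; the replicate's predictability is the
single Pearson correlation between observed heterosis and the pooled
out-of-fold predictions, and the reported value is the mean over replicates.
Heterosis is computed once from the BLUEs before cross-validation — folds
split hybrids, never phenotype records — and the LASSO penalty search is
nested inside each training fold with a seed derived from (seed, replicate,
fold).

One numerical subtlety deserves a note. If each fold's predictions carry that
fold's own fitted intercept, a trait with *no* genetic signal scores a
spurious negative predictability of about `-1/sqrt(fold size)` — the held-out
fold is exactly what the training mean is missing. Out-of-fold predictions
are therefore anchored at the full-sample mean (a single scalar; fold models
still estimate everything else from their own training data), which restores
a near-zero null and agrees closely with the fold-intercept convention
whenever genuine signal is present. Even so, pooled cross-validated
correlations retain a small negative bias under the null (about -0.05 at 400
individuals with 10 folds), which is why the package's null calibration is
run at the study's own population size.

External validation refits the chosen model on the full training population
and correlates predictions with observations on an independent test
population (hybrid IDs must be disjoint from training; parents may overlap,
as they do when the same female pool is crossed to new testers). Per-group
correlations (e.g. per male tester) support comparing restorer candidates.

## The synthetic cross population

Because the original resequencing data are not publicly deposited, the
package ships a seeded simulator that reproduces the *shape* of the study:
50 inbred female (CMS) lines crossed to 8 inbred male (restorer) lines in a
full factorial (400 F1s), optional held-out testers (e.g. 2 x 50 = 100 test
hybrids), six yield-related traits, 3 environments x 3 replicates.

* **Genomes.** Founder haplotypes are drawn per site from alternate-allele
  frequencies ~ Beta(0.5, 0.5) truncated to (0.05, 0.95) (a U-shaped folded
  site-frequency spectrum typical of resequencing panels); each inbred parent
  is a homozygous mosaic of founders on a fixed 250-kb segment grid, creating
  block LD at roughly the scale reported for rapeseed breeding pools
  (LD decay < 100 kb; segments a few times larger keep windows internally
  correlated). The default genome is 4 chromosomes x 5 Mb at 1 SNP/kb
  (20,000 SNPs, 200 windows of 100 kb) so that the full pipeline runs in
  minutes; a 19-chromosome A/C-named preset exercises naming and subgenome
  logic. What the simulator does *not* emulate: coalescent-accurate LD,
  recombination-map heterogeneity, selection history, genotyping error, and
  genome-scale marker counts — so passing tests demonstrate correctness and
  qualitative behavior of the method, not field-scale accuracy figures.
* **Traits.** Per trait, hybrid genetic value =
  `mu + GCA_female + GCA_male + sum_w beta_w * PGSI_w(cross)` with 10
  negative-coefficient (dissimilarity-favoring) and 10 positive-coefficient
  planted windows; coefficients are rescaled so the window term explains a
  configured fraction (default 0.5) of a unit hybrid genetic variance, the
  remainder split equally between the two general-combining-ability terms.
  Parents get `mu + 2*GCA - delta` with an inbreeding depression of
  `delta = 0.5` genetic-SD units, which makes mean MPH visibly positive
  (about +5% at the default trait mean of 10). Observations add a common
  random environment offset (SD 0.5) and replicate noise sized from the
  entry-mean heritability (default 0.7). The GCA vectors and the window term
  are empirically centered and scaled, so the planted variance fractions are
  exact in every realization; the planted truth (windows, signed
  coefficients, GCA, offsets) is serializable for recovery scoring.

With these defaults the window-LASSO model recovers the planted windows with
median recall around 0.7, its high-impact set has precision around 0.5, and
mean predictability orders window-PGSI LASSO > GBLUP_A > LASSO_SNP — the
qualitative pattern expected when effects are window-structured and the SNP
model sees only a 0.05% marker subsample.

## Numerical and design choices

* Seeds are explicit everywhere randomness occurs (simulation, marker
  subsampling, fold partitions, penalty search); child streams are derived
  deterministically and recorded in outputs.
* REML search ranges: `log(lambda)` in [-6, 6] for GBLUP (tolerance 1e-8),
  [-12, 12] for the BLUE environment ratio; two-component fits use
  Nelder-Mead with `reltol` 1e-10.
* Minor-allele ties at exactly 0.5 frequency resolve to the alternate
  allele; monomorphic markers are coded constant and flagged, not dropped.
* Missing genotype codes stay missing at the coding layer; kinship
  mean-imputes per marker, PGSI excludes the locus, LASSO features
  mean-impute per column.
* Half-open window intervals mean a gene starting exactly at a window end is
  *not* counted inside it.
* Test-suite and acceptance problem sizes (20k-SNP genomes, 400 hybrids,
  2 CV replicates per seed, 5-10 simulation seeds per study) were chosen so
  the whole suite runs in a few minutes on one CPU while keeping every
  qualitative conclusion stable across seeds.

## Known limitations

* The BLUE model has no genotype-by-environment interaction term and no
  spatial field adjustment, matching the source protocol.
* PGSI windows ignore LD boundaries by design; an h-QTL window may span
  several LD blocks and its gene list is correspondingly coarse.
* The dominance kinship construction (centered heterozygosity indicator) is
  one standard choice among several; with fully inbred parents and a single
  F1 generation it is near-degenerate, which is exactly the regime in which
  additive and additive-plus-dominance fits coincide.
* Predictability estimates from pooled cross-validation are slightly
  conservative (see the null-bias note above).
* The published headline numbers (predictabilities near 0.97, 172 GY-HPH
  h-QTLs) depend on the study's unreleased 4.44-million-SNP panel; they are
  not reproducible from this package's synthetic data and are not asserted
  by its tests.
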