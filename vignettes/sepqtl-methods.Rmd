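---
title: "Models and methods behind sepqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sepqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sepqtl` maps genetic regulation of gene expression in cohorts of
critically ill patients sampled serially during intensive-care admission.
This vignette explains the models, the tunable parameters and their
defaults, what the synthetic cohort generator does and does not emulate,
and the design decisions taken where more than one reasonable choice
existed.

## The repeated-measures mixed model

Every association stage rests on one engine: a Gaussian linear mixed model
with a single random intercept per individual,

$$ y_{is} = x_{is}^\top\beta + u_i + \varepsilon_{is}, \qquad
   u_i \sim N(0, \sigma^2_u),\quad \varepsilon_{is} \sim N(0, \sigma^2_e), $$

where $i$ indexes individuals and $s$ their serial samples (up to three
per patient). The random intercept lets all samples contribute without
pseudo-replication. `fit_lmm()` maximizes the *marginal likelihood*
profiled over the variance ratio $\lambda = \sigma^2_u/\sigma^2_e$: given
$\lambda$, the group-mean shrinkage transform reduces the model to
ordinary least squares, so fitting is a one-dimensional search over
$\log\lambda$ with the boundary $\lambda = 0$ (no between-individual
variance) permitted; there the fit equals OLS exactly. Maximum likelihood
rather than REML is used throughout because every hypothesis test in the
pipeline is a likelihood-ratio test between nested *fixed-effect*
specifications, which requires ML fits. No boundary correction is applied
to the $\chi^2$ reference for fixed-effect tests; the simulated size of
the 1-df test at $\alpha = 0.05$ is about 0.055--0.06 at 150 individuals
with two samples each, i.e. very close to nominal. Exactly collinear
covariates are dropped deterministically (leftmost kept) with a warning.

## cis-eQTL mapping and hierarchical correction

For each gene, SNPs within 1 Mb of the TSS (both sides; minor-allele
dosage coding, cohort MAF at least 1%) are tested by a 1-df LRT on the
dosage term, with fixed covariates: seven genotype principal components,
twenty hidden expression factors, inverse-normal-transformed measured
cell proportions, SRS1 status and diagnosis. Correction is hierarchical:

1. *Local:* the gene's peak p-value is Bonferroni-corrected by the
   effective number of tests $M_\mathrm{eff}$, computed from the
   eigenvalues of the dosage correlation matrix after Ledoit-Wolf-style
   shrinkage toward the identity, in consecutive partitions of at most
   200 SNPs, with the 0.99 cumulative-eigenvalue rule. These parameter
   values are the conventions of the standard effective-test estimator;
   all are exposed as arguments.
2. *Global:* BH across gene-level peak values at FDR 0.05 defines eGenes;
   the largest passing locally adjusted value $q^*$ sets each eGene's
   nominal threshold $q^*/M_{\mathrm{eff},g}$ for additional significant
   SNPs.

Conditional discovery is forward-backward: rescan conditioning on all
previous leads and adopt the new peak while it clears the gene threshold;
then re-test each signal conditioning on the *other* leads, replacing or
dropping it; finally report joint effects from one model containing all
retained leads. Two details are deliberate: the per-gene threshold is
computed once from the first pass and reused throughout (keeping the
procedure monotone), and the primary lead is seeded from the first-pass
peak unconditionally, because the eGene call has already established its
significance - a strict `p < threshold` gate would reject the boundary
eGene whose peak p equals $q^*/M_\mathrm{eff}$ exactly. Ties on p are
broken toward the smaller genomic position.

## Interactions and their permutation null

Independent signals are tested for genotype-by-context interactions with
SRS1, diagnosis, the three measured cell proportions (inverse-normal
scale) and sex. Eligibility demands at least two minor-allele-homozygote
individuals in each environment subgroup, or each half of a continuous
environment split at the median (ties to the lower half). The model adds
`G + E + G:E` to the standard covariates (E removed from the covariate
list when already present) and other same-gene leads; the interaction p
is a 1-df LRT on `G:E`. For sex, which is not a standard covariate, the
main eQTL must first stay significant with sex in the model. Environments
are coded SRS1 = 1, FP = 1, female = 1, so that a significant interaction
with the same sign as the genotype main effect ("top-right / bottom-left
quadrant") is a *magnifier* and an opposing sign a *dampener*; the
classification is invariant to flipping the coded allele.

The permutation null permutes SRS across samples but diagnosis across
patients (it is constant within a patient), re-runs the full analysis,
and counts BH-significant interactions. The headline empirical p uses the
add-one count estimator. Because that count is a small discrete statistic
(ties at zero dominate under the null), the count-based p is inherently
conservative, so `permutation_null()` also returns a refined p that
breaks count ties by the smallest nominal interaction p; the refined
version is uniform under the null, which is what the calibration tests
check. Both are reported.

## Effect sharing between conditions

To compare effects measured in two conditions (for instance a disease
cohort against a reference cohort's summary statistics), the prior on the
true effect pair is a mixture over canonical covariance patterns - the
point-mass null, equal effects, independent effects, each
condition-specific pattern, and heterogeneous correlations 0.25/0.5/0.75 -
each scaled over an automatic geometric grid of variances, plus an
optional rank-1 data-driven component from the strong-set SVD. EM on
"random" pairs estimates only the mixture weights; a Dirichlet
pseudo-count of 10 on the null directs weight the data cannot
distinguish onto the null rather than spreading it over near-null scales.
Posterior means and local false sign rates on the "strong" pairs then
categorize condition-1-significant effects: *opposite* when significant
in both with opposite posterior signs; *shared* when same-signed with
$|\tilde b_1|/|\tilde b_2|$ inside the band $[1/2, 2]$; *magnified* above
the band or when significant only in condition 1; *dampened* otherwise.
The band is the ratio reading of "within a factor of 0.5"; the phrase
also admits a difference reading $|\tilde b_1 - \tilde b_2| \le
0.5|\tilde b_2|$, selectable via `rule = "difference"`. Note that with
point-mass components the lfsr ranges over $[0,1]$, approaching 1 for
null pairs.

## Regulatory drivers

The motif stage scans reference and alternate alleles of each eSNP (and
its LD proxies at $r^2 \ge 0.8$ within 1 Mb) against position weight
matrices in JASPAR text format, scoring uniform-background log-odds over
every window overlapping the SNP on both strands; a hit is a window
reaching 80% of the matrix's maximum achievable score, a transparent
re-scoring convention standing in for precomputed hit databases
(`hit_fraction` is exposed). Per independent signal and motif, the calls
collapse to a binary "at least one site altered" indicator; a one-sided
Fisher test per motif compares interaction against non-interaction
signals, BH-corrected over motifs altered at least once, with a
1000-fold permutation of interaction labels giving the expected number of
enriched motifs by chance.

TF activity is estimated per sample from curated regulons (evidence
levels A-C, at least five targets present): expression is standardized
within the sample and regressed on the regulon mode vector; the slope's
t-statistic is the activity. This univariate-regression estimator is a
single deterministic choice standing in for multi-method consensus
scores and is named in the output metadata. Differential activity between
SRS groups uses the random-intercept LMM per TF with BH correction and an
optional SRS-permutation check; activity-cell-proportion relationships
use Spearman correlation on each patient's first available sample.

## Co-expression modules

Module discovery works on between-individual variation: the top 20
expression PCs are regressed out (gene-centered residuals), serial
samples are averaged per individual, and the biweight midcorrelation
(median/MAD weights, unscaled MAD, Pearson fallback for zero-MAD genes)
gives a robust similarity matrix. Spatial quantile normalization removes
the mean-correlation bias: genes are ranked by mean expression into
contiguous blocks (21 blocks in the study-scale configuration, reference
block 18 - a high- but not top-expression block whose correlations are
least biased), and every block pair's correlations are quantile-mapped
onto the reference block's distribution, preserving rank order, symmetry
and the unit diagonal.

The network uses unsigned adjacency $a_{ij} = |\rho_{ij}|^{\beta}$ with
soft power 4 by default (the automatic alternative picks the smallest
power in 1..20 whose connectivity distribution fits a scale-free log-log
line with $R^2 \ge 0.8$ over 10 bins), and the topological overlap
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})$.
Modules come from average-linkage clustering on $1-\mathrm{TOM}$ cut at
0.98 of the maximum merge height; clusters under 10 genes stay
unassigned, and modules whose eigengenes are closer than 0.1
(1 − correlation) merge iteratively. The cut rule is a deliberate static
simplification of adaptive branch cutting: tight co-expression branches
join far below the root while unclustered genes chain in just beneath it,
so a cut just under the root detaches the background; a cut at a
*quantile* of merge heights does not work, because on unstructured data
almost all merges sit below any high quantile and everything would fuse
into giant pseudo-modules. On planted two-block data the static rule
recovers memberships with Jaccard above 0.9 and leaves pure noise fully
unassigned. The module eigengene is the first right singular vector of
the standardized member matrix (unit-norm sample scores), sign-aligned to
the module mean profile; the alignment is equivariant, so negating all
members flips the eigengene - downstream tests are sign-symmetric.

Module annotation fits eigengene-phenotype mixed models, a Cox
proportional-hazards model (Efron ties) of 28-day survival on each
patient's last-time-point eigengene, and hypergeometric marker-set
enrichment against the expressed-gene universe, each family BH-corrected.

## Module QTLs, sensitivity, mediation, colocalization

Candidate SNPs (lead eSNPs with more than three minor-allele homozygotes)
are tested against every module eigengene with the standard mixed model
under the genome-wide Bonferroni threshold $\alpha/(n_\mathrm{SNPs}\times
n_\mathrm{modules})$ - at the study's scale (12,335 SNPs, 106 modules,
$\alpha=0.05$) this is $3.8\times10^{-8}$. Loci merge overlapping 1 Mb
windows per module. Replication on a second platform requires at least
five covered genes, compares eigengenes by Spearman correlation on
overlapping samples, retests the lead in independent samples, and judges
direction concordance by the sign product
$\mathrm{sign}(\beta_A)\,\mathrm{sign}(\rho)\,\mathrm{sign}(\beta_B)$.
The sensitivity analysis recomputes the eigengene after removing member
genes that are cis-eGenes of the module's QTL SNPs; a trans-network
association survives, a cis-driven artifact does not.

Mediation of SNP → module effects through a cis gene uses the
quasi-Bayesian approximation: mediator and outcome linear models on one
sample per individual (the first available - fixed-effect linear models
are what the quasi-Bayesian machinery is defined for, and the
repeated-measures treatment here is an open choice), coefficient draws
from the asymptotic normal, per-draw $\mathrm{ACME} = ab$, $\mathrm{ADE} =
c'$, percentile intervals over 1000 draws, effects per additional copy of
the minor allele. The proportion mediated reports the per-draw ratio's
median, since the mean explodes when total-effect draws approach zero.
Colocalization uses Wakefield log approximate Bayes factors
$\tfrac12\log\frac{V}{V+W} + \tfrac{z^2}{2}\frac{W}{V+W}$ with priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (the method's defaults) and
prior effect variance $W = 0.15^2$ on the standardized-trait scale
(configurable; a conventional quantitative-trait choice).

## The synthetic cohort generator

`simulate_cohort()` emulates the observational design the pipeline is
meant for: 200-700 genotyped individuals; one to three serial samples
each (the sample-count distribution is configurable; recovery experiments
in the tests use three samples per individual); per-sample SRS1 status
with individual-level persistence (logit-normal propensity, prevalence
0.35); diagnosis fixed per patient (40% FP); Dirichlet cell proportions
(neutrophil-dominated, weights 10.5/3/1.5) optionally shifted toward
neutrophils in SRS1 samples so interaction-overlap analyses have
structure; occasional missing proportions; exponential 28-day survival
whose log-hazard tracks the first module factor. Genotypes are
Hardy-Weinberg haplotypes with first-order autoregressive LD inside
blocks (copy probability 0.8, block size 20 by default) - enough LD
structure to exercise proxy expansion and effective-test logic without a
coalescent simulator. Expression is built additively from planted cis
effects, environment main effects and interactions, module factors,
an individual random intercept ($\sigma^2_u = 0.3$) and residual noise
($\sigma^2_e = 0.7$), an intraclass correlation in the range reported for
repeated blood transcriptomes. For a driven module the mediator gene
receives the driver's cis effect ($\beta = 0.8$ at MAF ~0.3) and the
module factor is $\rho\,\mathrm{std}(y_\mathrm{mediator}) +
\sqrt{1-\rho^2}\,z$ with mediation fraction $\rho = 0.85$, making the
driver explain about 15% of factor variance - a deliberately strong,
clearly detectable trans architecture.

What the generator does *not* emulate: population structure and
relatedness, imputation uncertainty, read-level measurement error,
library-size artifacts, or realistic gene-gene correlation beyond the
planted blocks. Passing recovery tests therefore demonstrates the
statistical machinery is correct and calibrated under its own model
assumptions, not that real sepsis cohorts satisfy those assumptions.

Two small-panel caveats matter when driving the pipeline on toy data:
genotype PCs computed from a few dozen SNPs in one LD region align with
the tested SNPs themselves, and expression PCs computed from a few dozen
genes align with individual planted genes - both then absorb the signal
they are meant to leave alone. At genome scale neither can happen; the
test fixtures therefore disable these nuisance covariates rather than
misuse them.

## Numerical choices

Profiled-likelihood search over $\log\lambda \in [\log 10^{-8},
\log 10^{4}]$ with `optimize` at tolerance $10^{-6}$; residual variance
floored at $10^{-12}$ with the fit flagged degenerate rather than
failing; EM stops at relative penalized-log-likelihood change below
$10^{-6}$ or 500 iterations; rank-based inverse normal transforms use the
Blom offset 3/8 with average ranks for ties and median imputation *before*
the transform (the natural reading of imputing on the measurement scale);
quantile mapping uses type-7 quantiles at mid-rank positions; and all
stochastic functions accept explicit seeds.

Problem sizes used by the test-suite and the acceptance script - cohorts
of 120-300 individuals, 8-60 SNPs, 6-55 genes, 100 cis replicates, 200
permutation meta-replicates, 1000-2000 null simulations, 5000
effect-sharing pairs - were chosen as the smallest designs at which each
planted effect is unambiguously recoverable, keeping the whole suite in
the minutes range on a single core.
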