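---
title: "Weighted linear mixed models for cis/trans QTL mapping and SNP-induced networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted linear mixed models for cis/trans QTL mapping and SNP-induced networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Expression profiles of the same genotyped lymphoblastoid cell lines are
available from several RNA-seq datasets produced by different laboratories,
on different platforms, at very different sequencing depths.  Pooling them
buys sample size but brings three statistical complications at once:

* **batch effects** — each dataset has its own location shift;
* **heteroscedasticity** — shallow datasets yield much noisier expression
  values than deep ones;
* **repeated measures** — many cell lines are measured in two or three
  datasets, so their samples are correlated.

`wlmmqtl` implements the analysis built around a weighted linear mixed model
(WLMM) that addresses all three, and everything downstream of it: genotype
encoding and composite-LD pruning, exon-level expression indexes,
permutation-based FDR thresholds, cis and trans association scans,
genomic-region profiles, and the assembly of cis-to-trans regulatory
relationships into four network paradigms.

# The model

For one gene and one SNP, with samples $i = 1 \dots r$,

$$ Y = X\beta + Zb + e, \qquad b \sim N(0, \sigma_b^2 I_q), \qquad
   e \sim N(0, \sigma_e^2 W^{-1}) $$

where $X$ holds the fixed effects — a cell-means indicator block for the
dataset GROUP (batches) and the additive genotype code (0/1/2 reference
alleles, coefficient $\beta_G$) — $Z$ is the indicator matrix of the SUBJECT
(cell line) random intercept, and $W$ is diagonal with known weights.  The
weight of a sample is the reciprocal of the sample variance of the trait in
its dataset group (normalised to mean 1; the proportionality constant is
arbitrary and recorded in the output), the classical weighted-least-squares
treatment of group heteroscedasticity.

Dropping the random effect gives the heteroscedastic fixed-effects model
(HLM, weighted least squares); dropping the weights too gives the ordinary
linear model (OLM).  These reductions are exact: with equal weights the HLM
fit *is* the OLM fit, and with $\sigma_b^2$ pinned at zero the mixed fit
reproduces ordinary least squares — both identities are asserted in the test
suite to $10^{-8}$.

**Expression (eQTL) testing.** $H_0:\beta_G = 0$ is tested with
$z = \hat\beta_G / SE(\hat\beta_G)$ against the standard normal.  The normal
reference is the large-$q$ approximation; the number of cell lines is
carried in every test record so callers on small studies can warn.

**Splicing (sQTL) testing.** The response is the rescaled exon expression
index: an exon's RPKM divided by the mean RPKM of the exons of its gene in
the same sample, so the indexes of one (sample, gene) average exactly 1 and
carry relative splicing signal rather than overall expression.  The model
adds EXON cell means, GROUP×EXON batch terms, and the tested
GENOTYPE×EXON interaction block; weights are computed per
(group, exon) cell — the most literal reading of weighting "with respect to
a specific exon" — and the subject intercept is kept.  The Wald $F$ for the
interaction block with $v_1$ estimable coefficients is converted to
$X^2 = F \cdot v_1$ and referred to $\chi^2_{v_1}$, the large-residual-df
approximation; for fixed-effects fits the exact $F$ p-value is recorded
alongside.  The Wald form of the block test is used (the alternative,
sequential sums of squares, is not implemented; the choice is labelled in
the output).

# REML fitting

Variance components are estimated by REML, profiling the ratio
$\lambda = \sigma_b^2/\sigma_e^2$.  With a single grouping factor $Z'WZ$ is
diagonal, so after one pass over the data (cross-products of $X$, $y$ and
the per-subject weight sums) each profile evaluation costs $O(p^2 q)$ via
the Woodbury identity, and the scalar search over
$\log\lambda \in [-12, 12]$ (tolerance $10^{-8}$) is cheap enough to run
hundreds of thousands of fits in the permutation scans.  Boundary optima
are reported as $\sigma_b^2 = 0$ fits with a flag; singular cross-products
yield a non-convergence flag rather than an exception, and non-converged
pairs are excluded from scans and counted.  The fit is verified in the test
suite against three independent oracles: the closed-form balanced-ANOVA
variance-component estimators, a dense GLS solve at pinned components, and
`lme4::lmer` (fixed effects, standard errors, both variance components and
the REML criterion agree to $10^{-5}$ or better on replicated
heteroscedastic data).

AIC uses $-2\log L + 2k$ with $k$ = fixed effects + variance parameters
($p+1$ for the fixed-effects models under Gaussian ML, $p+2$ for the mixed
model from the REML objective).  Comparing a REML-based AIC with an ML-based
one across model families is a heuristic, and `compare_models()` labels it
as such; adjusted $R^2$ is reported for the fixed-effects models only,
since the criterion is not recommended for mixed models.

# Scans, FDR and the two-step sQTL procedure

A SNP is **cis** to a gene when it lies within the transcript span extended
by 20,000 nt on each side (inclusive boundaries, strand-agnostic since the
flanks are symmetric); a pair is **trans** when on different chromosomes or
at least 1,000,000 nt apart; pairs in the band between are never tested.
Within each gene's cis set, SNPs are pruned to composite-LD independence:
the correlation of 0/1/2 codes over jointly observed lines (the standard
composite estimator for unphased diploids) is $t$-tested, p-values are
Bonferroni-adjusted by the number of pairs in the subset, and SNPs are
retained greedily in genomic order, dropping any SNP whose adjusted p
against a retained one falls below 0.01 (degenerate zero-variance pairs
count as dependent).  Greedy positional order makes pruning deterministic
and idempotent; both properties are tested.

Significance thresholds come from permutation: genotypes are permuted
across *cell lines* (replicates keep a common, wrong genotype, preserving
the subject dependence structure under the null; sample-level permutation
would break it), k = 4 times for the mixed-model scans and k = 10 for the
fixed-effects refinement.  Null p-values are pooled across tests, and the
threshold $z$ is the largest observed p-value at which
$\hat P(p_0 < z) / \hat P(p_1 < z) \le x$, with strict inequalities on both
sides and candidates restricted to observed p-values.  eQTLs are called at
$x = 0.01$.  sQTLs use the two-step procedure: the mixed splicing model
screens at $x = 0.05$, then the weighted fixed-effects splicing model
refines the survivors at $x = 0.01$; final calls survive both steps, and
mixed-model non-convergence excludes a pair from step 1 with a count.

Trans scanning starts only from SNPs already called cis — the mediation
assumption that the host gene relays the genotype's effect — and applies
the same raw-p thresholds derived in the cis scans: the expression
threshold for trans-expression, and (by default) both two-step thresholds
for trans-splicing.  The wording of the original criterion admits a second
reading, the step-2 threshold alone, which is available as
`trans_sqtl_rule = "model2b_only"`; both choices are recorded in the
output.

Edges are then regulator → target pairs per paradigm: the cis mechanism
(expression/splicing) crossed with the trans mechanism gives C1–C4, a SNP
with both cis mechanisms contributes to both corresponding paradigms, and
hub modules group edges by (regulator, paradigm) with distinct-SNP and
distinct-target counts.  Because the unit of a "connection" is
convention-dependent, the per-paradigm summary reports both distinct gene
pairs and (SNP, gene-pair) triples.  The average targets-per-regulator
ratio is truncated (not rounded) to one decimal, matching how such ratios
are conventionally printed.  The target-count CCDF $P(X > x)$ is emitted
with optional upper truncation for double-log plotting; power-law exponent
fitting is deliberately out of scope.

# What the generator emulates — and what it does not

`simulate_qtl_study()` reproduces the design the models exist for, at a
desk scale chosen to keep the full test suite within minutes:

* 140 cell lines from two populations measured in four dataset groups
  (41 + 59 partially overlapping lines once each in the first population;
  69 lines measured twice in the second), so 70% of lines are replicated;
* group batch offsets and group-specific residual standard deviations
  (deepest dataset least noisy: 1, 2, 2, 1.2 expression units), and a
  subject effect with $\sigma_b = 1$ — a variance ratio around 0.2–0.5,
  i.e. a substantial subject component;
* Hardy–Weinberg genotypes at MAF ∈ [0.1, 0.5] with AR(1) Gaussian-copula
  LD blocks (block size 4, latent $\rho = 0.8$) and 1% missing calls,
  reference allele = major allele;
* 30 genes, 2 Mb apart on two chromosomes so every non-host gene is trans;
  exon counts drawn Poisson around the RPKM-implied mean for a target
  index carrying exon, group×exon and planted genotype×exon effects;
* planted effects: $\beta_G = 1.5$ expression units per allele and
  $\gamma = 1.0$ index units on a ±0.5 two-exon contrast, each class with
  an effect-strength ladder (four full-strength genes, then 0.6× and
  0.4×), and a trans architecture of two hubs per paradigm with two
  targets each (effects 2.0 / 0.8 per allele).

Two generator choices deserve their rationale spelled out.  First, the
**effect-strength ladder**: at desk scale the permutation-FDR threshold has
coarse candidate resolution — candidates are observed p-values, so when all
signals are uniformly strong the largest qualifying candidate is typically
the weakest signal itself, which the strict inequality then excludes, and
the step-2 sQTL survivor list degenerates to astronomically small
candidates that make the transferred trans-splicing threshold unusable.
Real data do not behave this way because effects come in a spectrum;
borderline signals are precisely what give the estimator resolution near
the cutoff.  The ladder reproduces that spectrum.  Second, **hubs sit on
full-strength genes**: detected top modules in this kind of analysis are
hubs of strong cis signals, and spreading the planted edges over eight
regulators keeps any single threshold-granularity event from dominating
the sensitivity estimate.

The generator does **not** emulate read-level sequencing (counts are
Poisson, with no mapping ambiguity or overdispersion beyond the expression
noise), population structure beyond two labels (genotypes are drawn from a
common MAF), within-group re-measurement of a line, junction reads, or
non-coding genes.  Consequently a passing suite says the *procedure* is
correct and calibrated under its stated assumptions at these sizes — it
does not certify discovery counts or thresholds on any real dataset.

One measured property of the index pathway matters for interpretation:
dividing exon RPKMs by the noisy per-sample mean makes the exon indexes
compositional and slightly non-Gaussian, which inflates the interaction
test's *raw* type-I error (about 0.08–0.10 at $\alpha = 0.05$ under Poisson
counts; about 0.04 when responses are drawn from the model's own Gaussian
assumptions).  This is precisely why the discovery thresholds are
permutation-based: the permuted nulls carry the same inflation, so the FDR
estimate self-corrects — the realised false-discovery proportion stays
within twice the nominal target in the calibration suite.  The calibration
of the statistic itself is therefore checked by parametric simulation from
the fitted null model, while the count pathway is exercised by the FDR and
end-to-end suites.

# Numerical choices and edge policies

* REML search on $\log\lambda \in [-12, 12]$, `optimize()` tolerance
  $10^{-8}$; boundary hits reported as $\sigma_b^2 = 0$.  `fix_lambda`
  pins the ratio (0 gives the OLS reduction, a positive value the GLS fit
  at that ratio).
* Weight cells with (near-)zero variance get a floored variance of
  $10^{-8}\times$ the overall trait variance and a flag, so degenerate
  simulated groups cannot produce infinite weights.
* Genotype class occupancy: a pair is testable when at least two genotype
  classes have at least three observations (configurable); missing
  genotypes exclude their cell lines from that SNP's fit and are never
  imputed; mitochondrial SNPs are dropped at encoding.
* Aliased design columns (e.g. a group emptied by missing-genotype
  exclusion) are dropped with a warning; single-level factors are padded
  internally so one-group designs fit cleanly.
* Tag-SNP ties are broken toward the smaller genomic coordinate and
  flagged.
* Region assignment is a strict seven-way partition (U1-20K, U0-1K, 5'UTR,
  CDS, 3'UTR, D0-1K, D1-20K) with upstream defined by strand.  Introns are
  not a separate class: positions genomically inside the CDS span fall in
  the CDS bucket, positions between transcript edge and CDS span in the
  adjacent UTR bucket — this keeps the partition total exact.  Non-coding
  genes report a single inside-transcript bucket and are excluded from the
  UTR/CDS columns.  Average region lengths use the genomic spans consistent
  with this policy; the flank classes are fixed at 1 kb and 19 kb by
  construction.
* Coordinates are 1-based inclusive throughout; both cis-window boundaries
  are inclusive.

# Problem sizes used by the test suite

The suite runs the calibration checks at 2000 null traits on the 100-line
replicated design (exact-binomial 99% acceptance band around
$\alpha = 0.05$), the FDR calibration at 20 seeds × 1000 SNP::gene pairs
with 5% planted effects at 80 lines, parameter recovery over 200
replicates, and the end-to-end network recovery over three default studies
(48 planted edges pooled, ≥80% required in the correct paradigm with zero
mediation violations).  At 80–100 cell lines a full-strength
($\beta_G = 1.5$) planted eQTL has an expected $|z|$ near 4.5 against
permutation thresholds of $10^{-3}$–$10^{-6}$, so per-gene recovery sits
around 0.75–0.85 — the scan tests assert that level rather than certainty,
and the network-level sensitivity criterion is met through the multi-hub
architecture.

# Limitations

The package fits one SNP at a time with a single random intercept: no
kinship or relatedness structure (the cell lines are assumed genetically
independent), no multi-SNP or conditional models, no covariates beyond the
dataset group, and no fine-mapping of causal variants.  FDR estimation is
the permutation ratio estimator only — no analytic Benjamini–Hochberg or
q-value path is offered, and with k = 4 permutations the threshold estimate
is itself noisy at small test counts.  Exon models are interval-based;
junction-aware splicing quantification is out of scope.
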