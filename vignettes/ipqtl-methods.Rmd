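---
title: "Methods: intermediate-phenotype QTL models and CDA risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intermediate-phenotype QTL models and CDA risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipqtl)
```

## The problem

Cardiotoxicity due to anthracyclines (CDA) is a complex trait: heart
damage after doxorubicin-type chemotherapy varies widely between
genetically different individuals, yet the variants found by direct
association explain only a small part of the heritable variation. The
strategy implemented here attacks that "missing heritability" through
intermediate molecular phenotypes (IMPs): myocardial molecules —
phospho-proteins, miRNAs, telomere length — whose levels sit on the causal
path between genotype and histopathological damage. A locus controlling an
IMP (an *ipQTL*) can contribute to CDA variation even when its own direct
linkage to the damage phenotype is too weak to reach significance; a locus
linked directly to damage (a *cdaQTL*) anchors the model. Combining both
in a multi-QTL fixed model and asking how much *additional* phenotypic
variance the ipQTLs explain is the core analysis of this package. On the
human side, variants of the genes encoding CDA-associated IMPs are
screened in patient cohorts and distilled into a polygenic risk score.

## Backcross genetics

The mapping population is a backcross (F1 x recurrent parent): every locus
is either homozygous for the recurrent strain or heterozygous, so a single
probability `p_het` per individual per position captures the full genotype
uncertainty. Conditional genotype probabilities on a grid of markers plus
pseudomarkers (default step 2.5 cM) come from a two-state hidden Markov
model: stationary prior 1/2 per state, transition probability between
adjacent positions equal to the recombination fraction of their distance,
and a symmetric genotyping-error emission (`error_prob`, default 0.001);
missing genotypes emit uniformly. Posteriors are computed by scaled
forward-backward and are tested against exhaustive enumeration of all
hidden paths on short chromosomes (agreement to 1e-10).

**Map function.** The source study does not state a map function; Haldane
(no crossover interference), the common default of backcross mapping
software, is used throughout, with Kosambi available via `map_function=`.
The X chromosome is excluded from simulation and scans.

## Genome scans and peaks

`scan_em()` is interval mapping by expectation-maximization: at each grid
position the phenotype is a two-component normal mixture (genotype-class
means, common SD) with the HMM probabilities as fixed per-individual
mixing weights; `LOD = log10 L(alt)/L(null)` against a single normal. EM
convergence is 1e-4 on the log-likelihood with at most 4000 iterations;
non-convergence is flagged, never hidden. `scan_hk()` is the Haley-Knott
approximation — ordinary regression of the phenotype on `p_het`, with
`LOD = (n/2) log10(RSS0/RSS1)`. The two coincide exactly at fully typed
markers. Between markers they agree within ~0.02 LOD at the 99th
percentile of positions, but isolated excursions (up to ~0.7 LOD at
n = 130) occur where a recombinant individual's genotype is effectively
resolved by its phenotype: the mixture likelihood uses that information,
the regression cannot. The EM maximum was verified against direct BFGS
maximization of the same likelihood, so these excursions are a genuine
methodological difference, not an implementation artifact. Heavy
simulation layers (null calibration, recovery) therefore use the HK scan.

Peaks are one per chromosome-local maximum at or above the suggestive
threshold, classified *significant* (LOD > 3) or *suggestive*
(1.5 <= LOD < 3, a half-open band). Ties on a plateau resolve to the
lowest cM; a secondary maximum on the same chromosome survives only if
separated by a valley at least 1.5 LOD below the smaller peak. Support
intervals are 1.5-LOD drops. Scans are run *within* strata (therapy arm x
age group), mirroring the stratified design of the source analysis, rather
than fitting covariates inside the scan. Condition-specific peaks whose
support intervals overlap on a chromosome are merged transitively into
registry entries; the original consolidation rule was unstated, so the
registry count is a convention of this package, not a reproduced quantity.

## Multi-QTL models and the mediation question

`fit_qtl_model()` regresses the phenotype on `p_het` at the model loci
(Haley-Knott, as in the source), with optional pairwise interactions
(default off; the published models are additive). Percent variance
explained obeys the identity `%var = 100 (1 - 10^(-2 LOD / n))` —
equivalently the model R-squared — and is checked to 1e-9 on every fit.
`drop_one_analysis()` refits without each term (a locus takes its
interactions with it) and reports an F-test; a term is retained at
p < 0.05, the inclusion rule for extended models. `compare_models()`
reports an extended model as an improvement only when *every* added term
passes that rule. A removal that leaves the RSS numerically unchanged is
assigned F = 0, p = 1 exactly.

The published model table labels one basal row by the wrong locus name (a
typo); this package always labels basal rows by the actual locus.

## What the mouse generator states, and what it does not

`simulation_config()` fixes the stated world: 130 backcross mice (70
doxorubicin, 60 combined therapy), ages uniform on 51-114 weeks with the
young/old split at the cohort median, 19 autosomes of 70 cM carrying 1499
equally spaced markers (17 x 79 + 2 x 78), 2% missing genotypes. Effect
sizes are in residual-SD units; a backcross locus of additive effect `a`
contributes genetic variance `a^2/4` because the genotype indicator has
variance 1/4. The default architecture routes variance both directly and
through mediation: one cdaQTL (chr 11, effect 1.2) acts on fibrosis
directly, and one IMP (noise SD 0.7) fed by two ipQTLs (chr 3 and chr 9,
effects 1.0 each) feeds fibrosis with coefficient 1.0. Expected basal
%var is then `0.36/2.35 ~ 15%` and the three-locus model
`0.86/2.35 ~ 37%`, so extended models gain ~20 points — the same
qualitative pattern (basal < 2-QTL < 3-QTL) as the published mediation
table, at comparable magnitudes. The age effect on latent fibrosis is
arm-specific (0.03 SD/week in the combined arm, 0 under doxorubicin
alone), reproducing the published age-fibrosis correlation asymmetry.
Fibrosis maps to percent as `8 + 2.5 x latent`, truncated to [0, 100];
the truncation almost never binds at these settings, which keeps variance
arithmetic exact. Where the source prints no value (IMP noise SDs, arm
offset, the percent scale) the defaults were chosen once as
field-plausible and are not tuned against test outcomes.

The generator emulates the *statistical* structure only: no linkage
disequilibrium beyond the backcross map, no selection, no shared-litter
or cage effects, no measurement batch structure. A green test therefore
establishes that the estimators recover the stated architecture — not
that any particular biological cohort satisfies it.

## IMP association layer

Expression is quantified by the 2^-ddCt rule. Correlations and two-group
comparisons are gated by a one-sample Kolmogorov-Smirnov test against a
normal with the sample's mean and SD (alpha 0.05): Pearson / t-test when
all inputs pass, Spearman / Mann-Whitney otherwise. The plain KS gate is
what the source names; a Monte Carlo Lilliefors correction (which accounts
for the estimated parameters) is available via `lilliefors = TRUE`.
`select_imps()` screens molecules univariately at p < 0.05 and fits the
survivors jointly by multiple regression, pruning collinear candidates by
highest VIF (> 10) first. No multiple-testing correction is applied at
this stage — deliberately, matching the exploratory design of the source —
so selected molecules are candidates, not confirmed associations. IMP
levels are not transformed by default (`log_transform = TRUE` exists).

## Human risk-score pipeline

SNVs with imputation R^2 strictly below 0.7 are removed. A patient is a
CDA case when the cardiac-function index (LVEF or LVFS) drops by >= 5
percentage points from baseline at any follow-up (pediatric LVFS and
adult LVEF share one rule with a configurable threshold). Single-SNV
association offers the five standard encodings (codominant, dominant,
recessive, overdominant, log-additive) with likelihood-ratio p-values;
"the best-supported model" for a SNV is operationalized as lowest AIC.
Complete separation is flagged and the odds ratio re-estimated under a
light ridge penalty.

The risk score follows the published three-stage design with an 80/20
stratified train/test split: (1) bootstrap pre-selection — 100 iterations,
each splitting the *training* data 80/20, a SNV scoring a hit when its
log-additive association is significant (p < 0.05) in both portions, with
>= 5 hits required; (2) an L1-penalized (LASSO) logistic model on the
candidates, lambda by stratified 10-fold cross-validation minimizing
deviance (one-SE rule optional); (3) a probability cutoff maximizing
Youden's J on the training scores (smallest threshold on ties), then a
single evaluation on the held-out 20%. Inside the bootstrap the
significance test is the Rao score test of the logistic model, vectorized
across SNVs — asymptotically the same test as the glm likelihood-ratio,
but fast enough for the iteration counts involved. Missing dosages are
mean-imputed for penalized fitting and excluded pairwise for single-SNV
association. No per-SNV multiple-testing correction is applied; the
>= 5/100 rule is the stabilizer.

**A calibration caveat worth stating plainly.** The bootstrap iterations
resample one and the same training sample, so per-SNV hits are correlated
across iterations: a null SNV that is by chance associated in that sample
(full-sample p < 0.01, expected for 1-3% of a 200-SNV null panel) will
clear the >= 5/100 rule. Measured on null panels, the procedure admits
roughly one false SNV per run — far more than a naive independent-
iteration calculation (0.05 x 0.05 per iteration) suggests. The LASSO
stage removes some but not all of these. Users should read the selection
as "stable in this sample", not "replicated"; the package keeps the
published rule as its default rather than silently hardening it.

## Numerical choices

- LOD values are floored at 0 (tolerance 1e-8); a perfect fit caps
  RSS1 at RSS0 x 1e-12 and flags the position instead of overflowing.
- Monomorphic positions score LOD 0; constant phenotypes are an error.
- Rank-deficient model designs raise an error naming the aliased terms.
- Every generator and fitted pipeline is a pure function of
  (configuration, integer seed); RNG state is restored after each call.
- The median age split sends ties to "old" (>= median rule) with a
  warning when all ages coincide; the PCA median split sends ties to
  "low".

## Known limitations

Permutation genome-wide thresholds, composite interval mapping,
two-dimensional epistasis scans, model search (stepwise QTL discovery),
genotype imputation beyond the HMM posterior, and covariate-adjusted
survival modelling are out of scope. The published percent-variance
values for the real cohort depend on deposited data that this package
does not ship; all quantitative claims here are about the synthetic
stated world and are computed by the test suite and the acceptance
script, never asserted from the literature.
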