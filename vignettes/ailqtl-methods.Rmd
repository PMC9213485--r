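---
title: "Methods: QTL mapping and candidate-gene prioritization in advanced intercross lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL mapping and candidate-gene prioritization in advanced intercross lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ailqtl)
```

## The statistical model

`ailqtl` implements the analysis chain used for advanced intercross line
(AIL) crosses between two inbred mouse lines, where one line carries a
metabolic phenotype of interest (obesity, fatty liver) and the other is a
lean reference. Because the founders are fully inbred, every marker is
biallelic with known line of origin, and each animal falls into one of
three genotype classes: homozygous line 1 (`HOM1`), heterozygous (`HET`),
homozygous line 2 (`HOM2`).

The association model per marker is the fixed-effects linear model

$$y_i = \mu + \sum_c \beta_c x_{ic} + \gamma_{g(i)} + e_i,
\qquad e_i \sim N(0, \sigma^2),$$

with $x_{ic}$ the selected covariates and $\gamma_{g(i)}$ a free mean per
genotype class. The genotype term is tested with the partial F-test
against the covariates-only null. Modelling genotype as a categorical
factor (2 df with three observed classes) rather than an allele-dosage
slope is deliberate: overdominant loci — where heterozygotes outperform
both homozygotes, a pattern actually observed at body-weight loci in
these crosses — carry most of their signal in the dominance contrast and
would be invisible to a purely additive coding. The cost is one extra
degree of freedom.

LOD is defined operationally as $-\log_{10}(p)$ of that F-test. This is
the convention of the motivating analyses; it is not the likelihood-ratio
LOD of interval mapping, and the two should not be mixed when comparing
thresholds across studies.

### Covariate screening and kinship

Sex, subfamily (the identity of the dam) and litter size are screened
marginally — one linear model per covariate per trait, an overall F-test
for the factors and a slope test for litter size — and selected at
α = 0.05 (`alpha_covariate`). Marginal rather than joint screening
reflects how such covariate tables are usually reported (one p-value per
covariate per trait) and keeps the selection interpretable; jointly
selected sets can differ when covariates are correlated, a known
limitation. Subfamily as a fixed effect is a coarse kinship correction:
it absorbs between-family variance but, unlike a genomic relationship
matrix, does not model within-family relatedness. Residual structure is
instead handled empirically by genomic control (below). Missing values
are excluded listwise per model fit and never imputed.

### Genomic control

The scan's p-values are converted to 1-df χ² quantiles,
$\lambda = \mathrm{median}(q) / 0.4549364$, and when λ exceeds
`lambda_trigger` (default 1.05) the quantiles are deflated by λ before
conversion back. The 1-df convention is used regardless of the F-test's
df because genomic control is conventionally defined on 1-df statistics
and the trigger value 1.05 is calibrated to that scale; λ is computed per
trait scan, since different traits have different covariate models and
residual structure. Note one consequence: a scan containing a true strong
QTL inflates the median quantile slightly, so λ-correction is mildly
conservative for secondary loci — visible in the MQM analyses, where
removing the primary QTL as a cofactor lowers λ and raises the corrected
LOD of the secondary locus. That behaviour is not a bug; it mirrors the
published analyses.

### Multiple testing: simpleM

Markers in an AIL are in strong local linkage disequilibrium, so
Bonferroni on the raw marker count would be badly conservative. The
effective number of tests is estimated per chromosome: the marker–marker
correlation matrix (calls coded 0/1/2, pairwise-complete) is
eigendecomposed, negative eigenvalues are clipped to zero, and
$M_\mathrm{eff}$ for the chromosome is the smallest $k$ whose leading
eigenvalues reach `simpleM_variance_fraction` (default 0.995, the
method's published default) of the eigenvalue sum. Chromosome
contributions are summed — LD does not extend across chromosomes, and a
genome-wide decomposition (available via `per_chromosome = FALSE`) would
mostly estimate noise in the cross-chromosome correlations. Thresholds
are $-\log_{10}(\alpha / M_\mathrm{eff})$ at α = 0.05 and 0.01; all
comparisons use full precision, with one-decimal values for display.

### Support intervals and MQM

A QTL's support interval is the 1.5-LOD-drop region: from the top marker
(maximum corrected LOD; ties broken toward the smaller bp) walk outwards
to the first marker whose LOD is at least `lod_drop` (default 1.5) below
the top, or to the chromosome end. The bounding markers themselves define
the interval ends. `mqm_scan()` repeats the scan with a chosen marker's
genotype class added as a covariate; the cofactor itself and any marker
collinear with it are reported as NA records rather than silently
dropped, and the new p-value list gets its own λ.

### Expression and scoring stages

Expression intensities are log2-transformed and quantile normalized
across all samples (both lines together — normalizing the groups
separately would remove exactly the differences being tested), then each
gene is tested with a two-sample t-test (pooled variance by default;
Welch by flag) and BH-adjusted. Fold changes are reported as differences
of log2 group means, so magnitudes like −0.03 to −0.19 are log2 units,
not linear ratios; a negative value means downregulated in line 1.

The prioritization decision tree awards: stop gain/loss 3; missense in a
functional protein domain 3; missense SIFT deleterious 3 or tolerated 1
(deleterious dominates, and the domain and SIFT components of one variant
add); promoter or splice-site variant 3; UTR, enhancer, CTCF-binding-site
variant 1 each; liver differential expression (BH-adjusted p below
`de_alpha`) 2; membership in the configured KEGG metabolic gene set 1.
Each category counts at most once per gene however many variants trigger
it ("category-once"); this reading exactly reproduces the published
worked totals for the two genes whose annotation strings are fully
printed, without further assumptions. The KEGG set is supplied as a plain
gene list (`kegg_gene_set`); the package makes no database calls.
Positional filtering of candidates to a QTL interval is a simple midpoint
test, not transcript-model intersection.

## The synthetic-data generator

`simulate_ail()` exists so that every downstream stage can be tested
end to end with known truth. It emulates the breeding design: two fully
inbred founders, F1 from the single founder pair, then random monogamous
pairing within each generation up to generation 10 (default), excluding
full-sib pairs from F2 onward (all F1 animals are sibs by construction,
as in a real F2 cross). Meiosis follows Haldane's model — Poisson
crossover counts with mean (chromosome length in cM)/100, uniform
positions, no interference — on a linear map of 0.5 cM/Mb (the mouse
genome-wide average scale; both configurable). Default chromosome length
is 80 cM with 100 markers; default family structure is 25 pairs × 5
offspring per generation, giving ~125 animals per generation, the scale
of a real AIL mapping population. Each generation's offspring total is
allocated to pairs multinomially so litter size varies realistically (a
constant litter size would make that covariate degenerate). Sexes are
Bernoulli(1/2).

Trait values follow
$y = \mu + \beta_\mathrm{sex}\,1[\mathrm{male}] + u_{\mathrm{dam}} +
\beta_\mathrm{litter}\,\ell + \sum_q g_q + e$, with
$u_\mathrm{dam} \sim N(0, \sigma_f^2)$, $g_q \in \{+a, d, -a\}$ for
HOM1/HET/HOM2 at the marker nearest the QTL position, and
$e \sim N(0, \sigma_e^2)$ (σ_e defaults to 1 so effects are in residual-SD
units). Expression data are Gaussian on the log2 scale (baseline
N(8, 2²), per-sample noise SD 0.25, planted shifts in group 1, exported
as raw 2^x intensities); annotation tables draw each scoring category
independently per gene and also return the score each gene must receive,
computed by arithmetic independent of the scoring module.

The random streams are ordered pedigree → meioses → missingness, and
genotype emission from crossover breakpoints is deterministic, so the
same seed reproduces the population byte for byte and changing marker
density does not perturb the pedigree.

What the generator does **not** model — and what passing tests therefore
do not establish about real data: genotyping error beyond uniform
missingness, selection and mutation, X-specific inheritance (all
simulated chromosomes behave autosomally), crossover interference,
non-Gaussian trait distributions, and realistic LD/allele-frequency
structure of a genotyping array designed on reference strains. Drift is
real, though: with a two-founder bottleneck and ~125 animals per
generation, allele frequencies at generation 10 wander noticeably, which
is why QC occasionally masks a small genotype class even in simulation.

## Numerical and edge-case choices

* QC rules apply in the order all-missing → non-segregating →
  small-group; the order affects only the attribution of removals in the
  report, not the surviving marker set. "Non-segregating" means exactly
  one observed class, so an all-heterozygous marker is removed. The
  small-group mask is symmetric: a small HET class is masked like a small
  homozygote class.
* Adjusted class means are least-squares means with numeric covariates at
  their sample means and factor covariates at observed proportions
  (proportional weighting); with no covariates they equal raw class means
  exactly. Classes with no observations are NA.
* A marker whose genotype term gains no rank over the null (collinearity
  with the cofactor) yields an NA record; a trait fully explained by its
  covariates yields p = 1 at every marker.
* Spearman p-values use the asymptotic t approximation on
  pairwise-complete observations; constant traits give NA, flagged not
  significant. The Bonferroni test count defaults to the number of
  supplied trait pairs and is configurable, since published correlation
  tables sometimes use a different count than the printed matrix implies.
* Genes with zero expression variance in both groups get p = 1 when the
  group means are equal and NA otherwise (no variance estimate exists to
  justify any finite p).
* BED output is 0-based half-open; all in-memory coordinates are 1-based
  inclusive; conversion back recovers the original positions.
* The F1-pairing exception aside, pairing retries random shuffles up to
  100 times before failing with advice to enlarge the population.

## Problem sizes used by the test suite

The simulation-based checks run at the scale of the motivating study:
null-scan family-wise error uses 100 replicate populations of 123
animals × 500 markers on 5 chromosomes; QTL recovery uses 100 replicates
of 400 animals × 200 markers with a 1 σ additive effect; MQM unmasking
uses 100 replicates with 1.5 σ primary and 0.5 σ secondary QTLs; FDR
control uses 200 replicate expression sets of 500 genes (6 vs 5 samples).
These sizes give binomial standard errors small enough for the asserted
rates while keeping the default test run short.

## Known limitations

* No interval mapping between markers (single-marker tests only), no
  mixed-model kinship, no permutation thresholds — the simpleM-Bonferroni
  route is the method implemented.
* Scans treat the X chromosome like an autosome; no sex-stratified scans.
* The λ/trigger machinery assumes enough markers for a stable median;
  scans over a handful of markers should set `lambda_trigger = Inf`.
* The scoring tree is deliberately literal: it does not weight by allele
  frequency, conservation or expression magnitude, and its DE component
  is binary at `de_alpha`.
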