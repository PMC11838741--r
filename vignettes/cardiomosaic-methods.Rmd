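---
title: "Models and methods behind cardiomosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiomosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomosaic)
```

cardiomosaic analyses somatic single-nucleotide variants (sSNVs) called
from amplified single cardiomyocyte genomes, together with the
transcriptional consequences seen in single-nucleus RNA-seq. This
vignette explains the models, the tunable parameters, and the design
choices made where the methodology left genuine freedom — the things a
maintainer or reviewer would want stated explicitly.

## The generative burden model

The central object is the per-cell somatic burden, expressed in sSNVs
per gigabase of diploid genome. For cell $i$ of donor $j$ with age
$\alpha_j$:

$$y_{ij} = \beta_0 + \beta_1 \alpha_j + \beta_I \cdot \mathbb{1}[\text{IHD}_j] + u_j + \varepsilon_{ij},
\qquad u_j \sim N(0, \sigma_u^2),\ \varepsilon_{ij} \sim N(0, \sigma^2).$$

*Model 1* omits $\beta_I$ (control-only aging), *model 2* is the full
form, and *model 3* drops the random donor intercept $u_j$ (ordinary
linear regression). `fit_burden_model()` fits models 1–2 by maximum
likelihood through lme4 and reports Satterthwaite-approximate t-tests
via lmerTest; if Satterthwaite degrees of freedom are unavailable the
fit falls back to a flagged normal approximation. The same machinery
serves the total burden, covariate-adjusted burden
(`adjust_covariate()`, e.g. MAPD or depth as a fixed technical term) and
per-signature burdens (`signature_burden_series()`).

**Singular fits.** When a signature is nearly absent from the control
group, the donor variance is estimated at the boundary and mixed-model
P values can vanish. We detect this with `lme4::isSingular()` or
$\hat\sigma_u^2 < 10^{-8}\hat\sigma^2$ and, when no valid P value is
produced, automatically refit the same fixed effects as a linear
regression (model 3), flagging `fallback = TRUE`. The threshold is ours;
the fallback behaviour itself is standard for this analysis.

**Truncation.** The synthetic cohort generator truncates simulated
burdens at zero by default — a physical constraint, counts cannot be
negative. The recovery experiments in `scripts/acceptance.R` and the
test suite instead simulate the untruncated Gaussian model
(`simulate_burden(truncate = FALSE)`): with a near-zero baseline the
truncation would add a half-normal mean shift that is not part of the
model being estimated, and the experiments are designed to test the
estimator against its own generative assumptions.

**Simulated study conditions.** The default `cohort_design()` mirrors
the study scale: 10 control and 5 diseased donors, 5 cells per donor,
ages spread evenly over 0.5–82 years (individual donor ages are not
published, so an even spread is a stand-in, not a reconstruction),
aging rate 7.90 sSNVs/GB/year, disease excess 686 sSNVs/GB, donor SD 50
(150 for diseased donors, which show larger inter-individual spread) and
residual SD 100 sSNVs/GB. Sex is generated but has no effect, matching
the reported null. The per-cell conversion constant is 5.845 GB of
diploid genome, chosen so the per-GB and per-cell headline rates are
mutually consistent; it is configurable everywhere it appears.

## Amplification QC

Evenness of whole-genome amplification is summarized on binned depth
profiles (default 100 kb bins for real data; the toy fixtures use 10 kb
so that a 50–200 kb reference still has hundreds of bins — bin size is a
parameter, not a constant). Ratios are $\log_2(d_b/\tilde d)$ against
the median positive depth; zero-depth bins become missing rather than
imputed, consistent with the separate zero-depth handling in burden
estimation. MAPD is the median of absolute adjacent-ratio differences;
CoV is SD/mean of those differences, with the *population* SD (divide by
$n$) fixed by convention since either choice is defensible and the
difference is a factor $\sqrt{n/(n-1)}$. If a cohort's maximum MAPD or
CoV is zero the corresponding penalty contributes its full weight
(avoids 0/0 and respects "higher = worse"). The composite score weights
depth and coverage 0.3 each and the two evenness penalties 0.2 each;
inclusion is strict (`score > 0.5`).

## Sensitivity-corrected burden

Detection sensitivity is estimated as the fraction of known germline
heterozygous sites recovered in the cell, stratified by depth within the
trimmed central part of the depth distribution (default the 25th–75th
percentiles; the exact bounds of the original trimmed-mean routine are
not published, so ours are configurable and documented — the package's
stratified version is a faithful-in-spirit stand-in, not a line-by-line
port). The genome-wide burden is

$$\hat b = \frac{\text{calls in trimmed strata}}{\sum_s \hat s_s \cdot L_s}\ \text{per bp, scaled to GB}.$$

Under the **standard** method the trim quantiles are taken over *all*
bins. A cell with a large zero-depth block drags the lower quantile to
zero, the trimmed region is undefined, and the estimate is reported as a
failure. The **refined** method excludes zero-depth bins before taking
quantiles — exactly the cells whose only failure mode is missing
territory are thereby rescued, and the two methods agree exactly when no
zero-depth bins exist (a tested invariant).

## Spectra, refitting and de novo extraction

Spectra are built over the 96 pyrimidine-standardized trinucleotide
channels, with context always read from the reference sequence (never
trusted from a VCF), and CpG status taken from the standardized
downstream base (no methylation data is consulted). Catalog attribution
uses deterministic non-negative least squares with exposures rescaled to
the spectrum total; this replaces network-based attribution because the
downstream quantities (exposure-weighted burdens) only require a
non-negative refit, and determinism makes the whole pipeline
reproducible. Duplicate catalog columns are collapsed to the first with
a warning, making ties deterministic.

De novo extraction is non-negative matrix factorization with
multiplicative Frobenius updates, `n_restarts` random restarts per
candidate rank (50 by default), and consensus clustering of cells by
dominant signature across restarts. Rank selection uses the two
published criteria together: the cophenetic correlation of the consensus
matrix must still be high (`coph_min = 0.9`, i.e. the rank lies before
the stability falls off) and the rank must be the inflection point of
the residual-sum-of-squares curve — operationalized as the largest rank
whose incremental RSS improvement is at least `rss_frac = 0.05` of the
total RSS range *and* after which the mean improvement collapses below
half of it. The second condition is what distinguishes structure (step
improvements) from noise (steady small improvements); with pure
rank-one data stability is the binding criterion. All per-rank
diagnostics are returned so the choice is auditable, and
`plot_rank_selection()` displays them.

Transcriptional strand assignment calls the pyrimidine-standardized base
on the gene's annotated strand "untranscribed" and the opposite strand
"transcribed"; positions covered by genes on both strands get an
`ambiguous` label and are excluded from strand-bias counts (a
conservative choice — the alternative of double-counting would let one
locus vote twice).

## Context-preserving permutation null

Associations between mutation density and expression or accessibility
are tested against a null that preserves two confounders by
construction: the trinucleotide context composition of the call set
(exactly — a tested invariant) and the phaseable-region geometry. Each
of the default 1,000 permutations redraws every call uniformly among
same-context positions inside phaseable intervals, without duplicate
positions within a permutation (somatic calls are unique sites). Units
(genes, or fixed-width bins for accessibility, default 10 kb) are ranked
and split into eight equal-count groups — equal *count*, not equal
span, because footprint differences are exactly what the permutation
null corrects for. The result reports per-group observed density,
permutation mean and SD, observed/expected ratios with permutation SDs,
and the Pearson R with the P value of the least-squares slope across
group index.

## Annotation and selection

Region categories follow fixed precedence
(splicing > exonic > 5′UTR > 3′UTR > intronic > upstream > downstream >
intergenic) so every variant receives exactly one label even under
overlapping transcripts; splicing means within 2 bp of an intronic
junction, upstream/downstream within 1 kb of the TSS/TTS, strand-aware.
Functional classes come from strand-aware codon translation under the
standard genetic code. Selection is summarized as exonic:intronic and
dN/dS ratios of somatic calls *normalized by the same ratios in germline
variants* — the germline carries the gene-structure and mutational-
opportunity baseline — with two-sided Fisher exact tests (verified
against full hypergeometric enumeration for tables up to n = 200).

## Leave-one-out consensus differential expression

Counts are library-size normalized to 10,000 and log1p-transformed, and
log-fold-changes are natural logs of group means of normalized counts
with pseudocount 1 — the ecosystem convention the published thresholds
(0.30 up, 0.25 down, `min.pct = 0.1`) were tuned against. Each LOO
iteration drops one control and one diseased donor (3 × 3 donors gives
exactly 9 iterations) and recomputes markers on the remaining cells; the
consensus is the intersection across iterations, reported separately for
up- and down-regulation. Iterations enumerate donor pairs regardless of
cell counts; the "minimum cells per donor" pre-filter is available but
off by default for synthetic data. The donor — not the cell — is the
unit of analysis for cell-type proportions, compared with an exact
permutation rank-sum test when donor counts are small (ties make the
textbook exact Wilcoxon unavailable).

## What the synthetic data does and does not emulate

The generator reproduces: the donor/cell hierarchy with its two noise
scales, signature-mixture mutation spectra placed at context-matching
phaseable positions (without within-cell duplicates), depth profiles
with a contiguous zero-depth block (15% of bins by default) to exercise
the refined burden path, germline variants for sensitivity and
selection baselines, and negative-binomial count matrices with
injectable condition- and donor-level shifts. It does **not** simulate
reads, amplification chimeras/artifacts, indels or structural variants,
replication timing or regional mutation-rate covariates beyond context,
or doublets in the expression data. Passing tests therefore demonstrate
the correctness and calibration of the estimators under the stated
models — not robustness to artifact classes the generator does not
produce.

## Numerical choices and problem sizes

Tolerances: catalog columns must sum to 1 within $10^{-6}$; singularity
threshold $10^{-8}$ relative; NNLS ties broken by first column; NMF
converges on a relative RSS change of $10^{-6}$ checked every 20
iterations (cap 400), with a $10^{-9}$ floor guarding all-zero rows.
Degenerate inputs are first-class: all-tied group values are flagged,
all-zero strand classes report P = 1 with a degenerate flag, empty call
sets give zero spectra, and zero expected densities exclude a group with
a warning.

The test suite and the acceptance script run on deliberately small
problems — 50 kb–1 Mb toy references, tens of cells, 20 simulation
replicates per recovery experiment, 100–1,000 permutations — sizes at
which every stochastic check has comfortable margins while the whole
suite stays fast enough to run routinely. The recovery experiments
(10 donors × 5 cells, the study's noise scales, 20 replicates) put the
Monte-Carlo standard error of each mean estimate several-fold below the
tolerance applied to it.

## Known limitations

- The trimmed-mean sensitivity correction is a stratified
  reimplementation of the idea, not a port of the original calling
  pipeline's internal routine.
- Catalog content is a user input; no signature catalog is bundled, and
  the synthetic catalogs are labelled as such.
- The NMF rank rule, like all such heuristics, can under- or over-select
  on pathological inputs; the full diagnostics are always returned and
  should be inspected for real data.
- The permutation null conditions on trinucleotide context and
  phaseability only; regional covariates such as replication timing are
  out of scope.
- Mixed models assume Gaussian residuals on the burden scale; with very
  low counts a count model would be more appropriate than the linear
  approximation.
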