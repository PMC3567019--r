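---
title: "Methods: population-genetic analysis of SNP array panels"
author: "arraypopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genetic analysis of SNP array panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arraypopgen)
```

# Scope and data model

`arraypopgen` implements the standard analysis battery applied to diploid,
biallelic SNP chip panels from multi-population diversity studies: quality
control, within-population diversity, individual genetic distances and
neighbor-joining trees, LD-pruned principal component analysis,
Weir-Cockerham $F_{ST}$, linkage-disequilibrium decay under the Sved
hyperbolic model, runs of homozygosity (ROH), and a Bayesian
$F_{ST}$-outlier scan for loci under divergent selection.

The central container, `GenotypePanel`, is a `RangedSummarizedExperiment`
whose single assay stores the dosage of each SNP's second (alt-like) allele
per individual (0, 1, 2; `NA` for a missing call), with the marker map
(chromosome, 1-based bp position, allele pair) as row ranges and the
population label of every sample as column data. PLINK text `.ped`/`.map`
filesets plus a two-column population file are the interchange format;
dosages are oriented against the lexicographically greater observed allele
so that a write/read round trip is lossless. Chip-style QC retains SNPs with
call rate $\ge 0.9$ and MAF $\ge 0.05$ (both inclusive, MAF computed over
called genotypes only — the standard chip convention), and cross-group
common subsets can be formed by requiring MAF $\ge 0.2$ within every
super-group. Sex-labelled chromosomes are carried in the container but
excluded from LD, $F_{ST}$ and ROH stages, which are autosomal analyses.

# Diversity

Three measures summarise within-population variability over a common SNP
subset:

* $P_N$ — the proportion of subset SNPs at which both alleles are observed
  among called genotypes;
* $H_E$ — the mean Hardy-Weinberg heterozygosity $2p(1-p)$. The plug-in
  estimator is used without a small-sample correction; published chip
  studies rarely state the correction and the quantity is used
  comparatively across populations of similar size;
* $A_R$ — allelic richness by rarefaction: the expected number of distinct
  alleles in a draw of $g$ gene copies without replacement,
  $\sum_a \left[1 - \binom{N - N_a}{g} \big/ \binom{N}{g}\right]$,
  averaged over loci. Binomial coefficients are computed in log space
  (`lchoose`) so large panels cannot overflow. The default depth is
  $g = 2 \min_i n_i$, twice the smallest per-SNP called sample size across
  populations — the standardization rarefaction tools apply; it is exposed
  as a parameter because published tables rarely state the depth used.

# Distance and trees

The allele-sharing distance between two individuals is $1 - D_{st}$ with
$D_{st} = (\mathrm{IBS2} + 0.5\,\mathrm{IBS1})/N$, where IBS2/IBS1 count
loci sharing two/one alleles identical by state and $N$ counts loci called
in both individuals (pairwise-complete: each pair uses its own $N$, which is
what the per-pair normalisation in the formula implies). Neighbor-joining is
the Saitou-Nei algorithm with the Studier-Keppler Q-criterion; ties on the
criterion are broken towards the label-sorted smallest pair so output is
deterministic, and negative branch lengths are clamped to zero with the
deficit moved to the sister branch (standard practice). On additive
matrices the implementation provably recovers the generating topology; the
test suite verifies this on random trees and cross-checks both topology and
branch lengths against `ape::nj` as an independent oracle.

# Structure PCA

To avoid LD-driven artifacts the panel is first pruned: within sliding
windows (default 50 SNPs advanced by 5 — the cutoff is the scientifically
meaningful parameter, the window only bounds how far apart pairs are
examined), whenever two surviving SNPs have genotype $r^2 \ge 0.2$ the
later SNP is dropped, so surviving within-window pairs all fall below the
threshold. PCA then uses the frequency-normalised genotype matrix
(centre $2\hat p$, scale $\sqrt{2\hat p(1-\hat p)}$, mean-impute missing
dosages after centring, drop monomorphic SNPs) and eigendecomposes the
sample covariance — the EIGENSTRAT construction.

# Weir-Cockerham F_ST

Per SNP with $s$ groups, $n_i$ called gene copies and frequencies $p_i$:

$$MSP = \frac{1}{s-1}\sum_i n_i (p_i - \bar p)^2,\quad
  MSG = \frac{\sum_i n_i p_i (1 - p_i)}{\sum_i (n_i - 1)},\quad
  n_c = \frac{\sum_i n_i - \sum_i n_i^2 / \sum_i n_i}{s-1},$$

$$\hat F_{ST} = \frac{MSP - MSG}{MSP + (n_c - 1) MSG},$$

with $\bar p$ the $n$-weighted mean frequency. Sample sizes are counted in
gene copies (twice the called diploids), the convention under which these
mean squares are the two-level ANOVA of allele indicators. Negative
estimates, which carry no biological interpretation, are clamped to 0 (and,
for numerical safety, values above 1 to 1); the raw value is reported
alongside.

Two aggregations are reported. The mean and SD of clamped per-SNP values is
the genome-scan style summary that published tables print. For a single
differentiation parameter, however, `groupMeanFst()` also returns the
multilocus Weir-Cockerham estimate — the ratio of summed components
$\sum(MSP - MSG) / \sum(MSP + (n_c-1) MSG)$ — which is the aggregation the
estimator's authors recommend. The distinction matters: under a pure
Balding-Nichols model at $F = 0.2$ the mean of per-locus ratios converges
to $\approx 0.149$ (a Jensen-inequality effect of averaging ratios whose
numerators and denominators co-vary), while the multilocus ratio recovers
0.20; parameter-recovery checks therefore use the multilocus form.

# LD decay and the Sved model

Pairwise LD is the squared Pearson correlation of dosage vectors
(genotype $r^2$, the PLINK `--r2` quantity) over pairwise-complete samples,
for autosomal pairs within 1,000 kb, after screening SNPs within the
analysed subset for MAF $\ge 0.10$ and missingness $< 0.10$. Distances are
binned into the 19 classes 0-4, 4-8, 8-12, 12-20, 20-30, 30-40, 40-60,
60-80, 80-100, 100-120, 120-160, 160-200, 200-250, 250-300, 300-360,
360-460, 460-620, 620-800, 800-1,000 kb; intervals are half-open
$[\mathrm{lo}, \mathrm{hi})$ with the last class closed so every retained
pair maps to exactly one class (the printed class lists are ambiguous at
the boundaries; a convention had to be fixed).

Decay is summarised by the Sved hyperbola $E[r^2] = 1/(1 + \beta d)$.
$\beta \ge 0$ is fitted by least squares on the raw pairs by default (the
regression formulation with a per-pair residual implies per-pair fitting;
a binned route is also provided). The objective is smooth and unimodal in
$\beta$, so a golden-section search over $\log_{10}\beta$ (interval
$10^{-12}$-$10^{0}$ per bp, tolerance $10^{-13}$) is used rather than a
general nonlinear solver; it has no starting-value or zero-residual failure
modes. $\beta$ is carried per bp internally and reported per kb. The LD
extent $r^2_t$ is the distance where the fitted curve crosses the
threshold, $(1/t - 1)/\beta$, with $t = 0.3$ by default; a zero $\hat\beta$
is flagged and yields an infinite extent. Inter-population LD pools a
seeded random subsample of individuals per population and reruns the same
pipeline on the pool.

# Runs of homozygosity

The caller follows the PLINK scheme. Windows contain 50 consecutive SNPs
and are valid when their physical span is at most 5 Mb — the span figure
acts as an upper bound that disqualifies windows stretched across sparse
regions. (Reading the published "5 Mb (minimum 50 SNPs)" as physical-span
windows with an SNP floor is untenable: a 5-Mb window can never fit inside
a sub-5-Mb homozygous tract, so no tract shorter than 5 Mb — including
everything near the stated 500-kb minimum — could ever be called.) A valid
window is homozygous when it contains at most 1 heterozygous and 5 missing
calls; a SNP is ROH-eligible when the homozygous fraction of valid windows
covering it reaches the hit threshold; maximal runs of eligible SNPs,
trimmed so both ends are homozygous called genotypes, are emitted when
their bp span reaches 500 kb.

The hit threshold defaults to $1/\mathrm{window\ SNPs}$ (= 0.02 at the
50-SNP default): a single homozygous covering window makes a SNP eligible.
The PLINK default of 0.05 would demand $\ge 3$ homozygous windows, and the
first/last SNPs of a clean homozygous tract are covered by fewer fully
interior windows than that, so 0.05 systematically erodes both boundaries
by about two SNPs and a tract at exactly the minimum length would never be
emitted — contradicting the minimum-length semantics. With the default,
the trimming rule, and the per-window allowances, a clean planted tract is
recovered at exactly its planted boundaries, which the sweep test
demonstrates by construction. Both the threshold and the minimum length are
configurable; autozygosity is summarised as the fraction of the analysed
autosomal span covered per individual, averaged per population, plus a
segment-length histogram.

# Bayesian F_ST-outlier scan

Counts of one allele per locus $i$ and group $j$, $a_{ij}$ of $n_{ij}$
gene copies, follow
$a_{ij} \sim \mathrm{Binomial}(n_{ij}, \tilde p_{ij})$ with
$\tilde p_{ij} \sim \mathrm{Beta}(\theta_{ij} p_i, \theta_{ij}(1 - p_i))$,
$\theta_{ij} = 1/F_{ij} - 1$ and
$\mathrm{logit}(F_{ij}) = \alpha_i + \beta_j$: a locus effect
$\alpha_i$ (selection) and a group effect $\beta_j$ (drift). The
group-specific frequency is integrated out analytically, leaving a
beta-binomial likelihood — this halves the dimensionality relative to
sampling $\tilde p_{ij}$ and removes its mixing problems. $F_{ij}$ is
clamped to $[10^{-6}, 1-10^{-6}]$ for numerical stability.

Priors: $\alpha_i \sim N(0, 1)$, $\beta_j \sim N(-2, 1.8)$ (the reference
implementation's defaults for this model family; the analysis protocol the
package follows states only chain lengths and thresholds), $p_i$ uniform
on $(0,1)$. The reversible-jump move toggles each $\alpha_i$ with prior
inclusion probability $\pi = 0.5$; insertion proposals draw $\alpha^*$
from its prior, so the acceptance ratio is the likelihood ratio times the
prior odds — a valid RJ kernel with no tuning of its own. $\pi = 0.5$
(prior odds 1) is the default because the stated Bayes-factor/posterior
correspondences (BF 10 $\to$ 0.91; BF 100 $\to \ge 0.99$) hold exactly at
prior odds 1. Random-walk Metropolis updates for $p_i$ (reflective at the
unit interval), $\alpha_i$ and $\beta_j$ have proposal widths tuned by
pilot runs towards acceptance in 0.25-0.45; tuning failure (any block
outside [0.05, 0.9] after all pilots) aborts with diagnostics.

Chain defaults follow the published protocol — 10 pilot runs of 5,000
iterations, 50,000 burn-in, 100,000 sampling steps; a `fast` profile
(10 x 500 pilots, 5,000 burn-in, 10,000 sampling) is provided for tests
and exploratory runs. The posterior inclusion frequency $q_i$, clamped away
from 0/1 by half a retained-sample unit so Bayes factors remain finite,
gives $BF_i = \frac{q_i}{1-q_i} \cdot \frac{1-\pi}{\pi}$; evidence is
classed *strong* for $\log_{10} BF \in (1, 2]$ and *decisive* above 2.

# The synthetic-data generator

No genotypes are distributed with the studies this package targets, so the
generator reproduces the study *design* as the test bed; its defaults are
the emulated study conditions, and `studyDesignConfig()` bundles them: 18
populations (14 + 4 in two super-groups) with the published sample sizes
(304 animals), mean marker spacing 55.6 kb over 18 autosomes, nested
Balding-Nichols divergence (group level 0.12, population level 0.06-0.15,
giving between-group differentiation around 0.3 and within-group values
around 0.1), default LD decay $\beta = 0.01$/kb (extent $r^2_{0.3} \approx
233$ kb, mid-range of the published per-breed extents of 83-757 kb),
per-call missingness 1% (typical post-calling chip missingness), and two
admixed populations formed as 50/50 crosses, mirroring the two admixed
breeds in the emulated design.

Population frequencies follow the Balding-Nichols model: given ancestral
frequency $p$ (uniform on [0.05, 0.95], avoiding degenerate Beta shapes)
and divergence $F$, population frequencies are drawn from
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ — expectation $p$, variance
$F p (1-p)$. With super-groups the draw is nested: ancestral $\to$ group
ancestor $\to$ population.

**LD mechanism.** With LD enabled, each haplotype carries a latent founder
coordinate $u \in (0,1)$ along the chromosome that survives between
adjacent SNPs with probability $e^{-\lambda d}$ and is otherwise redrawn
uniformly; alleles are $z_k = \mathbf 1\{u < p_k\}$. Within a genomic
region (default 10 Mb) the rate is constant, $\lambda = U_r \beta / 2$,
with multipliers $U_r \sim \mathrm{Exp}(1)$ assigned by shuffled quantile
stratification across regions. Two sites at distance $d$ in the same
region then have genotype correlation $e^{-U_r \beta d / 2}$, and since
$\int_0^\infty e^{-u\beta d} e^{-u}\,du = 1/(1 + \beta d)$, the mixture of
exponential decays across regions reproduces the Sved hyperbola exactly in
expectation. Stratified (rather than iid) multipliers shrink the
realisation variance of the mixture so that moderate region counts
(around 20-30) already trace the curve; population frequencies are held
constant within a region in this mode, which makes the surviving-pair
correlation exactly 1 and keeps the realised curve on target. Region
boundaries force a renewal, so cross-boundary pairs are uncorrelated —
a fraction $d/L_{\mathrm{region}}$ of pairs at distance $d$, the price of
the mixture construction. A first-order SNP-to-SNP copying chain was
evaluated first and rejected: with per-SNP frequencies the chain's
correlation must pass through every intermediate SNP and collapses at any
low-MAF marker, flattening the curve far below target.

With `phase_mode = "independent"` each population additionally flips the
coupling orientation per SNP at random ($z_k = \mathbf 1\{u > 1 - p_k\}$,
same margin), which decorrelates the *phase* of LD between populations so
pooled samples lose LD faster than either population alone — the
inter-population contrast. The flip costs within-population $r^2$ at loci
away from frequency 0.5 (binary variables with unequal margins cannot be
perfectly anticorrelated), so the default is `"shared"`, under which the
within-population curve is the analytic one.

With LD disabled (`ld_beta_per_kb = NULL`) every SNP is an independent
Balding-Nichols draw with its own ancestral frequency — the exact model
under which the Weir-Cockerham and outlier-scan recovery properties are
stated, and the mode used for those checks.

**Planted features.** ROH plants overwrite one haplotype with the other
inside the interval, forcing homozygosity while preserving frequencies.
Admixed populations draw each haplotype from one of two source processes
with the configured fraction. Outlier loci are redrawn at divergence
$F^\*$ using *antithetic* Beta quantiles across the two groups (quantile
$v$ and $1-v$): marginally still Balding-Nichols at $F^\*$, but guaranteed
to land on opposite extremes — independent redraws would put both groups
on the same side half the time, making a "planted divergent locus"
unreproducible. All randomness flows from the single config seed.

**What the generator does not emulate.** Ascertainment bias of chip SNP
discovery panels, mutation and recombination-map realism, pedigree
structure within populations, and genotype-calling error modes. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated generative models, not robustness to every artifact of real
chip data.

# Problem sizes and numerical choices

The test suite and worked examples run the estimators at desk scale chosen
to make Monte-Carlo tolerances meaningful while keeping runs quick:
$F_{ST}$ recovery uses two populations of 30 at 6,000 SNPs ($\pm 0.02$
absolute); Sved-$\beta$ recovery uses 24,000 SNPs at 10-kb spacing over
10 chromosomes with 5-Mb rate regions, mid-range ancestral frequencies
(so the MAF screen cannot delete whole rate regions and distort the
mixture) and pairs to 500 kb (inside the region scale, avoiding boundary
renewals), giving over $10^6$ pairs (20% relative); the planted
selection outlier uses 1,000 loci under the fast MCMC profile; the ROH
length sweep uses a 50-Mb chromosome at 5-kb spacing, where the caller's
output is fully deterministic. The pipeline demo uses six populations at a
few thousand SNPs. Degenerate inputs are handled explicitly throughout:
all-missing loci error (distinct from frequency zero), monomorphic SNPs
are excluded from PCA and contribute zero heterozygosity, doubly fixed
SNPs yield no $F_{ST}$ estimate and are counted as excluded, zero-variance
dosage pairs are skipped (and counted) in LD, and a zero decay estimate is
flagged with an infinite extent rather than silently reported.

# Known limitations

* The per-SNP $F_{ST}$ mean is reported for comparability with published
  tables but is not an unbiased estimate of the generative divergence; use
  the multilocus value for parameter interpretation.
* The RJ-MCMC's prior-proposal insertion move mixes slowly for loci whose
  posterior $\alpha$ sits far in the prior tail; the pilot-tuned
  random-walk refreshes included coefficients, and the planted-outlier and
  null-calibration tests bound the practical impact, but very long chains
  remain advisable for borderline loci (the published chain lengths are
  the defaults).
* ROH boundary placement inherits the window rule's single-SNP resolution:
  a heterozygous call immediately flanking a tract can extend eligibility
  by one marker before trimming; boundaries are exact only for clean
  tracts.
* NJ is quadratic-to-cubic in samples and intended for the hundreds of
  individuals typical of diversity panels, not biobank scale.
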