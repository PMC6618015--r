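---
title: "Detecting sexual-conflict signatures from genotype likelihoods: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sexual-conflict signatures from genotype likelihoods: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexconflictr)
```

# The scientific problem

Intralocus sexual conflict — an allele that benefits one sex at a cost
to the other — maintains variation at intermediate allele frequencies.
Its population-genomic footprint is elevated Tajima's D; conflict acting
through sex-differential *survival* additionally elevates intersexual
F_ST, the allele-frequency differentiation between adult males and
females of a single population. Contrasting these two statistics across
gene classes that differ in sexual dimorphism (gonad-biased versus
somatic, sex-biased versus unbiased) and across species that differ in
mating system lets one ask where conflict is ongoing, where it has been
resolved, and what resolves it.

`sexconflictr` implements that full analysis as composable,
tibble-returning functions plus a pipeline driver, together with a
synthetic-data generator that plants known structure so that every claim
the package makes about real data can first be demonstrated on data with
known truth.

# Population-genetic model

## Genotype likelihoods

RNA-seq read depth is too uneven for reliable hard genotype calls, so
every estimator works directly on genotype likelihoods. The per-read
model is a mixture: under genotype $g \in \{0,1,2\}$ copies of the
derived allele, a read matches the derived allele with probability
$(g/2)(1-\varepsilon) + (1-g/2)\,\varepsilon/3$, where $\varepsilon$ is
the per-base error rate ($P(\text{match}) = 1-\varepsilon$, each
specific mismatch $\varepsilon/3$). Likelihoods are products over reads,
normalized to sum one; no reads gives the flat triple $(1/3,1/3,1/3)$.
This mixture form is an explicit modelling choice for both the generator
and the estimators; it shares the structure, though not every detail, of
the genotype-likelihood models used by standard variant callers.

## SAF likelihoods and the SFS

The likelihood $h(j)$ that $j$ of the $2N$ sampled chromosomes carry the
derived allele marginalizes genotype uncertainty by dynamic programming
over individuals:

$$w_i(k) = \sum_{g} w_{i-1}(k-g)\, g_i(g) \binom{2}{g}, \qquad
  h(j) = w_N(j) \Big/ \binom{2N}{j},$$

max-scaled per site. The unfolded site frequency spectrum $\xi$ is the
maximum-likelihood mixture over sites, fitted by EM
($q_s(j) \propto \xi_j h_s(j)$; $\xi'_j = \overline{q_s(j)}$) from a
uniform start, tolerance $10^{-8}$ on the largest coordinate change, at
most 200 iterations (non-convergence warns rather than fails). The
marginal log-likelihood is provably non-decreasing and is asserted at
every step in the test suite. Polarization (ancestral vs derived) is
known in simulation; real inputs must arrive polarized.

Missing individual-sites enter pooled computations as flat triples — the
no-data likelihood, which is exactly how a genotype-likelihood framework
represents absent reads — keeping $2N$ common across sites so all sites
can share one SFS. The single-site `saf_likelihood()` instead adapts its
length to the informative individuals.

## Thetas and Tajima's D

With the fitted SFS as prior, per-site posteriors give
$p_\text{var} = 1 - \text{post}(0) - \text{post}(2N)$, a Watterson
contribution $p_\text{var}/a_1$, and a pairwise contribution
$\sum_j \text{post}(j)\, j(2N-j)/\binom{2N}{2}$. Gene-level values are
sums over sites, and D uses the classical constants with
$n = 2N$ and the effective segregating-site count
$S_\text{eff} = \sum p_\text{var}$; D is undefined (NA) when
$S_\text{eff} \le 0$. On error-free, deep-coverage hard calls this
reduces exactly to the textbook estimator, which the acceptance suite
verifies to $10^{-6}$.

Because demography moves the whole D distribution, cross-species work
uses **relative D**: the class median minus the non-tissue-biased
median within the same species. The difference (not ratio) of medians
was chosen because a difference is well-defined when the background
median is near zero and is the quantity a median-shift contrast
(Wilcoxon) speaks to.

The Z chromosome is analysed with male samples only (females are
hemizygous ZW, so Hardy–Weinberg genotype priors only hold in males),
and is excluded from intersexual F_ST entirely — with one hemizygous
sex there is no power for a within-generation frequency contrast.

## Intersexual F_ST

Per-sex derived-allele frequencies are maximum-likelihood estimates
under a Hardy–Weinberg prior, obtained by golden-section search on
$[0,1]$ (bracket tolerance $10^{-6}$), vectorized across sites. Hudson's
small-sample-robust components are

$$\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
  \qquad \hat D = p_1(1-p_2) + p_2(1-p_1),$$

and per-gene F_ST is the **ratio of sums** $\sum \hat N / \sum \hat D$
(the weighted average), never a mean of per-site ratios — a property the
tests assert on a crafted two-site example where the two differ. Sites
must pass the data filter in *each sex separately* so that sex-limited
genes are not discarded. The count test for "elevated" F_ST uses the
strict threshold F_ST > 0, expectation from the non-tissue-biased
background, and a 2×2 chi-squared (df = 1, no continuity correction);
the 2×2 construction is an interpretive choice — a one-sample
observed-versus-expected statistic is equally defensible and both counts
are reported by the pipeline.

## Inbreeding

Per-individual inbreeding coefficients come from an EM on the mixture
prior $P(g \mid p, F)$: with probability $F$ the two alleles are
identical by descent (homozygous ancestral with probability $1-p$,
derived with $p$), otherwise Hardy–Weinberg. The E-step computes the
posterior IBD probability per site; the M-step averages it. $F$ is
clipped to $[0,1]$ and iterated to $|\Delta F| < 10^{-6}$ from a start
of 0.5 (both bounds are fixed points, so the start must be interior).

# Expression classification

Genes are removed when FPKM < 2 in half or more individuals
(`ceiling(n/2)`, the literal reading of "half or more" for odd n) in
either tissue; exactly 2 FPKM counts as expressed. Normalization is TMM
(via edgeR, the standard implementation) and fold changes are computed
on TMM-scaled CPM group means with a pseudo-expression offset of 1 CPM —
the offset handles zeros and retains sex-limited genes; the choice of
CPM over FPKM for fold changes is configuration-exposed. Thresholds are
inclusive (≥ 2 for tissue bias, ≥ 1 for sex bias within tissue-biased
sets) for determinism at boundaries. Tissue bias is classified within
one sex (male by default, female by a switch) to avoid biasing against
sex-limited genes, and Z-linked genes are classified in a separate pass
because incomplete dosage compensation gives the Z a distinct expression
profile. Fold-change rules are deliberately not significance-tested:
the classification is a fold-change rule, and classification is
invariant to any global rescaling of all samples (asserted as a
property test). For genes that are not tissue-biased, the sex-bias call
is taken from either tissue (biased in either counts as sex-biased),
the conservative rule when such genes must be *excluded* from the F_ST
contrasts.

Orthologues are reciprocal best BLAST hits after filtering at e-value
≤ 1e−10 and identity ≥ 30%, best hit by bitscore, ties broken by
identity, residual ties discarded. Immune/MHC-flagged loci are excluded
throughout, because heterozygote advantage in immunity mimics the
balancing-selection signature under study.

# Comparative analysis

PGLS assumes Brownian residual covariance $V(\lambda)$: shared
root-to-tip path lengths off the diagonal scaled by Pagel's $\lambda$,
unscaled tip depths on the diagonal. The GLS estimate
$(X^\top V^{-1}X)^{-1}X^\top V^{-1}y$ is computed through a Cholesky
whitening; $\lambda$ is either fixed or profiled by maximum likelihood
on $[0,1]$ (Brent search, tolerance $10^{-6}$, with an explicit
boundary check). Slope inference is a t-test with $n-2$ degrees of
freedom, and $r^2$ is defined in the whitened space against the GLS
intercept-only fit (the analogue of ordinary $r^2$; the choice matters
and is stated because no single convention exists). ML rather than REML
is the default; a fixed-λ route is provided. At $\lambda = 0$ on an
ultrametric tree the fit is exactly OLS, asserted to $10^{-10}$.

**A calibration caveat:** with six species, profiling $\lambda$ by ML
and then using the df $= n-2$ t-test is anticonservative — in our
simulations roughly 17% rejections at nominal 5% even under pure
Brownian residuals. This is a small-sample property of the procedure,
not an implementation error: at the generating $\lambda$ the test is
calibrated (~5%), which is how the package's null-calibration check is
run. Slope estimates and signs are unaffected; p-values from ML-λ fits
at n ≈ 6 should be read with this in mind.

The Z-subsampling test asks whether the weaker Z-linked trait
association is a gene-count artefact: autosomal focal genes are
subsampled to the Z-linked count per species, relative D recomputed, and
the cross-species Pearson r and OLS slope re-estimated per replicate;
one-sided p-values count replicates at or below the observed Z-based
statistics, ties included.

Resampling p-values use the +1 correction (never exactly zero), and the
permutation enrichment reports the two-sided distance-from-mean p, both
one-sided tails, and a df = 1 chi-squared against the permutation-mean
expectation, since the choice among them is itself a reporting decision.
No multiple-testing correction is applied across species by default —
tests are reported per species — though Benjamini–Hochberg can be
applied downstream.

# The synthetic-data generator

The generator's role is to produce inputs with exactly the statistical
structure the estimators assume, plus truth labels.

- **SFS shapes.** Neutral sites follow $1/j$ weights over segregating
  classes; balancing selection multiplies them by a bump
  $\exp(-4s\,(j/2N - 1/2)^2)$ centered at intermediate frequency, with
  strength $s \ge 0$. This is a direct control on the quantity D
  measures, not a coalescent with selection — deliberately, since it
  makes the planted effect interpretable and desk-scale.
- **Genotypes** are trinomial draws from the inbreeding-adjusted
  Hardy–Weinberg distribution; **likelihoods** come from
  Poisson-distributed depth and the same per-read error model the
  estimators use. Depth is coupled to expression by a decile multiplier
  (0.5× to 1.5×), emulating the depth–expression coupling of
  transcriptome data. Depth is otherwise independent across individuals.
- **Counts** are negative binomial around
  baseline × 2^(tissue effect) × 2^(sex effect) × length × library
  factor.
- **Phylogeny and traits.** A random coalescent tree rescaled to unit
  depth carries Brownian traits. The dichromatism proxy evolves around
  a positive clade baseline (`trait_root = 1.5`) — dimorphism proxies
  are positive-scale scores, and a positive baseline keeps the linear
  link `strength = max(0, coupling·trait + noise)` from being silenced
  by its floor for entire clades. Sperm number and residual testes mass
  are 0.5·dichromatism plus independent Brownian components, so the
  proxies correlate as real ones do.
- **Sexes share site frequencies**, so intersexual F_ST is null by
  construction — the generator cannot plant true sexually antagonistic
  viability selection, which is exactly why the F_ST stage is validated
  as a *calibration* (correct null behaviour) rather than as power.

Default study conditions (chosen once, as the conditions the analyses
target): 6 species, 5 individuals per sex, gonad + spleen, mean depth
20 with error 0.01, background balancing strength 4, truth tissue/sex
effects of 3 and 2 log2 units (comfortably above the 2/1 calling
thresholds; the true effect-size distribution in real birds is unknown
and these are not claimed to match it), coupling 2 with Brownian
strength noise at 0.25 of the trait rate. A single global seed drives
every stage through stage-named derived seeds, and all outputs are
bit-for-bit reproducible.

What the generator does **not** emulate: linkage and recombination
(sites are independent), read-level artefacts (mapping bias, PCR
duplicates, indel noise), isoform structure, expression-level
phylogenetic signal, and true antagonistic viability selection. Passing
tests therefore demonstrate correctness of the estimators and
calibration of the tests under the stated model, not robustness to
those real-data complications.

# Default world and planted structures

By default a simulated species plants *resolved conflict in the gonad*:
truly gonad-biased genes draw from a neutral (or species-coupled) SFS
while background genes carry the balancing bump. This single world
reproduces the two qualitative patterns the statistics are designed to
detect: gonad-biased genes sit below the background in D
(negative relative D), and across species the coupled strength of the
focal class makes gonad relative D rise with the dimorphism proxies
(positive PGLS slope). Null worlds (strength 0, coupling 0, no sex
effects) are used for every calibration check.

# Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen for adequate
precision of median-D contrasts: oracle equivalence at N ≤ 3
(enumeration) and 20 genes × 50 sites (textbook D); SFS recovery at 500
sites, 2N = 10, depth 20; inbreeding recovery at F = 0.3 with 1,000
sites (the ±0.05 check compares the mean across individuals with the
planted value, since per-individual realized inbreeding at 1,000 sites
has sampling noise of ~0.035); directional checks with 20 paired runs
of 60–80 genes × 30 sites; null calibrations with 200 replicates; PGLS
recovery with 100 replicates on 20-tip trees; and 20 end-to-end
six-species runs of 100 genes × 30 sites. Golden-section searches use
bracket tolerance $10^{-6}$; EM tolerances are $10^{-8}$ (SFS) and
$10^{-6}$ (inbreeding); quantile flags use type-7 quantiles with
inclusive ties.

# Known limitations

- The per-read error model is a single-parameter mixture; base-quality
  heterogeneity within a site is not modelled.
- Tajima's constants use the nominal 2N of the sample, not a per-site
  effective n; sites with heavy missingness are instead filtered.
- ML-λ PGLS p-values are anticonservative at very small n (above).
- The elevated-F_ST chi-squared assumes independent genes; linked genes
  would inflate its effective sample size.
- The stochastic SFS-initialization variant (sampling one allele
  frequency per site from its likelihood) is available but off by
  default; the full-likelihood EM is strictly less noisy.
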