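---
title: "Models and methods behind xtrd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xtrd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtrd)
```

# The problem

Transmission ratio distortion (TRD) is a deviation from the Mendelian
expectation that a heterozygous parent transmits each allele to half of its
offspring. On the X chromosome the analysis splits by region. Over most of
the chromosome (the heterosomal region) males carry a single X, so only dams
can be heterozygous and only dam-TRD is estimable; SNP arrays report the
hemizygous male calls as homozygous (codes 0/2), and a heterozygous male
call there is itself evidence against heterosomal inheritance. The terminal
pseudoautosomal region (PAR) recombines with the Y in male meiosis and is
analysed like an autosome, with sire- and dam-specific and
offspring-sex-specific parameters. Alleles near the pseudoautosomal boundary
(PAB) are in strong population linkage disequilibrium with the X or Y and
are therefore delivered preferentially to daughters or sons — an *opposite*
sire-TRD between offspring sexes whose magnitude decays with genetic
distance from the boundary. `xtrd` estimates all of these effects from
sire–dam–offspring genotyped trios.

# Region classification

For every marker, each complete trio is checked for Mendelian consistency
under two inheritance models:

* **pseudoautosomal** — the offspring genotype must be composable from one
  sire allele and one dam allele (the standard autosomal check);
* **heterosomal** — a male offspring carries a single maternal allele
  (call 0 or 2; call 1 is inconsistent), and a female offspring carries the
  sire's hemizygous allele (sire call 1 is inconsistent) plus one dam
  allele.

A marker is labeled heterosomal when its heterosomal inconsistency rate is
below 1% while the pseudoautosomal rate is at least 5%, and conversely.
Published examples of misassigned markers show contrasts of roughly ≥ 9%
against ≤ 0.31%, so the 1%/5% margins are wide but conservative; both are
arguments of `classify_markers()`. A determinately labeled marker whose
label contradicts the unanimous labels of its two neighbours on each side
(`k = 2`) is relabeled `discordant-removed` — the typical signature of a
genotyping artifact or a misplaced probe — and excluded from scans. The
choice of a small unanimous neighbourhood, rather than a majority vote, errs
toward keeping markers near genuine boundaries. Male heterozygosity is
reported as a diagnostic but deliberately not used for labeling: it is
informative only where the minor-allele frequency is appreciable. QC then
retains markers with at least 100 complete trios (10 at preliminary intake)
and an own-model inconsistency below 1%.

# Transmission extraction

At a heterosomal marker, offspring of heterozygous dams resolve the
transmitted maternal allele directly: sons by their hemizygous call,
daughters by subtracting the sire's hemizygous allele. Daughters whose sire
is ungenotyped or heterozygous are excluded rather than guessed — the sire
call is required because it is the phase reference, and a heterozygous sire
call is a model inconsistency. At a pseudoautosomal marker, matings with
exactly one heterozygous parent resolve that parent's transmission; AB×AB
matings resolve both parents for AA or BB offspring, while their AB
offspring form an *ambiguous* class that enters the likelihood as the
mixture `P_s(A)P_d(B) + P_s(B)P_d(A)` instead of being split into
fractional counts — this preserves the exact multinomial likelihood.

# Allelic model and inference

Each resolved transmission from a heterozygous parent is Bernoulli with

> P(A) = 0.5 + α,  P(B) = 0.5 − α,  α ∈ (−0.5, 0.5),

with a separate α per parent and offspring-sex stratum as requested
(`alpha_d`, `alpha_s_m`, `alpha_d_f`, …) and independent uniform priors.
When the active model reduces to independent binomials (any dam-only model,
or sire/dam models without ambiguous offspring), the posterior of
p = 0.5 + α is Beta(n_A + 1, n_B + 1) and `fit_allelic()` uses it in closed
form. Otherwise a single Metropolis-within-Gibbs chain of 110,000 iterations
with 10,000 burn-in (the package default) samples the joint posterior.
Proposals are reflecting random walks whose scales adapt during burn-in
toward 44% acceptance; after burn-in each update mixes in (with probability
0.9) an independence proposal from a Beta approximation learned on the
second half of burn-in. The mixture remains a valid Metropolis–Hastings
kernel and raises the effective sample size to near the nominal chain
length, which matters because the Bayes-factor ordinate is
variance-sensitive (below).

**Bayes factors.** Significance is tested with the Savage–Dickey density
ratio at the Mendelian null α = 0: BF = prior ordinate / posterior ordinate.
With the uniform prior the closed-form path gives
BF = 1 / dbeta(0.5; n_A + 1, n_B + 1). The sampler path estimates the
posterior ordinate by moment-matching a Beta density on the parameter's
bounded support to the post-burn-in draws. A kernel density cannot work
here: decisive results place the null 5–40 posterior SDs into the tail,
where ordinates of order 10⁻²⁰ must be evaluated and no sample ever falls.
The parametric estimate is exact in the binomial-reducible case (the
posterior *is* Beta) and is the package's documented choice elsewhere.
Decisive evidence is declared at BF ≥ 100 (log10 ≥ 2, Jeffreys' scale).

**Empirical null.** Because extreme counts make BFs scale-free but not
error-calibrated, each estimate also receives a "probability of random TRD"
class: transmissions are simulated under α = 0 with the observed number of
informative transmissions, the posterior-mean α of each replicate is
computed (closed form), and the upper-tail probability of the observed |α̂|
is binned into the printed classes ≤0.001%, ≤0.01%, ≤0.1%, ≤1%, ≤5%, >5%.
One million replicates resolve the finest class; null draws are cached per
informative-count bin (3 significant digits).

# Genotypic (recessive) model

Recessive lethality removes homozygous offspring without distorting
allele-level transmission much, so it is targeted with a genotypic model on
female offspring in the heterosomal region (males are hemizygous and a
recessive X-linked lethal would remove sons at the allele level instead).
Within each mating class the Mendelian offspring-genotype expectations are
reweighted by

> w(AA) = 1 + α_g, w(AB) = 1 + δ_g, w(BB) = 1 − α_g,

renormalized per class, with uniform priors on (−1, 1) (all weights are then
non-negative). The recessive signature is α_g < 0 compensated by δ_g > 0.
This concrete parameterization is one of several in the genotypic-TRD
literature; published α_g/δ_g values under other parameterizations are
comparable in sign and ordering but not numerically identical, so the
package's tests assert sign patterns and its own quadrature oracle rather
than third-party point values. Only the hemizygous-A-sire × heterozygous-dam
class is directly informative about the AA deficit; with very few such
matings the Bayes factor is honestly modest even when the AA category is
empty.

# Phasing and haplotype scans

Phasing is rule-based and conservative, using only trio information:
hemizygous male calls are trivially maternal; daughters inherit the sire's
hemizygous allele as paternal and the remainder as maternal; in the PAR a
heterozygous offspring call resolves only when at least one parent is
homozygous. Unresolved sites are dropped (the trio is excluded from windows
touching them) rather than imputed — statistical imputation would
manufacture certainty the downstream counts cannot distinguish from data.

Sliding windows of 2, 4, 10 and 20 SNPs (step 1) are scanned with the
*biallelic haplotype procedure*: every distinct window haplotype with
frequency ≥ 0.5% (a floor below which counts cannot pass the retention
filters anyway) is recoded in turn as pseudo-allele A against all others
pooled as B. The dam's untransmitted haplotype is obtained by subtracting
the phased transmitted haplotype from her genotypes, so dam heterozygosity
for the focal haplotype needs no dam phasing. Windows with fewer than 10
heterozygous dams or fewer than 50 informative offspring are discarded.
Overlapping significant windows (BF ≥ 100 and, when computed, a random-TRD
class at the chosen level) are consolidated: per-window log10 BF is smoothed
along the marker index with a Gaussian kernel (bandwidth = window size, in
markers — the scale over which sliding windows share most of their SNPs),
windows are grouped by overlap, and the member at the smoothed maximum
represents the group.

# The synthetic-data generator

Because the motivating datasets (hundreds of thousands of genotyped dairy
cattle under data-transfer agreements) are not redistributable, the
simulator is a first-class module and the test bed. Its defaults emulate the
study design: many trios per sire (round-robin over 200 sires, 5,000 trios),
one genotyped dam per offspring, a 1:1 offspring sex ratio, 500 heterosomal
markers spanning 29,245–137,034,696 bp and 100 PAR markers spanning
143,865,210–148,816,634 bp (the bovine X layout), and allele-B frequencies
uniform on (0.2, 0.8).

Mechanisms, not labels, generate the signals:

* Dams transmit one recombinant X per meiosis under a uniform genetic map
  (1.5 Morgan across the chromosome, the right order for a bovine X in
  female meiosis); injected dam-TRD redraws the transmitted allele at a
  marker with P(A) = 0.5 + α, optionally per offspring sex, and haplotype
  distortion picks the carrier haplotype as a block.
* Sires pass their intact X heterosomal haplotype to daughters and nothing
  heterosomal to sons; the transmitted PAR segment is a recombinant mosaic
  of the X- and Y-borne PAR haplotypes, starting in the Y state for sons
  and the X state for daughters at the boundary, with per-interval
  recombination from a linear 0.5-Morgan PAR map (the PAR is a male
  recombination hotspot with an obligate crossover). With the same allele
  riding the Y-PAR across sires (`y_linked_fraction = 1` by default, since
  α is a population parameter while phase is per-sire), this produces
  opposite sire-TRD of equal magnitude between sexes at the boundary,
  decaying with distance — ±0.5 at a fully linked boundary marker.
* Recessive lethality rejects female conceptuses homozygous for the
  configured haplotype and redraws the meiosis; a mating that can produce
  no viable daughter at all (homozygous-carrier dam × carrier sire)
  contributes a son instead, mirroring the sex-ratio consequence of an
  X-linked female-lethal.
* Array-style emission doubles male hemizygous calls (0/2); genotyping
  error (random code replacement) and missingness are applied last, after
  the truth is recorded.

What the simulator does **not** emulate: multi-generation pedigrees and
selection, realistic site-frequency spectra and background LD (founder
haplotypes are drawn in linkage equilibrium except for seeded carrier
haplotypes), genotyping-array ascertainment, and pedigree errors. Passing
tests therefore demonstrate that the estimators recover what the stated
mechanisms generate at realistic sample sizes — not that every artifact of
real array data is handled.

# Numerical choices and degenerate inputs

* Genotype codes count copies of allele B; coordinates are 1-based bp.
* Missing genotypes are never imputed; each computation skips incomplete
  trios on its own terms.
* Zero informative transmissions give a flagged result with BF = 1 and no
  estimate; a mating class with zero total drops out of the genotypic
  likelihood; markers with no informative trios classify as undetermined.
* MCMC proposals reflect at the prior bounds (a triangle-wave fold, exact
  for any step size); adaptation is frozen at the end of burn-in, keeping
  the sampled kernel valid.
* Chain lengths: the flagship per-marker fits use the 110,000/10,000
  default; window scans and the test suite use shorter chains
  (4,000–20,000) with Monte-Carlo-error-aware tolerances, a deliberate
  problem-size choice documented per call site.
* Ties in the empirical null are counted conservatively (observed |α̂|
  attained by a null replicate counts against significance); the null
  cache key includes replicate count and seed.
* Every stochastic routine takes an explicit seed; simulator output is
  byte-identical under a fixed seed.

# Known limitations

* Dam-TRD at heterosomal markers requires a genotyped homozygous sire for
  daughter trios; cohorts with many ungenotyped sires lose daughters from
  those counts.
* The moment-matched Beta ordinate behind sampler-path Bayes factors is
  parametric; for posteriors piled hard against a bound it can misstate the
  ordinate by a few tenths of a log10 unit, which is immaterial at decisive
  strength but should not be over-read near the BF ≥ 100 threshold.
* Consolidation is a pragmatic smoothing-and-grouping rule, not a formal
  multiple-testing correction; counts of consolidated regions depend on the
  bandwidth.
* The genotypic model assumes complete lethality acts before genotyping;
  late-acting or partial effects shrink α_g toward zero rather than
  appearing as a distinct class.
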