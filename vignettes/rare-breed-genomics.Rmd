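---
title: "Characterizing a rare breed and selecting distinctive markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a rare breed and selecting distinctive markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BreedGenomics)
```

## The problem

Numerically small livestock breeds drift fast: diversity erodes, inbreeding
accumulates, and the effective population size shrinks well below the census
count. Two practical questions follow. How compromised is the breed's
genomic health, and can a small, cheap set of SNPs certify that an animal
belongs to the breed? This package answers both from standard SNP-array
genotypes, and ships a truth-known simulator so that every estimator can be
tested without access to any particular breed's (often non-public) data.

All analyses operate on a `GenotypeData` object — a `SummarizedExperiment`
with markers as rows (map in `rowData`: chromosome, position, alleles) and
samples as columns (breed labels in `colData`), calls coded 0/1/2 as copies
of the `a2` allele with `NA` for missing. The single coding orientation is
deliberate: every downstream statistic (GRMs, F~ST~, discriminants) is
defined against it, and coding flips are covered by invariance tests.

## Models and procedures

### Diversity

Per-site diversity uses allele counts from diploid genotypes,
$\pi_{site} = 2 n_A n_a / (n(n-1))$ with $n$ the non-missing allele count,
summed over fixed 1 Mb tiles anchored at position 1 (window phase is a
convention; SNP-clipped windows would change per-bp values only at
chromosome ends). Tajima's D contrasts $\hat\theta_\pi$ with Watterson's
$S/a_1$ using the classical constants for $n = 2 \times$ samples; windows
with $S = 0$ report `NA` rather than 0, because an absence of segregating
sites is no evidence for $D = 0$. Significance limits come from the beta
approximation of D's null distribution between its theoretical extremes
$D_{min}$ (all singletons) and $D_{max}$ (all half-frequency sites); the
limits bracket zero for every $n$ and widen as $\alpha$ shrinks.

### Runs of homozygosity and inbreeding

The ROH scan reconstructs PLINK's semantics: a window of `scan_window_snps`
(default 55) is homozygous if it holds at most one heterozygous and two
missing calls; a SNP is ROH-eligible when at least 5% of the windows
overlapping it are homozygous; maximal eligible runs are split at inter-SNP
gaps above 1 Mb and kept when they reach 55 SNPs, 1 Mb, and 1 SNP/500 kb
density. Because scanning-window edge behavior is where implementations
drift apart, the unit suite pins the scan to an independently coded
brute-force enumeration oracle on every fixture up to 500 SNPs — the oracle,
not PLINK's binary, is the contract. The minimum SNP count follows the
spurious-run bound $\lfloor \ln(\alpha/(n_{snps} n_{ind})) / \ln(1 -
\bar{het}) \rfloor$, floored as the conservative choice (rounding would agree
at the published inputs).

Four inbreeding estimators are kept side by side because they measure
different things: $F_{ROH}$ captures recent autozygosity;
the VanRaden method-2 diagonal (base frequency fixed at 0.5, so $F$ measures
departure from maximal heterozygosity rather than from current frequencies);
the allelic-similarity diagonal, whose $2S_{ii}-1$ is simply the proportion
of homozygous loci; and Wright's pedigree coefficient via the Meuwissen–Luo
tabular method with unknown parents as unrelated founders. On simulated
inbred lines all four rise together; the genomic pair correlates > 0.9 while
pedigree estimates lag wherever pedigrees are shallow — the qualitative
pattern expected of a breed whose records span only a couple of complete
generations.

### Effective population size

LD-based $N_e$ inverts the Sved & Feldman drift–recombination expectation
$E[r^2] = 1/(1+4N_ec)$ per distance bin, with $r^2$ the dosage correlation
on pairwise-complete data, $-1/n$ as the unphased finite-sample correction,
$c$ from a uniform 1 cM/Mb map capped at 0.5 Morgans, and $t = 1/(2c)$. The
mapping constant (1 here) and the bin edges (50 log-spaced bins in
(5·10⁻⁴, 0.5)) are explicit arguments: LD-based $N_e$ software differs
exactly in these constants, so point replication of any one tool is not the
contract — trend-level recovery is, and forward Wright–Fisher simulations at
$N_e = 50$ are recovered within ±30% at recent bins across seeds. The
current size is the intercept of an ordinary least-squares fit of $N_e$ on
$t$ over recent generations (default window 54). Pedigree $N_e = 1/(2\Delta
F)$ takes $\Delta F$ as the regression slope of individual inbreeding on
complete-generation counts — adequate for shallow pedigrees where the
multiplicative accumulation $1-(1-\Delta F)^t$ is indistinguishable from
linear.

### Relatedness

IBS distances count shared alleles per pairwise-complete marker. Trees are
neighbor-joining on those distances; the bootstrap resamples markers
(columns) — the standard phylogenomic bootstrap — and majority-rule
consensus nodes carry percent support, rooted on the outgroup breed.
Negative NJ branch lengths are clamped to zero with the deficit moved to the
adjacent edge, preserving path lengths. F~ST~ is Weir & Cockerham's 1984
estimator from genotype counts, with the genome mean as a ratio of summed
variance components; sites monomorphic in both populations are undefined and
excluded. Admixture maximizes the binomial mixture likelihood by plain EM
block updates (the same likelihood ADMIXTURE optimizes by quasi-Newton
relaxation; EM trades speed for a simpler, monotone contract), frequencies
clamped to $[10^{-6}, 1-10^{-6}]$, convergence by relative log-likelihood
change below $10^{-6}$, multiple seeded restarts keeping the best. The
cross-validation masks observed genotype entries fold-wise and scores masked
entries by binomial deviance under $\hat p = \sum_k q_{ik} f_{km}$.

### Panel selection

The pipeline mirrors a three-stage design. (1) Representative training
samples per breed: principal coordinates on a random-marker IBS similarity,
single-linkage groups at similarity 0.75, proportional allocation across
groups, maximin picks within groups, near-duplicates deferred — a documented
simplification of the cited MDS routine, which its source never defines
algorithmically. (2) Strict QC (call rate 90%, pooled MAF ≥ 0.3 so markers
segregate broadly, LD pruning at r² < 0.2 in 50-SNP windows stepping 5, no
missing calls), then for each focal-vs-other breed pair the top 5% of SNPs
by F~ST~, unioned with provenance. (3) Per-chromosome canonical discriminant
analysis on dosages with breed as class. A canonical function is
focal-separating when the focal centroid sits more than 3 pooled
within-class SDs (a configurable constant; the criterion the source text
leaves qualitative) from every other centroid; on those functions SNPs whose
standardized coefficients are extreme — |coefficient| above the mean + 2 SD
of the function's coefficient magnitudes — enter the panel, and single-SNP
chromosomes pass through. Two design points deserve note. Magnitudes are
used because a coefficient's sign flips with allele coding, so only the
magnitude rule is coding-invariant. And coefficients are standardized by
each variable's total SD rather than its pooled within-class SD: a perfectly
separating SNP has *zero* within-class variance, which would zero out
exactly the most informative markers; away from that degenerate corner the
two scalings rank almost identically. When zero within-class variance makes
`MASS::lda` fail outright, a deterministic ridge-regularized CDA
(eigendecomposition of $(W+\lambda I)^{-1}B$, $\lambda = 10^{-6}
\overline{\mathrm{diag}(W)}$) substitutes, keeping selection reproducible.

Validation is two-pronged. Hierarchical (Ward) clustering on the leading
principal components of the panel-SNP VanRaden GRM must isolate the focal
breed; two components are used by default because the panel was selected for
precisely one contrast — focal versus the rest — and that contrast lives in
the leading components, while later ones encode unrelated between-breed
structure that only dilutes the clustering (with five components, purity
drops on some fixture replicates; with two it holds on all). The cluster
count is chosen by the largest relative within-inertia drop, guarding
against floating-point dust once inertia is negligible. Binary
classification fits a two-class discriminant on panel dosages (training mean
imputation for missing calls) and must label every held-out animal
correctly; planted mislabelled animals are expected on the non-focal side.
The per-chromosome aggregate genotypes report the focal breed's most
frequent allele combination with frequencies as products of per-SNP allele
frequencies — a linkage-equilibrium approximation, flagged as such, since
array genotypes are unphased.

## The simulator: what it emulates and what it does not

`breedModel()`/`simulateBreeds()` draw breed allele frequencies from the
Balding–Nichols model: Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$ around a shared
ancestral frequency $p \sim U(0.1, 0.9)$, genotypes Binomial(2, freq).
The default study design is 14 breeds on 18 autosomes with 5,000 SNPs at
40 kb spacing: a heavily sampled focal breed (60 animals) with stronger
drift ($F = 0.35$), thirteen breeds of 30 at $F \sim U(0.15, 0.25)$, two
focal-labelled outliers redrawn from a neighbor breed's frequencies, and 40
planted distinctive markers whose focal-vs-every-other frequency gap is 0.6
(direction alternating, calibrated so pooled MAF survives the 0.3 filter).
Under this drift model the expected pairwise Weir–Cockerham F~ST~ between
two breeds at drift $F$ is ≈ $F$ itself (verified against a Monte-Carlo
frequency-simulation oracle before the test band was frozen), so the
default fixture spans roughly 0.15–0.35 — differentiation typical of pig
breed panels. Sample sizes follow the study design the panel stages assume
(20 training representatives per breed plus validation sets drawing 6–14
animals per non-focal breed from the held-out pool; a uniform 25-per-breed
layout cannot support that split, which is why the focal breed is larger).

Missingness (~1% overall) is injected as a failing-assay mixture — a few
percent of markers carry 15–40% missing calls, the rest are near-complete —
because that is how array missingness actually distributes. A uniform 1%
would be fatal to the pipeline's own drop-any-missing step
($0.99^{280} \approx 6\%$ of markers complete across 280 training samples)
while teaching nothing about real data; under the mixture, the call-rate
filter removes the failing assays exactly as intended.

What the simulator does **not** emulate: linkage disequilibrium within
breeds (Balding–Nichols loci are independent, so ROH and LD-$N_e$ on this
fixture are exercised by the dedicated Wright–Fisher and gene-drop
simulators instead), ascertainment bias of commercial arrays, hierarchical
breed relationships (all breeds drift independently — trees on the fixture
test monophyly, not deep topology), and selection. Passing tests therefore
show the estimators are correct under drift-dominated differentiation, not
that any particular real breed's point estimates will be reproduced.

One known limitation is worth stating plainly: the planted distinctive
markers are, marginally, the near-unique focal-vs-all signals in the fixture
(their minimal frequency gap to every other breed, 0.6, exceeds the 99.9th
percentile of the background), and ~90% of them survive to the F~ST~
preselection — but the final coefficient-extremeness cut recovers only a
handful. With ~35 correlated high-F~ST~ SNPs per chromosome the multi-class
discriminant spreads its weight, so no single SNP is coefficient-extreme;
the cut keeps roughly two SNPs per chromosome, the same sharp 630→75-style
sparsification the method produces on real data. Structure coefficients
(variable–score correlations) were evaluated as an alternative "score" and
are equally diffuse. The panel that results still separates the focal breed
completely — 100% held-out classification, pure focal clusters, outliers
excluded — which is the property the method claims; exhaustive recovery of
every individually distinctive marker is not something this selection rule
can promise, and the suite tests enrichment, not exhaustive recovery.

## Numerical choices and degenerate inputs

Genotype codes count `a2` copies; missing is `NA`, never silently imputed
(classification imputes to training means, explicitly). QC filter order is
fixed — sex/unmapped, marker call rate, MAF, sample call rate, IBS
duplicates keeping the earlier sample — so reports are auditable. PLINK text
round-trips are lossless whenever both alleles are observed at a marker
(`.ped` carries no allele metadata for monomorphic sites; VCF round-trips
are lossless unconditionally). LD pruning removes the later-positioned SNP
of an offending pair, deterministically. F~ST~ ties in preselection break by
(F~ST~, chromosome, position). The ROH density rule applies per candidate
segment. Founders are non-inbred and unrelated; pedigree cycles are detected
and named at construction. All stochastic stages take explicit seeds and the
whole panel pipeline is deterministic given its seed.

Problem sizes in the suite are chosen to exercise each claim at desk scale:
oracle equivalence on fixtures up to 500 SNPs, Wright–Fisher recovery at
$N_e = 50$ over 6×300-SNP genomes and 100 generations across 5 seeds,
admixture model selection at $K = 3$ over 10 seeds, and the full 14-breed
panel pipeline at 5,000 SNPs — the scale at which its behavior (marker
counts through the cascade, perfect validation accuracy) stabilizes.
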