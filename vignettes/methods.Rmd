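---
title: "Models and methods behind glacialdemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glacialdemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

glacialdemog implements the analysis chain used to ask whether a
high-latitude population of a coastal species survived the last glaciation
in southern refugia or was founded from the north after the ice retreated.
This vignette explains the statistical models, the defaults and why they
were chosen, what the synthetic-data generator does and does not emulate,
and the numerical decisions a maintainer would want written down.

## Diversity statistics

Haplotype (gene) diversity uses Nei's small-sample-corrected estimator
$h = \frac{n}{n-1}(1 - \sum_i p_i^2)$ with the exact variance
$V(h) = \frac{2}{n(n-1)}\{2(n-2)[\sum p_i^3 - (\sum p_i^2)^2] +
\sum p_i^2 - (\sum p_i^2)^2\}$. Reports round $h$ to two decimals and its
SD to three, the precision at which such tables are normally printed.

Nucleotide diversity $\pi$ is the mean proportion of differing sites over
all sequence pairs, computed after *complete deletion*: any alignment
column containing `-` or `N` in any sequence is removed before haplotype
collapsing and all distance work. A single missing-data rule applied
everywhere keeps the two routes to $h$ (count table vs collapsed
alignment) exactly consistent, which the tests assert. No multiple-hit
correction is applied to $\pi$ itself; the Jukes–Cantor correction lives
in the distance model used by $\Phi_{ST}$, where it belongs.

Rarefied haplotype richness is the exact individual-based hypergeometric
expectation $E[S_g] = \sum_h [1 - \binom{n-n_h}{g}/\binom{n}{g}]$ with the
Heck et al. variance, evaluated through `vegan::rarefy()` rather than
resampling; a seeded resampling mode exists purely as a cross-check. On
the packaged count table the southern column rarefied to $g = 24$ gives
5.94 ± 1.05. Published tables sometimes print slightly different values
for this quantity without stating the rarefaction depth or algorithm
variant; the package always reports the exact formula's value.

## AMOVA, $F_{ST}$, $\Phi_{ST}$ and the phylogeography test

The two-level haploid AMOVA partitions the pairwise-distance sum of
squares: within-group $SSD_k = \frac{1}{n_k}\sum_{i<j \in k}\delta_{ij}$,
$\sigma_b^2 = SSD_w/(N-P)$, $n_c = (N - \sum n_k^2/N)/(P-1)$,
$\sigma_a^2 = (MS_{among} - \sigma_b^2)/n_c$ and
$\Phi = \sigma_a^2/(\sigma_a^2 + \sigma_b^2)$. With identity distances
($\delta_{ij} = 1$ for distinct haplotypes) $\Phi$ reduces to the
haplotype-frequency $F_{ST}$; with Jukes–Cantor-corrected p-distances it
is $\Phi_{ST}$. Negative variance components are kept internally — the
permutation null needs them — and truncated to zero only in user-facing
summaries, with both values retained in the result object. $\Phi$ is
invariant to rescaling $\delta$, which the tests verify.

Permutation p-values use the add-one estimator
$(\#\{\Phi^* \ge \Phi_{obs}\} + 1)/(B + 1)$ and mandatory seeds. Two
different nulls are deliberately used. The AMOVA p-value permutes
*individuals* among populations with sizes fixed. The
phylogeographic-structure test instead permutes *haplotype identities on
the distance matrix*: haplotype frequencies, and therefore $F_{ST}$, are
held exactly fixed while $\Phi_{ST}$ is recomputed, so the test isolates
the association between haplotype relatedness and geography (the Pons &
Petit logic). Identity distances make this test vacuous
($\Phi_{ST} \equiv F_{ST}$) and are rejected with an error. A comparison
of $\ge 3$ haplotypes is required; with $k$ haplotypes split evenly
between two clades the smallest attainable p-value is about
$2(k/2)!^2/k!$, so very small haplotype sets cannot reach conventional
significance no matter how strong the structure.

## Bottleneck tests

For each microsatellite locus the observed unbiased heterozygosity
$He = n(1-\sum p_a^2)/(n-1)$ ($n$ = typed gene copies) is compared with
the distribution of $Heq$, the heterozygosity expected at mutation–drift
equilibrium *given the observed allele count* $k$. $Heq$ is simulated
with a constant-size coalescent (compiled inner loop) under SMM or TPM
(default TPM: 90% single-repeat steps; multi-steps geometric with mean
2.8 — the classic implementation's variance setting is not printed
anywhere, so the value is configurable). $\theta$ is first tuned by
bisection on the mean simulated allele count (monotone in $\theta$), then
replicates are retained only when the simulated allele count equals $k$
exactly; the default of 1000 retained replicates per locus follows the
classic program's convention and matters: with only a few hundred
retained replicates, noise in the estimated mean and SD of $Heq$ inflates
the standardized differences and makes the $T2$ test anti-conservative
(about 0.10 at nominal 0.05 in our calibration), while at 1000 replicates
all three tests sit inside the binomial confidence band of the nominal
level.

The three tests: (i) sign test on the number of loci in excess, with
per-locus excess probabilities estimated from each $Heq$ distribution and
an *exact Poisson–binomial* tail rather than a 0.5-binomial; (ii)
standardized differences $T2 = \sum_l DH_l/\sqrt{L}$ with
$DH_l = (He_l - \overline{Heq_l})/sd(Heq_l)$ against a standard normal;
(iii) Wilcoxon signed-rank on the $DH_l$. Direction (deficit vs excess)
is labelled by the sign of the mean $DH$; a heterozygosity *deficit* is
the expansion signature, *excess* the bottleneck signature. Loci with
degenerate $Heq$ (SD 0) are dropped with a warning and at least four
informative loci are required.

Power depends strongly on where the expansion sits relative to the
ancestral coalescent timescale. The packaged expansion experiment uses a
10-fold growth (500 → 5000 individuals) 1000 generations ago with
$\mu = 10^{-4}$ over 21 loci — about one coalescent time unit of the
ancestral population, where new singleton alleles inflate $k$ relative to
$He$ and the sign test detects the deficit in most replicates. Much more
recent expansions, or high-$\theta$ regimes where homoplasy saturates
allele counts, genuinely weaken or even reverse the signal; that is a
property of the method, not of this implementation.

## Coalescent engine and scenario templates

The simulator is a standard backward-time structured coalescent: within a
population holding $k$ lineages and $Ne$ gene copies
($Ne = \text{ploidy} \times N$; mtDNA passes ploidy 1, autosomal loci 2),
each pair coalesces at rate $1/Ne$ per generation; events (size changes,
merges) are applied at their times. It is validated against
$E[T_2] = Ne$, $E[L_n] = 2Ne\sum_{i<n} 1/i$, Watterson's $E[S]$ (in the
low per-site-$\theta$ regime where recurrent hits are negligible) and the
Ohta–Kimura SMM heterozygosity $1 - 1/\sqrt{1+2\theta}$, all at three
Monte-Carlo standard errors.

The two scenario templates share parameters $(N, Nb, t1, t2, t3)$ with
$Nb < N$ and $t1 < t2 < t3$ (sizes in individuals, times in
years, converted by a configurable generation time that defaults to 1 —
i.e. the priors are taken at face value in calendar years, a deliberate
simplification that is easy to change). Looking backward: both scenarios
shrink the south to $Nb$ at $t1$; the *northern shift* merges south into
north at the deglaciation time $t2$ (colonization at ice retreat), the
*in situ refugia* scenario at the glaciation onset $t3$ (an old split
with a long refugial bottleneck). The source material does not print
which time carries the merge in each scenario; this reading is the
package's documented canonical one, and `demographic_model()` accepts
explicit event lists so alternatives are testable. With $Nb \to N$ and
equal merge times the two templates provably coincide, which the tests
check by distributional comparison.

Sequence mutation is HKY: mutations Poisson on branches at rate
$L\mu$ per generation, each hitting a uniform site and substituting via
the HKY kernel (transition rates weighted by $\kappa$). Defaults
$\kappa = 10$ and base frequencies (0.30, 0.25, 0.15, 0.30) are documented
stand-ins typical of cetacean control regions — the original model
parameters are not printed anywhere — and both are configurable. The
default clock is 1.5%/Myr per lineage, i.e. $1.5\times10^{-8}$/site/year.
Microsatellite mutation is generalized stepwise: per-locus rates, ±1
steps with probability 0.9, otherwise geometric multi-steps (mean 2.8),
reflecting at a one-repeat floor.

## ABC

The reference table draws parameters from the per-marker uniform priors
(with $t1<t2<t3$ and $Nb<N$ by rejection; the mtDNA clock has prior
$U(5\times10^{-9}, 5\times10^{-8})$/site/year around the default clock,
since no rate prior is printed; microsatellite mean rate
$U(10^{-5},10^{-3})$ with per-locus Gamma(shape 2, mean tied) truncated to
$[10^{-5},10^{-2}]$ — the shape is a documented choice). Summary
statistics (mtDNA: per-population haplotype count, segregating sites,
mean pairwise differences, $h$; between: identity-AMOVA $F_{ST}$ and mean
between-population pairwise differences; microsatellites: mean allele
number, mean $He$, mean allele-size variance per population, plus
$F_{ST}$ and $(\delta\mu)^2$) are a reasoned reconstruction of the
standard set — the original list is not printed. Columns are normalized
by median/MAD over the table (constant columns dropped with a warning).

Scenario choice: the *direct* estimate is the scenario share among the
$k$ nearest rows by Euclidean distance on normalized statistics. Because
low-diversity data make many simulations land on identical statistic
vectors, ties at the $k$-th distance are frequent and the whole tie set
is used, making the estimate invariant to row order; scenarios are also
interleaved in the table so no ordering artifact can enter. The
*logistic* estimate fits a distance-weighted (Epanechnikov) logistic
regression of the scenario indicator on the statistic deviations over the
closest 1% of rows, evaluated at the observed point; a small ridge
penalty ($10^{-4}$, intercept penalized at 1% of that) keeps the fit
defined under separation, Newton steps are damped, and if the closest
fraction ties completely at distance zero the method degenerates — by
design — to the tie-set share. CIs are binomial (direct) or delta-method
on the logit scale (logistic); how the published CIs were computed is not
stated, so this is a documented choice.

Parameter estimation restricts the table to one scenario, accepts the
closest rows (at least 100), logit-transforms each parameter to its prior
bounds, applies the weighted local-linear adjustment, and back-transforms
— which clamps adjusted draws inside the prior support. Because the
adjustment acts per parameter, it can break the joint ordering
constraints; such draws cannot be simulated from and are discarded (the
count is recorded). Confidence-in-choice simulates pods from each
scenario's prior and classifies them with the same logistic settings;
model checking simulates at posterior draws and reports two-sided
posterior-predictive tail probabilities per statistic.

## The synthetic-data generator

`table1_fixture()` is the study's haplotype-count table (14 haplotypes;
24 northern + 40 southern samples; H1 the only shared haplotype).
`sequences_from_table()` expands it into a 663-bp alignment with exactly
15 biallelic segregating sites placed at seeded random positions, such
that collapsing inverts the construction exactly — frequencies, and hence
every frequency-based statistic, are preserved by construction.
`generate_pseudo_observed()` simulates full datasets under a scenario and
writes FASTA/GenePop plus a truth JSON (scenario, parameters, seed) for
recovery experiments. Microsatellite pods default to 24/29 individuals
per population (the 53 genotyped samples' split is not printed; this is
configurable) over 21 loci.

What the generator does *not* emulate: the real variant positions and
haplotype genealogy (the synthetic variants are random, so
$\Phi_{ST}$-style distance-weighted statistics on fixture expansions
estimate the same quantity as $F_{ST}$, and the published
$\Phi_{ST} = 0.39$ cannot be reproduced without the undeposited
sequences); sampling geography beyond a two-label split; genotyping
error and null alleles; linkage. Passing tests therefore demonstrate
correctness of the machinery and qualitative behavior of the inference,
not agreement with unpublished raw data.

A related low-information caveat: at the 1.5%/Myr clock and the
posterior-mean demography, a 663-bp fragment carries on the order of one
mutation, so single-replicate diversity comparisons between populations
are tie-dominated. The packaged "founded population is less diverse"
check therefore runs at a $5\times10^{-8}$/site/year clock (inside the
ABC rate prior), where mean pairwise differences match their closed-form
pair-TMRCA expectations and the ordering emerges reliably.

## Problem sizes and numerical choices

Simulation experiments in the test suite use desk-scale sizes chosen to
keep the full suite comfortably reproducible on a laptop while leaving
the conclusions statistically meaningful: a 20,000-row reference table
and 50 pods for scenario recovery (the correct scenario must win for at
least 80% of pods); 100 constant-size replicates at 21 loci for the
type-I calibration (binomial CI half-width ±0.043); 10 pods for
parameter recovery with a fixed clock, requiring the average posterior
mean within a tenth of the prior width of the truth for $N$ and $t1$; 400
replicates at 99 permutations for p-value uniformity. The published
analysis ran $10^7$ simulations per scenario; all counts here are
configurable and the pipeline warns when inference uses fewer than
$10^4$ rows.

Other numerical decisions: bisection for $\theta$ runs 25 iterations on
$\log\theta \in [\log 10^{-4}, \log 10^4]$ with 300 simulations per
evaluation; the exact-$k$ rejection aborts if acceptance falls below
$10^{-4}$; logit transforms clamp at $10^{-8}$ from the bounds; the
Jukes–Cantor correction refuses $p \ge 3/4$; GenePop allele codes are
interpreted as repeat counts, `00`/`000` as missing, and diploid
genotypes pair consecutive simulated gene copies.

## Known limitations

No recombination, migration after founding, or selection; two scenarios
and two populations only; the standardized-differences test should be
read with care below ~20 loci and with small $Heq$ replicate counts; ABC
posteriors at desk scale rank scenarios reliably but their absolute
probabilities carry Monte-Carlo error of a few percent; and mtDNA-only
configurations have limited power against deep-merge alternatives (high
type II error), consistent with a single-locus genealogy's stochasticity.
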