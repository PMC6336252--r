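---
title: "Multigenerational genomic-selection calibration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multigenerational genomic-selection calibration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`multigen` is a self-contained simulation study of genomic-selection
(GS) reliability across breeding generations. It asks a practical
question: when marker effects are estimated in one population, how
quickly does prediction reliability erode in descendant generations
under different mating systems — and how much of it can be recovered by
re-training on pooled, multigenerational data? Everything is simulated,
so predicted genomic values can be validated against *true* genetic
values rather than phenotypes.

This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the simulation can show.

## The simulated genome and populations

The genome is a diploid map of 10 linkage groups, each with 101
markers at 1 cM spacing: 1,010 biallelic markers over 1,000 cM
(`build_map()`). Two fully divergent inbred founders (all loci fixed
for alternative alleles) are crossed; their F1 is heterozygous at every
locus with known phase, and the F2 base population of N = 500 is formed
from pairs of independent F1 gametes. All linkage disequilibrium (LD)
in the F2 therefore comes from physical linkage, and every locus has
expected allele frequency 1/2.

Meiosis uses the Haldane mapping function with no interference: the
recombination fraction for a distance $d$ cM is
$c = \tfrac12(1 - e^{-2d/100})$, applied as an independent switch
probability per adjacent 1 cM interval; linkage groups assort freely.
The mapping function is a package choice — the study conditions state
map distances only.

From the F2, four generations are advanced under three systems
(`advance()`):

* **selfing** (`S1..S4`): each individual contributes exactly one
  selfed offspring. One offspring per parent keeps the census size
  constant and avoids drift from family-size variance; family structure
  was otherwise unspecified.
* **random mating** (`A1..A4`): offspring from two distinct parents
  drawn uniformly with replacement (self-fertilisation excluded — a
  package choice). Two modes exist, see below.
* **backcross** (`Bc1..Bc4`): each offspring combines a gamete from a
  random current-generation parent with a gamete from the recurrent
  parent. The default recurrent parent is the F1 — the "parent of the
  F2" — regenerated as the deterministic all-heterozygous genotype;
  either inbred founder can be configured instead.

### The two random-mating modes

`mode = "meiosis"` is standard sexual reproduction: gametic $D$ between
a pair of loci decays by $(1 - c)$ per generation, which on a 1 cM map
is very slow. `mode = "allele_resampling"` draws each offspring
haplotype locus-by-locus from Bernoulli(current allele frequency),
destroying inter-locus LD in a single generation while preserving
allele frequencies.

The second mode exists because several breeding-software simulators
advance "random-mating" populations by locus-wise resampling, so their
outcrossing LD collapses essentially to the independence baseline after
a single generation — a dynamic that standard meiosis on a 1 cM map
cannot produce. `allele_resampling` is a reconstruction of that
behaviour, not a claim about biology; it is the default in
`scenario_grid()` (whose outcrossing series is defined by the collapse)
and *not* the default in `advance()` (where the biologically standard
meiosis is). The choice is recorded in the grid object.

## Trait simulation

Twenty QTL control the trait, two per linkage group, placed at the
markers nearest 25 and 75 cM within each group. QTL genotypes are part
of the 1,010-marker panel by default (the map saturates the genome;
"hidden QTL" can be configured by excluding those columns from the
panel). Locus $j$ carries weight
$w_j = \binom{19}{j-1} / 2^{19}$ — the terms of the symmetric binomial
expansion $(\tfrac12 + \tfrac12)^{19}$ — so the weights sum to one,
with a few intermediate-effect loci and many small ones. The true
genetic value of individual $i$ is

$$
G_i = \mu + \sum_j a_j x_{ij} + \sum_j d_j h_{ij},
$$

with $x_{ij} \in \{+1, 0, -1\}$ for QTL dosage 2/1/0,
$h_{ij} = 1$ for heterozygotes, $a_j = w_j$ (homozygote scale
$a = 1$) and $d_j = (d/a)\, a_j$. The grid crosses three degrees of
dominance $d/a \in \{0, 0.5, 1\}$ with two broad-sense heritabilities
$h^2 \in \{0.30, 0.70\}$ — six architectures. $\mu = 0$ by default; it
cancels in every correlation computed downstream.

Phenotypes are $P_i = G_i + E_i$ with
$E_i \sim N(0, \sigma^2_e)$ and

$$
\sigma^2_e = \sigma^2_g \frac{1 - h^2}{h^2},
$$

where $\sigma^2_g$ is the **empirical** variance of $G$ in the
replicate's F2. Two choices are deliberate here:

* *Empirical rather than closed-form $\sigma^2_g$.* The closed form
  $\sum_j (a_j^2/2 + d_j^2/4)$ assumes linkage equilibrium among QTL,
  but the two QTL within a group are 50 cM apart and positively
  associated in an F2, so the realised variance is larger. Scaling the
  noise to the realised variance makes the realised $h^2$ match the
  target. The closed form is available for comparison
  (`genetic_variance_f2(..., method = "closed_form")`).
* *$\sigma^2_e$ fixed at the F2 value for all descendant generations.*
  Heritability is thus defined in the base population and the
  environment does not change as genetic variance drifts across
  generations — the standard convention when a single trait is tracked
  through a breeding scheme.

## The additive-dominance G-BLUP model

Training phenotypes follow
$y = X b + u_a + u_d + e$ with $X$ an intercept column (the simulation
has no other fixed effects), $u_a \sim N(0, G_a \sigma^2_a)$,
$u_d \sim N(0, G_d \sigma^2_d)$, $e \sim N(0, I \sigma^2_e)$, one
record per individual. Marker codings use the centered
parameterization: for allele frequency $p$ ($q = 1 - p$),

* additive `W`: $2 - 2p$, $1 - 2p$, $-2p$ for dosage 2/1/0;
* dominance `S`: $-2q^2$, $2pq$, $-2p^2$.

$G_a = WW' / \sum_i 2 p_i q_i$ and
$G_d = SS' / \sum_i (2 p_i q_i)^2$. Markers monomorphic in the
training set are zero-coded and excluded from the denominators; their
effects are exactly zero. **All frequencies — coding, denominators, and
the coding of validation individuals — come from the training set.**
This is what makes marker effects transferable across generations: the
validation coding must live on the same scale as the effects.

The dominance term is always in the model, including for $d/a = 0$
scenarios (its variance component then collapses to the floor), so
every scenario is fitted with the same machinery.

### REML

Variance components maximise the restricted likelihood. The maximiser
is an average-information (AI) Newton scheme with a monotone EM-REML
safeguard: the first step is an EM step, and any AI step that would
decrease the restricted log-likelihood or leave the parameter space is
replaced by the (always-ascending) EM update. The log-likelihood trace
is therefore non-decreasing — asserted in the test suite on every fit —
while convergence takes roughly ten iterations instead of the hundreds
EM alone needs when a component sits near zero. Components are floored
at $10^{-8} \times \mathrm{var}(y)$; convergence is declared when every
component changes by less than $10^{-6}$ relative (500-iteration cap;
non-convergence is flagged in the model metadata, not fatal). When the
AI matrix is solved, components pinned at the floor with negative
gradient are frozen out of the Newton step — their near-singular rows
otherwise stall it.

### Marker effects and prediction

The marker-level model $y = Xb + W m_a + S m_d + e$ with
$\sigma^2_{ma} = \sigma^2_a / \sum 2p_iq_i$ and
$\sigma^2_{md} = \sigma^2_d / \sum (2p_iq_i)^2$ is equivalent to the
G-BLUP above. `solve_effects()` offers both routes: the ridge
mixed-model equations (shrinkage $\lambda_a = \sigma^2_e /
\sigma^2_{ma}$, $\lambda_d = \sigma^2_e / \sigma^2_{md}$) and the
backsolve $m_a = \sigma^2_{ma} W' P y$, $m_d = \sigma^2_{md} S' P y$
from the REML projection $P$. They agree to numerical precision (a
standing test asserts $10^{-6}$ relative agreement of the resulting
predictions); the pipeline uses the backsolve because it is $O(np)$
once the fit is in hand. Predictions for new individuals are
$W_{val} m_a + S_{val} m_d$ with training-frequency coding, intercept
free. **Reliability** is the squared Pearson correlation between this
total (additive + dominance) prediction and the true genetic value.

## The three calibration strategies

Run over a `scenario_grid()` by `run_strategies()`; within a replicate
all strategies share the same F2, the same advanced populations and the
same phenotypes, so comparisons are paired.

1. **F2 calibration.** Train on the F2; validate in-sample and on every
   advanced generation of every system.
2. **Contemporary/outdated calibration.** For each system and each
   $n$, train on generation $n$; validate on generations $n..4$. The
   diagonal is in-sample (same individuals in training and validation —
   no holdout, matching the study design).
3. **Multigenerational calibration.** Pool the F2 with the first $k$
   generations ($k = 1, 2, 3$; 1,000 / 1,500 / 2,000 individuals),
   validate on generations $k..4$. Pooled sets get a single intercept —
   the simulation has no generation effects. Validation sets fully
   overlap the training pool where the layouts coincide.

Replicates default to 10; reliabilities are reported per cell as mean
± SD over replicates (`aggregate_reliability()`), and block averages
(`block_average()`) average cells within replicate first.

## Seeds and reproducibility

A single master seed fans out via a deterministic hash
(`derive_seed()`) into named streams per (replicate, architecture,
stage), so adding a stage or strategy does not shift existing streams,
and any run is bit-reproducible from its grid. REML and prediction are
deterministic.

## LD measurement

`r2_from_haplotypes()` computes $D = f_{AB} - f_A f_B$ and
$r^2 = D^2 / (p_A q_A p_B q_B)$ over the observed gamete pool — the
simulator knows true phase. `r2_em_unphased()` is the
maximum-likelihood estimator for unphased genotypes, resolving the
double-heterozygote phase ambiguity by EM (tolerance $10^{-8}$,
1,000-iteration cap); it exactly reproduces the phase-known estimator
when no double heterozygotes are present and is the estimator to use on
real data. Decay summaries (`ld_decay_table()`) are computed within
linkage groups only; pairs with a monomorphic locus are skipped and
counted.

## What the simulation does and does not show

The generator emulates idealised breeding populations: no mutation, no
selection during advancement, constant census size, no crossover
interference, no epistasis, no genotyping error, and founders divergent
at every single locus. Real training panels have allele-frequency
spectra, missing data, and family structure this ignores; passing tests
demonstrate internal correctness of the models and the orderings among
strategies, not calibrated reliability forecasts for any real crop.

Two findings from this implementation deserve emphasis:

* Under genetically standard advancement, selfing and backcrossing
  conserve most gametic LD on a 1 cM map (selfing decays $D$ only
  through residual heterozygosity; backcrossing re-injects F1 gametes
  every generation). Marker effects estimated in the F2 therefore
  transfer well: the selfing-series reliabilities decline gently from
  the in-sample value rather than dropping steeply. Published
  multigeneration tables produced by simulators whose LD decays much
  faster per generation will sit well below what linkage theory
  predicts here; this package reproduces the F2 in-sample values and
  all ordering patterns, but not those steeper transfer decays, and its
  LD summaries follow two-locus theory (F2 adjacent-marker
  $r^2 \approx (1-2c)^2 \approx 0.96$).
* With total LD collapse (`allele_resampling`), F2-trained ridge
  predictions lose almost all signal even though the QTL are in the
  panel: shrinkage spreads each QTL effect over its (formerly)
  correlated neighbours, and that smeared representation does not
  survive the collapse. Pooling post-collapse generations into the
  training set (strategy 3) recovers most of the reliability — the
  study's central claim, which this package confirms as an ordering.

## Problem sizes used by the shipped checks

The test suite exercises the full genome at the study's N = 500 and
10 replicates for the F2 in-sample quantities, and reduced replicate
counts (3–5) for the heavier multigeneration blocks; the acceptance
script (`scripts/acceptance.R`) runs every reported quantity at the
full 10 replicates. Oracles (direct likelihood maximisation, dense
ridge inversion, two-locus enumerations) run on miniature instances
where exhaustive computation is cheap.
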