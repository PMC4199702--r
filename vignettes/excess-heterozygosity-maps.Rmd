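---
title: "Modeling excess heterozygosity in selfed RIL genetic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling excess heterozygosity in selfed RIL genetic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exHetMap)
```

## The model

A selfed recombinant inbred line (RIL) population descends from a fully
heterozygous F1 by repeated self-fertilization. For two linked loci with
recombination fraction $r$, selfing symmetry collapses the ten possible
genotypes into five classes: (1) parental fixed, (2) recombinant fixed,
(3) single heterozygote, (4) coupling double heterozygote (AB/ab),
(5) repulsion double heterozygote (Ab/aB). Their probabilities evolve as
a Markov chain
$$p_{F_{t+1}} = \mathbf{T}\, p_{F_t}, \qquad p_{F_1} = (0,0,0,1,0)',$$
where column $j$ of $\mathbf{T}$ is the class distribution of the selfed
offspring of a class-$j$ parent.

The classical Mendelian chain halves heterozygosity each generation.
Many plant RIL populations do not: they retain a per-generation
proportion $h \neq 0.5$ of heterozygosity. `exHetMap`'s chain
(`transitionMatrix()`) encodes that as follows:

* classes 1 and 2 are absorbing;
* a class-3 parent segregates $\tfrac{1-h}{2} : \tfrac{1-h}{2} : h$
  into classes 1, 2, 3 — heterozygosity is retained at rate $h$ by
  construction;
* a class-4 parent segregates into classes 1–5 in the ratio
  $2(1-r)^2 : 2r^2 : 8ur(1-r) : 2u^2(1-r)^2 : 2u^2r^2$ (class 5 swaps
  the $(1-r)^2$ and $r^2$ factors), normalized by
  $d = 2(1-r)^2 + 8ur(1-r) + 2r^2 + 2u^2[(1-r)^2 + r^2]$.

Here $u$ is the relative viability of a heterozygous locus in the
offspring of a double heterozygote. It is not a free parameter: it is
pinned by requiring that one generation of segregation from a double
heterozygote also retains heterozygosity $h$,
$$h = \tfrac{1}{2}\,p(3\mid4) + p(4\mid4) + p(5\mid4),$$
which reduces to the quadratic $2a(h-1)u^2 + b(2h-1)u + 2ah = 0$ with
$a = (1-r)^2 + r^2$, $b = 4r(1-r)$. Its coefficients satisfy
$AC < 0$ for $h \in (0,1)$, so exactly one positive root exists
(`solveViability()` takes it); at $h = 0.5$ the root is $u = 1$ and the
whole chain reduces to the classical Mendelian recursion, which the test
suite verifies to $10^{-12}$ against an independently coded classical
recursion for $t \le 20$.

Population-level consequences: per-locus heterozygosity is exactly
$H = h^{t-1}$ at every generation (the basis of `hFromH()`/`HFromh()`
and of estimating $h$ from data), and the model is deterministic given
$(r, h, t)$.

### Assumptions

Constant $h$ across generations and loci; a single generation number $t$
for the whole population (a population spanning several generations is
treated at a nominal $t$); no mutation or gene conversion; no crossover
interference (Haldane mapping); viability acting on zygotes through the
heterozygote advantage $u$ only.

## From classes to data: the observable genotype table

Genotype data cannot distinguish coupling from repulsion double
heterozygotes, and within a class the member genotypes are equiprobable
by the selfing symmetry that defines the classes. `jointGenotypeTable()`
therefore unfolds the class vector into the observable $3\times3$ table:
$p_1/2$ on each parental corner, $p_2/2$ on each recombinant corner,
$p_3/4$ on each single-heterozygote cell, and $p_4 + p_5$ on the central
double-heterozygote cell. Both marginals place probability $h^{t-1}$ on
the heterozygous genotype — a conservation the tests check at $10^{-10}$.

## Recombination-fraction estimation

`estimateRf()` maximizes the multinomial log-likelihood of the observed
3×3 counts over $r \in [0, 0.5]$ by golden-section search. The bracket
is $[10^{-6}, 0.5 - 10^{-6}]$ with convergence tolerance $10^{-6}$
(roughly 30 iterations); the method names only the search algorithm, so
bracket and tolerance are this package's choices, and the suite checks
the search against both a fine grid and an independent Brent optimizer.
Individuals missing either genotype of a pair are dropped for that pair
only ("pairwise" deletion), which maximizes the informative count per
pair. `adjacentRfScan()` applies this to every physically adjacent
marker pair within a chromosome; grouping and ordering come from
physical positions, not from LOD-based linkage grouping.

Fitting data generated under $h > 0.5$ at $t = 7$ with a Mendelian model
overestimates $r$ (and hence expands the map); the direction reverses at
small $t$ (e.g. $t = 3$), where the Mendelian fit underestimates. Both
directions are asserted in the acceptance tests over an $r$-grid up to
0.3.

## Map construction

`buildMap()` anchors the first marker of each chromosome at 0 cM (an
arbitrary convention; the data carry no anchoring information) and
accumulates Haldane distances $d = -50\ln(1-2r)$ over adjacent pairs.
Estimates at the unlinked boundary or from uninformative pairs are
flagged and propagate `Inf` rather than being silently dropped.
`compareMaps()` reports differences in cM, percent, and "recombinations
per meiosis" using the 50 cM $\leftrightarrow$ 1 recombination
convention — a reporting convention only, not a model quantity.

## Quality control

The QC steps mirror an iterative map-construction workflow; each returns
the filtered object with an audit `QcReport` attached to its metadata.

* **Missingness** (`filterMissingness()`): markers, then individuals, at
  $\ge 60\%$ missing calls are removed (both thresholds configurable;
  the boundary is inclusive).
* **Duplicates** (`dropDuplicateIndividuals()`): concordance over
  mutually non-missing markers $\ge 0.9$ links individuals; one
  representative per connected component is kept — least missingness,
  ties by input order. The component rule is this package's choice for
  chains like A~B~C where A and C do not directly exceed the threshold.
* **Segregation distortion** (`filterMarkersByDistortion()`): a
  $\chi^2$ goodness-of-fit test (df = 2) against the expected ratio
  $\tfrac{1-H}{2} : H : \tfrac{1-H}{2}$, defaulting to $p < 10^{-15}$,
  with per-chromosome overrides (e.g. relaxing to $10^{-30}$ where a
  known selected region distorts an entire chromosome). P-values are
  computed on the log scale so such thresholds stay meaningful far below
  double underflow. Choosing the null $H$ matters enormously: the same
  marker counts that pass under an excess-heterozygosity null fail under
  the Mendelian null, so `iterativeDistortionFilter()` re-estimates $H$
  on the survivors and re-applies the test to the original marker set
  (two passes by default; the adjustment is non-increasing and settles
  quickly on clean data).
* **Tight double recombinations**
  (`maskTightDoubleRecombinants()`): a run of identical calls flanked on
  both sides by a different shared call within a short window (2 kbp
  physical or 2.0 cM genetic are typical) is treated as a genotyping
  error and the interior run is set to missing. Distance is measured
  flank-to-flank between the nearest non-missing calls (missing calls
  are transparent); chromosome ends are never masked; decisions use a
  snapshot of the input, making the operation idempotent; masking only
  ever converts calls to missing. The flank-to-flank reading of the
  window is this package's documented choice.
* **Outlier individuals** (`flagOutlierIndividuals()`): per-individual
  genotype proportions outside $k \cdot \mathrm{IQR}$ (default $k = 3$)
  of the quartiles on any of the three proportions are flagged; removal
  is opt-in. The criterion is deliberately simple and exposed as a
  parameter, since no standard rule exists for this step.

## Simulators

`simulatePopulation()` is the primary generator: markers are equally
spaced on one linkage group, the first marker is drawn from the marginal
$((1-H)/2, H, (1-H)/2)$, and each next marker from the conditional
distribution implied by the model's joint table at the adjacent-pair
$r$. By construction the simulated data obey *exactly* the pairwise
distributions the estimator assumes, which makes the recovery experiment
well-posed: with the true $h$, summed Haldane distances recover the
simulated length up to sampling noise. The cost of this construction is
that dependence beyond adjacent markers is first-order Markov — real
meiosis induces higher-order structure (and crossover interference)
that this generator does not emulate, so passing tests certify the
estimator against the model, not against every property of real data.
Genotyping noise is symmetric misclassification among the three codes
plus independent missingness (`injectNoise()`); real error processes
are typically asymmetric (heterozygote dropout), which is not modeled.

`simulateForward()` is an independent oracle: explicit selfing from an
all-heterozygous F1 with no-interference gametes and rejection sampling
on zygotic viability. The weighting follows the model's two regimes:
offspring of a single-heterozygote parent carry relative viability
$h/(1-h)$ per heterozygous locus (equivalent to retaining heterozygosity
at exactly rate $h$), and offspring of a double-heterozygote parent
carry $u$ per heterozygous locus with $u$ from `solveViability()`. A
single uniform per-locus viability cannot do both jobs — it would give
single-heterozygote retention $u/(1+u) \neq h$ — so the regime-dependent
weighting is what faithfulness to the chain requires. Because the model
defines viability only for one- and two-locus states, viability mode is
restricted to $\le 2$ loci; Mendelian mode (all offspring accepted)
supports any number. The acceptance suite verifies the forward oracle
against the chain at $10^5$ lines over a grid of $(r, h, t)$.

## Numerical choices

* The chain is propagated by $t-1$ matrix–vector products rather than a
  symbolic general solution; for the $t$ of interest (tens of
  generations) this is exact to machine precision and avoids
  transcribing an unpublished closed form.
* The viability quadratic is solved in closed form; the root is checked
  to reproduce the retention identity to $10^{-10}$, and a brute-force
  scan confirms it in the tests.
* $r = 0$ and $r = 0.5$ are handled by the exact formulas (no
  divisions degenerate in this parameterization; the likelihood search
  stays $10^{-6}$ inside the boundaries where zero-probability cells
  would make it $-\infty$).
* Probability comparisons in the tests use absolute tolerances
  ($10^{-12}$ for stochastic-matrix algebra, $10^{-10}$ for derived
  conservation identities).

## Problem sizes

The test suite validates estimator consistency at 200 replicates of
$n = 1000$ multinomial draws per $r$; oracle agreement at $10^5$
forward-simulated lines per parameter combination; and the headline map
experiment at its full size — 1000 individuals × 1000 markers on 200 cM,
three seeds — which completes in well under a minute per fit. The worked
examples use smaller populations (hundreds of individuals, tens of
markers) purely for readability.

## Known limitations

* $h$ is global (per population, optionally per chromosome via
  `estimateH(x, byChromosome = TRUE)`); no per-marker-pair viability is
  fitted, deliberately, to avoid overfitting.
* One generation number $t$ describes the population; mixed-generation
  populations are approximated at a nominal $t$.
* Two-point estimation only: no multipoint/HMM likelihood, no de novo
  marker ordering, Haldane mapping only.
* The chain simulator's higher-order dependence is approximate (see
  above); the forward simulator's viability mode does not extend beyond
  two loci because the model does not define a multilocus fitness.
* LOD scores are not reported alongside $\hat r$.
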