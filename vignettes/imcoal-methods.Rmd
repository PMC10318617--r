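---
title: "Methods: isolation-with-migration simulation and posterior analysis with imcoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isolation-with-migration simulation and posterior analysis with imcoal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imcoal)
```

## The model

`imcoal` works throughout in mutation-scaled coalescent units, the native
units of multilocus coalescent samplers for RAD-type data:

* $\theta = 4 N_e \mu$ per site — the expected pairwise nucleotide
  diversity of a population;
* $\tau$ — divergence time in expected substitutions per site per lineage,
  so $T_\text{years} = (\tau / \mu)\, g$ for mutation rate $\mu$ (per site
  per generation) and generation time $g$ (years);
* $m$ — a directed migration band's per-generation migration probability
  divided by $\mu$.

A `DemographyModel` is a rooted binary population tree with one $\theta$
per branch (tip and ancestral), one $\tau$ per internal node (tips sit at
$\tau = 0$) and a list of directed bands. A population exists on
$[\tau_\text{birth}, \tau_\text{parent})$ and a band is active exactly on
the intersection of its endpoints' existence intervals — the band dies as
soon as either endpoint population merges away. Whether migration should
instead transfer to the merged ancestor is not observable from a band
specification alone; the interval-intersection convention is the one we
adopt and validate against, and it matches the common sampler behaviour of
defining bands between named contemporary populations. A bidirectional
band is stored as two directed bands sharing a `pair` id so that posterior
screening can keep one direction and drop the other.

Absolute units exist only after calibration: $\mu$ and $g$ are uncertain
for most wild populations, so keeping the core model mutation-scaled
defers that uncertainty to a single, explicit Monte-Carlo step
(`monteCarloConvert()`).

## The simulator

`simulateGenealogy()` is an event-driven structured coalescent run
backward in time. Between consecutive divergence breakpoints, a population
holding $k$ lineages coalesces at total rate $k(k-1)/\theta$ per unit
$\tau$, and each lineage in the target of an active band jumps to the
band's source (the forward-time donor) at rate $m$. At a breakpoint all
lineages of the two daughters relabel instantaneously to the parent and
all rates are rebuilt. Exponential racing across event classes makes exact
ties a measure-zero event; if floating-point equality ever occurred the
category draw resolves it in the fixed order coalescence before migration.

`dropMutations()` places infinite-sites mutations: a branch of length $b$
receives $\text{Poisson}(b \ell)$ mutations on a locus of $\ell$ bp, each
creating a new biallelic site at a uniform unique integer position,
carried by all haplotypes below the branch. Under these units the
classical identities hold and are what the test suite checks at 3
standard errors over thousands of loci: $E[\pi] = \theta$,
$E[S]/\ell = a_{n-1}\theta$ with $a_{n-1} = \sum_{i<n} 1/i$, and
$E[d_{xy}] = 2\tau + \theta_\text{anc}$ under isolation. An independent
coalescent engine (msprime, driven through Python) provides a
distribution-level cross-check of pairwise coalescence times for a
two-population scenario with migration.

`simulateDataset()` draws independent non-recombining loci, pairs
haplotypes into diploids uniformly at random within populations (no
inbreeding model), and applies whole-locus dropout per
(individual, locus) — the dominant missingness mode of RAD assemblies,
where an allele at the restriction site removes the entire locus for an
individual. Per-site missingness, sequencing error and genotype
likelihoods are deliberately out of scope: the generator emulates the
shape of a filtered RAD genotype matrix (defaults: 649 bp loci, two
diploid individuals per population), not a sequencer. Consequently,
passing calibration tests demonstrate correctness of the coalescent and
mutation machinery, not robustness to genotyping error in real data.

## Summary statistics

The joint two-population SFS counts every complete-case biallelic site
into one cell of an $(n_1 + 1) \times (n_2 + 1)$ matrix. Because
missingness is whole-locus, "complete-case per site" means a locus
contributes only when every individual of the two populations carries it.
Folding orients each site by the pooled two-population minor allele (ties
at 50% keep the derived orientation), matching MAF spectra estimated
jointly per population pair.

Weighted $F_{ST}$ is ratio-of-sums: per-site numerators and denominators
are summed over all sites polymorphic in the pooled pair before the ratio
is taken, which makes the estimate invariant to duplicating sites and
robust to rare-variant noise (a mean of per-site ratios is neither). Two
estimators are provided and the mode is recorded in every output:

* `hudson` (default): $num = (p_1 - p_2)^2 - \frac{p_1 q_1}{n_1 - 1} -
  \frac{p_2 q_2}{n_2 - 1}$, $den = p_1 q_2 + p_2 q_1$ — fully specified,
  robust to unequal sample sizes.
* `reynolds`: a method-of-moments coancestry estimator in the
  Reynolds–Weir–Cockerham framework. With the sample-size-weighted pooled
  unbiased gene diversity
  $\bar h = \left[\tfrac{n_1^2}{n_1-1} 2 p_1 q_1 +
  \tfrac{n_2^2}{n_2-1} 2 p_2 q_2\right] / (n_1 + n_2)$, the components are
  $a = 2(p_1 - p_2)^2 - \bar h (1/n_1 + 1/n_2)$ (method-of-moments
  unbiased for twice the between-population variance component) and
  $b = 2 \bar h$, with $F = \sum a / \sum (a + b)$. Both estimators return
  exactly 1 on fixed differences, are invariant to folding, and agree on
  balanced designs and in the large-sample limit; they differ at unequal
  sample sizes through the pooled versus per-population heterozygosity
  correction. We derive rather than transcribe the 1983 algebra, and the
  default is `hudson` precisely so that no silent transcription error can
  leak into headline statistics.

Sites monomorphic across the pooled pair are excluded from the sums, the
standard behaviour of SFS-based tools. Slatkin's linearization
$F_{ST}/(1 - F_{ST})$ is provided for isolation-by-distance plots against
log distance.

Individual genetic distances use pairwise-complete sites with either
allele-sharing distance ($\sum_s |d_a - d_b| / 2S$ on 0/1/2 dosages) or
scaled Euclidean dosage distance ($\sqrt{\sum_s (d_a - d_b)^2 / S}$); the
underlying genotype-distance convention of published pipelines varies, so
both are exposed and the metric is recorded in the output. Population
distances are means over cross-population individual pairs, the same
convention used to aggregate geographic distances between sampling sites.

`mantelTest()` correlates lower triangles, permutes rows and columns of
the second matrix jointly, and reports the one-tailed "greater" p-value
with the add-one rule $p = (1 + \#\{r_\pi \ge r_\text{obs}\}) /
(1 + n_\pi)$ — the convention of the ecology packages this mirrors, stated
in the output metadata. 9999 permutations is the pipeline default.
Permuted statistics within $10^{-10}$ of the observed one count as ties so
that label automorphisms are not lost to floating-point noise; an
exhaustive 120-permutation enumeration at $n = 5$ backs this in the tests.

The moment estimators exist for parameter-recovery checks, not inference:
Watterson's $\hat\theta_W$ per population, and
$\hat\tau = [d_{xy} - (\pi_A + \pi_B)/2]/2$, which is unbiased under
isolation with equal $\theta$ and biased otherwise (documented, accepted).

## Posterior post-processing

`readTrace()` consumes tab-separated sampler traces (header row of
parameter names, one numeric row per retained sample), removes
$\lceil 0.10 \cdot \text{rows} \rceil$ burn-in rows per chain by default,
and classifies columns into $\theta$/$\tau$/$m$ roles with configurable
regexes (`theta_<id>`, `tau_<id>`, `m_<src>-><tgt>` by default).

The HPD interval is the narrowest window of $\lceil mass \cdot n \rceil$
consecutive sorted samples, ties resolved to the lowest start; a
brute-force scan over every window is the property-test oracle. The
zero-overlap screen for migration bands retains a band iff the HPD lower
bound is strictly greater than zero at the parsed precision — no epsilon,
since trace files already carry finite precision. ESS uses
initial-positive-sequence truncation of the empirical autocorrelation,
$n / (1 + 2\sum_k \hat\rho_k)$ summed to the first non-positive estimate,
deterministic for fixed input and capped at $n$ (a perfectly alternating
series would otherwise report more than $n$); constant series report $n$
with a warning flag.

`monteCarloConvert()` draws one independent $(g, \mu)$ pair per retained
sample — per-sample rather than per-summary, so calibration uncertainty
propagates into every converted posterior and widens HPDs exactly as it
should (a stochastic-ordering test verifies this) — and converts row-wise:
$N_e = \theta / 4\mu$, $T = (\tau/\mu) g$, and the population migration
rate $2Nm = m\,\theta_\text{target}/2$, derived from
$N_t m_\text{pergen} = (\theta_t / 4\mu)(m \mu) = m \theta_t / 4$ so that
twice that is $\mu$-free. Which side's $\theta$ enters $2Nm$ is a
convention (we use the receiving population, matching the
donor-to-recipient reading of a forward band); the factor and the choice
are documented here rather than buried in code.

The default calibrations are a lognormal generation time (location
$\ln 3.5$, scale $\ln 1.16$, years) and a gamma mutation rate with mean
$1.236 \times 10^{-8}$ and standard deviation $0.107 \times 10^{-8}$ per
site per generation. The gamma spread is interpreted as a standard
deviation: read literally as a variance, $0.107 \times 10^{-8}$ would
exceed the squared mean by nine orders of magnitude and collapse the
distribution onto zero, so the SD reading is the only one consistent with
a usable calibration. Fixed-value mode bypasses the draws
deterministically.

Replicate-run summaries report both conventions: the mean of per-chain
means (the convention for point estimates across replicate runs) and
pooled-sample HPDs; per-chain ESS values are summed.

## The genealogical divergence index

$gdi = 1 - e^{-2\tau/\theta}$ is the probability that two lineages
sampled in a daughter population coalesce more recently than the
divergence at $\tau$ — a property the tests verify directly against the
simulator at $\tau/\theta \in \{0.1, 0.5, 1, 2\}$. Classification follows
the 0.2 / 0.7 rule of thumb (below: intraspecific; above: species-level;
between: ambiguous). Both published threshold rules are strict
inequalities, so the boundary values themselves classify as ambiguous —
a convention, made explicit here. Because the index depends on which
daughter's $\theta$ is used, `gdiPosterior()` computes either choice and
`gdiTable()` reports both per node.

Aggregation across a two-set partition (`gdiAggregate()`) computes, for
every cross-partition population pair, the per-sample index with $\tau$
at the pair's MRCA and each tip $\theta$ in turn, then averages across
pairs and $\theta$ choices per posterior sample before summarizing.
Averaging before summarizing preserves the joint correlation structure —
an HPD of a mean requires the joint samples, not a mean of HPDs. Using
tip $\theta$s with the pair-MRCA $\tau$ is itself a choice (ancestral
$\theta$s would be defensible too); tip $\theta$s are implemented because
the index is asked about contemporary lineages. The index is
conventionally computed from a no-migration model's posterior; traces
containing migration columns are accepted with a warning.

## The packaged study-system fixture

`exampleDemography()` ships a seven-tip model of a lowland mouse-lemur
system from eastern Madagascar: five *Microcebus gerpi* populations
(Vohiposa/Sahafina merged into one lineage — the two sites are not
reciprocally monophyletic, and the merged lineage is treated as a single
tip from time 0 — plus Ambodisakoana and Antanambao south of the Rianila
river; Sahamamy and Andobo north of it) and the sister species
*M. jollyae* and *M. marohita*, with twelve directed migration bands.
Published divergence times (41, 43, 150*, 254, 272, 453 ka; * synthetic),
the two published effective population sizes (3,600 and 14,900) and the
published population migration rates (e.g. 1.15 migrants per generation
from Sahamamy into Andobo) are converted to mutation-scaled units at
$\mu = 1.236 \times 10^{-8}$, $g = 3.5$; every remaining $\theta$, the
Antanambao-side split time and the unreported band rates are synthetic
fill-ins of realistic magnitude (thousands of individuals; $2Nm$ between
0.02 and 0.8), chosen once and marked in the fixture-building comments.
The fixture exists so that every entry point has a runnable offline
example of realistic shape; its synthetic trace
(`syntheticTrace()`: lognormal jitter with mild AR(1) autocorrelation
around the model values) demonstrates the post-processing workflow and
carries no inferential meaning.

## Numerical choices and problem sizes

* All randomness flows through explicit integer seeds; dataset manifests
  record seed and a canonical-document hash of the demography.
* The canonical JSON writer sorts populations, edges, bands and parameter
  keys, so save–load–save is byte-identical.
* Infinite-sites saturation (more mutations than positions on a locus) is
  an error, not a silent truncation; it is unreachable at realistic
  $\theta \ell$.
* Calibration suites run at 2,000 loci of 300–1,000 bp with 4–16
  haplotypes, 5,000 replicate genealogies against the independent engine,
  20,000 replicates for the gdi probability check and 100,000 calibration
  draws — sizes at which 3-standard-error bands separate real defects
  from Monte-Carlo noise while the whole suite stays desk-scale.
* Known limitations: no recombination, selection, or genotype-likelihood
  modelling; the moment $\hat\tau$ is biased under migration or unequal
  $\theta$; ESS is a univariate diagnostic; the simulator is pure R and
  tuned for RAD-scale samples (tens of haplotypes), not for
  population-scale resequencing.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
out <- tempfile()
model <- exampleDemography()

sim <- runSimulate(model, file.path(out, "sim"), n_loci = 200, seed = 1)
ss  <- runSumstats(sim$vcf, sim$popmap, file.path(out, "stats"), seed = 1)

tr  <- syntheticTrace(model, n_samples = 500, n_chains = 4, seed = 1)
paths <- writeTrace(tr, file.path(out, "trace.tsv"))
pp  <- runPostprocess(paths, model, file.path(out, "post"), seed = 1)
head(pp$converted)
```
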