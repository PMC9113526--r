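---
title: "Neutral assembly analysis of host-associated microbiomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral assembly analysis of host-associated microbiomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmfit)
```

## The scientific question

Gut bacterial communities of individual hosts — the motivating case is
caterpillars sampled from wild populations — differ from host to host.
`ncmfit` asks how much of that variation is explained by *neutral*
processes: ecological drift plus immigration from a shared source pool,
with all taxa functionally equivalent. Taxa that deviate from the neutral
expectation are flagged as candidates for host-level selection (present in
more hosts than their abundance warrants) or elimination (present in
fewer).

## The model

Consider a local community of `N` individuals per host. Each death is
replaced with probability `m` by an immigrant drawn from a metacommunity
in which the focal taxon has relative abundance `p`, otherwise by the
offspring of a random local survivor. For large `N`, Sloan's
approximation gives the stationary local relative abundance as
`Beta(N*m*p, N*m*(1-p))`, and hence a detection probability at read
threshold `d` of

```
F(p) = 1 - I(d/N; N*m*p, N*m*(1-p)),
```

implemented in `predicted_occurrence()` via `pbeta()`. Assumptions worth
keeping in mind:

* one well-mixed source pool per population; `p` is estimated by the mean
  relative abundance across hosts, so source and samples are conflated;
* equal per-capita demography across taxa (the null being tested);
* `N` is identified with the post-rarefaction reads per host. Sequencing
  is then an extra multinomial sampling layer the model does not see;
  its main visible effect is a slight smoothing of the occupancy curve
  near the detection limit;
* communities are observed at stationarity.

## Fitting and its tunables

`fit_neutral()` estimates a single `m` per population by bounded
one-dimensional least squares of observed detection frequencies against
`F(p)`:

* `m` is searched on `(1e-6, 1]` with `optimize()` (tolerance `1e-10`),
  plus an `nlminb()` refinement started from `m_start` (default 0.1); the
  iterate with the lower sum of squares wins. A property test checks the
  optimum against 50 random restarts.
* Fit quality is the generalised R², `1 - SSR/SST`; it may be negative
  and is never clamped. If all observed frequencies are equal
  (`SST = 0`), R² is undefined and flagged with a warning.
* `d` (detection limit, default 1 read) and the band level `alpha`
  (default 0.05) are configurable.
* Preconditions: at least 5 hosts and 10 detected OTUs; depths should be
  equal (rarefy first — the fitter warns if they differ by more than 5%).
  OTUs never detected in the population are excluded from that
  population's fit and tracked as *absent* by
  `cross_population_summary()`.

## The 95% band and the partition rule

The band drawn around the fitted curve is the binomial Wilson score
interval evaluated algebraically at `x = F(p) * n_hosts` successes in
`n_hosts` trials — non-integer `x` is deliberate, matching common
practice for this analysis. Classification compares each OTU's observed
frequency with the band using a **half-count continuity correction**: an
OTU leaves the `within` class only when its observed host count clears
the bound by more than half a host. The correction exists because the
observation lives on the grid `0/n, 1/n, ..., n/n` while the Wilson bound
shrinks strictly inside `[0, 1]`: without it, an OTU predicted at
occupancy 0.999 and observed in *all* hosts — exactly what the model
expects — would sit a few 1e-5 above the bound and be labelled `above`,
and symmetrically every rare undetected OTU would be labelled `below`.
With the correction, simulations under pure neutrality put 93–99% of OTUs
within the band (nominal 95%); without it, coverage collapses to ~80%,
entirely at the two boundaries. Exact ties classify as `within` —
conservative toward neutrality.

## The simulator: what it emulates

`simulate_study()` generates data shaped like a multi-population per-host
16S survey. Its defaults are the package's stated world and are not
tuning knobs:

| parameter | default | why |
|---|---|---|
| `n_taxa` | 300 | hundreds of OTUs survive typical read filters |
| `sad` | lognormal, `sdlog = 2` | heavy-tailed rank-abundance curves typical of 16S surveys; log-series and user fractions also available |
| `n_hosts` | 15 | mid-range of the 8–20 hosts per population in field studies |
| `local_size` | 5000 | community size matched to read depth, so `N*m` in the fit corresponds to the simulated immigration |
| `m` | 0.1 | produces the mix of saturated, marginal and rare occupancies real fits show |
| `generations` | 30 | burn-in; pair-coalescence arguments give a relaxation factor `exp(-2G(m + 1/N))`, i.e. >95% relaxed at `m = 0.05` and fully relaxed at `m >= 0.1`; a test compares summary statistics at 30 vs 60 generations |
| `depth` | 5000 | multinomial reads per host |

Local dynamics are a discrete Moran process (kill one uniformly chosen
individual, replace by immigrant with probability `m`, else by a copy of
a surviving individual), run in compiled code. All per-population,
per-host and per-read seeds derive from one master seed through a single
`sample.int()` stream, so studies are reproducible bit-for-bit; the
`simulation_truth` object records every seed, the metacommunity, and the
pre-sequencing local compositions.

What the generator does *not* emulate: taxon-correlated sequencing biases
(PCR/primer effects), chimeras and contamination, phylogenetic structure,
within-host spatial niches, and time dynamics. A green test therefore
establishes that the estimator recovers the model's own world, not that
real gut data satisfy the model.

## Engineering non-neutral taxa

The package had to make a genuine design choice here. The obvious
mechanism — multiplying a taxon's immigration weight in the source pool,
identically in all hosts — turns out to be *incapable* of producing
above-partition taxa: the marginal dynamics of each taxon remain those of
a neutral community with a modified metacommunity (the stationary
marginal is a beta with the community-wide concentration and a shifted
mean), so abundance and occupancy move together and the taxon stays
within the band. The same argument applies to per-immigration-event
rejection on the exclusion side. Detectable deviations require breaking
the occupancy–abundance relation, which means acting on the *between-host
variance*:

* **Selected taxa** are modelled as occupants of a host-maintained niche
  of fixed carrying capacity (their expected metacommunity share, at
  least one individual): individuals are exempt from death while the
  taxon is at or below its quota, replacements that would overfill the
  niche are redrawn, and immigration below quota is boosted by the
  configured weight. Every host then carries the taxon at a small stable
  abundance: high occupancy, low mean — the `above` signature.
* **Excluded taxa** are rejected wholesale by individual hosts: each host
  independently bans the taxon with the configured probability (no
  immigration, absent from initialisation). Their mean abundance across
  hosts stays respectable (they are unaffected in permissive hosts) while
  occupancy collapses — the `below` signature.

In validation, sensitivity is computed over engineered taxa *observed in
the data*: a taxon banned by every host never enters the table and is
unclassifiable (it is, of course, also maximally excluded). At the
default settings (10 selected taxa near the detection-marginal abundance
of ~1e-3, weight 10; 10 abundant taxa with per-host rejection 0.9;
`m = 0.1`) both sensitivities are at or near 100% and unperturbed taxa
leave the within class at only the nominal band rate.

## Preprocessing decisions

* Filter order: minimum total reads (default 100) → lineage exclusion
  (default `Chloroplast`, case-insensitive token match on parsed ranks) →
  rarefaction → and, for the neutral fit only, the relative-abundance
  filter.
* The relative-abundance rule for the neutral fit is interpreted as
  *retain an OTU iff its per-sample relative abundance reaches the
  threshold (default 0.5%) in at least one sample*. The literal
  alternative ("remove if below the threshold in any sample") would
  remove nearly every OTU in heavy-tailed data and cannot be what a
  working analysis does; a mean-across-samples variant is available via
  `stat = "mean"`.
* Rarefaction is a single draw without replacement per sample (counts
  stay integral); averaging over repeated draws is deliberately not
  offered. The depth defaults to the smallest sample total; the seed is
  mandatory and recorded.

## Diversity and community structure

* Shannon uses natural logarithms by default (base configurable);
  Simpson is reported as Gini–Simpson `1 - sum(p^2)` (plain and inverse
  variants by flag). Both computed on rarefied counts.
* Rank-sum comparisons use the exact null distribution when both groups
  have ≤ 12 values and no ties, otherwise the normal approximation with
  tie and continuity corrections.
* Sample distances are Bray–Curtis on counts and binary Jaccard on
  presence/absence. Weighted UniFrac is *not* supported: it requires a
  phylogeny the pipeline does not build, and Bray–Curtis is the
  documented substitute.
* PCoA is Gower double-centering plus symmetric eigendecomposition;
  negative eigenvalues are reported unmodified, proportions explained are
  over positive eigenvalues only, and each axis's largest-magnitude
  loading is made positive so outputs are reproducible. (Where a source
  figure labels this analysis "principal component analysis" on a Jaccard
  matrix, principal *coordinates* is the meaningful reading and is what
  is implemented.)
* PERMANOVA is the one-way distance-based pseudo-F; ANOSIM is the
  mid-rank r statistic. Permutation p-values use `(b + 1)/(B + 1)` so
  they are never zero, seeds are recorded, and both tests offer exact
  exhaustive enumeration of distinct label assignments for small designs.
  The composition contrast between above- and below-partition OTUs is
  examined by `partition_ordination()` (Jaccard distances among OTUs'
  presence/absence profiles, then PCoA) rather than a full
  distance-based redundancy analysis, which is out of scope.
* A "logistic regression on presence/absence and partition type"
  mentioned in the motivating analysis is under-specified (neither
  response nor covariates are stated); partitions here are defined by the
  confidence-band comparison only.

## Degenerate inputs and numerical corner cases

* Zero-total samples are rejected wherever relative abundances are
  needed; all-equal distance matrices make the pseudo-F uninformative and
  are flagged with a warning; fits with all-equal observed frequencies
  have undefined R².
* `p` must be strictly inside (0, 1) for the beta shapes to exist; OTUs
  at `p = 1` of a population (all reads) would be excluded from that fit.
* The beta approximation itself deviates from discrete multinomial truth
  when `N*p` is of order 1 (e.g. detection 0.74 vs 0.87 at `N*p = 2`);
  tests of the simulator at `m = 1` therefore use the exact multinomial
  oracle `1 - (1-p)^N` rather than the beta formula.

## Limitations

Single source pool per population; no phylogenetic information (no
UniFrac, no phylogenetic null models); one global `m` per population
rather than per-taxon immigration; partition labels inherit the multiple
testing inherent in drawing one band and classifying hundreds of OTUs
against it; and the simulator's selection mechanisms are two idealised
endpoints of host control, not a model of real host immunity.
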