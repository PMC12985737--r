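---
title: "Measuring and mapping meiotic crossovers from fluorescent seed typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and mapping meiotic crossovers from fluorescent seed typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xomapr)
```

## The measurement problem

Fluorescence-tagged interval lines (FTLs) — and their short-interval
variants (ESILs) — carry seed-expressed eGFP and dsRed reporter
transgenes flanking a genomic interval on one homolog. After a cross to
an unmarked accession and self-pollination of the F1, each F2 seed
inherits two independent gametes, and its fluorescence class is the
union of the reporters those gametes carry. A parental gamete carries
both reporters (RG) or neither; a recombinant gamete carries exactly
one. Single-color seeds therefore mark recombination events in the
interval, and deep sequencing of preselected single-color seeds ("seed
typing") localizes each crossover between flanking SNP markers that
distinguish the two parental genomes (here labelled Col and Ler).

`xomapr` implements the analysis chain downstream of seed imaging and
read alignment: map-distance estimation, breakpoint calling, landscape
and hotspot statistics, and a fully seeded simulator that makes every
stage testable by parameter recovery.

## The segregation model and the centimorgan estimator

Let $r$ be the recombinant-gamete fraction for the interval. F1 gamete
frequencies are

$$\Pr(RG) = \Pr(--) = \tfrac{1-r}{2}, \qquad
  \Pr(R-) = \Pr(-G) = \tfrac{r}{2}.$$

A seed is green-only when at least one gamete carries G and neither
carries R, which happens with probability

$$p_{\text{green}} = p_{\text{red}} = \frac{1-(1-r)^2}{4}.$$

`expected_seed_class_probs()` returns these probabilities;
`estimate_rf()` inverts the model: with $NG$ green-only, $NR$ red-only
and $NT$ total seeds,

$$\widehat{\mathrm{RF}} \;=\; 100\times\left(1-\sqrt{1-\frac{2(NG+NR)}{NT}}\right)
\ \text{cM}.$$

This inverse is exact — applied to the expected class counts at
fraction $r$ it returns $100r$ to machine precision (the suite checks
this against a brute-force enumeration of all 16 ordered gamete pairs)
— and for the small $r$ typical of kilobase-scale intervals it reduces
to the intuitive $100\,(NG+NR)/NT$. Counts with $2(NG+NR) > NT$ are
impossible under the model and raise a domain error. The "other" seed
class (both-color plus nonfluorescent) is never split: only $NG$, $NR$
and $NT$ enter the estimator.

Uncertainty comes from a percentile bootstrap
(`rf_bootstrap_ci()`, default 2000 multinomial resamples at fixed
$NT$, 95% level, caller-supplied seed). Between-genotype comparisons
(`compare_rf()`) wrap Welch's $t$, Student's $t$ and the Mann-Whitney
$U$ test; the rank test always uses the normal approximation with
continuity correction so tied per-cross values are handled silently
and identical groups give $p = 1$.

Two aggregates are reported by `summarize_rf()`: the unweighted mean of
per-cross estimates (matching plots in which each point is a cross and
the center line the mean) and the pooled estimate from summed counts.
With roughly equal seed numbers per cross they agree closely; the
pooled value is what the pipeline uses to scale landscapes when no
explicit interval size is configured.

## Breakpoint calling from allele depths

A selected single-color seed carries one recombinant chromatid over a
non-recombinant Ler homolog, so along the interval its genotype is
homozygous Ler on one side of the crossover and heterozygous on the
other. `call_site_genotypes()` classifies each marker from the Col-read
fraction $f$ at total depth $d$:

| condition | call |
|---|---|
| $d <$ `min_depth` (20) | `MISSING` |
| $f \le$ `hom_max` (0.15) | `HOM_LER` |
| $f \in$ `het_band` (0.30–0.70) | `HET` |
| $f \ge 1-$ `hom_max` | `HOM_COL` |
| otherwise | `MISSING` (ambiguous) |

At the ~1500× depth of amplicon seed typing these bands are extremely
loose — the analytic binomial tails put the per-site miscall
probability below $10^{-6}$ at 0.2% read error — but they keep the
caller usable at the low simulated depths where `MISSING` handling
matters. The thresholds are declared defaults, not values inferred from
any particular dataset.

`call_crossover()` segments the informative calls into maximal runs
(haplotype blocks) and accepts a recombinant when exactly one
HOM_LER/HET block boundary has at least `min_flank` (2) markers on each
side. Isolated miscalls form length-1 blocks and cannot create or
destroy an accepted boundary. Anything else is rejected with a reason:
`NO_TRANSITION`, `MULTIPLE_TRANSITIONS` (two eligible boundaries are
never arbitrated), or `UNEXPECTED_GENOTYPE` for any `HOM_COL` call,
which the single-chromatid model does not admit. The breakpoint
interval is the gap between the flanking informative markers, reported
0-based half-open in BED output, with
`midpoint = floor((left + right)/2)`; markers are points, so the
crossover is only ever localized *between* them. Orientation encodes
the reporter geometry: a green-only seed's chromatid is Ler-type on
the left (`LER_TO_HET`), a red-only seed's the mirror image.

`map_population()` applies this per recombinant and tallies statuses;
only `OK` calls feed landscapes. Recombinants with fewer than two
informative markers cannot show a transition and are tallied
`NO_TRANSITION` rather than aborting a population run.

## Landscapes, hotspot usage, and reduction

`build_distribution()` bins `OK` midpoints — by default into the
inter-marker intervals, the native mapping resolution — and normalizes
by the number of crossovers, so tracks sum to exactly 1 and two
populations of different size are directly comparable.
`differential_track()` subtracts two such tracks (sample − control);
the result sums to 0, so local suppression and compensatory gains are
read directly off the sign pattern. Crossovers enter at their midpoint
by default; an optional `smear` mode spreads each call uniformly over
its breakpoint interval instead.

`moving_average_cm_per_mb()` converts density to genetic-map units: the
interval's total cM is apportioned to sliding windows (defaults 1-kb
window, 100-bp step) by the fraction of midpoints they contain, divided
by window length in Mb. Windows advance on a grid anchored at the
interval start and are truncated at *both* edges — including the
leading partial windows — so that when the step divides the window
every position is covered by exactly `window/step` windows. That choice
is what makes the track exactly conservative: the coverage-corrected
integral implemented by `track_integral_cm()`,
$\frac{step}{window}\sum_w v_w \ell_w$, returns the supplied interval
cM to floating-point precision for any input. A window spanning the
whole interval degenerates to the flat value
$\mathrm{cM} / \mathrm{length}_{Mb}$.

`hotspot_usage()` reports each annotated hotspot's share of mapped
crossovers plus the background remainder (shares sum to 1);
annotations are user-supplied BED spans — no coordinates are
hard-coded. `hotspot_reduction()` compares one hotspot between
populations on the percent scale, $100\,(1 - s_{sample}/s_{control})$.
This is a *share-based* definition: each population is normalized to
its own total, so the statistic measures redistribution of crossovers
away from the hotspot, not the change in absolute recombination rate,
and is negative when the hotspot is enhanced. A summed-frequency
definition over the same span would coincide for populations of equal
total map distance and is not separately provided.

## What the simulator emulates — and what it does not

The generators mirror the study design stage by stage:

* `simulate_seed_counts()` draws (green-only, red-only, other)
  multinomially from the segregation model at a true $r$ — the forward
  model of the estimator, so estimator recovery is a true round trip.
* `make_snp_map()` stands in for a curated high-fidelity marker list
  (uniform or random spacing, distinct parental alleles).
* `simulate_recombinants()` places one breakpoint per recombinant from
  a hotspot mixture: a component chosen by weight, then a uniform
  position within its span. The reference conditions
  (`chp_like_mixture()`) are a 40-kb interval with three interior
  hotspots — a dominant central one (weight 0.50, 8 kb) flanked by two
  weaker ones (0.22 and 0.18, 4 kb each) — over a 10% background,
  emulating a pericentromeric interval whose crossovers concentrate in
  three narrow regions. The background is uniform over the
  *complement* of the hotspot spans, so each component's weight equals
  its expected share of crossovers exactly; `suppress_hotspot()`
  exploits this to build sample/control pairs with an exactly known
  reduction (the removed mass is redistributed proportionally,
  mimicking redistribution rather than loss). An option adds
  double-crossover chromatids to exercise `MULTIPLE_TRANSITIONS`.
* `simulate_allele_depths()` observes each chromatid through
  Poisson-distributed total depth (default mean 1500) and binomial
  allele counts with symmetric per-read error (default 0.2%), the
  scale of deep amplicon sequencing.

Every generator is a pure function of (parameters, seed) via an
isolated RNG scope, so fixed seeds reproduce outputs exactly without
touching the caller's RNG stream.

Deliberate simplifications: sequencing error is a symmetric allele
flip — no indels, mapping bias, allele-specific amplification or
chimeric LR-PCR artifacts; depths are independent across markers,
whereas amplicon data have strong positional covariance; breakpoints
are points with no gene-conversion tracts; at most two crossovers per
chromatid and no interference model; and marker positions are ideal,
with no misplaced or mis-ascertained sites beyond what
`filter_snp_candidates()` models. Passing recovery tests therefore
demonstrates the correctness of the estimators and callers under the
stated observation model, not robustness to every artifact of real
amplicon data.

## Numerical choices and degenerate inputs

* `estimate_rf` is exact at the boundaries: 0 cM at zero recombinants,
  100 cM at $NG+NR = NT/2$; beyond that it refuses. Bootstrap
  resamples that cross the boundary are truncated at 100 cM.
* With zero recombinant seeds the bootstrap interval collapses to
  `[0, upper]` and never fails.
* Tracks use 0-based half-open coordinates; a 1-based marker position
  $p$ is treated as the continuous point $p - 0.5$, making span and bin
  membership unambiguous at integer edges.
* Zero `OK` calls make normalization undefined and raise an error
  rather than returning NaNs.
* Two eligible boundaries after flank filtering reject the recombinant
  (`MULTIPLE_TRANSITIONS`); no tie-break is attempted.
* Exact conservation of the cM/Mb track requires `step` to divide
  `window` (the defaults do); other combinations are permitted but only
  approximately conservative.

## Problem sizes used in the checks

The shipped suite and the acceptance script use simulation sizes
chosen to mirror the study design while keeping runs desk-scale: 1000
simulated crosses of $10^5$ seeds for estimator recovery and CI
coverage at the wild-type 0.33 cM scale; 500 recombinants over a 40-kb,
100-marker interval at 1500× mean depth and 0.2% error for
breakpoint recovery; population sizes 243 (control) vs 164 (sample)
with 200 replicates for recovery of built-in central-hotspot
suppressions of 47.2% and 80.3%. The share-ratio estimator of the
reduction carries a small positive finite-sample bias
($\approx \hat R \cdot CV^2$ of the control share, under 0.3 points at
these sizes), well inside the Monte Carlo error at 200 replicates.

## Pipeline and reproducibility

`run_pipeline()` consumes a YAML configuration with one mandatory
master seed; each stochastic stage derives its own seed from the
master seed and the stage name, so a configuration fully determines
every output byte. The manifest records the package version, every
resolved parameter (defaults included), the per-stage seeds, and MD5
checksums of all products; re-running the same configuration
reproduces identical checksums. Validation — missing seed, unknown
keys, absent input files — fails before any stage runs, and stage
errors abort with the stage name. Configuration checking is explicit
key/type/file validation implemented in the package.

## Known limitations

Beyond the simulator simplifications above: the caller assumes the
single-chromatid recombinant model, so legitimate double recombinants
are rejected, not resolved; hotspot spans must be supplied by the
user; and the share-based reduction statistic is undefined when the
control share is zero.
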