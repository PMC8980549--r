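---
title: "Dating a founder mutation from carrier haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating a founder mutation from carrier haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderage)
```

## The problem

When the same pathogenic variant is found in several unrelated
consanguineous families, the usual explanation is a single founder: all
carrier chromosomes descend from one ancestral chromosome, and the marker
haplotype that surrounded the mutation in that ancestor is progressively
eroded by recombination (and, much more slowly, by marker mutation). The
length and frequency of the surviving ancestral haplotype therefore carry
information about the number of generations since the founder.

`founderage` implements that chain of inference for autozygous carriers —
affected individuals homozygous across the region, as is typical in
consanguineous pedigrees — so haplotypes can be read directly off the
genotypes without statistical phasing. The packaged data set is the carrier
panel of the CLCC1 c.75C>A (chr1:108,950,376 G>T, GRCh38) retinitis
pigmentosa founder mutation: 98 SNPs plus the mutation site spanning about
3.5 Mb, for 18 carrier chromosomes from nine families, together with the
per-block control frequencies used by the age estimators.

## Founder-haplotype reconstruction

Within the *shared core* — the maximal contiguous marker run containing the
mutation at which all carrier chromosomes agree (`find_shared_core()`;
missing genotypes are compatible with anything) — the founder haplotype is
simply the shared allele. Outward of the core, `infer_founder()` extends
the founder one marker at a time on each side: among the chromosomes still
consistent with the founder on that side, the founder allele is the
plurality allele; chromosomes carrying a different non-missing allele are
retired from all farther markers on that side (their recombination
breakpoint has been passed). `support` records, per marker, how many
still-active chromosomes match, and is non-increasing outward by
construction.

Plurality ties do occur — in the packaged panel, twice on the distal right
arm, where exactly six active chromosomes carry each of two alleles. The
package breaks ties toward the alphabetically smallest allele and flags the
marker. On the packaged panel this choice keeps the one carrier family
whose haplotype is intact everywhere else on both arms identical to the
founder, which is the behaviour one wants when the ancestral haplotype is
anchored to an observed, unrecombined carrier chromosome (the most common
complete haplotype among carriers). We experimented with a look-ahead rule
(choose the branch with the greater total downstream agreement) and
rejected it: on this panel it breaks the intact carrier lineage and
produces a founder that no sampled chromosome carries in full, while the
total recombination-event count it saves is marginal. The tie flag in the
output makes the decision auditable.

## Haplotype blocks and the published layout

Scanning outward, every marker at which one or more chromosomes first
leave the founder is a *divergence marker*; between divergence markers no
recombination is observed in the cases, so those runs are collapsed into
haplotype blocks (`partition_blocks()`), each labelled by its member
nearest the mutation and assigned

* `theta`: the recombination fraction to the mutation, taken as physical
  distance to the label marker times 1 cM/Mb, divided by 100 (the map-rate
  default; `cm_per_mb` is a parameter), and
* `n_shared`: the number of chromosomes carrying the founder haplotype
  intact from the mutation through the label marker (missing-compatible).

Two layouts are available. `layout = "scan"` is the plain rule — every
divergence marker opens a block; all markers are assigned. The default
`layout = "published"` reproduces the layout convention of the source
analysis at the distal arm ends, where single families carry the last
surviving copies of the founder: a divergence that leaves no more than two
conserved families (with further divergence beyond it on the same arm)
closes the current block instead of opening one; the divergence that breaks
the final conserved pair opens a terminal block of exactly two markers,
analysed downstream as a paired-marker system; markers not covered are
reported as unassigned tail markers rather than forced into blocks. On the
packaged panel this yields the familiar ten-block structure with four
unassigned distal markers; on data without such distal singleton events the
two layouts coincide.

Per-family derivations (`derive_family_events()`) collapse the two
chromosomes of each family (the carriers are autozygous; discordances are
reported as data errors, not silently dropped), call left/right breakpoints
as the outermost intervals where the family leaves the founder, and count
events (0, 1 or 2). Families diverging at the same marker with identical
alleles across the block containing that divergence are assigned a common
post-founder ancestor group. Identity is deliberately required only over
that block: IBD between two such families is certain near their shared
breakpoint but may itself be eroded by later recombination farther out, and
requiring full-arm identity would miss exactly the pairs the pedigree
structure supports.

## The age estimators

**Decay closed form** (`risch_age()`). With carrier-side frequency
$P_D$, control-side frequency $P_N$ and recombination fraction $\theta$,
the excess association $\delta = (P_D - P_N)/(1 - P_N)$ equals 1 at
generation 0 and is multiplied by $(1-\theta)$ each generation, giving
$g = \ln\delta / \ln(1-\theta)$. We state the decay base explicitly because
a plausible-looking alternative, $\ln(1-\delta)$ in the denominator, does
not describe the recombination process and does not reproduce any entry of
the packaged per-block grid; $\ln(1-\theta)$ reproduces all of them.
Blocks with $\delta \le 0$ (carrier frequency at or below the control
frequency — the distal two-marker block of the packaged panel is an
example) are flagged not estimable rather than dated.

**Iterative transition-matrix decay** (`goldstein_age()`). The state
vector of a carrier chromosome — (still ancestral, no longer ancestral) —
starts at $(1,0)$ and is multiplied each generation by
$K = cR + \mu M + (1-c-\mu)I$: with probability $c=\theta$ recombination
resets the marker to its population frequencies, with probability $\mu$ the
marker mutates, and otherwise nothing changes. The SNP mutation matrix is
$M_{11}=0$, $M_{12}=1/3$, $M_{21}=1$, $M_{22}=2/3$: any mutation of an
ancestral-state marker destroys the ancestral allele, while a mutation of a
non-ancestral marker hits the ancestral base in one of three possible
changes. The age is the generation at which the ancestral-state frequency
falls to the observed $P_D$. Because a two-state chain approaches its
stationary point geometrically, the fractional generation is obtained by
geometric (not linear) interpolation between the bracketing generations,
using the chain's stationary frequency and subdominant eigenvalue; this
makes the $\mu = 0$ case agree with the closed form to floating-point
accuracy rather than to the ~$10^{-3}$ generations linear interpolation
leaves behind. The default $\mu = 10^{-8}$ per site per generation is a
typical SNP rate; at that scale the $\mu M$ term shifts ages by far less
than a generation, which is why the two estimators agree so closely.

**Gamma segment-length method** (`gamma_age()`). One-sided conserved
segment lengths (Morgans) around the mutation are Exponential($g$) under
the same no-interference model the simulator uses. With $S$ the sum of the
$2n$ one-sided lengths and $d$ the number of uncensored segments, the point
estimate is $(d-1)/S$ — the unbiased correction of the MLE $d/S$, which
matters at these small $n$ — and the equal-tail CI is
$[q_{\Gamma}(\alpha/2; d)/S,\; q_{\Gamma}(1-\alpha/2; d)/S]$. Censored
segments (no recombination observed before the map or genotypes run out)
contribute their observed length to $S$ but not to the shape, the standard
censored-exponential likelihood; `correction = "mle"` switches off the
bias correction. Segment endpoints are placed at the midpoint of the
interval between the last founder-matching and first discordant marker
(`segment_lengths()`), the least-biased point choice given that the true
breakpoint is only known to lie in the interval; `last-match` and
`first-mismatch` conventions are available and bracket the midpoint. For
the correlated genealogy, chromosomes of one family and families of one
post-founder ancestor group are collapsed to a single effective lineage on
their shared side, since IBD segments carry one recombination history, not
several.

Confidence intervals for the frequency-based estimators come from a
parametric bootstrap (`bootstrap_ci()`): the sharing count is resampled as
Binomial($2n$, $P_D$) and the percentile interval of the re-estimated ages
is reported. The packaged per-block inputs also carry interval annotations
from the source analysis whose construction is not documented; the
bootstrap intervals here are not expected to match them and are not
compared against them.

## What the simulator emulates — and what it does not

`simulate_carriers()` implements exactly the model the estimators assume:
a founder haplotype transmitted $g$ generations; recombination as a Poisson
process on the genetic map (Haldane, no crossover interference), so the
nearest breakpoint per side is Exponential($g$); material beyond the
breakpoint replaced by a draw from a stationary background haplotype pool;
per-site marker mutation at rate $\mu$ with the same 1/3–2/3 base
semantics as $M$. Only the breakpoint nearest the mutation is tracked per
side — the estimators never see replaced material, so its later history is
equivalent to a fresh pool draw at sampling time. `simulate_controls()`
draws Hardy–Weinberg diplotypes from the same pool and discards phase.

This is deliberately the estimators' own world: no population growth or
demography, no interference, no linkage disequilibrium within the
background pool beyond its finite haplotype list, and carrier chromosomes
sampled independently rather than through pedigrees. Passing the recovery
tests therefore shows the estimators are correct under their stated model;
it does not certify them against demographic model misspecification, which
on real data is the dominant uncertainty (the map-rate approximation of
1 cM/Mb is the other).

Validation problem sizes, chosen to exercise the study-scale geometry: 18
carrier chromosomes, 96-sample control panels, $g = 100$ (the order of the
packaged estimates), 200 seeded replicates for coverage checks, and
$10^4$ chromosomes for distributional checks of the simulator itself.

## Numerical conventions and degenerate inputs

* Reported generation values are rounded half-up to integers alongside the
  float; all internal arithmetic is double precision.
* EM (`em_frequencies()`) initialises uniformly over the
  observed-compatible haplotype set for determinism; the log-likelihood is
  asserted non-decreasing every iteration, convergence is the maximum
  absolute frequency change falling below `tol` (default `1e-8`, cap
  `1e4` iterations), and seeded Dirichlet restarts are available to probe
  multimodality. Missing genotypes are marginalised by enumerating alleles
  observed at the marker. CHM (`chm_frequencies()`) is equal-weight
  fractional phase counting — a reimplementation of the composite
  haplotype idea, not bit-compatible with proprietary tools.
* `P_D = 1` dates to 0 generations; $\delta \le 0$, $\theta = 0$ (the
  focal block), targets below the transition chain's stationary frequency,
  and all-censored segment data are flagged or raise errors naming the
  condition, never silently dated.
* All stochastic code (simulator, bootstrap, EM restarts) is driven by
  explicit integer seeds and replays identically.

## Known limitations

* The published-layout block convention at distal arm ends is a
  reconstruction of how such tables are assembled by hand; `"scan"` is the
  assumption-free alternative and the two disagree only beyond the last
  three conserved families.
* The Gamma estimates depend on endpoint and censoring conventions; other
  implementations may place segment endpoints differently, so agreement at
  the confidence-interval level, not point identity, is the right
  expectation.
* Blocks whose ancestral haplotype is at high population frequency can be
  non-datable by decay ($\delta \le 0$); a paired-marker likelihood for
  such blocks is not implemented.
* Bayesian intra-allelic coalescent dating (which requires explicit
  population-growth assumptions) is out of scope.
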