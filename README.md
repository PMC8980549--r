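# founderage

Haplotype analysis and allele-age estimation for founder mutations, built
around the CLCC1 c.75C>A (chr1:108,950,376 G>T, GRCh38) retinitis pigmentosa
founder mutation of the Pakistani population, whose carrier-haplotype panel
and per-block summary inputs are packaged as machine-readable data.

The package is written for medical and population geneticists who have SNP
haplotypes of mutation carriers from consanguineous families and want to
know how old the mutation is: it reconstructs the ancestral (founder)
haplotype, delimits recombination-free haplotype blocks, and dates the
mutation in generations by three estimator families.

## Methods at a glance

Let `P_D` be the frequency of the ancestral haplotype on mutation-bearing
chromosomes, `P_N` its frequency on control chromosomes, and `θ` the
recombination fraction between a haplotype block and the mutation
(approximated from physical distance at 1 cM/Mb).

* **Linkage-disequilibrium decay** (closed form). The excess association
  `δ = (P_D − P_N) / (1 − P_N)` decays by a factor `(1 − θ)` per
  generation, so the age is `g = ln δ / ln(1 − θ)`.
* **Iterative transition-matrix decay.** The carrier-chromosome state
  vector `(ancestral, non-ancestral)`, starting at `(1, 0)`, is multiplied
  each generation by the column-stochastic matrix
  `K = cR + μM + (1 − c − μ)I`, with `c = θ`, `R` resetting to the control
  frequencies (`R11 = R12 = a`, `R21 = R22 = 1 − a`), and SNP mutation
  matrix `M11 = 0, M12 = 1/3, M21 = 1, M22 = 2/3`; the age is the
  generation at which the ancestral frequency reaches `P_D`. With `μ = 0`
  this is analytically identical to the closed form.
* **Gamma (segment-length) method.** One-sided conserved ancestral segment
  lengths around the mutation are Exponential(`g`) in Morgans; with `S` the
  sum of the `2n` one-sided lengths the bias-corrected estimate is
  `ĝ = (2n − 1)/S`, with Gamma-quantile confidence limits, and a
  correlated-genealogy variant that collapses lineages descending from a
  shared post-founder ancestor.

Control-side haplotype frequencies (`P_N`) can be estimated from unphased
genotypes by expectation-maximization (`em_frequencies()`) or by
equal-weight composite counting (`chm_frequencies()`). A forward simulator
(`simulate_carriers()`, `simulate_controls()`) generates carrier and
control panels from a known founder age with a ground-truth record, so
every estimator is validated by parameter recovery.

## Worked example

```r
library(founderage)
report <- run_pipeline(quiet = TRUE)   # packaged CLCC1 panel and inputs
print(report)
```

```
Shared core: 9 markers, rs10857972 .. rs570812
Blocks (10), tail markers: 4
            label n_markers  side      theta n_shared
1      rs12403629        10  left 0.01241675        4
2        rs345292        13  left 0.01067943        6
...
6  CLCC1-MUTATION         9 focal 0.00000000       18
...
10     rs11102121         2 right 0.01522041        2
...
Summary: 79-196 generations, about 1975-4900 years
```

The fully shared autozygous core around the mutation spans 9 markers
(rs10857972..rs570812). Exactly one family (61224) still carries the intact
founder haplotype, one (61244) shows a single recombination, and every
carrier haplotype derives from the founder by at most two recombination
events; three family pairs diverge at the same SNP and are flagged as
sharing a post-founder ancestor. Across all datable blocks and both
frequency sources the mutation age ranges from 79 to 196 generations —
roughly 2,000–4,900 years at 25 years per generation. The Gamma method
gives 95 generations (95% CI 66–136) under an independent genealogy and 74
(41–137) under the correlated genealogy the pedigree structure suggests.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/founderage.R reproduce --out report
```

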