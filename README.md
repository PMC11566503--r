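# biomon

Biomonitoring indices for community data with heterogeneous taxonomic
resolution.

Freshwater biomonitoring rests on community samples — macroinvertebrates,
macrophytes, diatoms, fish — in which different rows are identified to
different taxonomic levels (species here, genus or family there), and on
three families of metrics computed from them: **diversity indices**
(Shannon, Simpson, Pielou, Margalef, Brillouin, McIntosh, Fisher's α, …),
**sensitivity-score biotic indices** (BMWP, ASPT, WHPT, LIFE, PSI/EPSI,
EPT, log₁₀(SEL_EPTD+1), 1-GOLD, DEHLI, IBMR, biocontamination ACI/RCI/SBCI)
and **functional trait-based indices** (FRic, FDis, FEve, Rao's Q,
redundancy, CWM, CSI) built from fuzzy-coded traits. `biomon` is for the
people who compute these routinely — environmental consultants, ecologists,
water-agency analysts — and handles the unglamorous parts: validating a
taxonomic reference, catching misspelled names, aggregating
mixed-resolution data to every rank, and keeping a complete trace of which
taxa produced each index value.

## The core machinery

* Communities are matched against a **reference dataset** (one row per
  terminal taxon, one column per rank); unmatched names are excluded and
  reported with Damerau–Levenshtein suggestions, then abundances are
  aggregated additively to every rank.
* With per-sample relative abundances *pᵢ*, the package computes e.g.
  *H* = −Σ *pᵢ* log *pᵢ*, Gini–Simpson 1 − Σ *pᵢ*², BMWP = Σ scores of
  present scoring families, ASPT = BMWP / n, class-weighted WHPT/LIFE/PSI
  via log-10 abundance classes, and Fisher's α solving
  *S* = α ln(1 + *N*/α).
* Fuzzy trait tables are matched across ranks, averaged or sampled, turned
  into Gower dissimilarities and a PCoA trait space (Cailliez, Lingoes,
  square-root and quasi-Euclidean corrections; correlation, r² and mSD
  axis-quality criteria), then into functional indices such as Rao's
  *Q* = Σᵢⱼ *pᵢ pⱼ dᵢⱼ*.
* Indicator taxa are found with Dufrêne–Legendre IndVal
  (*A*·*B*·100, permutation p-values) and exported as plot-ready data
  structures (Sankey, prevalence, cluster-ordered composition).
* Every input a study needs can be generated synthetically
  (`generate_reference()`, `generate_community()`, `generate_traits()`,
  `generate_scores()`), so the whole package is testable offline; published
  national score sets are loaded from user files, not redistributed.

## Worked example

```r
library(biomon)

ref    <- generate_reference(seed = 42)          # synthetic reference
com    <- generate_community(ref, n_samples = 4, seed = 42)
tagged <- as_biomonitor(com, ref)                # match names to lineages
tagged
#> biomon tagged community: 30 matched taxa, 0 unmatched, 4 samples

agg <- aggregate_taxa(tagged)                    # tables at every rank

shannon(agg, tax_lev = "Family")
#> shannon at rank Family
#>       S1       S2       S3       S4
#> 1.829797 2.350959 2.123159 2.051302

aspt(agg, show_scores("bmwp"))                   # synthetic default scores
#> aspt at rank Family
#>       S1       S2       S3       S4
#> 5.307692 5.307692 5.307692 5.307692

ept(agg)                                         # EPT family richness
#> ept_richness at rank Family
#> S1 S2 S3 S4
#>  9  9  9  9
```

The Shannon values are per-sample family-level diversities (natural log);
ASPT is the mean sensitivity score of the scoring families present (equal
here across samples because the same 13 scoring families occur in all
four); `ept()` counts families of the three pollution-sensitive insect
orders. Passing `trace_b = TRUE` to any biotic index attaches the full
per-sample trace (taxa used with scores, taxa excluded with reasons), and
`recompute_from_trace()` reproduces the value from it exactly.

A command-line interface wraps the same machinery:

```sh
inst/cli/biomon fixtures --preset demo --out demo/
inst/cli/biomon import --community demo/community.csv \
  --reference demo/reference.csv --out agg.json
inst/cli/biomon calc --index aspt --scores demo/scores_bmwp.csv \
  --in agg.json --trace --out aspt.csv
```

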