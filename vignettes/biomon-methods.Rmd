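---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomon)
```

`biomon` computes biomonitoring metrics — diversity indices, sensitivity-score
biotic indices and functional trait-based indices — on community tables whose
taxa may be identified at mixed taxonomic resolution (some rows at species,
others at genus or family level). This vignette records the models the package
implements, the conventions it adopts where several exist in the literature,
and the reasoning behind the open design choices. It states no empirical
result that the test suite does not itself compute.

## 1. Taxonomic backbone

All computation happens against a *reference dataset*: one row per terminal
taxon, one column per rank of the fixed ordered list

```{r}
biomon_ranks()
```

`"Taxa"` is a pseudo-rank holding the finest non-empty name of each row.
Three invariants are enforced (`validate_reference()`): `Taxa` values are
unique and non-empty; each equals the finest non-empty rank value of its row;
and lineages are consistent — two rows sharing a name at rank *r* agree at
every coarser rank. Internal nodes (a family with no listed genera) are
terminal taxa in their own right, which is what lets family-level records in a
community table match directly.

**Name matching** (`as_biomonitor()`) is exact after whitespace trimming and
case folding. Fuzzy matching never occurs silently: unmatched names are
excluded from the joined table and reported with candidate corrections ranked
by optimal-string-alignment (restricted Damerau–Levenshtein) distance, within
a cutoff of 2 by default. The metric and cutoff are conventions of this
package — transpositions are among the commonest typing errors in Latin
binomials, and distance 2 already spans one wrong ending plus one typo —
and both are configurable. Suggested corrections are applied only after
interactive confirmation or with `force = TRUE`.

**Aggregation** (`aggregate_taxa()`) produces one abundance table per rank by
summing input taxa sharing the rank value. Taxa whose lineage is empty at a
rank are *dropped* from that rank's table rather than pooled into an
"unidentified" pseudo-taxon: pooling would silently inflate a fake taxon and
corrupt score lookups downstream. Consequently a rank table's column totals
can be smaller than the mixed-resolution (`Taxa`) totals; additivity — each
rank-level abundance is exactly the sum of its contributing input rows — is a
tested invariant.

## 2. Diversity indices

Per sample, with abundances $n_i$, $N=\sum n_i$, richness $S$ and
$p_i=n_i/N$, the package implements Shannon $H=-\sum p_i\log_b p_i$, the
Simpson family built on $D=\sum p_i^2$, Pielou $J=H/\log_b S$, Berger–Parker
$\max n_i/N$, Margalef $(S-1)/\ln N$, Menhinick $S/\sqrt N$, Brillouin
$(\ln N!-\sum\ln n_i!)/N$, McIntosh $(N-U)/(N-\sqrt N)$ with
$U=\sqrt{\sum n_i^2}$, and Fisher's $\alpha$ solving
$S=\alpha\ln(1+N/\alpha)$ by bracketed root finding (tolerance $10^{-9}$; the
left bracket approaches 0 where the defining function tends to $0^-$, the
right bracket is doubled until it is positive).

Conventions worth stating explicitly:

* `simpson()` returns the Gini–Simpson index $1-D$; the concentration $D$
  itself is available via `variant = "concentration"`, and the choice is
  recorded in the result's `index` attribute. Both conventions are called
  "Simpson" in the literature.
* Simpson evenness is $(1/D)/S$. The alternative $\,(1/D)/\log S$ exists; the
  simpler form is adopted and documented here.
* Pielou always uses the same logarithm base as the Shannon value it
  normalises.
* Undefined values (empty sample, $S\le1$ for Pielou, $N\le1$ for
  Margalef/McIntosh, all-singleton samples for Fisher's $\alpha$) are `NaN`
  with a machine-readable flag — never a silent zero.
* Indices that need true abundances (Brillouin, McIntosh, Fisher, and the
  class-weighted biotic indices) refuse presence/absence input. Occurrence
  data are detected heuristically as a 0/1 matrix that records at least one
  absence; a community in which every taxon genuinely has one individual and
  no zeros is (correctly) not flagged.

## 3. Sensitivity-score biotic indices

A `score_table()` carries everything an index needs: scalar scores
(BMWP/ASPT/DEHLI), per-abundance-class scores (WHPT), a flow group plus a
group-by-class score matrix (LIFE), sensitivity groups A–D with
group-by-class weights (PSI), empirical per-taxon weights (EPSI), sensitivity
and stenoecy coefficients (IBMR), or bare taxon lists (EPTD families, alien
taxa). Published national score sets are *not* redistributed; the package
ships loaders (`read_scores()`) plus deterministic synthetic stand-ins
(`generate_scores()`, surfaced by `show_scores()`), so every index is testable
offline and users plug in licensed tables as CSV + JSON sidecar.

Abundance classes default to the log-10 convention 1–9 → 1, 10–99 → 2,
100–999 → 3, ≥ 1000 → 4 (`class_rule()`), overridable per score table; no
authoritative class bounds are printed in the literature this package
follows, so the default is a documented convention.

Scoring semantics, applied uniformly by one engine:

* Indices are computed at the score table's rank (default Family). Input taxa
  resolved *finer* are scored through their ancestor at that rank — this is
  exactly what rank aggregation already does, and it is why computing at
  Family on species-level data equals computing on data pre-aggregated to
  Family (a tested identity). Taxa resolved *coarser* never reach the rank
  table and thus cannot be scored; present-but-unscored taxa are excluded and
  recorded.
* With `composite = TRUE`, families declared members of a composite rule are
  scored once through the composite's own entry, however many members are
  present; ASPT's denominator counts the composite once.
* WHPT taxa with a defined class score count in the denominator even when
  that score is 0.
* Every index accepts `trace_b = TRUE` and then guarantees *trace
  completeness*: `recompute_from_trace()` reproduces the reported value
  exactly from the recorded per-taxon scores/classes/weights, and
  used + excluded taxa partition the taxa present at the index rank.

Biocontamination (`bioco()`) reports ACI (alien share of abundance), RCI
(alien share of richness) and the ordinal SBCI class. The default class table
assigns class $k$ when the value falls in $[t_k,t_{k+1})$ for lower bounds
$(0,\,0.01,\,0.1,\,0.2,\,0.5)$ and takes the worse of the ACI and RCI
classes; the thresholds are configurable because the concept, not the bounds,
is standardised.

Flow-T is deliberately *not* a bespoke operation: it is registered as an
instance of `fuzzy_trait_ratio()` with the flow-intermittency modalities as
numerator over their full block (`flow_t()`).

## 4. Fuzzy traits and trait spaces

Trait tables are fuzzy-coded: non-negative affinities partitioned into
blocks. `assign_traits()` matches trait rows to community taxa across ranks,
tagging each candidate with a signed distance that counts the *non-empty*
rank steps along the reference lineage (so a genus-level trait row under a
family-level taxon is at +1 when no subfamily or tribus intervenes).
`manage_traits()` keeps nearest candidates (optionally sign-constrained;
a +1/−1 tie under `nearest` keeps both rather than secretly preferring
finer). `average_traits()` averages candidates arithmetically and then
renormalises each block to sum 1 — renormalisation keeps the profiles valid
fuzzy codes for Gower; `sample_traits()` draws one candidate uniformly,
seeded. When identical profiles would put zero distances in the trait space,
`zerodist_rm()` merges such taxa (abundances summed, alphabetically first
name kept) and `add_bias_to_traits()` instead perturbs every modality with
uniform noise on $(0,\text{magnitude})$ — uniform, not Gaussian, because the
bounded support is itself the "small amount" guarantee; if identical rows
survive, the magnitude doubles for up to three retries.

**Gower dissimilarity** (`gower_distance()`): affinities are block-normalised,
each modality contributes a range-scaled absolute difference, a block
contributes the mean over its modalities, and the distance is the mean over
blocks informative in both rows (a row informative in no block is an error).
The result is generally non-Euclidean — which is the point of the
corrections.

**PCoA** (`pcoa()`) eigendecomposes the double-centred squared-distance
matrix. Corrections: `sqrt` (element-wise), `lingoes`
($d'=\sqrt{d^2+2c_2}$ off-diagonal, $c_2$ the magnitude of the most negative
eigenvalue), `cailliez` ($d'=d+c_1$ off-diagonal, $c_1$ the largest
eigenvalue of the standard $2n\times2n$ companion problem — tested to be
minimal), and `quasi` (drop negative-eigenvalue axes). Constants are
reported; on Euclidean input both are 0 (up to numerical tolerance) and the
retained coordinates reproduce the input distances to $10^{-8}$.

**Axis selection** (`select_pcoa_axes()`) reports, for each dimensionality
$m$: the Pearson correlation between $m$-axis and input distances; $r^2$, the
cumulative share of positive eigenvalues (the regression variant cited in
some sources can be substituted behind the same interface); and the mean
squared deviation between max-scaled reduced and input distances — each
distance vector is scaled by its own maximum so mSD is comparable across
$m$ and is exactly 0 at full rank on Euclidean input. Recommended $m$ is the
argmin of mSD, or the smallest $m$ reaching the 0.95 threshold for the other
two criteria.

**Functional indices.** FRic is the convex hull volume of the present taxa in
$m$ axes (more than $m$ taxa required). Hulls are computed exactly in 1-D and
2-D (monotone chain + shoelace); for $3\le m\le6$ the package shells out to
the system Python's `scipy.spatial.ConvexHull` (qhull), and refuses $m>6$ by
default because hull complexity explodes combinatorially. Degenerate
configurations are flagged `NaN`, with a tolerance scaled to coordinate range
to absorb the $\sim10^{-9}$ PCoA reconstruction noise. FDis is the
abundance-weighted mean distance to the abundance-weighted centroid. FEve
follows the minimum-spanning-tree formulation: branch weights
$EW_l=d_l/(p_i+p_j)$, normalised, then
$FEve=\frac{\sum\min(PEW_l,\tfrac1{S-1})-\tfrac1{S-1}}{1-\tfrac1{S-1}}$,
requiring $S\ge3$. Rao's $Q=\sum_{ij}p_ip_jd_{ij}$ uses the distance matrix
as given; functional redundancy is Gini–Simpson minus $Q$ with distances
scaled to $[0,1]$ (making redundancy non-negative), and the scaling choice is
visible in the code path rather than hidden. CWM is $\sum_i p_i t_i$ per
modality over the taxa covered by the trait table, with $p$ renormalised over
covered taxa. The taxon specialization index is computed per block as
$(K-1/\sum a^2)/(K-1)$ on block-normalised affinities — 1 for a
single-modality specialist, 0 for a uniform generalist — averaged over
informative blocks; CSI is its abundance-weighted community mean. Any
monotone-equivalent TSI variant can be substituted without touching CSI.

## 5. Indicator taxa and plot data

`indval()` implements Dufrêne–Legendre indicator values with group-size
corrected specificity by default (`corrected = FALSE` gives the raw-sum
variant), and permutation p-values
$p=(1+\#\{IndVal^{perm}\ge IndVal\})/(1+n_{perm})$ per (taxon, group),
seeded. Three plot-ready structures — and only three — are exported as data,
never rendered graphics: the Sankey structure of significant indicator taxa
(filtered by p-value at a configurable `alpha`; filtering by IndVal magnitude
was the other defensible reading and is achievable by filtering the returned
`indval` table), the prevalence of a rank within an upper rank, and
cluster-ordered per-sample composition. Where groups are derived rather than
given, samples are clustered with Bray–Curtis dissimilarity and average
linkage — unremarkable defaults for abundance data, stated here because any
would do.

## 6. Synthetic data: what the generators emulate

The generators exist so every module is testable with no downloads; they are
first-class, tested code.

* `generate_reference()` hangs synthetic, pronounceable families, genera and
  species (uniqueness enforced) under a *fixed real scaffold* of up to nine
  orders with correct upper lineages (Ephemeroptera, Plecoptera, Trichoptera,
  Diptera, Coleoptera, Odonata, Hemiptera, Basommatophora/Gastropoda,
  Haplotaxida/Oligochaeta) — so EPT and GOLD semantics are meaningful on
  synthetic data. Defaults (6 orders × 3 families × 2 genera × 2 species)
  give a reference of realistic shape for a regional macroinvertebrate list
  while keeping tests fast.
* `generate_community()` draws taxa at mixed resolution (default 60 %
  species / 20 % genus / 20 % family, reflecting the typical dominance of
  species- and genus-level records in monitoring data) and gives them
  independent log-series abundances. The log-series was chosen *because* it
  makes Fisher's $\alpha$ a known ground truth: given target $N$ and
  $\alpha$, the parameter is $x=N/(N+\alpha)$ and expected richness
  $S=\alpha\ln(1+N/\alpha)$, so the diversity module gets a genuine
  parameter-recovery test ($\alpha$ recovered within 15 % at $N=10^4$).
  Defaults $\alpha=5$, $N=500$ are ordinary values for a single riffle
  kick-sample.
* `generate_traits()` draws Dirichlet-distributed fuzzy profiles
  (concentration $1/\text{specialization}$) per block; `generate_scores()`
  builds one synthetic table per index family, satisfying all score-table
  invariants.

What a green test does *not* establish: synthetic communities have no spatial
or temporal structure, no detection bias, no correlation between traits and
sensitivity scores, and name errors only when injected. The generators
validate the machinery, not any ecological claim about real assemblages.

## 7. Numerical choices and degenerate inputs

* Tie-breaks are total everywhere randomness is absent: suggestion lists sort
  by (distance, name); merged taxa take the alphabetically first name;
  candidate lists sort by (|distance|, distance, name). Identical inputs give
  identical outputs byte for byte.
* All randomness (generators, `sample_traits()`, permutation tests) flows
  through explicit integer seeds and restores the caller's RNG state.
* Symmetry of distance matrices is required to $10^{-12}$; eigenvalues below
  a relative $10^{-9}$ tolerance are treated as zero when building
  coordinates.
* Empty samples, empty candidate sets, zero denominators and
  fewer-taxa-than-axes samples all produce flagged `NaN`s, not errors, so a
  single bad sample never aborts a batch.

## 8. Known limitations

* The CLI covers the common paths (import, index calculation, trait
  averaging/sampling, trait-space export, IndVal, plot data, fixtures);
  exotic combinations remain library-level.
* Hulls above 6 dimensions are refused rather than approximated; 3–6
  dimensions require a Python with scipy on the PATH.
* Score tables apply at a single rank; cross-rank score interpolation is
  deliberately out of scope (excluded taxa are traced instead).
* Ecological-status class boundaries (High/Good/…) and EQR normalisation are
  jurisdiction-specific and not implemented.
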