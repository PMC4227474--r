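---
title: "Response-mode analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-mode analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respmode)
```

## The data model

Everything in `respmode` operates on a *call table*: a gene × contrast
grid in which each cell is one of three response calls, `up`, `nc`,
`down`. The package deliberately starts downstream of differential
expression: how the calls were produced (normalisation, test,
thresholds) is out of scope, and `derive_calls()` exists only as a
documented default (`up` iff significant and change ≥ threshold) for
users arriving with continuous values. Two modelling commitments follow
from this choice:

* **No missing codes inside the grid.** A gene either has a call for
  every listed contrast or is dropped (and reported). This keeps every
  contingency marginal an exact column sum, at the price of restricting
  each analysis to the genes with complete calls — the same restriction
  a cross-classification of "genes whose response modes are known"
  imposes in practice.
* **The grand total is always the sum of the observed cells**, never a
  user-supplied figure. When published tables disagree with their own
  totals (off-by-ten typos are common), the cells win, because the
  expected counts that make the table self-consistent are the ones
  derived from the cell sum.

## Contingency analysis

`cross_tabulate()` counts genes into the Cartesian product of trinary
levels over k row factors against one column factor (3^k × 3 cells).
Under the null that the classifications are independent, the expected
count in cell (r, c) is `E = R_r · C_c / N`, and the enrichment ratio
`O/E` measures how many times more genes occupy the cell than chance
alignment of the marginal responses would produce. The chi-squared
statistic is the plain `Σ (O−E)²/E` with `(rows−1)(cols−1)` degrees of
freedom, no continuity correction; cells with `E = 0` are skipped and
counted in `skipped_cells`. No per-cell exact tests or multiplicity
control are attempted — the ratios are descriptive effect sizes, and
the single chi-squared answers the one global question asked of the
table.

Display rounding is isolated in `format_ratio()`: half-up to one
decimal, switching to integer display once the rounded value reaches 10
(so 9.93 prints as "10", 20.85 as "21"). Full precision is always
retained internally; display never feeds back into computation.

`modifier_overrepresentation()` is the same idea applied to a gene set
rather than a table row: the frequency of a call level inside the set
divided by its frequency in the universe. It underlies
`cluster_modifier_profile()`, which asks whether a cluster is enriched
for genes whose hormone response depends on phospholipase D or on
diacylglycerol kinase.

## The cluster predicates

`assign_clusters()` encodes a mechanistic hypothesis as call-pattern
predicates over four contrasts. Writing X for the PI-PLC inhibitor
contrast, WB for basal wortmannin (W30 vs W1) and WS for
wortmannin-under-SA:

| cluster | pool      | predicate |
|---------|-----------|-----------|
| A       | SA-up     | WS = down, WB ≠ up, X ≠ down |
| B       | SA-up     | X = up, WB = up, WS ≠ down |
| D       | SA-down   | WS = up, WB ≠ down (default: also X ≠ up) |
| C       | SA-down, not D | X = down, WB = down |

Genes unaffected by all three of X, WB, WS are discarded first in each
pool. The sequential order matters only once: D is evaluated before C,
which guarantees C ∩ D = ∅; A and B are structurally exclusive because
A requires WS = down and B forbids it. Variant labels (`B^X`, `B^W30`,
`C^X`, `C^W30`) mark genes failing exactly one of the two basal
conditions — near-misses that would join the cluster under slightly
looser upstream thresholds — and are never assigned to cluster members.

Two points in the rule set are genuinely open and are therefore
switches with documented defaults:

* **`d_excludes_inhibitor_up` (default `TRUE`).** The published
  narrative states an inhibitor-direction exclusion for cluster A
  (induction incompatible with inhibitor repression) but is silent for
  the mirror case in cluster D. By the symmetry of the mechanism — a
  substrate-dependent repression cannot coexist with inhibitor-driven
  induction — the default applies the mirrored exclusion. Setting it
  `FALSE` gives the literal, weaker rule.
* **`c_excludes_w30sa_up` (default `FALSE`).** The C predicate as
  narrated filters only on basal repression; an optional guard
  additionally rejects genes derepressed under wortmannin+SA. Off by
  default because the narrated walk-through never applies it.

`reconcile()` intersects (stringent) and unions (loose) the two
single-inhibitor assignments. Stringent membership is the conservative
claim — the pattern must hold under two chemically unrelated inhibitors
— and is what the downstream enrichment, motif and modifier analyses
consume.

## Bootstrap category enrichment

`enrichment()` normalises category frequencies in a set to the same
frequencies over the background universe; a ratio of 3 means the
category is three times as frequent among set genes as genome-wide.
The resampling unit in `bootstrap_enrichment()` is the **gene**: each
of `n_boot` (default 100) replicates redraws `|set|` genes from the set
with replacement and recomputes all ratios. Resampling genes rather
than categories follows from what the input to the categorisation is —
a gene list — and makes the SD reflect sampling variability of the list
itself. Genes without any annotation dilute both numerator and
denominator by default (`annotated_only = FALSE`); multi-annotated
genes count once per category, which is why category bars can sum to
more than 100%. No DAG propagation or enrichment p-values are computed;
the output is the normalised profile with its bootstrap spread.

## Motif scanning

`scan_motifs()` tests every k-mer (4–10 bp by default) present in at
least one foreground promoter. Three decisions fix the statistic:

* **Counting unit is per-promoter presence**, not occurrence totals:
  the 2×2 table contrasts promoters containing ≥ 1 occurrence with
  those containing none, foreground vs background, because the
  biological question is about gene sets, and presence counting is
  insensitive to a single promoter stuffed with repeats. The decision
  is isolated in one counting function.
* **Both strands, merged canonically.** A promoter element is a
  double-stranded object; a motif and its reverse complement are
  reported as one hit under the lexicographically smaller string, and
  palindromes count once. Scanning a reverse-complemented promoter set
  therefore yields identical output.
* **Fixed threshold `p < 1e-5`, chi-squared with 1 dof, no continuity
  correction, no multiplicity adjustment.** With on the order of 10^5
  tested motifs, the implied family-wise false-positive budget is
  roughly `n_tested × 1e-5 ≈ 1` hits per null scan; the test suite's
  null-calibration runs measure exactly this. `N` bases never match.

`extract_promoters()` implements the conventional promoter definition:
up to 1000 bp immediately upstream of the TSS on the gene's strand,
excluding the 5′UTR by construction (the window ends at the TSS,
exclusive) and truncated at any other gene's annotated span so promoter
sequence is never taken from inside a neighbour. `match_catalog()`
matches hits against IUPAC patterns in either orientation, where
"match" means the motif contains, or is contained in, a string matching
the pattern — the appropriate relation when hit lengths (4–10) straddle
catalog element lengths.

## Similarity ranking

`build_signature()` keeps the `n_top` (default 200) most up- and most
down-regulated genes with their signed changes, breaking ties by gene
ID. `rank_panel()` computes, per experiment, the Euclidean distance to
the signature over shared genes, divided by `√n_shared` so experiments
with different overlap are comparable (switchable via `normalize`).

The published similarity score this mirrors comes from a proprietary
tool whose exact transform is unstated; the one property it documents
is that **a relative score of 1 means similarity equal to the panel
average**. The simplest function with that property is implemented:
`r_i = d̄ / d_i`, floored at `ε = 10⁻¹² · d̄` so an exact match (d = 0)
gets a large finite score instead of ∞. `r` is strictly decreasing in
`d`, invariant under positive rescaling of all change values, and the
ranking by `r` equals the ranking by distance. The function is
deliberately isolated so an alternative transform can be substituted
without touching the rest. A `direction_only` mode replaces signature
values by ±1 for call-level signatures; which variant a proprietary
compendium uses is unknowable, so both are provided. Reproducing any
published compendium ranking is explicitly out of scope — the scoring
contract, not the database, is the deliverable.

## The synthetic world

Every generator is seeded, emits a truth sidecar, and emulates exactly
the statistical structure the corresponding analysis assumes:

* `simulate_call_table()` draws genes multinomially from planted cell
  probabilities; `independence_probs()` builds those probabilities from
  marginals and optional per-cell multipliers. Note that boosting a
  cell also inflates its own marginals, so the planted observed/expected
  ratio (recorded in the `planted_ratio` attribute) is smaller than the
  raw multiplier.
* `plant_clusters()` samples call patterns uniformly from each cluster
  predicate's satisfying set (exercising every rule branch, not one
  canonical pattern) and rejection-samples background genes against all
  predicates, so sensitivity = specificity = 1.0 is attainable and any
  miss is an implementation defect.
* `simulate_promoters()` uses i.i.d. bases at a stated GC fraction
  (default 0.36, typical of *A. thaliana* intergenic sequence) with at
  most one planted-motif insertion per promoter, overwriting the
  background at a uniform position and strand.
* `simulate_annotations()` draws per-gene, per-category Bernoulli
  annotations with a planted enrichment factor on the set;
  `simulate_panel()` builds experiments as the signature plus Gaussian
  noise increasing along the panel.

What the generators do **not** emulate — probe-level noise, correlated
calls across contrasts, promoter composition heterogeneity (CpG/TA
skew, repeats), annotation co-occurrence structure — bounds what a
green test establishes: correctness of the inferential machinery on
data satisfying its own assumptions, not robustness of the upstream
calling pipeline. Published cluster sizes from the original microarray
data are not reproducible without the underlying per-gene call lists
and are used only as planted sizes for recovery tests, never asserted
as outputs.

## Numerical and interface choices

* Expected-count identities are exact to 1e-9 relative tolerance;
  chi-squared values are validated against brute-force recomputation.
* Enrichment ratios with a zero denominator carry `NA` (undefined), not
  0 or Inf; zero observed with positive expected is a genuine ratio 0.
* Tie-breaks are lexicographic on identifiers everywhere a selection
  could be ambiguous (signature extremes, hit ordering at equal p).
* The run configuration is JSON (`jsonlite`), one key per stage; every
  paper-gap rule switch above surfaces there with its default. A run
  writes a manifest with seed, config hash and per-output MD5s; reruns
  with identical config are byte-identical.
* Exit codes: 0 success, 1 configuration error, 2 runtime error.

## Known limitations

* The chi-squared motif statistic is asymptotic; at very small
  background presence counts it is conservative relative to an exact
  test, which only strengthens the fixed `1e-5` cutoff.
* `prune_nested()` resolves containment chains pairwise by smallest
  p-value; it does not attempt a full maximal-motif decomposition.
* Promoter truncation treats each gene's span as TSS..gene-end on its
  strand; annotations with trans-spliced or overlapping isoforms need
  pre-flattened coordinates.
* The similarity ε-floor makes exact matches rank first but their
  scores are not comparable between panels (they depend on d̄).
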