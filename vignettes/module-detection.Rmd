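---
title: "From cohort variants to disease modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cohort variants to disease modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modnet)
```

modnet implements a network-medicine analysis path for small, deeply
phenotyped cohorts: a cohort variant table is reduced to a seed gene set,
the seed set is expanded into a disease module on a protein–protein
interaction (PPI) network, and the module is characterised by enrichment,
similarity and permutation statistics. This vignette explains the model
behind each stage, the parameters that matter, the numerical choices, and
what the synthetic-data generator does and does not emulate.

## The variant stage

### High-confidence filtering

Variant calls from short-read sequencing carry systematic artefacts, so the
pipeline first applies five high-confidence filters, in a fixed order, with
each removed record attributed to the *first* filter it fails:

1. **strand** — the call must be supported by reads on both strands;
2. **conflicting** — sites where multiple variant types were called are
   dropped;
3. **repeat_region** — variants inside repetitive regions are dropped (the
   mask is an upstream annotation; the package does not pick a repeat
   catalogue);
4. **near_miscall** — variants close to known miscalls are dropped. The
   proximity window is not a property of the variant record itself, so the
   flag is normally supplied upstream; `flag_near_miscalls()` provides a
   reference implementation flagging variants within 10 bp of a recorded
   miscall site, which keeps the filter testable without re-deciding any
   caller's internals;
5. **no_hom_ref** — at least one patient must be homozygous reference,
   guarding against in-vitro contamination and systematic errors.

First-failure attribution makes the removal counts additive: the filter
report always satisfies `input = output + sum(removals)`, so the stage can
be audited from its counts alone.

### The odds-ratio background screen

Pathogenic and likely-pathogenic records are then screened against
background population allele frequencies. For a cohort of $n$ patients with
alternate-allele count $a$ and a background frequency $f$,

$$\mathrm{OR} = \frac{a/(2n-a)}{f/(1-f)},$$

and a record is removed when $\mathrm{OR} < 5$ against *any* database that
reports a frequency for it (databases with no entry are skipped; a record
with no reported frequency anywhere is retained, because no comparison is
possible). The threshold 5 is the screen's reference setting.

Numerical choices: when a cohort cell is zero ($a = 0$ or $a = 2n$) the
Haldane–Anscombe +0.5 correction is applied to the cohort odds. The
background side is a frequency, not a count table, so no pseudo-count is
invented there: $f = 0$ yields an infinite odds ratio (the record is
retained — the background provides no evidence of commonness) and $f = 1$
yields zero (removed). Division by zero cannot occur.

Whether published screens of this kind use allele counts or carrier counts
is generally not stated. The default is allele counts; `mode = "carrier"`
compares carrier counts against the Hardy–Weinberg implied carrier
frequency $1-(1-f)^2$ instead.

### Aggregation, recurrence, seeds

Retained variants are aggregated to genes. A gene's *affected patients* are
the patients with at least one non-reference genotype at any retained
variant in the gene; `recurrent_genes()` keeps genes affecting at least
`min_patients` (default 2, i.e. 10% of a 20-patient cohort). The seed set
for network expansion is **all** genes with a retained variant, not only
the recurrent ones — recurrence is a report, not a gate.

For GWAS-style external cohorts, `map_variants_to_genes()` builds seed sets
from intervals instead: a gene is selected when its interval intersects
`[block_start - w, block_end + w)` around a variant's precomputed LD block,
with `w` defaulting to 500 kb. All interval arithmetic is 0-based half-open
(BED convention); variant positions are 1-based (VCF convention); the
conversion happens only at this boundary, and a gene starting exactly `w`
after a block end is excluded.

## The network stage

The interactome is an undirected simple graph over gene symbols (igraph
object, vertex names as symbols). Reading an edge list deduplicates
reversed edges and drops self-loops with a logged count. Expansion and all
connectivity statistics are defined on a connected network, so the pipeline
reduces the input to its largest connected component first; ties between
equal-sized components break toward the component containing the
lexicographically smallest symbol, keeping the reduction deterministic.
Genes in seed or annotation sets that are absent from the network are
dropped, with a message, before any statistic is computed.

### Connectivity significance and expansion

The expansion score is the hypergeometric upper tail: for a candidate of
degree $k$ with $k_s$ links into the current module of size $s_0$ in a
network of $N$ nodes,

$$p(k, k_s) = \sum_{i = k_s}^{k}
  \frac{\binom{s_0}{i}\binom{N-s_0}{k-i}}{\binom{N}{k}},$$

the probability of at least $k_s$ module links under random wiring.
`diamond_expand()` iterates: score all candidates adjacent to the module,
absorb the lowest-p node, update, repeat `n_iter` times (default 200
additions, the reference setting for a cohort module).

Design and numerical choices:

* **Candidate restriction.** Only nodes with at least one module link are
  scored; an unlinked node has $p = 1$ and cannot win against any linked
  candidate under the tie rule, so the restriction changes nothing but
  cost.
* **Ties.** Equal p-values break by smaller degree first (the same number
  of module links from a lower-degree node is the more surprising
  connectivity), then lexicographic gene symbol. The rule is total, so the
  expansion is a deterministic function of the graph and the seeds,
  independent of node insertion order. Ties are real, not hypothetical:
  several $(k, k_s)$ pairs can give the same rational tail — $p = s_0/N$
  arises from both $(1, 1)$ and some $(k, k-1)$ configurations — and
  floating evaluation renders such mathematically equal values a few ulps
  apart. Candidates within a $10^{-10}$ relative tolerance of the minimum
  log-score are therefore treated as tied before the rule applies; genuinely
  distinct tails on desk-scale graphs are separated by far more than that.
* **Log-space comparison.** p-values are computed and compared as log tail
  probabilities (`phyper(..., log.p = TRUE)`), so scores far below the
  double underflow threshold (~1e-308) still order correctly instead of
  collapsing into spurious ties at zero.
* **Seed weighting.** The `alpha >= 1` generalization counts each seed
  link `alpha` times and inflates $s_0$ and $N$ by $(\alpha-1)$ per
  in-module seed. The default is `alpha = 1` (no weighting): published
  module-expansion analyses of this kind generally do not state a
  weighting, and unweighted expansion is the assumption this package
  documents.
* **Early stop.** If no linked candidate remains the expansion stops short;
  the module then holds fewer than `n_iter` additions.

The test suite pins the implementation to a brute-force reimplementation
(every candidate rescored from scratch by direct enumeration of the
hypergeometric mass) over 100+ random graphs of up to 30 nodes.

## Module statistics

**Fold enrichment** of an annotation set $S$ in module $M$ over universe
$U$ is $(|M \cap S|/|M|) / (|S|/|U|)$, paired with the cumulative
hypergeometric tail $P(X \ge |M\cap S|)$. The module here is the whole
object — seeds plus additions. The universe is a documented assumption, not
a derived quantity: by default it is the annotation collection's universe
intersected with the network's nodes (`intersect_with_network()`), and it
is overridable. Across a collection, p-values are Benjamini–Hochberg
adjusted. Cross-cohort support is reported by `shared_enriched_sets()`:
annotation sets significant (q ≤ 0.05 by default) in *every* module of a
labelled list.

**Module similarity** is the Jaccard index of protein interactions:
$J = |E_A \cap E_B| / |E_A \cup E_B|$ with $E_X$ the edge set of the
subgraph induced by module X's genes. Interaction lists including boundary
edges would be an alternative reading; induced-subgraph edges were chosen
and are what `induced_edges()` returns. When both induced edge sets are
empty the similarity is undefined and flagged `NA` — not 0, which would
conflate "no shared wiring" with "no wiring at all". Gene-level Jaccard and
directional overlaps ($|A \cap B|/|A|$) are reported alongside because
"module overlap" in the literature is ambiguous between the two; the
permutation null lets the caller pick the statistic.

**The random-seed permutation null** asks whether an observed overlap
between a query module and a reference module could arise from seed choice
alone: `n_perm` uniform random seed sets of the query's size are expanded
with the identical configuration, and the empirical p-value is
$(1 + \#\{\text{null} \ge \text{observed}\})/(n_\text{perm}+1)$, which is
never zero and equals $1/(n_\text{perm}+1)$ when the observed statistic
tops every draw.

Because module overlap statistics are discrete, exact ties between null
draws and the observed value accumulate in the $\ge$ count and bias the
empirical p upward — the p-value is conservative, never anticonservative.
The calibration test in the suite therefore uses conditions where the tie
mass is small (a 300-node uniform random graph, 60-gene modules,
gene-Jaccard statistic) and checks Kolmogorov–Smirnov uniformity at the
0.01 level over 200 replicates with `n_perm = 99`. On strongly hub-
dominated graphs, modules grown from random seeds concentrate on the hub
core and the tie mass grows; users comparing modules on such networks
should read small empirical p-values as trustworthy and mid-range ones as
conservative.

## The synthetic-data generator

The generator exists so every stage can be tested against known ground
truth; it is first-class, seeded, and pure: all outputs are deterministic
functions of the scenario parameters and `rng_seed`.

* **Network.** A preferential-attachment backbone (one growth parameter,
  default 3 edges per node) reproduces the heavy-tailed degree
  distribution typical of interactomes with minimal assumptions. Planted
  modules are disjoint uniform node sets whose induced subgraphs are
  topped up with random internal edges to reach the requested density
  exactly-or-above; membership is recorded on the graph. Gene symbols are
  synthetic tokens (`G0001`, ...) — no real gene names, so the fixtures can
  never be mistaken for biological claims.
* **Cohort.** The default scenario mirrors the study design the pipeline
  targets: 20 patients; 96 rare planted pathogenic/likely-pathogenic
  records over 93 planted-module genes, 9 of which affect 2 patients and
  the rest 1 (so the recurrence report returns 9 genes at the 2-patient
  cutoff); plus 7 common-frequency records whose background frequency
  equals their cohort frequency (odds ratio exactly 1, removed by the
  screen — 103 pathogenic in, 96 out); plus one decoy class per
  high-confidence filter (each fails exactly its targeted filter, so
  attribution is testable) and clean benign background records. Every row
  carries a `truth_role` label.
* **Annotation sets.** Per planted module, one enriched set (half its
  members drawn from the module, half from the rest of the network) and
  size-matched uniform decoy sets whose expected fold enrichment is 1.

What the generator does **not** emulate: realistic allele-frequency
spectra, linkage structure, sequence context, genotype error, the size and
clustering coefficients of any specific published interactome, or
correlated annotation sets. Passing tests on synthetic data therefore
demonstrate algorithmic correctness and statistical calibration under the
generator's assumptions — not that any particular biological finding would
replicate.

## Problem sizes used by the test suite

Property suites run at sizes where exact oracles are feasible and the
statistical checks are well-powered: exact-tail enumeration on universes up
to 60; brute-force expansion equivalence on graphs up to 30 nodes over 100+
seeded instances; planted-module recovery on 1,000-node networks (30-gene
planted module, density 0.5) paired against degree-matched random seeds
over 20 generator seeds; null calibration on a 300-node graph with 200
replicates of a 99-permutation null; and the bookkeeping chain on the full
default scenario (2,000-node network). These sizes are the package's
reference study conditions and are stated here so results can be
reproduced exactly.

## Known limitations

* The expansion recomputes candidate scores each step in R; networks of
  hundreds of thousands of edges are fine, but genome-scale runs with many
  thousands of iterations would benefit from a compiled core.
* The odds-ratio screen treats databases as independent columns; it does
  not model background sample sizes, so no confidence interval on the OR
  is available.
* Enrichment assumes a well-defined gene universe; results are sensitive
  to that choice, which is why the universe is explicit and logged.
* The permutation null holds the expansion configuration fixed; it does
  not propagate uncertainty in the seed set itself.
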