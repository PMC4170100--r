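---
title: "Methods: guided SSR network construction, testing and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guided SSR network construction, testing and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrnet)
```

`ssrnet` reconstructs a sugar-starvation responsive (SSR) gene network
from expression data by a guided-gene approach, characterises its
structure, and validates it against dye-swap microarray comparisons and
promoter motif content. This vignette is the package's own account of
the methods: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## Guided co-expression expansion

### Model and statistic

Co-expression is measured by the squared Pearson correlation r² between
two genes' expression profiles across the samples of a compendium. The
square is used because the guided approach is agnostic to the sign of
co-regulation at this stage; r² is also the statistic that genome-scale
co-expression services expose. `pairwise_r2()` computes query-vs-genome
correlations only (never all-vs-all): edges are recorded between a query
of some round and any other gene, which keeps the cost at
O(|queries| × G × S) and matches the guided design — the network is a
neighborhood of the seed biology, not a global graph.

Pairs involving a zero-variance profile are omitted and logged rather
than propagated as NaN. With missing values, a pair is computed on its
complete samples and omitted below 3 complete samples.

### Recursion and the final network

`expand_seeds()` runs a configurable number of rounds (default 3: the
seed pass plus two recursive passes). After each round, genes with at
least `expand_min_neighbors` (default 5) neighbors in that round's
thresholded graph join the query set; queries are never dropped, so the
query set is non-decreasing and the procedure terminates. After the last
round the union edge set is reduced to its `final_min_degree`-core
(default 2). The k-core is used deliberately: a single "remove nodes
with degree < 2" pass can leave nodes whose degree drops below the
threshold after their neighbors are removed, whereas the k-core
guarantees the stated property — every gene of the final network has at
least two neighbors — by construction.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `r2_cutoff` | 0.36 | minimum r² for an edge (\|r\| ≥ 0.6) |
| `expand_min_neighbors` | 5 | neighbors needed for promotion to query |
| `rounds` | 3 | seed pass + recursive passes |
| `final_min_degree` | 2 | k-core order of the final network |

The r² cutoff deserves a note: the upstream co-expression service used
in the original analysis applies "default settings" whose numeric value
is not published. The cutoff is therefore a first-class configuration
value here, defaulted to 0.36 (a conventional \|r\| ≥ 0.6 rule), stamped
into the network's graph attributes and the run manifest so that every
output records the value that produced it. The same applies to the
choice of computing correlations on the matrix exactly as provided:
normalisation is declared an upstream responsibility, and no internal
log-transform is applied.

## Network structure

`degree_summary()` bins degrees into [0, 10), [10, 100) and [100, ∞),
and reports hub genes (>100 neighbors, candidate master regulators) and
the structural class (>25 neighbors) whose dawn response is later used
as a validation criterion. `scale_free_summary()` reports the degree
histogram and the least-squares slope of log(count) against log(degree).
The slope is descriptive only — no statistical claim of scale-freeness
is made or tested, matching the qualitative use of the term for
biological networks; for degenerate distributions (fewer than two
distinct degrees) the slope is flagged undefined instead of fitted.

### MCODE

`mcode()` implements the canonical molecular-complex-detection
algorithm. Each vertex is weighted by the product of (a) the order k of
the highest k-core of its closed neighborhood and (b) the density of
that k-core. Modules grow greedily from the highest-weight unassigned
seed, admitting neighbors whose weight is at least
`seed_weight × (1 − node_score_cutoff)` (default cutoff 0.2), to a
maximum depth. The haircut step (on by default) keeps the module's
2-core, removing singly-connected periphery; "fluff" (off by default)
optionally adds dense periphery and may share vertices between modules,
while module cores are disjoint. A finished module must contain at least
a 2-core, which discards trivial connected pairs. The score is
density × size, and the tests recompute it independently from the edge
list for every reported module.

Two decisions are worth recording. First, the parameters are the
canonical MCODE defaults, stamped into the result, because the original
analysis names the algorithm but not its settings; reproducibility is
preferred over guessing. Second, everything is deterministic: seeds are
ordered by weight descending then node ID ascending, so module output is
invariant under node relabeling up to that documented tie-break (a
property the suite tests).

## Differential expression from dye-swap arrays

Each biological replicate is hybridised twice with the fluorophores
exchanged. Writing f and s for the forward and swapped log₂-ratios, the
replicate value is (f − s)/2: biological signal enters f and s with
opposite signs and is recovered, while gene-independent dye bias enters
with the same sign and cancels. The combination rule is a package
convention (the source protocol does not state one); it is the unique
linear combination that both cancels additive dye bias and has unit gain
on the signal.

Genes with extreme replicate variance — "too small or too large" — are
excluded by empirical quantiles of the per-gene variance distribution
(defaults 0.001 and 0.999). Quantiles make the rule scale-free and
self-calibrating; with ~1000 genes roughly two genes are excluded, with
24,576 spots about fifty.

The test assumes the log-ratio variance is common to all genes: the
pooled estimate `s² = Σ_g Σ_i (r_gi − m_g)² / (G(n − 1))` over included
genes replaces per-gene variances, and `t_g = m_g / √(s²/n)` is referred
to the standard normal. With G in the thousands the pooled degrees of
freedom G(n − 1) are so large that the normal and t references differ by
less than 10⁻⁴ in p; the reference used is recorded in the output
metadata. Bonferroni adjustment uses m = the number of genes surviving
exclusion (not the physical array size), with an explicit override for
users who prefer a fixed m; calls require both adjusted p ≤ α and a
mean-sign, and excluded genes are labelled as such rather than silently
dropped. The number of dye-swap pairs is not fixed by the package — any
n ≥ 2 is accepted and recorded — because source protocols differ on
whether a comparison comprises two or three swap pairs.

Calibration is verified by simulation: under the null generator the raw
false-positive rate lies within Monte-Carlo error of α, and the
family-wise error of the Bonferroni calls, measured over independent
simulated comparisons, is at the nominal level (measured ≈ 0.045 over
200 replicates at the suite's fixture scale). One subtlety: excluding
the top variance quantile slightly deflates the pooled s², making the
raw test marginally anticonservative (~0.052 at α = 0.05 at fixture
scale); this is inherent to the exclude-then-pool recipe itself, not an
implementation artifact, and stays well within the tested bands.

## Promoter motif over-representation

Two complementary tests are provided.

**Known motifs.** For each IUPAC motif, the statistic is containment:
the number of subset promoters with at least one match. Degenerate
patterns are expanded to concrete instances and counted by a
Boyer–Moore search implementing both the bad-character and the strong
good-suffix rules; the full-match shift equals the pattern period, so
overlapping occurrences are counted. The enrichment p-value is an exact
upper tail — hypergeometric when the background is a full promoter set,
binomial when it is a containment frequency. Exact tails are used
because the interesting p-values (10⁻³ and far below) live where normal
approximations fail. Matching is forward-strand by default (promoter
FASTA is assumed TSS-oriented), with a reverse-complement flag.

**Exhaustive k-mers.** Every k-mer occurring in the subset is compared
with its containment count on B random size-matched promoter sets
sampled without replacement from the genome set; the empirical p-value
is (1 + #{null ≥ observed})/(B + 1), bounded below by 1/(B + 1), and
B < 99 is refused as too coarse. The k-mer tabulation uses a single
left-to-right window pass rather than 4^k separate searches: when every
window of the sequence is itself a counted k-mer, one scan enumerates
all occurrences at once, and a per-pattern search would only repeat
work. The Boyer–Moore counter remains the single-pattern engine used
for targeted motifs.

A note on calibration testing: exact conditional tests have discrete,
super-uniform p-value distributions (P(p ≤ x) ≤ x with atoms). The
suite therefore checks that defining bound at several thresholds rather
than applying a continuous-uniform goodness-of-fit test, which would
reject any discrete distribution regardless of validity.

## Cross-examination and reporting

`cross_examine()` intersects network membership with per-comparison
calls, keeping all four direction × time-point cells per gene without
collapsing (whether a gene down at dawn may also be up at dusk is left
visible in the stored sets rather than resolved by an undocumented
rule). Venn partitions over 2–3 call sets are computed as exact disjoint
regions; more than three sets is refused because the report format is
Venn-bounded. Every printed percentage is an integer obtained by
rounding half away from zero — the rule that reproduces the published
percentages from their own counts (e.g. 220/820 → 27, 783/3332 → 23,
2549/3332 → 77, 15/820 → 2, 89/820 → 11) — and is recomputable from the
stored gene sets, a property the tests assert.

## Synthetic data: what it emulates, and what it does not

The generators provide the statistical structure each stage assumes,
with complete ground truth:

* `gen_compendium()` builds module genes as
  `latent_r · shared_profile + √(1 − latent_r²) · noise`. With unit
  noise the expected within-module correlation is exactly `latent_r²`
  (edge statistic `latent_r⁴`), which gives closed-form oracles: r = 1
  modules are perfectly correlated, r = 0 modules have
  E[r²] = 1/(n_samples − 1). Non-module genes are independent noise.
* `gen_two_color()` plants a mean shift of `effect` with opposite sign
  on swapped arrays, i.i.d. normal noise, and an exactly assigned DE
  gene count (`round(n_genes × de_fraction)`), so fixtures can assert
  exact counts. An explicit `de_genes` list allows planting the response
  on known (e.g. module) genes for end-to-end fixtures.
* `gen_promoters()` draws i.i.d. bases at a stated GC fraction and
  inserts concrete instances of IUPAC patterns (degeneracy resolved
  uniformly at insertion) at uniform non-overlapping positions,
  recording every insertion.

Fixture scales were chosen once, as study conditions: planted-module
recovery uses a 50-gene module at `latent_r = 0.95` among 500 noise
genes over 60 samples; MCODE recovery uses two 40-gene modules; the
planted-word fixture uses 500 bp promoters because the background
containment of a 5-mer in 500 bp of random sequence is ≈ 40% (in
1000 bp it would be ≈ 62%), which together with an insertion
probability of 0.77 yields ≈ 86% subset containment — the regime of a
strongly over-represented core word; null calibration uses 2000 genes ×
3 dye-swap pairs. The end-to-end demonstration (`run_pipeline()`)
defaults to 600 genes × 60 samples with two planted 40-gene modules.

What passing these tests shows: the algorithms recover exactly the
structure they are designed to detect, at effect sizes where detection
is information-theoretically comfortable, and their test statistics are
calibrated under their own null models. What it does not show: that
real compendia satisfy the latent-factor model (real expression has
correlated noise, batch structure, and non-normal intensity
distributions deliberately not emulated), that real promoters are
i.i.d. sequence (they are not — composition varies with position and
isochore), or that the published network itself is recovered, which
would require the original compendium and hybridisations. Published
headline counts (820 nodes, 3880 edges, degree bins 717/89/15, 220
dawn-induced network genes) are treated as documented reference values,
and only their internal arithmetic (the percentage identities above) is
recomputed.

## Degenerate inputs and numerical conventions

Zero-variance expression profiles: omitted from correlation, logged.
Empty round-1 expansion: empty network with a warning, not an error.
Edgeless graphs: empty MCODE result. All-equal degree distributions:
slope flagged undefined. All-zero ratio tables: p = 1 everywhere, no
calls. Identical variances: nothing excluded. A single replicate:
refused (no within-gene variance). Motifs matching nothing: p = 1.
Empirical p-values never reach 0 by construction. All tie-breaks
(degree ordering, MCODE seeds and ranking, k-mer ordering) are
deterministic — weight or p first, lexicographic ID second — so equal
inputs give byte-identical outputs, which the determinism tests enforce
end to end through the pipeline's written artifacts.

## Known limitations

* The guided design never evaluates target–target correlations unless a
  target is promoted to query; a module none of whose members reaches
  the promotion threshold is represented only by its seed-adjacent
  edges.
* MCODE module identity for the original network cannot be checked
  (the original figure and settings are unavailable); only algorithmic
  properties (score identity, relabeling invariance, planted recovery)
  are validated.
* The k-mer null samples genome promoters; it does not implement
  sequence-shuffling nulls, so compositional bias shared by subset and
  genome is controlled, but subset-specific composition is attributed
  to enrichment.
* The pooled-variance assumption is the method's own; genes with truly
  heterogeneous variance are partially handled by the exclusion step,
  not modelled.
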