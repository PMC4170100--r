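# ssrnet

Seed-guided co-expression network analysis of the sugar-starvation
response, as an installable, tested R pipeline.

## The problem

When photosynthetic carbon runs out — at the end of the night in
starchless *Arabidopsis thaliana* mutants — a coordinated set of
sugar-starvation responsive (SSR) genes is induced. `ssrnet` implements
the full guided-gene workflow used to map that response:

1. **Guided network expansion.** Starting from a curated seed set of SSR
   genes, compute the squared Pearson correlation r² between each query
   gene and every other gene of an expression compendium, keep pairs with
   r² ≥ a cutoff (default 0.36, i.e. |r| ≥ 0.6), and recursively promote
   genes with ≥ 5 neighbors into the query set (three rounds by default).
   The final network is the 2-core of the accumulated edge set, so every
   retained gene has at least two neighbors.
2. **Network structure.** Degree binning (<10 / 10–99 / ≥100 neighbors),
   hub genes (>100 neighbors, candidate master regulators), the
   structural class (>25 neighbors), a descriptive log–log degree slope,
   and MCODE module detection (vertex weighting by the density × order of
   the highest k-core of the closed neighborhood; greedy seeded growth;
   haircut; module score = density × size).
3. **Differential expression on two-color dye-swap arrays.** Each
   replicate's forward/swapped pair is combined as `(forward − swapped)/2`
   (the dye bias cancels), genes with extreme replicate variance are
   excluded by empirical quantiles, and each gene's mean log-ratio is
   tested with a paired t-statistic using a *pooled* variance shared by
   all genes, `t_g = m_g / sqrt(s² / n)`, referred to the normal (pooled
   df are in the tens of thousands). Bonferroni-adjusted p ≤ 0.05 with a
   sign gives `up` / `down` calls.
4. **Promoter motifs.** For the promoters (1 kb upstream by convention)
   of a responsive gene subset: exact binomial/hypergeometric
   over-representation of known IUPAC motifs (containment statistic =
   promoters with ≥ 1 match, significance at p < 10⁻³), and exhaustive
   k-mer over-representation against an empirical null of size-matched
   promoter sets sampled from the genome, with p = (1 + #{null ≥ obs})/(B + 1).
   Single-pattern counting uses a Boyer–Moore search (bad-character +
   strong good-suffix rules, overlapping occurrences).
5. **Cross-examination.** Network membership is intersected with the DE
   calls per mutant line and time point: up-at-dawn in ≥1 / all lines,
   Venn partitions, integer percentages (rounded half away from zero),
   and the structural check that high-degree genes respond at dawn.

Seeded generators (`gen_compendium`, `gen_two_color`, `gen_promoters`)
produce compendia with planted co-expression modules, dye-swap ratio
tables with known DE genes, and promoters with recorded motif insertions,
so every stage is validated against ground truth without any download.

## Worked example

```r
library(ssrnet)

sim <- gen_compendium(compendium_spec(
  550, 60, modules = list(list(size = 50, latent_r = 0.95)), rng_seed = 3))
ex <- expand_seeds(sim$values, sim$truth$gene_id[1:3])
print(ex)
```

```
Seed-guided co-expression expansion
  rounds: 3, r2 cutoff: 0.36, expansion threshold: 5 neighbors
 round n_queries n_edges n_new
     1         3     144     0
     2         3     144     0
     3         3     144     0
  final network: 50 nodes, 144 edges (min degree 2)
```

The three seeds belong to a planted 50-gene module; the expansion
recovers exactly those 50 genes (144 seed–module edges cross the r²
cutoff) and no noise gene. Continuing with module detection and a
simulated dawn comparison in three mutant lines:

```r
degs <- degree_summary(ex$network)
tc   <- gen_two_color(two_color_spec(550, 3, effect = 1, sigma = 0.25,
          rng_seed = 4, de_genes = sim$truth$gene_id[!is.na(sim$truth$module)]))
tab  <- de_test(tc$ratios, tc$arrays)
calls <- lapply(c("adg1", "be2_be3", "adg1_be2_be3"), function(m)
  de_call_set(paste0(m, "_dawn"), m, "dawn", tab))
cross_examine(ex$network, degs, calls)
```

```
Network / DE cross-examination
  network: 50 genes
  up at dawn in >=1 line: 50 (100%); in all lines: 50
  down at dawn in >=1 line: 0; stable: 0 (0%)
  structural genes (>25 neighbors): 3, up at dawn: 3 (100%)
```

All 50 network genes carry the planted dawn response and are called up
in every line; the three high-degree (structural) genes are all dawn
responsive, the property used to validate the network against the
mutant transcriptomes.

A full end-to-end run (`run_pipeline()`, or
`Rscript inst/scripts/ssrnet-pipeline.R --out out/`) writes the
compendium, edge list, SIF/GraphML exports, degree and module tables,
per-comparison DE tables, motif enrichment results, the overlap report
and a manifest with config, seed and file digests; runs are
byte-identical given the same config.

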