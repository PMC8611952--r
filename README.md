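# chemogenlib

Design of diversity-optimised chemogenomics compound libraries from
ChEMBL-style bioactivity tables, for groups assembling focused screening
decks for phenotypic drug discovery.

A chemogenomics library is a compact compound set that covers as much of
the druggable target space as possible while staying chemically diverse.
`chemogenlib` builds one end-to-end:

1. **Bioactivity filtering** — retain molecule–target pairs with a Ki or
   IC50 strictly below 1 µM from binding (type B) assays at ChEMBL
   confidence 9 in human, rat or mouse; species orthologs collapse onto a
   species-agnostic protein entry (UI) so activity is not double-counted.
2. **Scaffold-tree decomposition** — each molecule is cut to its Murcko
   framework (level 1) and then one ring at a time down to a single ring,
   with a fixed deterministic rule cascade; selection works at level 2,
   and scaffolds hitting more than 6 targets are pruned as promiscuous.
3. **Profile clustering** — the binary scaffold × protein-entry matrix is
   clustered hierarchically on Jaccard distances
   (`d = (b + c) / (a + b + c)`) and one representative scaffold per
   cluster is chosen by a medoid → target-count → molecule-count →
   lexicographic cascade.
4. **Pareto subset selection** — an elitist non-dominated-sorting genetic
   algorithm evolves fixed-size molecule subsets under three maximised
   objectives: distinct protein entries covered (O1), distinct
   representative scaffolds present (O2), and mean hits per covered entry
   (O3). The final subset maximises (O1, O2, O3) lexicographically over
   the first Pareto front.
5. **Coverage completion** — every protein entry with bioactive chemistry
   but no selected compound gains the candidate whose scaffold captures
   the largest chemical series.
6. **Annotation & profiles** — per-compound hypergeometric
   over-representation of GO/KEGG/Disease Ontology terms with Bonferroni
   adjustment (cutoff 0.1), and Cell Painting feature processing
   (replicate averaging, zero-variance removal, pairwise |r| < 0.95
   greedy filter per cell/cytoplasm/nucleus compartment).
7. **Graph export** — the whole pharmacology network (molecules, assay
   results, targets, protein classes, scaffolds, terms, morphology
   descriptors) as GraphML or Neo4j bulk-import CSV.

A seeded synthetic-data module generates every input the pipeline
consumes — decorated scaffold families, log-normal potencies with planted
filter violations, a protein-class tree, planted enriched terms, and
replicate morphology matrices — with recorded ground truth, so the whole
workflow runs and is tested fully offline.

## Worked example

```r
library(chemogenlib)

gen <- gen_chemogenomics_inputs(seed = 1)   # 300 molecules, 40 protein entries
cfg <- pipeline_config(subset_size = 50, ga_population = 40,
                       ga_iterations = 60, n_clusters = 12, rng_seed = 1)
run <- run_pipeline(gen$inputs, cfg, out_dir = "results/run1")
print(run)
```

```
chemogenomics library run
  bioactive pairs: 597 (300 molecules, 36/40 UI on main path)
  scaffolds: 11 generated, 1 pruned as promiscuous
  clusters: 10 -> 10 representatives, pool 180 molecules
  chosen subset: O1 = 22 UI, O2 = 10 scaffolds, O3 = 6.227
  final library: 58 molecules (8 completion additions), 31 UI covered
```

Reading the output: 702 activity records collapse to 597 high-confidence
molecule–protein pairs; 11 distinct level-2 scaffolds are found and one is
pruned for hitting more than 6 targets. Clustering the 10 survivors yields
10 representatives whose 180 linked molecules form the GA candidate pool.
The chosen 50-compound subset covers 22 protein entries with all 10
scaffolds at 6.2 hits per entry; completion then adds 8 compounds so that
all 31 protein entries with any qualifying bioactivity are covered —
including those routed around the main path because they lack a level-1
protein class. `run$library` lists the final compounds with InChIKey,
selection scaffold and completion flag; `results/run1/` holds every stage
artifact (pairs, scaffold table, MTX matrix, clusters, Pareto fronts,
enrichment table, filtered morphology matrix, GraphML and Neo4j exports,
manifest).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/chemogenlib simulate --seed 1 --out inputs/
Rscript inst/cli/chemogenlib run-all --in inputs/ --out results/ --seed 1
```

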