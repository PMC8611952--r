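---
title: "Designing a chemogenomics library: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a chemogenomics library: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science behind `chemogenlib`: the procedure
each stage implements, its assumptions, the tunable parameters and their
defaults, the numerical and design choices made where the methodology was
genuinely open, and what the synthetic test data does and does not
demonstrate about real inputs.

## The problem

Phenotypic screening benefits from compact compound decks in which every
druggable protein is represented by potent, selective chemical matter and
the chemotype diversity is high enough that a phenotype can be attributed
to pharmacology rather than to one chemical series. Given a bioactivity
table (molecule, target, assay type, potency, confidence), target
metadata and a protein-class hierarchy, the package selects a fixed-size
molecule subset that trades off three coverage criteria, then patches any
remaining holes in the target space.

## Bioactivity filtering

A molecule–protein pair qualifies when at least one record satisfies all
five predicates: measure ∈ {Ki, IC50}; assay type B (binding); confidence
score exactly 9 (direct single-protein assignment); species ∈ {human,
rat, mouse}; potency strictly below `potency_threshold_nM` (default
1000 nM, i.e. "below 1 µM" — records at exactly 1000 nM are excluded;
the boundary is configurable but strict by default). Values must arrive
already standardised to nM: rows in other units are rejected by the
reader rather than silently converted, because unit conversion belongs to
the upstream standardisation step and silent guessing invites
order-of-magnitude errors. Multiple qualifying records collapse to the
minimum potency, giving a single activity edge per pair.

Species orthologs (e.g. a human and a rat serotonin receptor) share one
species-agnostic protein entry (UI); all counting — promiscuity, matrix
columns, coverage objectives — happens in UI space so that a molecule
measured against three species is not triple-counted.

## Scaffold tree

Level 1 is the Murcko framework: all terminal side chains removed, with
exocyclic double bonds retained when their ring-side atom is a ring atom
(the carbonyl of an oxindole stays; an amide C=O on an acyclic linker
does not — the chain is a side chain by this definition). Stereochemistry
is stripped first: scaffold identity here is 2-D chemotype identity.

Each deeper level removes exactly one ring until a single ring remains,
so a molecule whose framework has *R* rings yields a chain of length *R*.
Candidate removals are those that delete the atoms exclusive to one
smallest-set-of-smallest-rings ring and leave a connected scaffold with
exactly one ring fewer (dangling linkers are re-pruned). Among valid
candidates a fixed cascade decides which ring goes: fewest heteroatoms
first (heteroaromatic cores are the characteristic part of a chemotype),
then largest ring, then fewest attachment bonds (peripheral before
fused), with the lexicographically smallest resulting canonical SMILES as
the final tie-break. The cascade is a deliberately compact variant of the
published scaffold-tree prioritisation rules; it shares their intent —
keep the most characteristic core — while remaining small enough to
verify exhaustively, and the final SMILES tie-break makes decomposition
byte-reproducible across runs and platforms.

Two implementation notes. Ring perception uses the cyclomatic number and
a greedy minimum cycle basis (shortest cycle through each non-bridge
edge, GF(2) independence), which equals the SSSR count on molecular
graphs. When a subgraph is written back to SMILES, bonds of kept rings
whose atoms are all aromatic are emitted as aromatic bonds, and aromatic
nitrogens that lost an exocyclic substituent regain an explicit H —
otherwise deleting one ring of a fused aromatic system would leave a
stale Kekulé pattern (cyclohexadiene instead of benzene) or an
unkekulizable azole.

Selection operates at level 2 (`scaffold_level`): level-1 frameworks are
too specific (every analogue series is its own scaffold), while the
terminal single ring is too generic (benzene would absorb half of
medicinal chemistry). Molecules whose framework has a single ring have no
level-2 scaffold; they are excluded from clustering but remain eligible
for coverage completion. Scaffolds linked to more than
`max_targets_per_scaffold` (6) protein entries are removed as
promiscuous.

## Clustering and representatives

The binary scaffold × UI matrix (1 = some retained molecule with that
scaffold is bioactive on that entry) is clustered agglomeratively on the
Jaccard distance — computed with R's `dist(method = "binary")`, whose
definition `d = (b + c)/(a + b + c)` ignores shared absences, the right
behaviour for sparse bioactivity profiles. Linkage is UPGMA (average) by
default, the standard choice for binary fingerprint profiles; complete
and Ward linkage are configurable. The dendrogram is cut to
`n_clusters`; the orchestrator caps the cut at the number of available
scaffolds so small inputs still run, while the clustering function itself
treats an oversized k as a configuration error.

One scaffold represents each cluster, chosen by a four-step cascade: the
cluster medoid (minimal summed Jaccard distance to co-members — the
reference point of "lowest distance" is interpreted as the medoid; the
centroid of a binary Jaccard space is not itself a profile), then the
scaffold hitting the most targets, then the one carried by the most
molecules, then the lexicographically smallest scaffold SMILES. The last
step turns "take any of the remaining" into a deterministic rule, which
also makes representative choice invariant to cluster member order.

## Pareto subset selection

All bioactive molecules linked to representative scaffolds form the
candidate pool. A subset of `subset_size` molecules is scored by three
maximised objectives:

* **O1** — distinct protein entries covered. The alternative reading
  (sum of per-molecule target counts) is deliberately not the default:
  repeated hits are rewarded separately by O3, and coverage of distinct
  biology is the quantity a screening deck is judged on.
* **O2** — distinct representative scaffolds present (chemotype
  diversity).
* **O3** — total hits divided by O1, the mean number of subset molecules
  per covered entry (assay redundancy; defined as 0 for an empty
  subset).

Subsets evolve under an elitist non-dominated-sorting genetic algorithm:
fast non-dominated sort into Pareto fronts, crowding distance within
fronts, binary-tournament parent selection on (rank, crowding), union
crossover repaired to fixed size, and in/out swap mutation with
`ga_mutation_rate` expected swaps per individual (Poisson). Parents and
offspring compete jointly, so the best coverage never degrades. One
individual of the initial population is seeded with a deterministic
greedy maximum-coverage subset (ties by index, remainder filled by total
hit count); the other individuals are uniform random. The memetic seed
gives the search a coverage-optimal anchor that elitism preserves —
random initialisation alone wastes most of a short run rediscovering
easy coverage. Full-scale defaults are 1000 subsets × 600 generations;
the packaged analyses and tests run desk-scale sizes (population 40,
60 generations, subsets of 30–50 from pools of a few hundred), which
complete in seconds while exercising the identical code path.

The final subset maximises (O1, O2, O3) lexicographically over the first
front, ties broken by subset creation order; with `rng_seed` fixed the
entire selection is bit-reproducible.

## Coverage completion

Restricting the main path to protein entries with a level-1 protein
class, plus finite subset size, leaves some entries uncovered. For each
entry with at least one bioactive candidate but no selected compound,
the completion step appends the candidate whose selection-level scaffold
is shared by the most pool molecules — the compound that stands in for
the largest chemical series — with ties resolved by higher target count,
then smallest InChIKey. Completion draws on all filtered bioactive
molecules, including single-ring ones without a level-2 scaffold and
those on unclassified proteins; it never removes a selected compound.
Entries with no qualifying bioactivity anywhere are reported as
uncoverable rather than failed.

## Term enrichment

Per compound, each GO/KEGG/DO term overlapping the compound's bioactive
protein entries by at least `min_term_overlap` (2) is reported with a
hypergeometric upper-tail p-value (`phyper`) against the namespace's
annotated universe (all UI annotated in that namespace by default;
configurable). Bonferroni multiplies by the number of terms of the
namespace annotated in the universe — the whole test family — not by the
number of terms that happened to reach the overlap threshold:
conditioning the family on an observed overlap of ≥ 2 inflates the
familywise error well above the nominal cutoff (simulations in the test
suite measure roughly 3–4× at cutoff 0.1), whereas family-wide
Bonferroni controls it by construction. The overlap threshold is purely
a reporting condition. Namespaces are adjusted separately, mirroring the
practice of running separate enrichment tools per ontology. The default
cutoff on adjusted p-values is 0.1.

## Morphological profiles

Cell Painting profiles arrive as a wide table of compounds × features
(1–8 replicates per compound), each feature tagged by its compartment
via the CellProfiler-style name prefix (cell / cytoplasm / nuclei).
Replicates are averaged arithmetically with missing values ignored.
Within each compartment independently, zero-variance features are
dropped first (their correlation is undefined), then features are
scanned in input column order and kept only if their absolute Pearson
correlation with every already-kept feature is below `corr_threshold`
(0.95). Greedy keep-first filtering is order-dependent by design — the
input column order is the canonical order and is what makes the
surviving set reproducible; the result is invariant to compound (row)
order but not to column permutation, which is documented rather than
hidden. Profiled compounds join the network by exact 27-character
InChIKey match (a connectivity-block-only match is available for salt
tolerance).

## Property-graph export

The full pharmacology network — molecules, compound names, assay
results and parameters, species targets, protein entries, the protein
class hierarchy, scaffolds with their parent chains, annotation terms
and per-compartment morphology descriptors — serialises to GraphML or
to Neo4j bulk-import CSV (one node file per label with `:ID`/`:LABEL`
headers, one edge file per relation type with `:START_ID`/`:END_ID`/
`:TYPE`). Node ids are namespaced by label so a molecule and a scaffold
with identical raw ids cannot collide; import of either format
reproduces the bundle exactly, which the tests verify as a round-trip
identity. No database server is involved.

## Synthetic data: what it shows and what it does not

The generator emulates every input at desk scale: ~300 molecules built
by decorating 15 curated 2–4-ring template scaffolds with removable side
chains (so level-1 identity is known by construction), 40 protein
entries realised as 1–3 species targets each, log-normal potencies
around per-family means (geometric means 20–400 nM, sdlog 0.8),
per-predicate corrupted records (wrong assay type, confidence 8,
over-threshold and exact-boundary potencies, off-species, EC50), a
3-level protein-class tree with 10% of entries lacking a level-1 class,
planted enriched terms holding a compound's full target set, and
Gaussian morphology features with planted constants and collinear pairs
over 1–8 replicates. Everything derives from one seed and is
byte-reproducible.

Passing tests on this material demonstrates correctness of the
machinery — predicate logic including boundaries, exact truth recovery,
chain bookkeeping, GA reproducibility and coverage, FWER control — not
performance on real data: real ChEMBL chemistry has charged and
polycyclic structures far beyond the template set, real potency noise is
heteroscedastic and assay-dependent, real annotation terms overlap
heavily rather than being near-disjoint, and real Cell Painting features
have block covariance rather than isolated collinear pairs. Full-scale
behaviour (tens of thousands of scaffolds, 5000-compound subsets) is a
matter of the same code run with the full-scale configuration defaults
and corresponding compute.

## Parameter summary

| parameter | default | meaning |
|---|---|---|
| `potency_threshold_nM` | 1000 | strict upper potency bound (nM) |
| `allowed_measures` | Ki, IC50 | qualifying measure types |
| `required_assay_type` | B | binding assays only |
| `required_confidence` | 9 | exact ChEMBL confidence score |
| `allowed_species` | human, rat, mouse | qualifying species |
| `scaffold_level` | 2 | scaffold-tree level used for selection |
| `max_targets_per_scaffold` | 6 | promiscuity pruning bound |
| `n_clusters` | 5000 | dendrogram cut (capped at row count by the orchestrator) |
| `linkage` | average | UPGMA agglomeration |
| `subset_size` | 5000 | library subset evolved by the GA |
| `ga_population` | 1000 | subsets per generation |
| `ga_iterations` | 600 | generations |
| `ga_mutation_rate` | 0.1 | expected swaps per individual |
| `corr_threshold` | 0.95 | absolute Pearson redundancy bound |
| `p_cutoff` | 0.1 | Bonferroni-adjusted significance cutoff |
| `min_term_overlap` | 2 | reporting condition for terms |
| `rng_seed` | 1 | seed for all stochastic steps |

## Known limitations

* The ring-removal cascade is a compact stand-in for the full published
  scaffold-tree rule set; on complex fused systems the two can retain
  different rings (both deterministically).
* Aromaticity bookkeeping assumes rings whose atoms are all aromatic are
  aromatic rings; exotic systems such as biphenylene would be
  mis-marked.
* The GA provides no optimality certificate; the greedy seed guarantees
  only coverage-greedy quality as a floor.
* Exact reproduction of published per-compartment feature counts from
  real Cell Painting data depends on the (unstated) elimination order of
  the original analysis; the greedy order here is canonical but not
  guaranteed to match other implementations.
* Graph export holds the whole bundle in memory; it targets desk- to
  mid-scale networks, not billion-edge graphs.
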