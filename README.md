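# pancore

Comparative genomics for small sets of closely related bacterial isolates —
the analysis a microbiologist runs after assembling and annotating a handful
of new strains and asking: *which species are these, what do they share with
their relatives, and what is private to them?*

`pancore` implements the four standard answers as one tested R pipeline:

* **Core-genome** — orthologs as *bidirectional best hits* (BBH) between a
  pivot proteome and every other strain under end-gap-free (semi-global)
  affine alignment; hits below 40% (genus) / 80% (species) amino-acid
  similarity, or differing by more than 20% in protein length, are
  discarded; an optional positional filter keeps only orthologs consistent
  with conserved gene order. The core is the intersection across strains,
  reported also as a percentage of the smallest proteome.
* **Pan-genome** — all-against-all local alignments become homology edges
  when identity ≥ 40%/80%, the alignment covers ≥ 80% of the smallest
  protein, and E = K·m·n·e^(−λS) < 10⁻⁴; families are the single-linkage
  clusters (connected components), swept over thresholds 40/50/70/80%.
* **ANIb** — the query genome is cut into 1020-nt fragments, each fragment's
  best local hit in the subject (both strands) is kept if it reaches 30%
  identity over 70% of the fragment, and the average nucleotide identity is
  the mean hit identity; > 95% ANI indicates conspecificity.
* **Gene content and tree** — family presence/absence matrices, three-way
  Venn partitions, per-gene identity tables with 1/0 presence flags, and a
  neighbor-joining tree from mean core-ortholog p-distances
  (d = 1 − mean identity) written as Newick.

A seeded synthetic pan-genome generator (`simulate_pangenome()`) produces
genomes, proteomes, gene orders and full ground truth — family memberships,
the true core, the true ortholog map, realized divergences — so the whole
pipeline is exercised end-to-end without downloading assemblies. The
alignment engines are exact dynamic programs in C++; parsing, translation,
graph components and neighbor joining go through Biostrings, igraph and ape.

## Worked example

Simulate a three-strain species-like set at 2% pairwise nucleotide
divergence and run the main stages:

```r
library(pancore)

sim <- simulate_pangenome(sim_params(n_strains = 3, n_core_families = 25,
                                     n_accessory_families = 10,
                                     divergence = 0.02, seed = 42))

core <- core_genome(sim$proteomes[[1]], sim$proteomes[-1],
                    level_params("species")$filter)
core
#> CoreGenome: pivot S01 - 24 core genes across 3 strains
core_coverage_percent(length(core$core_members), core$smallest_proteome)
#> [1] 83

pangenome_summary(sim$proteomes, identity_thresholds = c(40, 80))
#>   identity_min n_families
#> 1           40         35
#> 2           80         35

m <- anib_matrix(sim$genomes[1:2])
m
#> ANIb matrix (rows = query, %):
#>      subject
#> query    S01    S02
#>   S01 100.00  97.96
#>   S02  97.95 100.00
classify_species(m)
#>     strain_a strain_b ani_mean verdict
#> S01      S01      S02   97.955    same

nj_tree(core_distance_matrix(core, core_pair_identities(core, sim$proteomes)))
#> [1] "(S03:0.0204409921361145,S02:0.0224759171360255,S01:0.0212773149354252);"
```

Reading the output: 24 of the 25 planted core families survive the strict
species filters (one gene was relocated by the simulator and is dropped by
the positional filter), covering 83% of the smallest proteome; all 35
planted families are recovered at both pan-genome thresholds; the
directional ANIb values sit at 97.96/97.95 against the designed
100·(1−0.02) = 98, so the pair is called the same species; and the NJ tree
places the three strains at p-distances matching the designed divergence.

`run_pipeline(pipeline_config(manifest, level = "species", outdir = "out"))`
runs every stage on FASTA/TSV inputs listed in a manifest and writes the
tables plus a JSON summary; the numbered scripts under `analysis/` drive the
same functions over two simulated study trios (simulate → core → pan → ANI →
gene content → tree) and write their tables under `results/`.

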