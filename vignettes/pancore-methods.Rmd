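---
title: "Methods: core/pan-genome construction, ANIb and the synthetic pan-genome"
author: "pancore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core/pan-genome construction, ANIb and the synthetic pan-genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancore)
```

# Scope

`pancore` implements a comparative-genomics workflow for small sets of
closely related bacterial isolates: a **core-genome** anchored on a pivot
strain via bidirectional best hits (BBH) under end-gap-free protein
alignment, a **pan-genome** by single-linkage clustering of local-alignment
homology edges, **ANIb** species assignment over genome fragments, gene
presence/absence reporting, and a distance-based neighbor-joining tree. A
seeded simulator generates complete synthetic study sets with ground truth,
so every stage is testable without downloading assemblies.

# Pairwise alignment

Two affine-gap dynamic programs (Gotoh) back everything; a gap of length
$L$ costs $\text{open} + L\cdot\text{ext}$.

* **End-gap-free (semi-global / "overlap")** alignment for orthology: a
  global alignment in which leading and trailing overhangs are free. The DP
  starts for free on an edge of either sequence and ends for free on an
  edge; a trailing *charged* gap run in one sequence followed by a free
  overhang of the other is a legal ending and is included in the final
  maximum. This suits full-length proteins of slightly different lengths:
  identity and similarity are measured over (essentially) the whole shorter
  protein rather than over an arbitrary high-scoring island.
* **Local (Smith-Waterman)** alignment for pan-genome homology and ANIb
  fragments. Nucleotide mode searches both subject strands; a minus-strand
  hit reports its span in plus-strand coordinates. A best score of zero or
  less is a *no-hit*.

Scoring defaults mirror the defaults of the standard protein search tools:
BLOSUM62 with gap open 11 / extend 1 for proteins, and match +2 /
mismatch −3 with gap open 5 / extend 2 for nucleotides. The ambiguity
residues `X` and `N` score −1 / −3 against everything (themselves included)
and never count as identical or similar: assemblies contain ambiguity
codes, and treating them as matches would inflate identity.

Reported statistics cover the aligned region only (first to last aligned
residue pair, interior gaps included). **Identity** is the percentage of
aligned columns with exactly matching residues; **similarity** the
percentage with a positive substitution score. Both use the aligned columns
as denominator, free terminal gaps excluded — the conventional reading when
both words are used side by side.

E-values use the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with the
published gapped constants ($\lambda = 0.267$, $K = 0.041$ for BLOSUM62
11/1; $\lambda = 0.625$, $K = 0.41$ for the nucleotide scheme). By default
$n$ is the summed length of all proteins in the analysis (database-style
search space); a pairwise option exists because the choice is a convention,
not a fact about the data.

**Determinism.** Ties among co-optimal alignments are broken by preferring
the diagonal move, then the query-consuming gap; among co-optimal end
cells, by a substitution-column ending, then the smallest subject and query
end coordinates. Identical inputs therefore always produce identical
results, down to the spans.

# Core-genome (BBH orthology)

For each non-pivot strain, every pivot protein is matched to its
highest-scoring target under the end-gap-free alignment (ties: higher
identity, then lexicographically smaller id), and vice versa; mutual pairs
are orthologs. Pairs are then discarded when percent similarity falls below
the level threshold — **40%** for genus-level sets, **80%** within species —
or when protein lengths differ by more than **20%** of the longer protein
(the symmetric, strictest reading of "20% difference"). Filtering happens
after best-hit determination, matching the "hits … were discarded"
protocol. The core-genome is the intersection: pivot proteins with a
retained ortholog in every strain. Coverage is reported as
`round(100 * core / smallest_proteome)` (halves away from zero), the
"percent of the smallest proteome" statistic.

The **positional filter** encodes the expectation that same-species genomes
are nearly collinear: a pair survives iff, on each side of the pivot gene,
at least one of its $w$ nearest neighbors has its own ortholog within $w$
positions of the partner gene. A side with no orthologous neighbor imposes
no constraint, so $w \geq$ proteome size is the identity. Defaults: off at
genus level ($w = 0$), $w = 5$ within species, where the synteny reasoning
applies. The pivot is configurable and defaults to the first strain listed.

# Pan-genome (single-linkage families)

All protein pairs — across *and within* strains, so families may contain
paralogs — are compared with the local aligner. A pair is a homology edge
iff identity $\geq$ the level threshold (40% genus / 80% species), the
aligned span covers $\geq 80\%$ of the *shorter* protein (measured on its
unaligned length), and the e-value is $< 10^{-4}$. Thresholds are inclusive
for "at least" wordings and exclusive for "smaller than". Families are the
connected components of the edge graph — a protein joins a family if it is
homologous to any current member — and are named by their smallest member
id. Because raising the identity threshold only removes edges, family
counts are non-decreasing in the threshold; the threshold sweep
(40/50/70/80%) reports that curve. A score cutoff derived from the e-value
threshold prunes pairs before traceback; since the e-value is monotone in
the score this cannot change the edge set.

# ANIb

The query genome is cut into consecutive non-overlapping **1020-nt**
fragments per replicon (a trailing piece is kept iff $\geq$ 100 nt). Each
fragment's best local alignment in the subject is found — both strands, one
hit per fragment, ties resolved toward the lowest subject coordinate — and
kept iff identity $\geq 30\%$ and the alignment covers $\geq 70\%$ of the
fragment. ANIb is the unweighted mean identity of kept hits, rounded to two
decimals; the matrix is directional and need not be symmetric. The diagonal
is reported as 100.00 (a value, even where display conventions print a
dash). Two strains are called conspecific when the mean of their two
directional values exceeds **95%**; a missing direction or an exact tie is
undetermined.

The fragment search uses exact 15-mer seeds to locate candidate diagonals
(up to 3 per strand, windows padded by 200 nt) and then aligns the fragment
against each candidate window with the exact local DP. At the divergences
where ANIb is meaningful (hits must reach 30% identity) a surviving exact
seed among ~16 per fragment is essentially guaranteed, and windows padded
beyond the maximal drift of qualifying alignments make the seeded search
agree with a full scan on all suites we exercise; it is a scan strategy,
not an approximation knob.

# Distance tree

For every strain pair, the identity fractions of their core orthologs
(pivot anchoring maps a core gene to its member in each strain) are
averaged and $d = 1 - \overline{\text{identity}}$ taken as a p-distance.
Neighbor joining (via `ape`) turns the matrix into an unrooted tree; on an
additive matrix the reconstruction is exact to floating-point precision
(Newick output carries 15 significant digits to preserve this). Negative
branches, possible on non-additive input, are clamped to zero with the
deficit moved to the sibling branch, preserving path lengths through the
parent. Q-criterion ties are resolved by `ape`'s deterministic
implementation. This stage is an explicit *substitute* for a
concatenated-alignment maximum-likelihood phylogeny: it preserves the
grouping structure (conspecific strains cluster) but its branch lengths are
mean protein p-distances, not substitutions per site under a model.

# The synthetic pan-genome generator

The simulator emulates exactly the structure the analysis assumes:

* **Families.** Ancestor genes are random sense-codon sequences (lognormal
  length, mean 300 codons, `sdlog` 0.25, minimum 50 — a realistic bacterial
  gene-length spread). Core families go to every strain; each accessory
  family is present per strain with probability 0.5, re-drawn if it lands
  in all strains or none, so truth labels stay unambiguous.
* **Divergence.** `divergence` ($d$) is the designed **pairwise** per-site
  substitution fraction. Every strain is mutated independently from the
  ancestor with per-branch probability $b$ solving
  $2b(1-b) + \tfrac{2}{3}b^2 = d$ (substitutions uniform over the three
  alternative bases), which makes every strain pair differ at a fraction
  $d$ of sites in expectation — the calibration the ANI suite relies on:
  indel-free, so `expected_ani(d) = 100(1-d)` exactly. Mutations creating
  an in-frame stop are re-drawn within the codon, keeping proteomes valid
  translations.
* **Scales.** Uniform per-site substitutions on random codons convert to
  amino-acid divergence at roughly 2.1 amino-acid % per nucleotide %
  (most single-nucleotide changes are nonsynonymous). Orthology-recovery
  suites are therefore parameterized by the *amino-acid* divergence they
  target — e.g. a 10% amino-acid regime uses $d = 0.048$ — while ANI suites
  speak nucleotide. The recovery tests measure the realized amino-acid
  divergence and assert it sits in the designed band, so the regime is
  explicit rather than implied.
* **Structure.** Genes are laid out in a shuffled ancestor order shared by
  all strains; each gene relocates with probability 0.01 per strain
  (occasional rearrangement); genes are joined by per-family intergenic
  spacers (50–200 nt) mutated at the same rate. An optional small-indel
  mode (geometric lengths, mean 2 nt) perturbs spacers only — coding frames
  are never disrupted — and is off by default so the ANI relation stays
  exact.
* **Truth and determinism.** The truth object records family memberships,
  the core set, the ortholog map per strain pair, and realized divergences
  per gene and genome-wide. All draws run through R's seeded generator;
  identical parameters give identical output.

What the simulator does *not* model — real codon usage, transition bias,
recombination, horizontal transfer, gene duplication, assembly artifacts —
bounds what green tests mean: they demonstrate that the pipeline recovers
planted structure under the stated noise model, not that thresholds tuned
for *Acinetobacter*-scale data generalize to arbitrary genera.

# Numerical and design choices

* Rounding: coverage percents round half away from zero; ANI to two
  decimals (display conventions of the tables they mirror).
* `read_fasta` treats the first whitespace token as the id (stable join
  key); descriptions are carried but never used as keys.
* Empty alignments (every substitution column negative) report score 0 and
  undefined (NA) identity; such pairs can never pass a similarity filter.
* The ANIb e-value is not used as a hit filter (identity and coverage are),
  matching the fragment-search convention.
* `run_pipeline` validates every manifest path before any computation and
  labels failures with the stage that raised them; identical configurations
  produce byte-identical reports.

# Problem sizes in the test suites

The suites are sized for a single CPU: exhaustive path-enumeration oracles
up to length 5, an independent matrix-form Gotoh check on all two-letter
pairs to length 5 and random pairs to length 8, 100 random 200-protein
edge sets against a union–find oracle, three-strain simulations with 45
gene families for recovery/Venn suites, and 240-family (~250 kb) genome
pairs giving 230+ fragments per direction for the ANI calibration at
$d \in \{0.01, 0.02, 0.032, 0.05\}$. The binomial error of a mean identity
over 200+ kb is far below the 0.3-point acceptance band, so those bands
test the method, not sampling luck.

# Known limitations

* BBH is one-to-one by construction: in-paralogs attach to families in the
  pan-genome stage but are invisible to the core-genome mapping.
* The positional filter intentionally drops genes relocated away from
  their conserved neighborhood; on simulations with rearrangement enabled
  the recovered core can sit a family or two below the planted count.
* The seeded ANI scan can miss hits between sequences diverged far beyond
  the regime where ANIb is interpretable (no exact 15-mer survives); such
  pairs are reported NA rather than with a value.
* Distances for the tree stage are protein p-distances; they saturate at
  high divergence and are not substitution-model corrected.
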