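# Shared helpers for the analysis drivers: where the simulated study sets
# live and how to load them back through the package's standard readers.

suppressPackageStartupMessages(library(pancore))

DATA_DIR <- "results/data"
OUT_DIR <- "results/analysis"
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)

# Two species-like study trios: a tight one at pairwise nucleotide
# divergence 0.02 (ANI ~ 98, an A. radioresistens-like regime) and a looser
# one at 0.032 (ANI ~ 96.8, an A. modestus-like regime).
TRIOS <- list(
  trioA = list(divergence = 0.020, seed = 4001),
  trioB = list(divergence = 0.032, seed = 4002)
)

load_trio <- function(name) {
  man <- read_tsv(file.path(DATA_DIR, name, "manifest.tsv"))
  proteomes <- list()
  genomes <- list()
  for (k in seq_len(nrow(man))) {
    st <- man$strain[k]
    prot <- read_fasta(man$proteome_fasta[k], "protein")
    ord <- read_tsv(man$gene_order_tsv[k])
    proteomes[[st]] <- proteome(st, prot,
                                gene_order = ord[match(prot$id, ord$id),
                                                 c("replicon", "rank")])
    genomes[[st]] <- genome_seq(st, read_fasta(man$genome_fasta[k], "nucleotide"))
  }
  list(proteomes = proteomes, genomes = genomes,
       truth = jsonlite::read_json(file.path(DATA_DIR, name, "truth.json")))
}
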