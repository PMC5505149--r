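#!/usr/bin/env Rscript
# Gene-content analytics: three-way Venn partition of the pan-genome families
# and the per-gene identity report for each trio's first strain pair.

source("analysis/common.R")

for (name in names(TRIOS)) {
  trio <- load_trio(name)
  ps <- trio$proteomes
  universe <- sort(unlist(lapply(ps, function(p) global_id(p$strain_id,
                                                           p$proteins$id))))
  cl <- cluster_families(homology_edges(ps, identity_min = 80), universe)
  pa <- presence_absence(cl, ps)
  v <- venn_partition(pa, names(ps))
  write_tsv(data.frame(region = names(v), n_families = as.integer(v)),
            file.path(OUT_DIR, paste0(name, "_venn.tsv")))
  cat(name, "Venn regions:\n"); print(unclass(v))

  pairs <- bbh_orthologs(ps[[1]], ps[[2]], level_params("species")$filter)
  rep_tab <- pairwise_gene_identity_report(ps[[1]], ps[[2]], pairs)
  write_tsv(rep_tab, file.path(OUT_DIR, paste0(name, "_gene_identity.tsv")))
  shared <- rep_tab$identity_pct[!is.na(rep_tab$identity_pct)]
  cat(sprintf("  %s vs %s: %d shared genes, mean identity %.1f%%; %d one-sided\n",
              names(ps)[1], names(ps)[2], length(shared), mean(shared),
              sum(is.na(rep_tab$identity_pct))))
}
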