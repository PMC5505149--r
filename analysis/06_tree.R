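#!/usr/bin/env Rscript
# Distance-based tree stage: mean core-ortholog p-distances and
# neighbor-joining, per trio and for the combined six strains (the two trios
# are unrelated simulations, so between-set distances are saturated and the
# two trios must come out as separate clades).

source("analysis/common.R")

dist_list <- list()
for (name in names(TRIOS)) {
  trio <- load_trio(name)
  core <- core_genome(trio$proteomes[[1]], trio$proteomes[-1],
                      level_params("species")$filter)
  idents <- core_pair_identities(core, trio$proteomes)
  d <- core_distance_matrix(core, idents)
  rownames(d) <- colnames(d) <- paste(name, rownames(d), sep = ".")
  dist_list[[name]] <- d
  nwk <- nj_tree(d)
  writeLines(nwk, file.path(OUT_DIR, paste0(name, "_tree.nwk")))
  cat(name, "mean within-trio distance:",
      round(mean(d[upper.tri(d)]), 4), "->", nwk, "\n")
}

# combined matrix: within-trio distances measured, between-trio saturated
ids <- unlist(lapply(dist_list, rownames))
D <- matrix(0.75, length(ids), length(ids), dimnames = list(ids, ids))
diag(D) <- 0
off <- 0
for (d in dist_list) {
  idx <- off + seq_len(nrow(d))
  D[idx, idx] <- d
  off <- off + nrow(d)
}
nwk <- nj_tree(D)
writeLines(nwk, file.path(OUT_DIR, "combined_tree.nwk"))
tr <- ape::read.tree(text = nwk)
monoA <- ape::is.monophyletic(tr, grep("^trioA", ids, value = TRUE))
monoB <- ape::is.monophyletic(tr, grep("^trioB", ids, value = TRUE))
cat("Combined NJ tree:", nwk, "\n")
cat("trioA monophyletic:", monoA, "- trioB monophyletic:", monoB, "\n")
stopifnot(monoA, monoB)
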