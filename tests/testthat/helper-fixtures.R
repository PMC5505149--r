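# Shared simulated data sets, built once per test run.

.fix_cache <- new.env(parent = emptyenv())

.fix_get <- function(key, build) {
  if (!exists(key, envir = .fix_cache)) assign(key, build(), envir = .fix_cache)
  get(key, envir = .fix_cache)
}

# noise-free 3-strain set: 30 core + 15 accessory families
fix_sim_d0 <- function() {
  .fix_get("sim_d0", function() {
    simulate_pangenome(sim_params(n_strains = 3, n_core_families = 30,
                                  n_accessory_families = 15, divergence = 0,
                                  seed = 101))
  })
}

# species-level divergence: ~10% amino-acid divergence between strain pairs
# (nucleotide substitution fraction 0.048; uniform per-site substitutions on
# random codons convert to amino-acid divergence at ~2.1x)
fix_sim_aa10 <- function() {
  .fix_get("sim_aa10", function() {
    simulate_pangenome(sim_params(n_strains = 3, n_core_families = 30,
                                  n_accessory_families = 15, divergence = 0.048,
                                  seed = 202))
  })
}

# deeper divergence for the threshold sweep (families split at strict cutoffs)
fix_sim_d15 <- function() {
  .fix_get("sim_d15", function() {
    simulate_pangenome(sim_params(n_strains = 3, n_core_families = 12,
                                  n_accessory_families = 6, divergence = 0.15,
                                  seed = 303))
  })
}

fix_core_d0 <- function() {
  .fix_get("core_d0", function() {
    sim <- fix_sim_d0()
    core_genome(sim$proteomes[[1]], sim$proteomes[-1],
                filter_params(80, 0.20, 0))
  })
}

# true ortholog pairs for one strain pair as "gene_a gene_b" keys
truth_pair_keys <- function(sim, sa, sb) {
  tm <- sim$truth$ortholog_map
  tm <- tm[tm$strain_a == sa & tm$strain_b == sb, ]
  paste(tm$gene_a, tm$gene_b)
}

# small deterministic proteome from explicit sequences
mk_proteome <- function(strain, seqs, order = NULL) {
  proteome(strain,
           data.frame(id = names(seqs), description = "",
                      sequence = unname(seqs), stringsAsFactors = FALSE),
           gene_order = order)
}

.pan_uni_ids <- function(ps) {
  unlist(lapply(ps, function(p) global_id(p$strain_id, p$proteins$id)))
}
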