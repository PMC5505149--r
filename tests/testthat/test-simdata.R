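test_that("simulation is deterministic under a fixed seed", {
  p <- sim_params(n_strains = 3, n_core_families = 8, n_accessory_families = 4,
                  divergence = 0.05, seed = 13)
  s1 <- simulate_pangenome(p)
  s2 <- simulate_pangenome(p)
  expect_identical(s1$genomes[[2]]$replicons$sequence,
                   s2$genomes[[2]]$replicons$sequence)
  expect_identical(s1$proteomes[[3]]$proteins, s2$proteomes[[3]]$proteins)
  expect_identical(s1$truth$ortholog_map, s2$truth$ortholog_map)

  s3 <- simulate_pangenome(sim_params(n_strains = 3, n_core_families = 8,
                                      n_accessory_families = 4,
                                      divergence = 0.05, seed = 14))
  expect_false(identical(s1$genomes[[1]]$replicons$sequence,
                         s3$genomes[[1]]$replicons$sequence))
})

test_that("zero divergence gives byte-identical core genes across strains", {
  sim <- fix_sim_d0()
  for (fam in sim$truth$core_families) {
    members <- sim$truth$families[[fam]]
    seqs <- vapply(names(members), function(st) {
      p <- sim$proteomes[[st]]
      p$proteins$sequence[p$proteins$id == members[[st]]]
    }, character(1))
    expect_equal(length(unique(seqs)), 1L)
  }
})

test_that("realized pairwise divergence matches the design within binomial bounds", {
  sim <- simulate_pangenome(sim_params(n_strains = 2, n_core_families = 120,
                                       n_accessory_families = 1,
                                       divergence = 0.02, seed = 15))
  dg <- sim$truth$divergence_genome
  expect_gte(dg$n_sites, 100000)
  bound <- 3 * sqrt(0.02 * 0.98 / dg$n_sites)
  expect_lt(abs(dg$divergence - 0.02), bound)
})

test_that("accessory families are present in some but never all strains", {
  sim <- fix_sim_d0()
  acc <- setdiff(names(sim$truth$families), sim$truth$core_families)
  n_present <- lengths(sim$truth$families[acc])
  expect_true(all(n_present >= 1 & n_present <= 2))
  expect_true(all(lengths(sim$truth$families[sim$truth$core_families]) == 3))
})

test_that("simulated proteins contain no stop codons and match their genes", {
  sim <- fix_sim_aa10()
  for (p in sim$proteomes) {
    expect_false(any(grepl("\\*", p$proteins$sequence)))
    expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", p$proteins$sequence)))
  }
  # genome = genes plus intergenic spacers, so it is strictly longer than
  # the coding complement alone
  for (st in names(sim$genomes)) {
    coding <- 3 * sum(nchar(sim$proteomes[[st]]$proteins$sequence))
    expect_gt(nchar(sim$genomes[[st]]$replicons$sequence), coding)
  }
})

test_that("expected ANI is the complementary substitution rate", {
  expect_equal(expected_ani(0), 100)
  expect_equal(expected_ani(0.02), 98)
  expect_equal(expected_ani(0.032), 96.8)
  expect_error(expected_ani(0.6), "0.5")
  expect_error(sim_params(divergence = 0.7), "configuration")
})

test_that("written simulation files are valid pipeline inputs", {
  sim <- fix_sim_d0()
  dir <- file.path(tempdir(), "simout")
  manifest <- sim_write(sim, dir)
  expect_true(file.exists(manifest))
  man <- read_tsv(manifest)
  expect_equal(nrow(man), 3L)
  prot <- read_fasta(man$proteome_fasta[1], "protein")
  expect_equal(prot$sequence, sim$proteomes[[1]]$proteins$sequence)
  gen <- read_fasta(man$genome_fasta[1], "nucleotide")
  expect_equal(gen$sequence, sim$genomes[[1]]$replicons$sequence)
  ord <- read_tsv(man$gene_order_tsv[1])
  expect_equal(ord$id, sim$proteomes[[1]]$proteins$id)
})

test_that("the optional indel mode perturbs spacers but never coding frames", {
  p0 <- sim_params(n_strains = 2, n_core_families = 10,
                   n_accessory_families = 1, divergence = 0.02,
                   indel_prob = 0, seed = 16)
  p1 <- sim_params(n_strains = 2, n_core_families = 10,
                   n_accessory_families = 1, divergence = 0.02,
                   indel_prob = 0.02, seed = 16)
  s0 <- simulate_pangenome(p0)
  s1 <- simulate_pangenome(p1)
  expect_false(nchar(s1$genomes[[2]]$replicons$sequence) ==
                 nchar(s0$genomes[[2]]$replicons$sequence))
  for (pp in s1$proteomes) {
    expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", pp$proteins$sequence)))
  }
  # ANI still lands near the designed value: indels sit between fragments'
  # aligned blocks and hit filters keep qualifying fragments
  r <- anib_directional(s1$genomes[[1]], s1$genomes[[2]])
  expect_lt(abs(r$ani - expected_ani(0.02)), 1)
})
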