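test_that("best hit maximizes the semiglobal score with documented tie-breaks", {
  target <- mk_proteome("T", c(p1 = "MKVLWAAL", p2 = "MKVLWAAV", p3 = "GGGGGGGG"))
  bh <- best_hit("MKVLWAAL", target)
  expect_equal(bh$id, "p1")
  expect_equal(identity_pct(bh$aln), 100)

  # exact copy beats a single-substitution copy
  bh <- best_hit("MKVLWAAV", target)
  expect_equal(bh$id, "p2")

  # score tie between identical sequences -> lexicographically smaller id
  target2 <- mk_proteome("T", c(z9 = "MKVLW", a1 = "MKVLW"))
  expect_equal(best_hit("MKVLW", target2)$id, "a1")
})

test_that("best hit equals an explicit argmax over all semiglobal alignments", {
  set.seed(41)
  s <- scoring_protein()
  seqs <- setNames(vapply(sample(30:60, 20, replace = TRUE), random_seq,
                          character(1), chars = AA20),
                   sprintf("t%02d", 1:20))
  target <- mk_proteome("T", seqs)
  for (rep in 1:5) {
    q <- random_seq(45, AA20)
    scores <- vapply(seqs, function(x) align_semiglobal(q, x, s)$score, numeric(1))
    bh <- best_hit(q, target, s)
    expect_equal(bh$aln$score, max(scores))
    if (sum(scores == max(scores)) == 1L) {
      expect_equal(bh$id, names(seqs)[which.max(scores)])
    }
  }
})

test_that("bidirectional best hits pair a proteome perfectly with its copy", {
  sim <- fix_sim_d0()
  a <- sim$proteomes[[1]]
  b <- a
  b$strain_id <- "COPY"
  pairs <- bbh_orthologs(a, b, filter_params(80))
  expect_equal(nrow(pairs), nrow(a$proteins))
  expect_equal(pairs$gene_a, pairs$gene_b)
  expect_true(all(pairs$identity_pct == 100))
})

test_that("non-mutual best hits are excluded", {
  # b1 is the best hit of both a1 and a2, but b1's best hit is a2;
  # a1 therefore stays unpaired
  base <- "MKVLWAALLVTFLAGCQAKVEELKE"
  mut1 <- sub("KVEELKE$", "KVEELKD", base)   # 1 difference from base
  a <- mk_proteome("A", c(a1 = mut1, a2 = base))
  b <- mk_proteome("B", c(b1 = base))
  pairs <- bbh_orthologs(a, b, filter_params(40))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$gene_a, "a2")
})

test_that("bbh is symmetric under swapping the two proteomes", {
  sim <- fix_sim_aa10()
  a <- sim$proteomes[[1]]; b <- sim$proteomes[[2]]
  f <- filter_params(80)
  ab <- bbh_orthologs(a, b, f)
  ba <- bbh_orthologs(b, a, f)
  expect_setequal(paste(ab$gene_a, ab$gene_b), paste(ba$gene_b, ba$gene_a))
  # one-to-one on both sides
  expect_false(anyDuplicated(ab$gene_a) > 0)
  expect_false(anyDuplicated(ab$gene_b) > 0)
})

test_that("bbh recovers the simulated ortholog map at 10% amino-acid divergence", {
  sim <- fix_sim_aa10()
  pairs <- bbh_orthologs(sim$proteomes[[1]], sim$proteomes[[2]],
                         filter_params(80))
  got <- paste(pairs$gene_a, pairs$gene_b)
  tru <- truth_pair_keys(sim, "S01", "S02")
  expect_gte(mean(got %in% tru), 0.99)
  expect_gte(mean(tru %in% got), 0.99)
})

test_that("positional filter keeps collinear pairs and drops transposed ones", {
  ord <- function(ids) data.frame(id = ids, replicon = "chr",
                                  rank = seq_along(ids))
  pairs <- data.frame(gene_a = sprintf("a%d", 1:8),
                      gene_b = sprintf("b%d", 1:8),
                      stringsAsFactors = FALSE)
  a_order <- ord(sprintf("a%d", 1:8))

  # perfectly collinear: all kept at w = 1
  b_order <- ord(sprintf("b%d", 1:8))
  expect_equal(nrow(positional_filter(pairs, a_order, b_order, 1)), 8L)

  # b4 transposed to the far end of b; neighbors elsewhere stay collinear
  b_order2 <- ord(sprintf("b%d", c(1, 2, 3, 5, 6, 7, 8, 4)))
  kept <- positional_filter(pairs, a_order, b_order2, 2)
  expect_false("a4" %in% kept$gene_a)
  expect_true(all(setdiff(pairs$gene_a, "a4") %in% kept$gene_a))

  # w >= proteome size: identity
  expect_equal(positional_filter(pairs, a_order, b_order2, 8)$gene_a,
               pairs$gene_a)

  expect_error(positional_filter(pairs, NULL, b_order, 2), "w = 0")
})

test_that("core genome is the intersection of per-strain ortholog lists", {
  set.seed(51)
  seqs <- setNames(vapply(rep(40, 5), random_seq, character(1), chars = AA20),
                   sprintf("g%d", 1:5))
  p1 <- mk_proteome("P1", seqs)
  p2 <- mk_proteome("P2", seqs)
  p3 <- mk_proteome("P3", seqs)
  core <- core_genome(p1, list(p2, p3), filter_params(80))
  expect_equal(length(core$core_members), 5L)

  # deleting one protein from one strain shrinks the core by one
  p3b <- mk_proteome("P3", seqs[-3])
  core2 <- core_genome(p1, list(p2, p3b), filter_params(80))
  expect_equal(length(core2$core_members), 4L)
  expect_false("g3" %in% core2$core_members)

  expect_error(core_genome(p1, list(), filter_params(80)), "at least one")
})

test_that("noise-free simulation yields exact core recovery", {
  sim <- fix_sim_d0()
  core <- fix_core_d0()
  expect_equal(length(core$core_members), length(sim$truth$core_families))
  # every mapped ortholog matches the simulator's truth
  for (st in names(core$pair_tables)) {
    pt <- core$pair_tables[[st]]
    tru <- truth_pair_keys(sim, "S01", st)
    expect_true(all(paste(pt$gene_a, pt$gene_b) %in% tru))
  }
})

test_that("core size never grows when strains are added or thresholds raised", {
  sim <- fix_sim_aa10()
  f <- filter_params(80)
  core12 <- core_genome(sim$proteomes[[1]], sim$proteomes[2], f)
  core123 <- core_genome(sim$proteomes[[1]], sim$proteomes[2:3], f)
  expect_lte(length(core123$core_members), length(core12$core_members))

  strict <- core_genome(sim$proteomes[[1]], sim$proteomes[2:3],
                        filter_params(95))
  expect_lte(length(strict$core_members), length(core123$core_members))
})

test_that("core coverage percent reproduces the published arithmetic", {
  expect_identical(core_coverage_percent(2391, 2936), 81L)
  expect_identical(core_coverage_percent(2637, 3347), 79L)
  expect_identical(core_coverage_percent(0, 100), 0L)
  expect_identical(core_coverage_percent(1, 200), 1L)   # 0.5 rounds away from zero
  expect_identical(core_coverage_percent(3, 8), 38L)    # 37.5 -> 38
  expect_error(core_coverage_percent(10, 5), "core_count")
  expect_error(core_coverage_percent(1, 0), "positive")
})
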