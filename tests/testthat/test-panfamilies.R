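test_that("identical proteins form an edge with full identity and coverage", {
  set.seed(61)
  seq200 <- random_seq(200, AA20)
  p1 <- mk_proteome("A", c(x = seq200))
  p2 <- mk_proteome("B", c(y = seq200))
  edges <- homology_edges(list(p1, p2), identity_min = 80)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$identity_pct, 100)
  expect_equal(edges$coverage_smallest, 1.0)
  expect_lt(edges$evalue, 1e-4)
})

test_that("a shared domain covers the smallest protein fully", {
  set.seed(62)
  domain <- random_seq(150, AA20)
  other <- random_seq(160, AA20)
  p1 <- mk_proteome("A", c(single = domain))
  p2 <- mk_proteome("B", c(twodom = paste0(other, domain)))
  edges <- homology_edges(list(p1, p2), identity_min = 80)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$coverage_smallest, 1.0)
})

test_that("pairs below the identity threshold form no edge", {
  set.seed(63)
  base <- strsplit(random_seq(200, AA20), "")[[1]]
  mut <- base
  flip <- sample(200, 140)  # ~30% identity left
  mut[flip] <- vapply(mut[flip], function(ch) sample(setdiff(AA20, ch), 1), "")
  p1 <- mk_proteome("A", c(x = paste(base, collapse = "")))
  p2 <- mk_proteome("B", c(y = paste(mut, collapse = "")))
  edges <- homology_edges(list(p1, p2), identity_min = 40)
  expect_equal(nrow(edges), 0L)
  expect_error(homology_edges(list(p1, p2), identity_min = 0), "configuration")
  expect_error(homology_edges(list(p1, p2), identity_min = 40,
                              coverage_min = 1.5), "configuration")
})

test_that("single-linkage clustering is transitive over qualifying edges", {
  uni <- c("A", "B", "C", "D", "E", "F")
  edges <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "C"))
  cl <- cluster_families(edges, uni)
  expect_equal(sort(cl$families[["A"]]), c("A", "B", "C"))
  expect_equal(length(cl$families), 4L)  # {A,B,C} plus three singletons

  edges2 <- data.frame(protein_a = c("A", "C"), protein_b = c("B", "D"))
  cl2 <- cluster_families(edges2, uni)
  expect_equal(lengths(cl2$families)[c("A", "C")], c(A = 2L, C = 2L))

  expect_error(cluster_families(data.frame(protein_a = "A", protein_b = "Z"),
                                uni), "data error")
})

test_that("clustering equals a brute-force union-find on random edge sets", {
  set.seed(64)
  for (rep in 1:25) {
    n <- 200
    uni <- sprintf("p%03d", sample(1000, n))
    n_edges <- sample(0:300, 1)
    ea <- sample(uni, n_edges, replace = TRUE)
    eb <- sample(uni, n_edges, replace = TRUE)
    keep <- ea != eb
    edges <- data.frame(protein_a = pmin(ea[keep], eb[keep]),
                        protein_b = pmax(ea[keep], eb[keep]))
    cl <- cluster_families(edges, uni)
    oracle <- uf_components(uni, edges$protein_a, edges$protein_b)
    expect_identical(cl$membership[sort(uni)], oracle[sort(uni)])
    # partition property
    expect_equal(sum(lengths(cl$families)), n)
  }
})

test_that("pan-genome families match the design on simulated strains", {
  sim <- fix_sim_d0()
  tab <- pangenome_summary(sim$proteomes, identity_thresholds = c(80))
  expect_equal(tab$n_families, length(sim$truth$families))

  sim10 <- fix_sim_aa10()
  tab10 <- pangenome_summary(sim10$proteomes, identity_thresholds = c(80))
  expect_equal(tab10$n_families, length(sim10$truth$families))
})

test_that("family counts are non-decreasing in the identity threshold", {
  sim <- fix_sim_d15()
  tab <- pangenome_summary(sim$proteomes, identity_thresholds = c(40, 50, 70, 80))
  expect_true(all(diff(tab$n_families) >= 0))
  # at this divergence the strictest threshold must actually split families
  expect_gt(tab$n_families[4], tab$n_families[1])
  expect_error(pangenome_summary(sim$proteomes, identity_thresholds = c(80, 40)),
               "ascending")
})

test_that("identical proteomes cluster into one family per protein", {
  set.seed(66)
  seqs <- setNames(vapply(rep(60, 10), random_seq, character(1), chars = AA20),
                   sprintf("g%d", 1:10))
  ps <- lapply(sprintf("S%d", 1:3), mk_proteome, seqs = seqs)
  tab <- pangenome_summary(ps, identity_thresholds = c(40, 80))
  expect_equal(tab$n_families, c(10L, 10L))
})
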