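test_that("semiglobal alignment handles the plain identity cases", {
  a <- align_semiglobal("ACDEFG", "ACDEFG")
  expect_equal(identity_pct(a), 100)
  expect_equal(similarity_pct(a), 100)
  expect_equal(a$aligned_cols, 6L)

  a <- align_semiglobal("AAAA", "CCCC")
  expect_equal(a$n_identical, 0L)

  expect_error(align_semiglobal("", "ACD"), "nonempty")
})

test_that("contained peptide aligns end-gap-free with correct spans", {
  a <- align_semiglobal("MKVLW", "KVL")
  expect_equal(identity_pct(a), 100)
  expect_equal(a$q_span, c(1L, 4L))
  expect_equal(a$s_span, c(0L, 3L))
  s <- scoring_protein()
  expect_equal(a$score, oracle_overlap_enum("MKVLW", "KVL", s))
})

test_that("both aligners equal exhaustive path-enumeration oracles on tiny pairs", {
  s <- scoring_nucleotide()
  set.seed(11)
  for (rep in 1:40) {
    a <- random_seq(sample(1:5, 1), c("A", "C", "G"))
    b <- random_seq(sample(1:5, 1), c("A", "C", "G"))
    expect_equal(align_semiglobal(a, b, s)$score, oracle_overlap_enum(a, b, s),
                 info = paste(a, b))
    got <- align_local(a, b, s, alphabet = "nucleotide")
    got_score <- if (is.null(got)) 0 else got$score
    # nucleotide local search covers both subject strands
    brc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    expect_equal(got_score,
                 max(oracle_local_enum(a, b, s), oracle_local_enum(a, brc, s)),
                 info = paste(a, b))
    # the independent R Gotoh oracle must agree with the enumeration too
    expect_equal(r_gotoh_score(a, b, s, "semiglobal"), oracle_overlap_enum(a, b, s))
    expect_equal(r_gotoh_score(a, b, s, "local"), oracle_local_enum(a, b, s))
  }
})

test_that("aligners match an independent Gotoh DP on all short two-letter pairs", {
  s <- scoring_nucleotide()
  seqs <- unlist(lapply(1:5, function(L) {
    apply(do.call(expand.grid, rep(list(c("A", "C")), L)), 1, paste, collapse = "")
  }))
  for (a in seqs) {
    for (b in seqs) {
      expect_equal(align_semiglobal(a, b, s)$score,
                   r_gotoh_score(a, b, s, "semiglobal"), info = paste(a, b))
      got <- align_local(a, b, s, alphabet = "nucleotide")
      brc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
      expect_equal(if (is.null(got)) 0 else got$score,
                   max(r_gotoh_score(a, b, s, "local"),
                       r_gotoh_score(a, brc, s, "local")), info = paste(a, b))
    }
  }
})

test_that("aligners match the independent Gotoh DP on random protein pairs <= 8", {
  s <- scoring_protein()
  set.seed(23)
  for (rep in 1:150) {
    a <- random_seq(sample(1:8, 1), AA20[1:6])
    b <- random_seq(sample(1:8, 1), AA20[1:6])
    expect_equal(align_semiglobal(a, b, s)$score,
                 r_gotoh_score(a, b, s, "semiglobal"), info = paste(a, b))
    got <- align_local(a, b, s, alphabet = "protein")
    expect_equal(if (is.null(got)) 0 else got$score,
                 r_gotoh_score(a, b, s, "local"), info = paste(a, b))
  }
})

test_that("semiglobal score is symmetric and bounded below by the global score", {
  s <- scoring_protein()
  set.seed(5)
  for (rep in 1:25) {
    a <- random_seq(sample(3:20, 1), AA20)
    b <- random_seq(sample(3:20, 1), AA20)
    expect_equal(align_semiglobal(a, b, s)$score, align_semiglobal(b, a, s)$score)
    glob <- oracle_global_enum(strsplit(substr(a, 1, 5), "")[[1]],
                               strsplit(substr(b, 1, 5), "")[[1]],
                               s$matrix, s$gap_open, s$gap_extend)
    expect_gte(align_semiglobal(substr(a, 1, 5), substr(b, 1, 5), s)$score, glob)
  }
})

test_that("local alignment finds embedded matches on either strand", {
  hit <- align_local("ACGT", "TTTACGTTT", alphabet = "nucleotide")
  expect_equal(identity_pct(hit), 100)
  expect_equal(hit$strand, "+")
  expect_equal(hit$s_span, c(3L, 7L))
  expect_equal((hit$q_span[2] - hit$q_span[1]) / nchar("ACGT"), 1)

  # non-palindromic probe embedded as reverse complement in a random flank
  probe <- "AACGTTGCAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(probe)))
  set.seed(2)
  subj <- paste0(random_seq(30, c("A", "C", "G", "T")), rc,
                 random_seq(30, c("A", "C", "G", "T")))
  hit <- align_local(probe, subj, alphabet = "nucleotide")
  expect_equal(hit$strand, "-")
  expect_equal(identity_pct(hit), 100)
})

test_that("unrelated sequences under a mismatch-only matrix give no hit", {
  chars <- c("A", "C", "D")
  mat <- matrix(-1L, 3, 3, dimnames = list(chars, chars))
  s <- scoring_scheme("mismatch-only", chars, mat, 2, 1, 0.5, 0.1)
  set.seed(4)
  a <- random_seq(50, chars)
  b <- chartr("ACD", "DAC", a)
  expect_null(align_local(a, b, s, alphabet = "protein"))
})

test_that("e-values scale with the declared search space", {
  s <- scoring_protein()
  a <- "MKVLWAALLVTFLAGCQA"
  h1 <- align_local(a, a, s, alphabet = "protein")
  h2 <- align_local(a, a, s, alphabet = "protein",
                    search_space = c(nchar(a), 10 * nchar(a)))
  expect_equal(h2$evalue / h1$evalue, 10, tolerance = 1e-12)
  expect_equal(h1$evalue,
               s$K * nchar(a)^2 * exp(-s$lambda * h1$score))
})

test_that("doubling identical flanking context never reduces a local score", {
  s <- scoring_nucleotide()
  set.seed(31)
  for (rep in 1:10) {
    core <- random_seq(20, c("A", "C", "G", "T"))
    flank <- random_seq(10, c("A", "C", "G", "T"))
    a1 <- paste0(flank, core)
    a2 <- paste0(flank, flank, core)
    b <- paste0(flank, core)
    s1 <- align_local(a1, b, s, alphabet = "nucleotide")$score
    s2 <- align_local(a2, b, s, alphabet = "nucleotide")$score
    expect_gte(s2, s1)
  }
})

test_that("unknown alphabet is a configuration error", {
  expect_error(align_local("ACGT", "ACGT", alphabet = "rna"), "unknown alphabet")
})

test_that("length filter implements the 20% longer-protein rule symmetrically", {
  expect_true(length_ratio_ok(100, 100))
  expect_true(length_ratio_ok(100, 80))
  expect_false(length_ratio_ok(100, 79))
  expect_equal(length_ratio_ok(80, 100), length_ratio_ok(100, 80))
  expect_error(length_ratio_ok(0, 10), "positive")
})

test_that("ambiguity residues mismatch everything including themselves", {
  s <- scoring_protein()
  a <- align_semiglobal("MKXML", "MKXML", s)
  expect_equal(a$n_identical, 4L)
  expect_lt(similarity_pct(a), 100)
  n <- scoring_nucleotide()
  b <- align_semiglobal("ACNGT", "ACNGT", n)
  expect_equal(b$n_identical, 4L)
})
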