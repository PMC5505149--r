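# Independent oracles used across the suite. None of these share code with
# the package's aligner or clustering implementation.

# Fully-charged global affine alignment score by exhaustive path enumeration:
# every alignment path is walked recursively; a gap run of length L costs
# gap_open + L * gap_extend wherever it sits.
oracle_global_enum <- function(A, B, mat, go, ge) {
  m <- length(A); n <- length(B)
  rec <- function(i, j, prev) {
    if (i > m && j > n) return(0)
    best <- -Inf
    if (i <= m && j <= n) {
      best <- max(best, mat[A[i], B[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= m) {
      best <- max(best, -(if (prev == "X") ge else go + ge) + rec(i + 1, j, "X"))
    }
    if (j <= n) {
      best <- max(best, -(if (prev == "Y") ge else go + ge) + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "S")
}

# End-gap-free score by enumeration: the aligned block starts on an edge of
# one sequence and ends on an edge of one sequence; everything outside is a
# free overhang, everything inside is charged. The empty alignment scores 0.
oracle_overlap_enum <- function(a, b, s) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  starts <- unique(rbind(cbind(0:m, 0L), cbind(0L, 0:n)))
  ends <- unique(rbind(cbind(m, 0:n), cbind(0:m, n)))
  best <- 0
  for (st in seq_len(nrow(starts))) {
    for (en in seq_len(nrow(ends))) {
      i0 <- starts[st, 1]; j0 <- starts[st, 2]
      i1 <- ends[en, 1]; j1 <- ends[en, 2]
      if (i1 < i0 || j1 < j0) next
      Ai <- if (i1 > i0) A[(i0 + 1):i1] else character(0)
      Bi <- if (j1 > j0) B[(j0 + 1):j1] else character(0)
      best <- max(best, oracle_global_enum(Ai, Bi, s$matrix, s$gap_open, s$gap_extend))
    }
  }
  best
}

# Smith-Waterman score by enumeration over all substring pairs.
oracle_local_enum <- function(a, b, s) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  best <- 0
  for (i0 in 0:(m - 1)) for (i1 in (i0 + 1):m) {
    for (j0 in 0:(n - 1)) for (j1 in (j0 + 1):n) {
      best <- max(best, oracle_global_enum(A[(i0 + 1):i1], B[(j0 + 1):j1],
                                           s$matrix, s$gap_open, s$gap_extend))
    }
  }
  best
}

# Independent matrix-form Gotoh DP (plain R, no traceback), both modes.
# Structured differently from the package's C++ engine: full matrices, no
# rolling rows, explicit -Inf sentinels.
r_gotoh_score <- function(a, b, s, mode = c("semiglobal", "local")) {
  mode <- match.arg(mode)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  go <- s$gap_open; ge <- s$gap_extend
  M <- matrix(-Inf, m + 1, n + 1); X <- M; Y <- M
  M[1, ] <- 0; M[, 1] <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      diag <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      if (mode == "local") diag <- max(diag, 0)
      M[i, j] <- s$matrix[A[i - 1], B[j - 1]] + diag
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    }
  }
  if (mode == "local") {
    return(max(0, M[2:(m + 1), 2:(n + 1)]))
  }
  max(0,
      M[m + 1, 2:(n + 1)], M[2:(m + 1), n + 1],
      Y[2:(m + 1), n + 1], X[m + 1, 2:(n + 1)])
}

# Brute-force union-find over an edge list; components labelled by their
# smallest member. Returns a named membership vector.
uf_components <- function(universe, edges_a, edges_b) {
  parent <- setNames(universe, universe)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(universe, find, character(1))
  labels <- tapply(universe, roots, min)
  setNames(as.vector(labels[roots]), universe)
}

random_seq <- function(len, chars) {
  paste(sample(chars, len, replace = TRUE), collapse = "")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
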