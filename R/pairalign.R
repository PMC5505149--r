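#' Scoring schemes for pairwise alignment
#'
#' A scoring scheme bundles a symmetric integer substitution matrix, affine gap
#' penalties (a gap of length L costs `gap_open + L * gap_extend`) and
#' Karlin-Altschul parameters for e-values in local mode.
#'
#' `scoring_protein()` is the default protein scheme: BLOSUM62 with gap open
#' 11 / extend 1 and the published gapped constants (lambda 0.267, K 0.041).
#' The ambiguity residue `X` is forced to score -1 against everything
#' (including itself) and never counts as identical or similar.
#'
#' `scoring_nucleotide()` scores match +2 / mismatch -3 with gap open 5 /
#' extend 2 (lambda 0.625, K 0.41); `N` mismatches everything.
#'
#' @param name Scheme label.
#' @param chars Alphabet characters, in matrix order.
#' @param matrix Symmetric integer substitution matrix over `chars`.
#' @param gap_open,gap_extend Nonnegative integers, `gap_extend <= gap_open`.
#' @param lambda,K Positive Karlin-Altschul parameters.
#' @param ambig Characters treated as ambiguity codes (mismatch everything).
#' @return An object of class `ScoringScheme`.
#' @export
scoring_scheme <- function(name, chars, matrix, gap_open, gap_extend,
                           lambda, K, ambig = character()) {
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) == length(chars), ncol(matrix) == length(chars))
  if (!isTRUE(all.equal(matrix, t(matrix)))) stop("substitution matrix must be symmetric")
  stopifnot(gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open,
            lambda > 0, K > 0)
  storage.mode(matrix) <- "integer"
  dimnames(matrix) <- list(chars, chars)
  structure(list(name = name, chars = chars, matrix = matrix,
                 gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K,
                 ambig = as.integer(chars %in% ambig)),
            class = "ScoringScheme")
}

#' @rdname scoring_scheme
#' @export
scoring_protein <- function(gap_open = 11, gap_extend = 1,
                            lambda = 0.267, K = 0.041) {
  chars <- .alphabet_chars("protein")
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[chars, chars]
  m["X", ] <- -1L
  m[, "X"] <- -1L
  scoring_scheme("BLOSUM62", chars, m, gap_open, gap_extend, lambda, K,
                 ambig = "X")
}

#' @rdname scoring_scheme
#' @export
scoring_nucleotide <- function(match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2,
                               lambda = 0.625, K = 0.41) {
  chars <- .alphabet_chars("nucleotide")
  m <- matrix(mismatch, 5, 5, dimnames = list(chars, chars))
  diag(m) <- match
  m["N", "N"] <- mismatch  # N mismatches everything, including itself
  scoring_scheme("NUC+2/-3", chars, m, gap_open, gap_extend, lambda, K,
                 ambig = "N")
}

#' @export
print.ScoringScheme <- function(x, ...) {
  cat("ScoringScheme", x$name, ": gap", x$gap_open, "/", x$gap_extend,
      " lambda", x$lambda, " K", x$K, "\n")
  invisible(x)
}

# encode a sequence as 0-based indices into the scheme alphabet
.encode <- function(seq, s) {
  codes <- match(strsplit(toupper(seq), "")[[1]], s$chars)
  if (anyNA(codes)) {
    bad <- strsplit(toupper(seq), "")[[1]][is.na(codes)][1L]
    stop("residue '", bad, "' not in the ", s$name, " alphabet")
  }
  codes - 1L
}

.aln_result <- function(raw, mode, strand = NA_character_, evalue = NA_real_) {
  structure(list(mode = mode,
                 score = raw$score,
                 aligned_cols = raw$aligned_cols,
                 n_identical = raw$n_identical,
                 n_similar = raw$n_similar,
                 q_span = c(raw$q_start, raw$q_end),
                 s_span = c(raw$s_start, raw$s_end),
                 strand = strand,
                 evalue = evalue),
            class = "AlignmentResult")
}

#' Percent identity / similarity of an alignment
#'
#' Identity is the percentage of aligned columns whose residues match exactly;
#' similarity the percentage whose substitution score is positive. Both use
#' the aligned columns (first to last aligned pair, interior gaps included) as
#' denominator; terminal free gaps are excluded. `NA` for empty alignments.
#'
#' @param x An `AlignmentResult`.
#' @return A percentage in `[0, 100]`, or `NA`.
#' @export
identity_pct <- function(x) {
  if (x$aligned_cols == 0L) return(NA_real_)
  100 * x$n_identical / x$aligned_cols
}

#' @rdname identity_pct
#' @export
similarity_pct <- function(x) {
  if (x$aligned_cols == 0L) return(NA_real_)
  100 * x$n_similar / x$aligned_cols
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("%s alignment: score %d, %d cols, %.1f%% id, %.1f%% sim, q [%d,%d), s [%d,%d)%s\n",
              x$mode, x$score, x$aligned_cols,
              if (x$aligned_cols) 100 * x$n_identical / x$aligned_cols else NA,
              if (x$aligned_cols) 100 * x$n_similar / x$aligned_cols else NA,
              x$q_span[1], x$q_span[2], x$s_span[1], x$s_span[2],
              if (!is.na(x$strand)) paste0(", strand ", x$strand) else ""))
  invisible(x)
}

#' End-gap-free (semi-global) protein alignment
#'
#' Global affine-gap alignment in which leading and trailing gaps cost
#' nothing, suited to comparing full-length proteins of slightly different
#' lengths. The score is symmetric in its arguments.
#'
#' @param a,b Nonempty residue strings.
#' @param s A [scoring_scheme()]; defaults to [scoring_protein()].
#' @return An `AlignmentResult` with 0-based half-open spans of the aligned
#'   region on each unaligned sequence.
#' @examples
#' aln <- align_semiglobal("MKVLW", "KVL")
#' identity_pct(aln)
#' @export
align_semiglobal <- function(a, b, s = scoring_protein()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  raw <- .align_pair_cpp(.encode(a, s), .encode(b, s), s$matrix, s$ambig,
                         s$gap_open, s$gap_extend, FALSE)
  .aln_result(raw, "semiglobal")
}

#' Local (Smith-Waterman) alignment with e-value
#'
#' Optimal local affine-gap alignment. In nucleotide mode both strands of the
#' subject are searched; a minus-strand hit reports its subject span on the
#' plus strand. The e-value is `K * m * n * exp(-lambda * score)` with `(m, n)`
#' from `search_space`.
#'
#' @param a Query sequence (nonempty string).
#' @param b Subject sequence (nonempty string).
#' @param s A [scoring_scheme()] matching `alphabet`.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param search_space Integer pair `(m, n)`: the effective query and subject
#'   (database) lengths for the e-value. Defaults to the two sequence lengths.
#' @return An `AlignmentResult`, or `NULL` (no hit) when the best local score
#'   is `<= 0`.
#' @export
align_local <- function(a, b, s = NULL,
                        alphabet = c("protein", "nucleotide"),
                        search_space = NULL) {
  alphabet <- tryCatch(match.arg(alphabet),
                       error = function(e) stop("unknown alphabet"))
  if (is.null(s)) {
    s <- if (alphabet == "protein") scoring_protein() else scoring_nucleotide()
  }
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  if (is.null(search_space)) search_space <- c(nchar(a), nchar(b))
  ea <- .encode(a, s)
  eb <- .encode(b, s)
  raw <- .align_pair_cpp(ea, eb, s$matrix, s$ambig, s$gap_open, s$gap_extend, TRUE)
  strand <- if (alphabet == "nucleotide") "+" else NA_character_
  if (alphabet == "nucleotide") {
    brc <- .revcomp(b)
    rawm <- .align_pair_cpp(ea, .encode(brc, s), s$matrix, s$ambig,
                            s$gap_open, s$gap_extend, TRUE)
    if (rawm$score > raw$score) {       # plus strand wins ties
      n <- nchar(b)
      rawm[c("s_start", "s_end")] <- list(n - rawm$s_end, n - rawm$s_start)
      raw <- rawm
      strand <- "-"
    }
  }
  if (raw$score <= 0L) return(NULL)
  ev <- s$K * search_space[1] * search_space[2] * exp(-s$lambda * raw$score)
  .aln_result(raw, "local", strand = strand, evalue = ev)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Protein length compatibility filter
#'
#' Orthology candidates whose protein lengths differ by more than `max_diff`
#' (relative to the longer protein) are discarded.
#'
#' @param a_len,b_len Positive integer lengths.
#' @param max_diff Maximum tolerated length difference as a fraction of the
#'   longer protein (default 0.20).
#' @return `TRUE` iff `(max - min) / max <= max_diff`. Vectorized.
#' @examples
#' length_ratio_ok(100, 80)   # TRUE: 20/100 = 0.20
#' length_ratio_ok(100, 79)   # FALSE
#' @export
length_ratio_ok <- function(a_len, b_len, max_diff = 0.20) {
  if (any(a_len <= 0) || any(b_len <= 0)) stop("lengths must be positive")
  hi <- pmax(a_len, b_len)
  lo <- pmin(a_len, b_len)
  (hi - lo) / hi <= max_diff
}
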