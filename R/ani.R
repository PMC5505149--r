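#' ANIb parameters
#'
#' Defaults follow the standard ANIb convention: 1020-nt fragments, hits kept
#' when they reach 30% identity and cover 70% of the fragment, and the 95%
#' conspecificity cutoff.
#'
#' @param fragment_len Fragment length in nt (default 1020).
#' @param min_trailing Minimum length of the trailing fragment kept (default 100).
#' @param hit_min_identity Minimum percent identity of a kept hit (default 30).
#' @param hit_min_coverage Minimum fraction of the fragment covered (default 0.70).
#' @param species_cutoff ANI percent above which two strains are called the
#'   same species (default 95).
#' @return An object of class `ANIParams`.
#' @export
ani_params <- function(fragment_len = 1020, min_trailing = 100,
                       hit_min_identity = 30, hit_min_coverage = 0.70,
                       species_cutoff = 95) {
  stopifnot(min_trailing > 0, min_trailing <= fragment_len,
            hit_min_identity > 0, hit_min_identity <= 100,
            hit_min_coverage > 0, hit_min_coverage <= 1,
            species_cutoff > 0, species_cutoff <= 100)
  structure(list(fragment_len = as.integer(fragment_len),
                 min_trailing = as.integer(min_trailing),
                 hit_min_identity = hit_min_identity,
                 hit_min_coverage = hit_min_coverage,
                 species_cutoff = species_cutoff),
            class = "ANIParams")
}

#' Cut a genome into consecutive fragments
#'
#' Non-overlapping windows of `fragment_len` nt per replicon, 0-based
#' half-open coordinates; a trailing piece is kept iff it is at least
#' `min_trailing` nt long.
#'
#' @param g A [genome_seq()].
#' @param p An [ani_params()].
#' @return Data frame with columns `replicon`, `start`, `end`, `sequence`.
#' @export
fragment_genome <- function(g, p = ani_params()) {
  stopifnot(inherits(g, "GenomeSeq"))
  if (sum(nchar(g$replicons$sequence)) < p$min_trailing) {
    stop("genome shorter than min_trailing")
  }
  out <- lapply(seq_len(nrow(g$replicons)), function(k) {
    seq <- g$replicons$sequence[k]
    len <- nchar(seq)
    starts <- seq.int(0L, max(len - 1L, 0L), by = p$fragment_len)
    ends <- pmin(starts + p$fragment_len, len)
    keep <- (ends - starts == p$fragment_len) | (ends - starts >= p$min_trailing)
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0L) return(NULL)
    data.frame(replicon = g$replicons$id[k], start = starts, end = ends,
               sequence = substring(seq, starts + 1L, ends),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Seeded best-local-hit search of query fragments against subject replicons.
# Exact k-mer seeds vote for diagonals; the top diagonals define windows that
# are aligned exactly (affine Smith-Waterman). Both strands are searched.
# Returns, per fragment, the best hit's identity and fragment coverage.
.fragment_hits <- function(frags, subject, s, seed_k = 15L, seed_step = 64L,
                           window_pad = 200L, max_diags = 3L) {
  n_frag <- nrow(frags)
  res_id <- rep(NA_real_, n_frag)
  res_cov <- rep(NA_real_, n_frag)
  res_score <- rep(-Inf, n_frag)

  # all seeds for all fragments
  seed_tab <- do.call(rbind, lapply(seq_len(n_frag), function(i) {
    fs <- frags$sequence[i]
    fl <- nchar(fs)
    if (fl < seed_k) return(NULL)
    offs <- unique(c(seq.int(1L, fl - seed_k + 1L, by = seed_step),
                     fl - seed_k + 1L))
    data.frame(frag = i, off = offs,
               seed = substring(fs, offs, offs + seed_k - 1L),
               stringsAsFactors = FALSE)
  }))
  if (is.null(seed_tab)) return(list(identity = res_id, coverage = res_cov))
  useed <- unique(seed_tab$seed)
  seed_rows <- split(seq_len(nrow(seed_tab)), match(seed_tab$seed, useed))

  enc_frag <- lapply(frags$sequence, .encode, s = s)

  for (k in seq_len(nrow(subject$replicons))) {
    for (strand in c("+", "-")) {
      sseq <- subject$replicons$sequence[k]
      if (strand == "-") sseq <- .revcomp(sseq)
      slen <- nchar(sseq)
      if (slen < seed_k) next
      subj_kmers <- substring(sseq, seq_len(slen - seed_k + 1L),
                              seq_len(slen - seed_k + 1L) + seed_k - 1L)
      hit <- match(subj_kmers, useed)
      pos <- which(!is.na(hit))
      if (length(pos) == 0L) next
      # expand to (fragment, diagonal) votes
      rows_l <- seed_rows[as.character(hit[pos])]
      rows <- unlist(rows_l, use.names = FALSE)
      votes <- data.frame(frag = seed_tab$frag[rows],
                          diag = rep.int(pos, lengths(rows_l)) - seed_tab$off[rows])
      enc_subj <- .encode(sseq, s)
      for (i in unique(votes$frag)) {
        dv <- votes$diag[votes$frag == i]
        tab <- sort(table(dv), decreasing = TRUE)
        diags <- as.integer(names(tab))[seq_len(min(max_diags, length(tab)))]
        diags <- diags[order(-tab[seq_along(diags)], diags)]
        fl <- nchar(frags$sequence[i])
        for (d in diags) {
          w0 <- max(0L, d - window_pad)
          w1 <- min(slen, d + fl + window_pad)
          if (w1 <= w0) next
          raw <- .align_pair_cpp(enc_frag[[i]], enc_subj[(w0 + 1L):w1],
                                 s$matrix, s$ambig, s$gap_open, s$gap_extend,
                                 TRUE)
          if (raw$score > res_score[i] && raw$aligned_cols > 0L) {
            res_score[i] <- raw$score
            res_id[i] <- 100 * raw$n_identical / raw$aligned_cols
            res_cov[i] <- (raw$q_end - raw$q_start) / fl
          }
        }
      }
    }
  }
  list(identity = res_id, coverage = res_cov)
}

#' Directional ANIb between two genomes
#'
#' The query genome is cut into fragments ([fragment_genome()]); each fragment
#' is searched against both strands of the subject for its best local
#' alignment; hits reaching `hit_min_identity` percent identity over at least
#' `hit_min_coverage` of the fragment are kept, and the ANI is their
#' unweighted mean identity, rounded to two decimals.
#'
#' @param query,subject [genome_seq()] objects.
#' @param p An [ani_params()].
#' @param s A nucleotide [scoring_scheme()].
#' @return List with `ani` (percent, or `NA` when no hit qualifies) and
#'   `n_fragments_used`.
#' @export
anib_directional <- function(query, subject, p = ani_params(),
                             s = scoring_nucleotide()) {
  stopifnot(inherits(query, "GenomeSeq"), inherits(subject, "GenomeSeq"))
  frags <- fragment_genome(query, p)
  hits <- .fragment_hits(frags, subject, s)
  keep <- !is.na(hits$identity) &
    hits$identity >= p$hit_min_identity &
    hits$coverage >= p$hit_min_coverage
  if (!any(keep)) return(list(ani = NA_real_, n_fragments_used = 0L))
  list(ani = round(mean(hits$identity[keep]), 2),
       n_fragments_used = sum(keep))
}

#' ANIb matrix over a set of genomes
#'
#' Every ordered pair of distinct genomes is computed (ANIb is directional and
#' the matrix need not be symmetric); the diagonal is reported as 100.00.
#'
#' @param genomes List of at least two [genome_seq()] objects.
#' @param p An [ani_params()].
#' @param s A nucleotide [scoring_scheme()].
#' @return An object of class `ANIMatrix`: list with `ani` (query x subject
#'   percent matrix) and `n_used` (fragments used per cell).
#' @export
anib_matrix <- function(genomes, p = ani_params(), s = scoring_nucleotide()) {
  if (length(genomes) < 2L) stop("at least two genomes are required")
  ids <- vapply(genomes, function(g) g$strain_id, character(1))
  n <- length(genomes)
  ani <- matrix(100.00, n, n, dimnames = list(query = ids, subject = ids))
  used <- matrix(0L, n, n, dimnames = list(query = ids, subject = ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- anib_directional(genomes[[i]], genomes[[j]], p, s)
      ani[i, j] <- r$ani
      used[i, j] <- r$n_fragments_used
    }
  }
  structure(list(ani = ani, n_used = used), class = "ANIMatrix")
}

#' @export
print.ANIMatrix <- function(x, ...) {
  cat("ANIb matrix (rows = query, %):\n")
  print(round(x$ani, 2))
  invisible(x)
}

#' Pairwise species verdicts from an ANI matrix
#'
#' Two strains are called the same species iff the mean of their two
#' directional ANIb values exceeds the cutoff (by convention 95%); a pair
#' with a missing direction, or sitting exactly on the cutoff, is
#' undetermined.
#'
#' @param m An [anib_matrix()] result.
#' @param p An [ani_params()] (only `species_cutoff` is used).
#' @return Data frame with columns `strain_a`, `strain_b`, `ani_mean`,
#'   `verdict` (`"same"`, `"different"`, `"undetermined"`).
#' @export
classify_species <- function(m, p = ani_params()) {
  stopifnot(inherits(m, "ANIMatrix"))
  ids <- rownames(m$ani)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      v <- c(m$ani[i, j], m$ani[j, i])
      mean_ani <- if (anyNA(v)) NA_real_ else mean(v)
      verdict <- if (is.na(mean_ani)) "undetermined"
                 else if (mean_ani > p$species_cutoff) "same"
                 else if (mean_ani == p$species_cutoff) "undetermined"
                 else "different"
      out[[length(out) + 1L]] <-
        data.frame(strain_a = ids[i], strain_b = ids[j],
                   ani_mean = mean_ani, verdict = verdict,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
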