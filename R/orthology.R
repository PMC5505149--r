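#' Ortholog filtering parameters
#'
#' The similarity threshold is 40 (percent) for genus-level and 80 for
#' species-level runs; candidate pairs whose protein lengths differ by more
#' than `max_len_diff` are discarded. `positional_window` enables the
#' positional-consistency (synteny) filter; 0 disables it.
#'
#' @param min_similarity Minimum percent similarity in `(0, 100]`.
#' @param max_len_diff Maximum protein length difference in `[0, 1)`.
#' @param positional_window Nonnegative integer window `w` (0 = off).
#' @return An object of class `FilterParams`.
#' @export
filter_params <- function(min_similarity = 80, max_len_diff = 0.20,
                          positional_window = 0) {
  stopifnot(min_similarity > 0, min_similarity <= 100,
            max_len_diff >= 0, max_len_diff < 1,
            positional_window >= 0)
  structure(list(min_similarity = min_similarity,
                 max_len_diff = max_len_diff,
                 positional_window = as.integer(positional_window)),
            class = "FilterParams")
}

#' Threshold bundle for an analysis level
#'
#' Genus-level runs use 40% minimum similarity/identity and no positional
#' filter; species-level runs use 80% and a positional window of 5.
#'
#' @param level `"genus"` or `"species"`.
#' @return List with elements `filter` (a [filter_params()]) and
#'   `identity_min` (pan-genome clustering threshold, percent).
#' @export
level_params <- function(level = c("species", "genus")) {
  level <- match.arg(level)
  if (level == "genus") {
    list(filter = filter_params(40, 0.20, 0), identity_min = 40)
  } else {
    list(filter = filter_params(80, 0.20, 5), identity_min = 80)
  }
}

.encode_proteome <- function(p, s) {
  lapply(p$proteins$sequence, .encode, s = s)
}

# resolve the best target index for each query given a score matrix;
# ties by score are broken by higher identity, then lexicographically
# smaller target id. Returns integer vector of target indices.
.best_by_row <- function(scores, enc_q, enc_t, target_ids, s) {
  vapply(seq_len(nrow(scores)), function(i) {
    row <- scores[i, ]
    cand <- which(row == max(row))
    if (length(cand) > 1L) {
      idents <- vapply(cand, function(j) {
        raw <- .align_pair_cpp(enc_q[[i]], enc_t[[j]], s$matrix, s$ambig,
                               s$gap_open, s$gap_extend, FALSE)
        if (raw$aligned_cols == 0L) -1 else raw$n_identical / raw$aligned_cols
      }, numeric(1))
      cand <- cand[idents == max(idents)]
      if (length(cand) > 1L) cand <- cand[order(target_ids[cand])][1L]
    }
    cand[1L]
  }, integer(1))
}

#' Best hit of a protein in a target proteome
#'
#' The target protein maximizing the end-gap-free alignment score; ties are
#' broken by higher identity, then by lexicographically smaller id.
#'
#' @param q A nonempty protein sequence (string).
#' @param target A [proteome()].
#' @param s A [scoring_scheme()].
#' @return List with elements `id` (target protein id) and `aln`
#'   (the `AlignmentResult` of `q` against it).
#' @export
best_hit <- function(q, target, s = scoring_protein()) {
  stopifnot(inherits(target, "Proteome"), nrow(target$proteins) >= 1L)
  enc_q <- list(.encode(q, s))
  enc_t <- .encode_proteome(target, s)
  scores <- .score_matrix_cpp(enc_q, enc_t, s$matrix, s$gap_open, s$gap_extend, FALSE)
  j <- .best_by_row(scores, enc_q, enc_t, target$proteins$id, s)
  raw <- .align_pair_cpp(enc_q[[1]], enc_t[[j]], s$matrix, s$ambig,
                         s$gap_open, s$gap_extend, FALSE)
  list(id = target$proteins$id[j], aln = .aln_result(raw, "semiglobal"))
}

#' Bidirectional best hits between two proteomes
#'
#' A pair `(x, y)` is reported iff `y` is the best hit of `x` in `b`, `x` is
#' the best hit of `y` in `a`, the pair's percent similarity is at least
#' `f$min_similarity`, and the protein lengths pass [length_ratio_ok()].
#' The similarity/length filters are applied after best-hit determination.
#'
#' @param a,b [proteome()]s (`a` is the pivot side).
#' @param f A [filter_params()].
#' @param s A [scoring_scheme()].
#' @return Data frame with columns `gene_a`, `gene_b`, `identity_pct`,
#'   `similarity_pct`, `score`, sorted by `gene_a`; strains recorded in
#'   attributes `strain_a`, `strain_b`.
#' @export
bbh_orthologs <- function(a, b, f = filter_params(), s = scoring_protein()) {
  stopifnot(inherits(a, "Proteome"), inherits(b, "Proteome"),
            nrow(a$proteins) >= 1L, nrow(b$proteins) >= 1L)
  enc_a <- .encode_proteome(a, s)
  enc_b <- .encode_proteome(b, s)
  scores <- .score_matrix_cpp(enc_a, enc_b, s$matrix, s$gap_open, s$gap_extend, FALSE)
  fwd <- .best_by_row(scores, enc_a, enc_b, b$proteins$id, s)
  rev <- .best_by_row(t(scores), enc_b, enc_a, a$proteins$id, s)
  mutual <- which(rev[fwd] == seq_along(fwd))
  rows <- lapply(mutual, function(i) {
    j <- fwd[i]
    raw <- .align_pair_cpp(enc_a[[i]], enc_b[[j]], s$matrix, s$ambig,
                           s$gap_open, s$gap_extend, FALSE)
    if (raw$aligned_cols == 0L) return(NULL)
    sim <- 100 * raw$n_similar / raw$aligned_cols
    if (sim < f$min_similarity) return(NULL)
    if (!length_ratio_ok(nchar(a$proteins$sequence[i]),
                         nchar(b$proteins$sequence[j]), f$max_len_diff)) {
      return(NULL)
    }
    data.frame(gene_a = a$proteins$id[i], gene_b = b$proteins$id[j],
               identity_pct = 100 * raw$n_identical / raw$aligned_cols,
               similarity_pct = sim, score = raw$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(.empty_pairs())))
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "strain_a") <- a$strain_id
  attr(out, "strain_b") <- b$strain_id
  out
}

.empty_pairs <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             identity_pct = numeric(), similarity_pct = numeric(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Positional-consistency (synteny) filter for ortholog pairs
#'
#' Genomes from the same species show low levels of rearrangement, so true
#' orthologs tend to sit in conserved neighborhoods. A pair is kept iff, on
#' each side of the pivot gene, at least one of its `w` nearest neighbors has
#' its own ortholog within `w` positions of the partner gene (on the partner's
#' replicon). A side with no orthologous neighbor at all imposes no
#' constraint, so with `w >=` proteome size the filter is the identity.
#'
#' @param pairs Ortholog pair table from [bbh_orthologs()].
#' @param a_order,b_order Gene-order data frames with columns `id`,
#'   `replicon`, `rank`.
#' @param w Window size (positive integer).
#' @return The filtered pair table.
#' @export
positional_filter <- function(pairs, a_order, b_order, w) {
  if (is.null(a_order) || is.null(b_order)) {
    stop("gene_order missing: set positional_window = 0 to disable the filter")
  }
  stopifnot(w >= 1)
  if (nrow(pairs) == 0L) return(pairs)
  a_idx <- match(pairs$gene_a, a_order$id)
  b_idx <- match(pairs$gene_b, b_order$id)
  if (anyNA(a_idx) || anyNA(b_idx)) stop("pair gene missing from gene_order")
  partner_of <- setNames(pairs$gene_b, pairs$gene_a)

  keep <- vapply(seq_len(nrow(pairs)), function(k) {
    ra <- a_order$rank[a_idx[k]]
    rep_a <- a_order$replicon[a_idx[k]]
    rb <- b_order$rank[b_idx[k]]
    rep_b <- b_order$replicon[b_idx[k]]
    side_ok <- function(lo, hi) {
      nb <- a_order$id[a_order$replicon == rep_a &
                       a_order$rank >= lo & a_order$rank <= hi]
      nb_partner <- partner_of[nb]
      nb_partner <- nb_partner[!is.na(nb_partner)]
      if (length(nb_partner) == 0L) return(TRUE)  # vacuous side
      nb_b <- match(nb_partner, b_order$id)
      any(b_order$replicon[nb_b] == rep_b & abs(b_order$rank[nb_b] - rb) <= w)
    }
    side_ok(ra - w, ra - 1) && side_ok(ra + 1, ra + w)
  }, logical(1))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("strain_a", "strain_b")] <-
    attributes(pairs)[c("strain_a", "strain_b")]
  out
}

#' Core-genome by intersection of pivot-anchored ortholog lists
#'
#' Bidirectional best hits are computed between the pivot proteome and every
#' other proteome (with the similarity/length filters, and the positional
#' filter when `f$positional_window > 0` and gene orders are available). The
#' core is the set of pivot proteins with a retained ortholog in every other
#' strain.
#'
#' @param pivot The pivot [proteome()].
#' @param others List of at least one other [proteome()].
#' @param f A [filter_params()].
#' @param s A [scoring_scheme()].
#' @return An object of class `CoreGenome`: pivot id, `core_members` (pivot
#'   protein ids), a membership `mapping` (rows = core genes, columns =
#'   strains, cells = ortholog ids), the per-strain pair tables, and the
#'   smallest proteome size in the set.
#' @export
core_genome <- function(pivot, others, f = filter_params(), s = scoring_protein()) {
  stopifnot(inherits(pivot, "Proteome"))
  if (length(others) < 1L) stop("at least one non-pivot proteome is required")
  pair_tables <- lapply(others, function(o) {
    pt <- bbh_orthologs(pivot, o, f, s)
    if (f$positional_window > 0L &&
        !is.null(pivot$gene_order) && !is.null(o$gene_order)) {
      ao <- cbind(id = pivot$proteins$id, pivot$gene_order)
      bo <- cbind(id = o$proteins$id, o$gene_order)
      pt <- positional_filter(pt, ao, bo, f$positional_window)
    }
    pt
  })
  names(pair_tables) <- vapply(others, function(o) o$strain_id, character(1))
  core <- Reduce(intersect, lapply(pair_tables, function(pt) pt$gene_a))
  core <- sort(core)
  mapping <- data.frame(gene = core, stringsAsFactors = FALSE)
  mapping[[pivot$strain_id]] <- core
  for (st in names(pair_tables)) {
    pt <- pair_tables[[st]]
    mapping[[st]] <- pt$gene_b[match(core, pt$gene_a)]
  }
  sizes <- c(nrow(pivot$proteins),
             vapply(others, function(o) nrow(o$proteins), integer(1)))
  structure(list(pivot_id = pivot$strain_id,
                 core_members = core,
                 mapping = mapping,
                 pair_tables = pair_tables,
                 strains = c(pivot$strain_id, names(pair_tables)),
                 smallest_proteome = min(sizes)),
            class = "CoreGenome")
}

#' @export
print.CoreGenome <- function(x, ...) {
  cat("CoreGenome: pivot", x$pivot_id, "-", length(x$core_members),
      "core genes across", length(x$strains), "strains\n")
  invisible(x)
}

#' Core-genome coverage of the smallest proteome
#'
#' The headline "percent of the smallest proteome" statistic: the number of
#' core gene families divided by the size of the smallest proteome in the
#' set, as a percent rounded to the nearest integer (halves away from zero).
#'
#' @param core_count Number of core gene families, `0 <= core_count <=
#'   smallest_proteome`.
#' @param smallest_proteome Size of the smallest proteome (positive).
#' @return Integer percent.
#' @examples
#' core_coverage_percent(2391, 2936)  # 81
#' core_coverage_percent(2637, 3347)  # 79
#' @export
core_coverage_percent <- function(core_count, smallest_proteome) {
  if (smallest_proteome <= 0) stop("smallest_proteome must be positive")
  if (core_count < 0 || core_count > smallest_proteome) {
    stop("core_count must lie in [0, smallest_proteome]")
  }
  as.integer(floor(100 * core_count / smallest_proteome + 0.5))
}
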