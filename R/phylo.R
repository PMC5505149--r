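#' Pairwise core-ortholog identities for all strain pairs
#'
#' For every pair of strains in a core-genome, aligns the two members of each
#' core gene (end-gap-free) and records the identity fraction. Pivot/other
#' identities are taken from the stored ortholog tables; other/other pairs
#' are aligned through the pivot anchoring.
#'
#' @param core A [core_genome()] result.
#' @param proteomes List of all [proteome()]s in the set (pivot included).
#' @param s A [scoring_scheme()].
#' @return Data frame with columns `strain_a`, `strain_b`, `gene`
#'   (pivot core gene id), `identity_frac`.
#' @export
core_pair_identities <- function(core, proteomes, s = scoring_protein()) {
  stopifnot(inherits(core, "CoreGenome"))
  if (length(core$core_members) == 0L) stop("core-genome is empty")
  seqs <- lapply(proteomes, function(p) {
    setNames(p$proteins$sequence, p$proteins$id)
  })
  names(seqs) <- vapply(proteomes, function(p) p$strain_id, character(1))
  strains <- core$strains
  map <- core$mapping
  rows <- list()
  for (i in seq_along(strains)) {
    for (j in seq_along(strains)) {
      if (j <= i) next
      si <- strains[i]; sj <- strains[j]
      if (si == core$pivot_id && sj %in% names(core$pair_tables)) {
        pt <- core$pair_tables[[sj]]
        idx <- match(core$core_members, pt$gene_a)
        idf <- pt$identity_pct[idx] / 100
      } else {
        idf <- vapply(seq_len(nrow(map)), function(k) {
          aln <- align_semiglobal(seqs[[si]][[map[[si]][k]]],
                                  seqs[[sj]][[map[[sj]][k]]], s)
          if (aln$aligned_cols == 0L) 0 else aln$n_identical / aln$aligned_cols
        }, numeric(1))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(strain_a = si, strain_b = sj, gene = core$core_members,
                   identity_frac = idf, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Core-genome p-distance matrix
#'
#' `d(i, j) = 1 - mean(identity fraction)` over the core ortholog pairs of
#' strains `i` and `j`; a simple evolutionary distance standing in for a
#' concatenated-alignment phylogeny.
#'
#' @param core A [core_genome()] result (used for the strain set).
#' @param alignments Pairwise identity table from [core_pair_identities()].
#' @return Symmetric numeric matrix with zero diagonal, values in `[0, 1]`.
#' @export
core_distance_matrix <- function(core, alignments) {
  stopifnot(inherits(core, "CoreGenome"))
  if (length(core$core_members) == 0L) stop("core-genome is empty")
  strains <- core$strains
  d <- matrix(0, length(strains), length(strains),
              dimnames = list(strains, strains))
  for (i in seq_along(strains)) {
    for (j in seq_along(strains)) {
      if (j <= i) next
      sel <- (alignments$strain_a == strains[i] & alignments$strain_b == strains[j]) |
             (alignments$strain_a == strains[j] & alignments$strain_b == strains[i])
      if (!any(sel)) stop("no core alignment for pair ", strains[i], "/", strains[j])
      d[i, j] <- d[j, i] <- 1 - mean(alignments$identity_frac[sel])
    }
  }
  d
}

#' Neighbor-joining tree with Newick output
#'
#' Standard neighbor joining on a distance matrix; on an additive matrix the
#' induced path lengths reproduce the input exactly. Negative branch lengths
#' (possible on non-additive input) are clamped to zero with the deficit
#' transferred to the sibling branch, preserving path lengths through the
#' parent node. Two taxa yield the trivial two-leaf tree splitting the
#' distance equally.
#'
#' @param d Symmetric distance matrix with row/column names.
#' @return Newick string with branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("at least two taxa are required")
  if (is.null(rownames(d))) stop("distance matrix must have taxon names")
  if (n == 2L) {
    h <- d[1, 2] / 2
    return(sprintf("(%s:%s,%s:%s);", rownames(d)[1], format(h, digits = 15),
                   rownames(d)[2], format(h, digits = 15)))
  }
  tr <- ape::nj(d)
  tr <- .clamp_negative_branches(tr)
  ape::write.tree(tr, digits = 15)
}

# clamp negative edges to 0 and push the deficit onto the sibling edge
.clamp_negative_branches <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs) > 0L) {
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
      if (tr$edge.length[sibs[1L]] < 0) tr$edge.length[sibs[1L]] <- 0
    }
  }
  tr
}
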