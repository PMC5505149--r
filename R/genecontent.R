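#' Family presence/absence matrix
#'
#' Counts, for every family of a clustering, how many members each strain
#' contributes. Column sums equal the proteome sizes and row sums the family
#' sizes.
#'
#' @param clustering A [cluster_families()] result whose universe is exactly
#'   the union of the proteomes' proteins.
#' @param proteomes List of [proteome()]s.
#' @return Integer matrix, rows = family ids, columns = strain ids.
#' @export
presence_absence <- function(clustering, proteomes) {
  stopifnot(inherits(clustering, "FamilyClustering"))
  uni <- .pan_universe(proteomes)
  if (!setequal(uni$gid, names(clustering$membership))) {
    stop("data error: clustering universe does not match the proteomes")
  }
  strains <- vapply(proteomes, function(p) p$strain_id, character(1))
  fam <- clustering$membership[uni$gid]
  m <- table(factor(fam, levels = names(clustering$families)),
             factor(uni$strain, levels = strains))
  out <- matrix(as.integer(m), nrow = nrow(m),
                dimnames = list(family = rownames(m), strain = colnames(m)))
  out
}

#' Three-way Venn partition of gene families
#'
#' Assigns every family to one of the 7 presence regions of three strains.
#' Presence is binary at the family level: a family with several members in
#' one strain still counts once.
#'
#' @param m A [presence_absence()] matrix.
#' @param strains Exactly three strain ids, all columns of `m`.
#' @return Named integer vector of class `VennPartition3` with the 7 regions:
#'   the three exclusive regions, the three pairwise-only regions, and the
#'   triple core, in the order `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC` (names
#'   use the strain ids).
#' @export
venn_partition <- function(m, strains) {
  if (length(strains) != 3L) stop("exactly three strains are required")
  if (!all(strains %in% colnames(m))) stop("strain missing from the matrix")
  pres <- m[, strains, drop = FALSE] > 0
  key <- pres[, 1] + 2L * pres[, 2] + 4L * pres[, 3]
  nm <- c(strains[1], strains[2], strains[3],
          paste(strains[1], strains[2], sep = "&"),
          paste(strains[1], strains[3], sep = "&"),
          paste(strains[2], strains[3], sep = "&"),
          paste(strains, collapse = "&"))
  codes <- c(1L, 2L, 4L, 3L, 5L, 6L, 7L)
  out <- vapply(codes, function(k) sum(key == k), integer(1))
  names(out) <- nm
  class(out) <- "VennPartition3"
  out
}

#' @export
print.VennPartition3 <- function(x, ...) {
  cat("Venn partition of", sum(x), "families:\n")
  print(unclass(x))
  invisible(x)
}

#' Per-gene identity report for a strain pair
#'
#' One row per shared ortholog with its stored alignment identity, plus rows
#' for genes present in only one strain flagged by the 1/0 presence
#' convention (identity `NA`). Identities come from the stored ortholog table
#' and are not recomputed.
#'
#' @param a,b [proteome()]s of the two strains.
#' @param pairs Ortholog pairs for `(a, b)` from [bbh_orthologs()].
#' @return Data frame with columns `gene_a`, `gene_b`, `present_a`,
#'   `present_b`, `identity_pct`.
#' @export
pairwise_gene_identity_report <- function(a, b, pairs) {
  shared <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                       present_a = 1L, present_b = 1L,
                       identity_pct = pairs$identity_pct,
                       stringsAsFactors = FALSE)
  only_a <- setdiff(a$proteins$id, pairs$gene_a)
  only_b <- setdiff(b$proteins$id, pairs$gene_b)
  rows_a <- data.frame(gene_a = only_a, gene_b = NA_character_,
                       present_a = 1L, present_b = 0L,
                       identity_pct = NA_real_, stringsAsFactors = FALSE)
  rows_b <- data.frame(gene_a = NA_character_, gene_b = only_b,
                       present_a = 0L, present_b = 1L,
                       identity_pct = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(shared, rows_a, rows_b)
  rownames(out) <- NULL
  out
}
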