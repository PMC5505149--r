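#' Global protein identifiers
#'
#' Pan-genome analyses pool proteins across strains; proteins are addressed as
#' `strain:protein_id`.
#'
#' @param strain,protein Character vectors.
#' @return Character vector of global ids.
#' @export
global_id <- function(strain, protein) paste(strain, protein, sep = ":")

.pan_universe <- function(proteomes) {
  do.call(rbind, lapply(proteomes, function(p) {
    data.frame(gid = global_id(p$strain_id, p$proteins$id),
               strain = p$strain_id,
               protein = p$proteins$id,
               sequence = p$proteins$sequence,
               stringsAsFactors = FALSE)
  }))
}

#' All-against-all homology edges
#'
#' Local alignments between every unordered protein pair (within and across
#' strains). A pair forms an edge iff the alignment has at least
#' `identity_min` percent identity, covers at least `coverage_min` of the
#' smallest (shorter) protein, and its e-value is smaller than `evalue_max`.
#'
#' A score cutoff derived from the e-value threshold prunes pairs before the
#' full traceback alignment; this cannot change the edge set because the
#' e-value is a monotone function of the score.
#'
#' @param proteomes List of [proteome()]s.
#' @param identity_min Percent identity threshold in `(0, 100]`.
#' @param coverage_min Fraction of the shorter protein that the aligned span
#'   must cover, in `(0, 1]` (default 0.80).
#' @param evalue_max E-value threshold (default `1e-4`, exclusive).
#' @param s A [scoring_scheme()].
#' @param search_space `"database"` (e-value uses the summed length of all
#'   proteins as subject size, the default) or `"pairwise"`.
#' @return Data frame with columns `protein_a`, `protein_b` (global ids,
#'   `a < b`), `identity_pct`, `coverage_smallest`, `evalue`, `score`,
#'   ordered by (`protein_a`, `protein_b`).
#' @export
homology_edges <- function(proteomes, identity_min, coverage_min = 0.80,
                           evalue_max = 1e-4, s = scoring_protein(),
                           search_space = c("database", "pairwise")) {
  search_space <- match.arg(search_space)
  if (identity_min <= 0 || identity_min > 100) {
    stop("configuration error: identity_min must be in (0, 100]")
  }
  if (coverage_min <= 0 || coverage_min > 1) {
    stop("configuration error: coverage_min must be in (0, 1]")
  }
  if (evalue_max <= 0) stop("configuration error: evalue_max must be positive")
  uni <- .pan_universe(proteomes)
  uni <- uni[order(uni$gid), , drop = FALSE]
  n <- nrow(uni)
  enc <- lapply(uni$sequence, .encode, s = s)
  lens <- nchar(uni$sequence)
  db_len <- sum(lens)

  scores <- .score_pairs_upper_cpp(enc, s$matrix, s$gap_open, s$gap_extend, TRUE)
  rows <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq((i + 1L), n)) {
      m <- lens[i]
      nn <- if (search_space == "database") db_len else lens[j]
      # minimal score for evalue < evalue_max
      smin <- log(s$K * m * nn / evalue_max) / s$lambda
      sc <- scores[i, j]
      if (sc <= 0 || sc <= smin) next
      raw <- .align_pair_cpp(enc[[i]], enc[[j]], s$matrix, s$ambig,
                             s$gap_open, s$gap_extend, TRUE)
      if (raw$aligned_cols == 0L) next
      idp <- 100 * raw$n_identical / raw$aligned_cols
      if (idp < identity_min) next
      short_is_a <- lens[i] <= lens[j]
      span <- if (short_is_a) raw$q_end - raw$q_start else raw$s_end - raw$s_start
      cov <- span / min(lens[i], lens[j])
      if (cov < coverage_min) next
      ev <- s$K * m * nn * exp(-s$lambda * raw$score)
      if (ev >= evalue_max) next
      rows[[length(rows) + 1L]] <-
        data.frame(protein_a = uni$gid[i], protein_b = uni$gid[j],
                   identity_pct = idp, coverage_smallest = cov,
                   evalue = ev, score = raw$score, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(protein_a = character(), protein_b = character(),
               identity_pct = numeric(), coverage_smallest = numeric(),
               evalue = numeric(), score = numeric(), stringsAsFactors = FALSE))))
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-linkage protein families
#'
#' Families are the connected components of the homology-edge graph: a protein
#' joins a family if it has a qualifying alignment to any protein already in
#' the family. Proteins without edges form singleton families. Each family is
#' identified by its lexicographically smallest member id.
#'
#' @param edges Edge table from [homology_edges()] (only `protein_a`,
#'   `protein_b` are used).
#' @param universe Character vector of all protein global ids.
#' @param params Optional list of the thresholds used (stored for reporting).
#' @return An object of class `FamilyClustering` with elements `families`
#'   (named list of member vectors), `membership` (member -> family id) and
#'   `params`.
#' @export
cluster_families <- function(edges, universe, params = list()) {
  if (anyDuplicated(universe)) stop("universe contains duplicate ids")
  dangling <- setdiff(c(edges$protein_a, edges$protein_b), universe)
  if (length(dangling) > 0L) {
    stop("data error: edge endpoint not in universe: ", dangling[1L])
  }
  universe <- sort(universe)
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = universe, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  fam_of <- tapply(names(comp), comp, function(ids) sort(ids), simplify = FALSE)
  attributes(fam_of) <- NULL                      # plain list, no array dims
  fam_ids <- vapply(fam_of, `[`, character(1), 1L)
  names(fam_of) <- fam_ids
  fam_of <- fam_of[order(fam_ids)]
  membership <- setNames(rep(names(fam_of), lengths(fam_of)),
                         unlist(fam_of, use.names = FALSE))
  structure(list(families = fam_of,
                 membership = membership,
                 params = params),
            class = "FamilyClustering")
}

#' @export
print.FamilyClustering <- function(x, ...) {
  cat("FamilyClustering:", length(x$families), "families over",
      length(x$membership), "proteins\n")
  invisible(x)
}

#' Pan-genome size across identity thresholds
#'
#' Rebuilds the single-linkage clustering at each identity threshold and
#' reports the family count. Edges are computed once at the loosest threshold;
#' stricter thresholds only remove edges, so family counts are non-decreasing
#' in the threshold.
#'
#' @param proteomes List of [proteome()]s.
#' @param identity_thresholds Percent thresholds, sorted ascending.
#' @param coverage_min,evalue_max,s,search_space As in [homology_edges()].
#' @return Data frame with columns `identity_min` and `n_families`.
#' @export
pangenome_summary <- function(proteomes, identity_thresholds = c(40, 50, 70, 80),
                              coverage_min = 0.80, evalue_max = 1e-4,
                              s = scoring_protein(),
                              search_space = c("database", "pairwise")) {
  if (is.unsorted(identity_thresholds, strictly = FALSE)) {
    stop("identity_thresholds must be sorted ascending")
  }
  edges <- homology_edges(proteomes, identity_min = min(identity_thresholds),
                          coverage_min = coverage_min, evalue_max = evalue_max,
                          s = s, search_space = search_space)
  universe <- sort(.pan_universe(proteomes)$gid)
  counts <- vapply(identity_thresholds, function(t) {
    sub <- edges[edges$identity_pct >= t, , drop = FALSE]
    length(cluster_families(sub, universe)$families)
  }, integer(1))
  data.frame(identity_min = identity_thresholds, n_families = counts)
}
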