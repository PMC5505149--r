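#' Pipeline configuration
#'
#' Bundles the input manifest, analysis level (which sets the 40/80 threshold
#' defaults), pivot choice and stage parameters. Every referenced file is
#' checked before any computation.
#'
#' @param manifest Data frame with columns `strain`, `genome_fasta`,
#'   `proteome_fasta` and optionally `gene_order_tsv` (NA allowed), or the
#'   path of a manifest TSV.
#' @param level `"species"` or `"genus"`: selects the default similarity /
#'   identity threshold bundle (80 / 40 percent) via [level_params()].
#' @param pivot Pivot strain id (default: first strain listed).
#' @param filter Optional [filter_params()] overriding the level defaults.
#' @param identity_thresholds Percent thresholds for the pan-genome sweep.
#' @param ani An [ani_params()].
#' @param outdir Output directory.
#' @param seed Integer seed recorded in the report (the analysis itself is
#'   deterministic).
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(manifest, level = c("species", "genus"),
                            pivot = NULL, filter = NULL,
                            identity_thresholds = c(40, 50, 70, 80),
                            ani = ani_params(), outdir = "pancore_out",
                            seed = 1) {
  level <- match.arg(level)
  if (is.character(manifest)) manifest <- read_tsv(manifest)
  stopifnot(is.data.frame(manifest),
            all(c("strain", "genome_fasta", "proteome_fasta") %in% names(manifest)),
            nrow(manifest) >= 2L)
  if (anyDuplicated(manifest$strain)) stop("duplicate strain in manifest")
  for (col in intersect(c("genome_fasta", "proteome_fasta", "gene_order_tsv"),
                        names(manifest))) {
    paths <- manifest[[col]]
    paths <- paths[!is.na(paths)]
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      stop("manifest validation error: file not found: ", missing[1L])
    }
  }
  lp <- level_params(level)
  if (is.null(filter)) filter <- lp$filter
  if (is.null(pivot)) pivot <- manifest$strain[1L]
  if (!pivot %in% manifest$strain) stop("pivot strain not in manifest")
  structure(list(manifest = manifest, level = level, pivot = pivot,
                 filter = filter, identity_min = lp$identity_min,
                 identity_thresholds = identity_thresholds,
                 ani = ani, outdir = outdir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.load_inputs <- function(cfg) {
  proteomes <- list()
  genomes <- list()
  for (k in seq_len(nrow(cfg$manifest))) {
    st <- cfg$manifest$strain[k]
    prot <- read_fasta(cfg$manifest$proteome_fasta[k], "protein")
    ord <- NULL
    if ("gene_order_tsv" %in% names(cfg$manifest) &&
        !is.na(cfg$manifest$gene_order_tsv[k])) {
      tab <- read_tsv(cfg$manifest$gene_order_tsv[k])
      ord <- tab[match(prot$id, tab$id), c("replicon", "rank")]
    }
    proteomes[[st]] <- proteome(st, prot, gene_order = ord)
    genomes[[st]] <- genome_seq(st, read_fasta(cfg$manifest$genome_fasta[k],
                                               "nucleotide"))
  }
  list(proteomes = proteomes, genomes = genomes)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full comparative-genomics pipeline
#'
#' Executes, in order: core-genome construction (pivot-anchored bidirectional
#' best hits), pan-genome clustering with the threshold sweep, the ANIb matrix
#' and species verdicts, gene-content reports (Venn partition for three-strain
#' sets, per-pair identity tables) and the neighbor-joining tree from core
#' ortholog distances. All tables are written as TSV under `cfg$outdir`,
#' together with a JSON summary recording every parameter actually used.
#' Identical configurations produce byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- .stage("load", .load_inputs(cfg))
  proteomes <- inputs$proteomes
  genomes <- inputs$genomes
  strains <- names(proteomes)
  s_prot <- scoring_protein()
  s_nuc <- scoring_nucleotide()

  core <- .stage("core", {
    pivot <- proteomes[[cfg$pivot]]
    others <- proteomes[setdiff(strains, cfg$pivot)]
    core_genome(pivot, others, cfg$filter, s_prot)
  })
  .stage("core", {
    write_tsv(core$mapping, file.path(cfg$outdir, "core_membership.tsv"))
    for (st in names(core$pair_tables)) {
      pt <- core$pair_tables[[st]]
      out <- cbind(strain_a = cfg$pivot, strain_b = st, pt)
      write_tsv(out, file.path(cfg$outdir, paste0("orthologs_", st, ".tsv")))
    }
  })

  pan <- .stage("pan", {
    edges <- homology_edges(proteomes, identity_min = min(c(cfg$identity_thresholds,
                                                            cfg$identity_min)),
                            s = s_prot)
    universe <- sort(.pan_universe(proteomes)$gid)
    level_edges <- edges[edges$identity_pct >= cfg$identity_min, , drop = FALSE]
    clustering <- cluster_families(level_edges, universe,
                                   params = list(identity_min = cfg$identity_min,
                                                 coverage_min = 0.80,
                                                 evalue_max = 1e-4))
    sweep <- vapply(cfg$identity_thresholds, function(t) {
      sub <- edges[edges$identity_pct >= t, , drop = FALSE]
      length(cluster_families(sub, universe)$families)
    }, integer(1))
    write_tsv(edges, file.path(cfg$outdir, "homology_edges.tsv"))
    fam_tab <- data.frame(family_id = names(clustering$families),
                          n_members = lengths(clustering$families),
                          members = vapply(clustering$families, paste,
                                           character(1), collapse = ","),
                          stringsAsFactors = FALSE)
    write_tsv(fam_tab, file.path(cfg$outdir, "families.tsv"))
    list(clustering = clustering,
         sweep = data.frame(identity_min = cfg$identity_thresholds,
                            n_families = sweep))
  })
  write_tsv(pan$sweep, file.path(cfg$outdir, "pangenome_sweep.tsv"))

  ani <- .stage("ani", anib_matrix(genomes, cfg$ani, s_nuc))
  verdicts <- .stage("ani", classify_species(ani, cfg$ani))
  .stage("ani", {
    am <- as.data.frame(round(ani$ani, 2))
    am <- cbind(query = rownames(ani$ani), am)
    write_tsv(am, file.path(cfg$outdir, "ani_matrix.tsv"))
    write_tsv(verdicts, file.path(cfg$outdir, "species_verdicts.tsv"))
  })

  genecontent <- .stage("genecontent", {
    pa <- presence_absence(pan$clustering, proteomes)
    venn <- if (length(strains) == 3L) venn_partition(pa, strains) else NULL
    if (!is.null(venn)) {
      write_tsv(data.frame(region = names(venn), n_families = as.integer(venn)),
                file.path(cfg$outdir, "venn_regions.tsv"))
    }
    for (st in names(core$pair_tables)) {
      rep <- pairwise_gene_identity_report(proteomes[[cfg$pivot]],
                                           proteomes[[st]],
                                           core$pair_tables[[st]])
      write_tsv(rep, file.path(cfg$outdir, paste0("gene_identity_",
                                                  cfg$pivot, "_", st, ".tsv")))
    }
    list(pa = pa, venn = venn)
  })

  tree <- .stage("tree", {
    idents <- core_pair_identities(core, proteomes, s_prot)
    d <- core_distance_matrix(core, idents)
    dm <- cbind(strain = rownames(d), as.data.frame(d))
    write_tsv(dm, file.path(cfg$outdir, "core_distances.tsv"))
    nwk <- nj_tree(d)
    writeLines(nwk, file.path(cfg$outdir, "core_tree.nwk"))
    list(distances = d, newick = nwk)
  })

  summary <- list(
    level = cfg$level,
    pivot = cfg$pivot,
    seed = cfg$seed,
    parameters = list(min_similarity = cfg$filter$min_similarity,
                      max_len_diff = cfg$filter$max_len_diff,
                      positional_window = cfg$filter$positional_window,
                      pan_identity_min = cfg$identity_min,
                      pan_coverage_min = 0.80,
                      pan_evalue_max = 1e-4,
                      ani_fragment_len = cfg$ani$fragment_len,
                      ani_hit_min_identity = cfg$ani$hit_min_identity,
                      ani_hit_min_coverage = cfg$ani$hit_min_coverage,
                      species_cutoff = cfg$ani$species_cutoff),
    n_strains = length(strains),
    core_size = length(core$core_members),
    smallest_proteome = core$smallest_proteome,
    core_coverage_pct = core_coverage_percent(length(core$core_members),
                                              core$smallest_proteome),
    pan_families = setNames(as.list(pan$sweep$n_families),
                            paste0("identity_", pan$sweep$identity_min)),
    ani_matrix = apply(ani$ani, 1, function(r) as.list(r), simplify = FALSE),
    species_verdicts = verdicts,
    venn = if (!is.null(genecontent$venn)) as.list(unclass(genecontent$venn)) else NULL,
    newick = tree$newick)
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(summary)
}
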