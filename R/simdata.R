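#' Synthetic pan-genome simulation parameters
#'
#' The generator emulates a clonal set of strains: a shared core gene
#' repertoire, accessory families under presence/absence variation, per-site
#' nucleotide divergence driving both protein similarity and ANI, and
#' conserved gene order with occasional relocation.
#'
#' `divergence` is the designed PAIRWISE per-site substitution fraction: every
#' strain is mutated independently from a common ancestor with a per-branch
#' probability `b` solved from `2 b (1 - b) + (2/3) b^2 = d`, so each strain
#' pair differs at a fraction `d` of sites in expectation.
#'
#' @param n_strains Number of strains (>= 2).
#' @param n_core_families Families present in every strain.
#' @param n_accessory_families Families present in some strains only (each is
#'   re-drawn until present in at least one and at most `n_strains - 1`
#'   strains).
#' @param accessory_presence_prob Per-strain presence probability of an
#'   accessory family, in `(0, 1)`.
#' @param mean_gene_len_codons Mean gene length in codons (lognormal,
#'   `sdlog = gene_len_sdlog`, minimum 50 codons).
#' @param gene_len_sdlog Lognormal spread of gene lengths.
#' @param divergence Designed pairwise per-site substitution fraction `d`,
#'   in `[0, 0.5)`. Substitutions only; mutations creating an in-frame stop
#'   codon are resampled.
#' @param rearrangement_prob Per-gene probability of relocation to a random
#'   genome position.
#' @param indel_prob Optional per-site probability of a small indel
#'   (geometric lengths, mean 2 nt) in the intergenic spacers; coding frames
#'   are never disrupted. Default 0 (off), which keeps the ANI-divergence
#'   relation exact.
#' @param spacer_len_range Intergenic spacer length range (nt).
#' @param seed Integer seed; all outputs are reproducible per seed.
#' @return An object of class `SimParams`.
#' @export
sim_params <- function(n_strains = 3, n_core_families = 30,
                       n_accessory_families = 15,
                       accessory_presence_prob = 0.5,
                       mean_gene_len_codons = 300, gene_len_sdlog = 0.25,
                       divergence = 0, rearrangement_prob = 0.01,
                       indel_prob = 0, spacer_len_range = c(50, 200),
                       seed = 1) {
  stopifnot(n_strains >= 2, n_core_families >= 1, n_accessory_families >= 0,
            accessory_presence_prob > 0, accessory_presence_prob < 1,
            mean_gene_len_codons >= 50, gene_len_sdlog > 0,
            rearrangement_prob >= 0, rearrangement_prob < 1,
            indel_prob >= 0, indel_prob < 0.5,
            length(spacer_len_range) == 2, spacer_len_range[1] >= 1,
            spacer_len_range[2] >= spacer_len_range[1])
  if (divergence < 0 || divergence >= 0.5) {
    stop("configuration error: divergence must lie in [0, 0.5)")
  }
  structure(list(n_strains = as.integer(n_strains),
                 n_core_families = as.integer(n_core_families),
                 n_accessory_families = as.integer(n_accessory_families),
                 accessory_presence_prob = accessory_presence_prob,
                 mean_gene_len_codons = mean_gene_len_codons,
                 gene_len_sdlog = gene_len_sdlog,
                 divergence = divergence,
                 rearrangement_prob = rearrangement_prob,
                 indel_prob = indel_prob,
                 spacer_len_range = as.integer(spacer_len_range),
                 seed = as.integer(seed)),
            class = "SimParams")
}

#' Expected ANI for a designed divergence
#'
#' Indel-free simulation makes the ANI-divergence relation exact:
#' `expected_ani(d) = 100 * (1 - d)`.
#'
#' @param d Designed pairwise substitution fraction in `[0, 0.5)`.
#' @return Percent.
#' @export
expected_ani <- function(d) {
  if (any(d < 0 | d >= 0.5)) stop("d must lie in [0, 0.5)")
  100 * (1 - d)
}

# per-branch substitution probability giving pairwise divergence d
.branch_prob <- function(d) {
  if (d == 0) return(0)
  0.75 * (1 - sqrt(1 - 4 * d / 3))
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.sense_codons <- function() {
  all64 <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  setdiff(all64, .STOPS)
}

# mutate a coding sequence with per-site probability b; substitutions are
# uniform over the three alternative bases; any mutation set creating an
# in-frame stop codon is re-drawn within that codon
.mutate_cds <- function(seq, b, coding = TRUE) {
  if (b == 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  hit <- which(runif(L) < b)
  if (length(hit) == 0L) return(seq)
  idx <- match(x[hit], .BASES)
  draw <- function(k) ((idx[k] - 1L + sample.int(3L, length(k), replace = TRUE)) %% 4L) + 1L
  x[hit] <- .BASES[draw(seq_along(hit))]
  if (coding) {
    hit_codon <- ((hit - 1L) %/% 3L) + 1L
    repeat {
      cod_start <- seq.int(1L, L - 2L, by = 3L)
      codons <- paste0(x[cod_start], x[cod_start + 1L], x[cod_start + 2L])
      bad <- which(codons %in% .STOPS)
      bad <- bad[bad %in% hit_codon]
      if (length(bad) == 0L) break
      for (bc in bad) {
        k <- which(hit_codon == bc)
        x[hit[k]] <- .BASES[draw(k)]
      }
    }
  }
  paste(x, collapse = "")
}

.random_spacer <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

# small indels (insertions/deletions of geometric length, mean 2) applied to
# non-coding sequence only
.indel_seq <- function(seq, p_indel) {
  if (p_indel == 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  sites <- which(runif(length(x)) < p_indel)
  if (length(sites) == 0L) return(seq)
  pieces <- character(0)
  prev <- 1L
  skip_until <- 0L
  for (k in sites) {
    if (k <= skip_until) next
    len <- rgeom(1L, 0.5) + 1L
    if (runif(1) < 0.5) {                     # insertion before site k
      pieces <- c(pieces, if (k > prev) paste(x[prev:(k - 1L)], collapse = "") else "",
                  paste(sample(.BASES, len, replace = TRUE), collapse = ""))
      prev <- k
    } else {                                  # deletion of [k, k+len)
      pieces <- c(pieces, if (k > prev) paste(x[prev:(k - 1L)], collapse = "") else "")
      prev <- min(k + len, length(x) + 1L)
      skip_until <- prev - 1L
    }
  }
  if (prev <= length(x)) pieces <- c(pieces, paste(x[prev:length(x)], collapse = ""))
  paste(pieces, collapse = "")
}

.translate_cds <- function(seqs) {
  aa <- Biostrings::translate(Biostrings::DNAStringSet(seqs))
  as.character(aa)
}

#' Simulate a synthetic pan-genome with ground truth
#'
#' Draws ancestor gene families (random coding sequences without in-frame
#' stops), assigns each strain every core family and accessory families by
#' independent presence draws, mutates every present gene and intergenic
#' spacer per strain, translates genes into proteomes, and concatenates genes
#' (in a possibly locally rearranged ancestor order) with spacers into a
#' single-replicon genome per strain.
#'
#' @param p A [sim_params()].
#' @return List with elements `genomes` (list of [genome_seq()]), `proteomes`
#'   (list of [proteome()] with gene order), `truth` (class `SimTruth`: family
#'   memberships per strain, true core family ids, the true ortholog map per
#'   strain pair, and realized pairwise substitution fractions per gene and
#'   genome-wide), and `params`.
#' @export
simulate_pangenome <- function(p = sim_params()) {
  stopifnot(inherits(p, "SimParams"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(p$seed)

  n_fam <- p$n_core_families + p$n_accessory_families
  fam_ids <- sprintf("fam%04d", seq_len(n_fam))
  core_ids <- fam_ids[seq_len(p$n_core_families)]
  strains <- sprintf("S%02d", seq_len(p$n_strains))

  sense <- .sense_codons()
  len_codons <- pmax(50L, round(rlnorm(n_fam,
                                       log(p$mean_gene_len_codons) - p$gene_len_sdlog^2 / 2,
                                       p$gene_len_sdlog)))
  anc_gene <- vapply(len_codons, function(L) {
    paste(sample(sense, L, replace = TRUE), collapse = "")
  }, character(1))
  anc_spacer <- vapply(seq_len(n_fam), function(i) {
    .random_spacer(sample(seq(p$spacer_len_range[1], p$spacer_len_range[2]), 1L))
  }, character(1))
  names(anc_gene) <- names(anc_spacer) <- fam_ids

  # presence matrix: core everywhere; accessory in >= 1 and <= n-1 strains
  pres <- matrix(TRUE, n_fam, p$n_strains, dimnames = list(fam_ids, strains))
  for (i in seq_len(p$n_accessory_families)) {
    repeat {
      row <- runif(p$n_strains) < p$accessory_presence_prob
      if (any(row) && !all(row)) break
    }
    pres[p$n_core_families + i, ] <- row
  }

  anc_order <- sample(fam_ids)
  b <- .branch_prob(p$divergence)

  gene_seq <- list()    # strain -> named vector fam -> mutated CDS
  gene_id <- list()     # strain -> named vector fam -> protein/gene id
  genomes <- list()
  proteomes <- list()

  for (st in strains) {
    fams <- anc_order[pres[anc_order, st]]
    # occasional relocation of single genes
    if (p$rearrangement_prob > 0 && length(fams) > 2L) {
      moved <- which(runif(length(fams)) < p$rearrangement_prob)
      for (mv in moved) {
        fam <- fams[mv]
        rest <- fams[fams != fam]
        at <- sample.int(length(rest) + 1L, 1L)
        fams <- append(rest, fam, after = at - 1L)
      }
    }
    genes <- vapply(fams, function(f) .mutate_cds(anc_gene[[f]], b), character(1))
    spacers <- vapply(fams, function(f) {
      sp <- .mutate_cds(anc_spacer[[f]], b, coding = FALSE)
      .indel_seq(sp, p$indel_prob)
    }, character(1))
    ids <- sprintf("%s_g%04d", st, seq_along(fams))
    names(genes) <- names(spacers) <- fams
    gene_seq[[st]] <- genes
    gene_id[[st]] <- setNames(ids, fams)
    chrom <- paste(paste0(spacers, genes), collapse = "")
    genomes[[st]] <- genome_seq(st, data.frame(id = "chr", sequence = chrom,
                                               stringsAsFactors = FALSE))
    prot <- .translate_cds(unname(genes))
    proteomes[[st]] <- proteome(
      st,
      data.frame(id = ids, description = "", sequence = prot,
                 stringsAsFactors = FALSE),
      gene_order = data.frame(replicon = "chr", rank = seq_along(fams)))
  }
  names(genomes) <- names(proteomes) <- strains

  truth <- .sim_truth(strains, fam_ids, core_ids, pres, gene_id, gene_seq)
  list(genomes = genomes, proteomes = proteomes, truth = truth, params = p)
}

.sim_truth <- function(strains, fam_ids, core_ids, pres, gene_id, gene_seq) {
  families <- lapply(fam_ids, function(f) {
    present <- strains[pres[f, ]]
    setNames(vapply(present, function(st) gene_id[[st]][[f]], character(1)),
             present)
  })
  names(families) <- fam_ids

  pair_rows <- list()
  div_gene <- list()
  div_genome <- list()
  for (i in seq_along(strains)) {
    for (j in seq_along(strains)) {
      if (j <= i) next
      si <- strains[i]; sj <- strains[j]
      shared <- fam_ids[pres[, si] & pres[, sj]]
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(strain_a = si, strain_b = sj,
                   gene_a = unname(gene_id[[si]][shared]),
                   gene_b = unname(gene_id[[sj]][shared]),
                   family = shared, stringsAsFactors = FALSE)
      divs <- vapply(shared, function(f) {
        xa <- strsplit(gene_seq[[si]][[f]], "")[[1]]
        xb <- strsplit(gene_seq[[sj]][[f]], "")[[1]]
        mean(xa != xb)
      }, numeric(1))
      lens <- nchar(gene_seq[[si]][shared])
      div_gene[[length(div_gene) + 1L]] <-
        data.frame(strain_a = si, strain_b = sj, family = shared,
                   divergence = unname(divs), stringsAsFactors = FALSE)
      div_genome[[length(div_genome) + 1L]] <-
        data.frame(strain_a = si, strain_b = sj,
                   divergence = sum(divs * lens) / sum(lens),
                   n_sites = sum(lens), stringsAsFactors = FALSE)
    }
  }
  structure(list(families = families,
                 core_families = core_ids,
                 ortholog_map = do.call(rbind, pair_rows),
                 divergence_per_gene = do.call(rbind, div_gene),
                 divergence_genome = do.call(rbind, div_genome)),
            class = "SimTruth")
}

#' Write a simulated data set to disk in standard formats
#'
#' Genomes and proteomes as FASTA, gene orders as TSV, ground truth as JSON,
#' plus a manifest TSV suitable for [pipeline_config()]. The pipeline consumes
#' these files exactly as it would real inputs.
#'
#' @param sim A [simulate_pangenome()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
sim_write <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strains <- names(sim$proteomes)
  manifest <- data.frame(strain = strains,
                         genome_fasta = file.path(dir, paste0(strains, ".fna")),
                         proteome_fasta = file.path(dir, paste0(strains, ".faa")),
                         gene_order_tsv = file.path(dir, paste0(strains, "_order.tsv")),
                         stringsAsFactors = FALSE)
  for (k in seq_along(strains)) {
    st <- strains[k]
    g <- sim$genomes[[st]]
    write_fasta(g$replicons, manifest$genome_fasta[k])
    write_fasta(sim$proteomes[[st]]$proteins, manifest$proteome_fasta[k])
    ord <- cbind(id = sim$proteomes[[st]]$proteins$id,
                 sim$proteomes[[st]]$gene_order)
    write_tsv(ord, manifest$gene_order_tsv[k])
  }
  jsonlite::write_json(list(core_families = sim$truth$core_families,
                            families = sim$truth$families,
                            divergence_genome = sim$truth$divergence_genome),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  manifest_path <- file.path(dir, "manifest.tsv")
  write_tsv(manifest, manifest_path)
  invisible(manifest_path)
}
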