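#' Read a multi-record FASTA file
#'
#' Parses a protein or nucleotide FASTA file into a data frame of records.
#' Sequences are uppercased and line wrapping is ignored. The first whitespace
#' token of each header is the record id (a stable join key across the
#' pipeline); the remainder is kept as the description but never used as a key.
#'
#' @param path Path to an existing FASTA file.
#' @param alphabet `"protein"` (20 standard residues plus `X`) or
#'   `"nucleotide"` (`A`,`C`,`G`,`T`,`N`).
#' @return A `data.frame` with columns `id`, `description`, `sequence`,
#'   in file order.
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">g1 some protein", "acd", "efg"), tf)
#' read_fasta(tf, "protein")
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty input: no FASTA records in ", path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop("format error in ", path, ": record with empty id")
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("format error in ", path, ": duplicate record id '", dup, "'")
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (any(!nzchar(seqs))) {
    stop("format error in ", path, ": empty sequence for id '",
         ids[!nzchar(seqs)][1L], "'")
  }
  legal <- .alphabet_chars(alphabet)
  bad <- !vapply(strsplit(seqs, ""), function(ch) all(ch %in% legal), logical(1))
  if (any(bad)) {
    stop("format error in ", path, ": illegal ", alphabet, " residue at line ",
         .find_bad_line(path, legal), " (record '", ids[bad][1L], "')")
  }
  data.frame(id = ids, description = descriptions, sequence = seqs,
             stringsAsFactors = FALSE)
}

.alphabet_chars <- function(alphabet) {
  if (alphabet == "protein") {
    c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  } else {
    c("A", "C", "G", "T", "N")
  }
}

# locate the first body line holding a character outside `legal` (for messages)
.find_bad_line <- function(path, legal) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) next
    ch <- strsplit(toupper(ln), "")[[1]]
    if (!all(ch %in% legal)) return(i)
  }
  NA_integer_
}

#' Write records to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f), ...)` recovers the
#' ids and sequences exactly.
#'
#' @param records Data frame with columns `id` and `sequence` (optionally
#'   `description`).
#' @param path Output file path.
#' @param width Positive line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records), width >= 1)
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (anyDuplicated(records$id)) {
    stop("duplicate record id '", records$id[duplicated(records$id)][1L], "'")
  }
  if (any(!nzchar(records$sequence))) stop("empty sequence in records")
  hdr <- records$id
  if (!is.null(records$description)) {
    has <- nzchar(records$description)
    hdr[has] <- paste(records$id[has], records$description[has])
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  ok <- try(Biostrings::writeXStringSet(set, filepath = path, width = width),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("I/O error writing FASTA to ", path)
  }
  invisible(path)
}

#' Construct a proteome
#'
#' The unit of orthology analysis: one strain's ordered protein records,
#' optionally with the gene order on replicons (used by the positional
#' ortholog filter).
#'
#' @param strain_id Strain identifier.
#' @param proteins Data frame with columns `id`, `sequence` (optionally
#'   `description`), e.g. from [read_fasta()].
#' @param gene_order Optional data frame parallel to `proteins` with columns
#'   `replicon` and `rank`; ranks must be unique within a replicon.
#' @return An object of class `Proteome`.
#' @export
proteome <- function(strain_id, proteins, gene_order = NULL) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L, nzchar(strain_id),
            is.data.frame(proteins), nrow(proteins) >= 1L)
  if (anyDuplicated(proteins$id)) {
    stop("duplicate protein id in strain ", strain_id)
  }
  if (!is.null(gene_order)) {
    stopifnot(is.data.frame(gene_order),
              all(c("replicon", "rank") %in% names(gene_order)))
    if (nrow(gene_order) != nrow(proteins)) {
      stop("gene_order must have one row per protein")
    }
    if (any(tapply(gene_order$rank, gene_order$replicon, anyDuplicated) > 0)) {
      stop("gene ranks must be unique within a replicon")
    }
  }
  structure(list(strain_id = strain_id,
                 proteins = proteins[, intersect(c("id", "description", "sequence"),
                                                 names(proteins)), drop = FALSE],
                 gene_order = gene_order),
            class = "Proteome")
}

#' @export
print.Proteome <- function(x, ...) {
  cat("Proteome", x$strain_id, "with", nrow(x$proteins), "proteins",
      if (!is.null(x$gene_order)) "(gene order available)" else "", "\n")
  invisible(x)
}

#' Construct a genome sequence set
#'
#' @param strain_id Strain identifier.
#' @param replicons Data frame with columns `id`, `sequence` (nucleotide), one
#'   row per replicon, e.g. from [read_fasta()].
#' @return An object of class `GenomeSeq`.
#' @export
genome_seq <- function(strain_id, replicons) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L,
            is.data.frame(replicons), nrow(replicons) >= 1L)
  if (sum(nchar(replicons$sequence)) == 0L) stop("genome has zero total length")
  structure(list(strain_id = strain_id,
                 replicons = replicons[, intersect(c("id", "description", "sequence"),
                                                   names(replicons)), drop = FALSE]),
            class = "GenomeSeq")
}

#' @export
print.GenomeSeq <- function(x, ...) {
  cat("GenomeSeq", x$strain_id, ":", nrow(x$replicons), "replicon(s),",
      sum(nchar(x$replicons$sequence)), "nt\n")
  invisible(x)
}

#' Write a data frame as a TSV file
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV file written by [write_tsv()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8", check.names = FALSE)
}
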