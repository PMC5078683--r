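## Readers/writers for the interchange formats. External formats keep their
## native conventions (FASTA; GFF3/BED 1-based inclusive / BED 0-based
## half-open); everything internal is 0-based half-open, converted exactly
## once here.

#' Read a genome from a FASTA file
#'
#' Multi-record FASTA, wrapped or unwrapped. Record ids are truncated at the
#' first whitespace, matching common assembly-header practice.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id`, `sequence` (upper-case), `length`.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  as_genome(dss)
}

#' Write a genome tibble to FASTA
#'
#' @param genome Genome tibble (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 60L) {
  g <- as_genome(genome)
  dss <- Biostrings::DNAStringSet(stats::setNames(g$sequence, g$seq_id))
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' NCBI-dialect gene annotation (gene/mRNA/exon/CDS, optionally explicit
#' five_prime_UTR/three_prime_UTR features). Coordinates are converted from
#' GFF3 1-based inclusive to the package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `seq_id`, `type`, `start` (0-based),
#'   `end` (exclusive), `strand`, `feature_id`, `parent`.
#' @export
read_gff3 <- function(path) {
  df <- rtracklayer::readGFF(path)
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  } else {
    rep(NA_character_, nrow(df))
  }
  tibble::tibble(
    seq_id = as.character(df$seqid),
    type = as.character(df$type),
    start = as.integer(df$start) - 1L,   # 1-based inclusive -> 0-based
    end = as.integer(df$end),            # inclusive end == half-open end
    strand = as.character(df$strand),
    feature_id = if ("ID" %in% names(df)) as.character(df$ID) else NA_character_,
    parent = parent
  )
}

#' Read intervals from BED (or a GFF3 fallback)
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged;
#' a `.gff`/`.gff3` path is routed through [read_gff3()] instead.
#'
#' @param path Path to a BED file (3+ columns) or GFF3.
#' @return A tibble with columns `seq_id`, `start`, `end`, `name`.
#' @export
read_intervals <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- read_gff3(path)
    return(tibble::tibble(seq_id = g$seq_id, start = g$start, end = g$end,
                          name = g$feature_id))
  }
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # rtracklayer re-inflates to 1-based
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  )
}

#' Write a tibble as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#'
#' @param path Input path.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Export SSR loci as GFF3
#'
#' Feature type `microsatellite`; coordinates converted to GFF3's 1-based
#' inclusive convention on the way out.
#'
#' @param loci Locus tibble from [find_ssrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_gff3 <- function(loci, path) {
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\tpalmsat\tmicrosatellite\t%d\t%d\t.\t+\t.\tID=ssr%06d;unit=%s;motif_class=%s;repeat_count=%d",
      loci$seq_id, loci$start + 1L, loci$end, seq_len(nrow(loci)),
      loci$unit, loci$motif_class, loci$repeat_count
    )
  )
  writeLines(lines, path)
  invisible(path)
}
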