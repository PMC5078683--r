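## Chromosome-scale distribution analysis: non-overlapping windows of
## SSR/gene/TE counts, per-chromosome correlations, and genic-context
## classification (CDS > UTR > intron precedence, by locus start position).

#' Windowed SSR, gene and TE counts
#'
#' Tiles each sequence with non-overlapping windows (the final partial
#' window keeps its true span) and counts features whose start coordinate
#' falls in each window; a feature starting exactly on a boundary belongs
#' to the right-hand window.
#'
#' @param loci SSR locus tibble ([find_ssrs()]).
#' @param seq_len_tbl Tibble `seq_id`, `length` (e.g. from a genome tibble).
#' @param genes,tes Optional interval tibbles (`seq_id`, `start`, `end`,
#'   0-based half-open); for a [read_gff3()] table, rows of type `"gene"`
#'   are used. Features on sequences absent from `seq_len_tbl` are skipped
#'   with a warning.
#' @param window_size Window span in bases (default 1 Mb, matching per-Mb
#'   density reporting).
#' @return Tibble: `seq_id`, `window_index` (0-based), `window_start`,
#'   `window_span`, `ssr_count`, `gene_count`, `te_count`.
#' @export
window_densities <- function(loci, seq_len_tbl, genes = NULL, tes = NULL,
                             window_size = 1e6) {
  stopifnot(window_size >= 1)
  if (!is.null(genes) && "type" %in% names(genes)) {
    genes <- dplyr::filter(genes, .data$type == "gene")
  }
  windows <- purrr::map_dfr(seq_len(nrow(seq_len_tbl)), function(i) {
    len <- seq_len_tbl$length[i]
    starts <- seq.int(0, max(0, len - 1), by = window_size)
    tibble::tibble(seq_id = seq_len_tbl$seq_id[i],
                   window_index = seq_along(starts) - 1L,
                   window_start = starts,
                   window_span = pmin(window_size, len - starts))
  })
  count_in <- function(feat, col) {
    if (is.null(feat) || nrow(feat) == 0) {
      windows[[col]] <<- 0L
      return(invisible())
    }
    unknown <- !feat$seq_id %in% seq_len_tbl$seq_id
    if (any(unknown)) {
      warning(sprintf("%d features on unknown sequences skipped (%s)",
                      sum(unknown), col), call. = FALSE)
      feat <- feat[!unknown, ]
    }
    cnt <- feat |>
      dplyr::mutate(window_index = as.integer(.data$start %/% window_size)) |>
      dplyr::count(.data$seq_id, .data$window_index, name = "n")
    windows <<- windows |>
      dplyr::left_join(cnt, by = c("seq_id", "window_index")) |>
      dplyr::mutate(!!col := dplyr::coalesce(.data$n, 0L)) |>
      dplyr::select(-"n")
    invisible()
  }
  count_in(loci, "ssr_count")
  count_in(genes, "gene_count")
  count_in(tes, "te_count")
  windows
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3). A constant vector
#'   leaves the correlation undefined, reported as `NA`.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Per-chromosome SSR-gene and SSR-TE correlations
#'
#' Correlates window counts within each sequence, the conventional way of
#' reporting how SSR density tracks gene density and (anti-)tracks TE
#' density along chromosomes.
#'
#' @param windows Output of [window_densities()].
#' @return Tibble: `seq_id`, `n_windows`, `ssr_per_mb`, `gene_per_mb`,
#'   `te_per_mb`, `cor_ssr_te`, `cor_ssr_gene`.
#' @export
density_correlations <- function(windows) {
  windows |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(
      n_windows = dplyr::n(),
      ssr_per_mb = sum(.data$ssr_count) / (sum(.data$window_span) / 1e6),
      gene_per_mb = sum(.data$gene_count) / (sum(.data$window_span) / 1e6),
      te_per_mb = sum(.data$te_count) / (sum(.data$window_span) / 1e6),
      cor_ssr_te = if (dplyr::n() >= 3)
        pearson(.data$ssr_count, .data$te_count) else NA_real_,
      cor_ssr_gene = if (dplyr::n() >= 3)
        pearson(.data$ssr_count, .data$gene_count) else NA_real_,
      .groups = "drop")
}

## Build per-seq IRanges lists (1-based inclusive) for one feature type.
context_ranges <- function(ann) {
  split_tbl <- function(tbl) {
    if (nrow(tbl) == 0) return(list())
    lapply(split(tbl, tbl$seq_id), function(d) {
      IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    })
  }
  genes <- split_tbl(dplyr::filter(ann, .data$type == "gene"))
  cds <- split_tbl(dplyr::filter(ann, .data$type == "CDS"))
  utr_types <- c("five_prime_UTR", "three_prime_UTR", "UTR")
  utr_tbl <- dplyr::filter(ann, .data$type %in% utr_types)
  if (nrow(utr_tbl) > 0) {
    utr <- split_tbl(utr_tbl)
  } else {
    # no explicit UTR features: UTR = exon minus CDS, per sequence
    exons <- split_tbl(dplyr::filter(ann, .data$type == "exon"))
    utr <- lapply(stats::setNames(nm = names(exons)), function(sid) {
      IRanges::setdiff(exons[[sid]], cds[[sid]] %||% IRanges::IRanges())
    })
  }
  list(gene = genes, cds = cds, utr = utr)
}

#' Classify loci as CDS, UTR, intron or intergenic
#'
#' A locus is classified by its start position against all overlapping
#' transcripts with precedence CDS > UTR > intron: inside any annotated CDS
#' is `CDS`; else inside a UTR (explicit `five_prime_UTR`/`three_prime_UTR`
#' features, or exon-minus-CDS when the annotation has none; 5' and 3' are
#' collapsed) is `UTR`; else inside a gene span is `intron`; otherwise
#' `intergenic`.
#'
#' @param loci Locus tibble with `seq_id` and `start` columns.
#' @param annotation Gene-annotation tibble from [read_gff3()].
#' @return `loci` with an added `genic_context` column.
#' @export
classify_genic_context <- function(loci, annotation) {
  rng <- context_ranges(annotation)
  hit <- function(kind, sid, pos1) {
    r <- rng[[kind]][[sid]]
    if (is.null(r)) return(rep(FALSE, length(pos1)))
    IRanges::overlapsAny(IRanges::IRanges(pos1, pos1), r)
  }
  out <- purrr::map_dfr(split(loci, loci$seq_id), function(d) {
    sid <- d$seq_id[1]
    pos1 <- d$start + 1L          # point query, 1-based
    d$genic_context <- dplyr::case_when(
      hit("cds", sid, pos1) ~ "CDS",
      hit("utr", sid, pos1) ~ "UTR",
      hit("gene", sid, pos1) ~ "intron",
      TRUE ~ "intergenic")
    d
  })
  dplyr::arrange(out, .data$seq_id, .data$start)
}

#' Genic-context proportions
#'
#' @param contexts Character vector of contexts (`"CDS"`, `"UTR"`,
#'   `"intron"`, `"intergenic"`) or a tibble with a `genic_context` column.
#' @return Tibble with `level` (`"overall"` rows: genic vs intergenic;
#'   `"genic"` rows: CDS/UTR/intron as a share of genic loci), `class`,
#'   `n`, `pct`.
#' @export
context_proportions <- function(contexts) {
  if (is.data.frame(contexts)) contexts <- contexts$genic_context
  if (length(contexts) == 0) stop("no classified loci", call. = FALSE)
  stopifnot(all(contexts %in% c("CDS", "UTR", "intron", "intergenic")))
  n_total <- length(contexts)
  n_genic <- sum(contexts != "intergenic")
  overall <- tibble::tibble(
    level = "overall", class = c("genic", "intergenic"),
    n = c(n_genic, n_total - n_genic),
    pct = percentage(c(n_genic, n_total - n_genic), n_total))
  if (n_genic == 0) return(overall)
  gen <- factor(contexts[contexts != "intergenic"],
                levels = c("CDS", "UTR", "intron"))
  counts <- as.integer(table(gen))
  within <- tibble::tibble(level = "genic",
                           class = levels(gen),
                           n = counts,
                           pct = percentage(counts, n_genic))
  dplyr::bind_rows(overall, within)
}
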