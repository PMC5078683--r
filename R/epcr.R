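## Electronic PCR: mismatch-tolerant primer-site location on both strands,
## enumeration of orientation-consistent products inside a size window, and
## copy-number classification. Stringent mode (the default here) is
## Hamming-only: at most 1 mismatch per primer, no gaps, and a strict
## < 100 bp deviation from the expected product size. The permissive
## NCBI-style mode (2 mismatches, 1 gap) is available via `max_gaps`.

#' Electronic-PCR parameters
#'
#' @param stringent If `TRUE` (default) the stringent screen: 1 mismatch,
#'   0 gaps, size deviation strictly below 100 bp. Otherwise the permissive
#'   convention: 2 mismatches, 1 gap.
#' @param size_deviation Override the size window (strict `<`), bases.
#' @param three_prime_protect Number of 3'-terminal primer bases where a
#'   mismatch disqualifies the site outright (default 0: a mismatch may sit
#'   anywhere).
#' @return A list with `max_mismatch`, `max_gaps`, `size_deviation`,
#'   `three_prime_protect`.
#' @export
epcr_params <- function(stringent = TRUE, size_deviation = 100,
                        three_prime_protect = 0) {
  stopifnot(size_deviation >= 0, three_prime_protect >= 0)
  list(
    max_mismatch = if (stringent) 1L else 2L,
    max_gaps = if (stringent) 0L else 1L,
    size_deviation = size_deviation,
    three_prime_protect = as.integer(three_prime_protect)
  )
}

## Gap-free scan of `pc` along `tc`; returns 0-based starts and mismatch
## counts for positions within the mismatch budget. `protect` gives pattern
## indices (1-based) where any mismatch disqualifies the site.
hamming_scan <- function(tc, pc, max_mismatch, protect = integer()) {
  n <- length(tc); m <- length(pc)
  if (n < m) return(list(start = integer(), mismatches = integer()))
  npos <- n - m + 1L
  mm <- integer(npos)
  hard <- integer(npos)
  for (j in seq_len(m)) {
    seg <- tc[j:(j + npos - 1L)]
    miss <- seg != pc[j] | seg == "N"      # N never matches
    mm <- mm + miss
    if (j %in% protect) hard <- hard + miss
  }
  ok <- which(mm <= max_mismatch & hard == 0L)
  list(start = ok - 1L, mismatches = mm[ok])
}

## Banded DP for the gapped (permissive) mode: does `pattern` align within
## text starting at offset i with <= max_mm substitutions and <= max_gaps
## indels? Returns best (gaps, mismatches, end_offset) or NULL.
gapped_fit <- function(tc, pc, i, max_mm, max_gaps) {
  m <- length(pc)
  tl <- min(length(tc) - i, m + max_gaps)
  if (tl < m - max_gaps) return(NULL)
  sub <- tc[(i + 1):(i + tl)]
  INF <- 1e9
  # cost = gaps * (max_mm + 1) + mismatches, so gap count dominates ties
  prev <- c(0, seq_len(tl) * (max_mm + 1))
  for (p in seq_len(m)) {
    cur <- rep(INF, tl + 1)
    cur[1] <- p * (max_mm + 1)
    for (t in seq_len(tl)) {
      d <- prev[t] + (sub[t] != pc[p] | sub[t] == "N" | pc[p] == "N")
      cur[t + 1] <- min(d, prev[t + 1] + (max_mm + 1), cur[t] + (max_mm + 1))
    }
    prev <- cur
  }
  best <- NULL
  for (t in max(0, m - max_gaps):tl) {
    cost <- prev[t + 1]
    gaps <- cost %/% (max_mm + 1); mmc <- cost %% (max_mm + 1)
    if (gaps <= max_gaps && mmc <= max_mm) {
      if (is.null(best) || cost < best$cost) {
        best <- list(cost = cost, gaps = gaps, mismatches = mmc, span = t)
      }
    }
  }
  best
}

scan_one_strand <- function(tc, pc, params, protect) {
  if (params$max_gaps == 0L) {
    h <- hamming_scan(tc, pc, params$max_mismatch, protect)
    return(tibble::tibble(start = h$start,
                          end = h$start + length(pc),
                          mismatches = h$mismatches, gaps = 0L))
  }
  m <- length(pc)
  hits <- list()
  for (i in 0:(length(tc) - (m - params$max_gaps))) {
    fit <- gapped_fit(tc, pc, i, params$max_mismatch, params$max_gaps)
    if (!is.null(fit)) {
      hits[[length(hits) + 1]] <- tibble::tibble(
        start = i, end = i + fit$span,
        mismatches = fit$mismatches, gaps = fit$gaps)
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          mismatches = integer(), gaps = integer()))
  }
  hits <- dplyr::bind_rows(hits)
  # gapped alignments at adjacent offsets describe the same site: greedy
  # non-overlapping selection, best (fewest gaps+mismatches) first
  hits <- hits[order(hits$gaps + hits$mismatches, hits$start), ]
  sel <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- sel & hits$start < hits$end[i] & hits$end > hits$start[i]
    if (!any(ov)) sel[i] <- TRUE
  }
  hits[sel, , drop = FALSE][order(hits$start[sel]), ]
}

#' Find primer binding sites in a genome
#'
#' Locates every position, on either strand, where the primer matches the
#' sequence within the mismatch (and, in permissive mode, gap) budget.
#' N never matches. With `three_prime_protect > 0`, sites carrying a
#' mismatch within that many bases of the primer's 3' end are rejected.
#'
#' @param genome Genome tibble or named character vector.
#' @param primer DNA string (length >= 8), 5'→3'.
#' @param params See [epcr_params()].
#' @return A tibble: `seq_id`, `strand` (`"+"`/`"-"`), `start` (0-based),
#'   `end` (exclusive), `mismatches`, `gaps`. A `+` site means the primer
#'   matches the forward strand and extends rightward; a `-` site matches
#'   the reverse strand and extends leftward.
#' @export
find_binding_sites <- function(genome, primer, params = epcr_params()) {
  g <- as_genome(genome)
  pc <- assert_unambiguous(primer, "primer")
  if (length(pc) < 8) stop("primer length must be >= 8", call. = FALSE)
  m <- length(pc)
  tpp <- params$three_prime_protect
  prot_plus <- if (tpp > 0) seq.int(m - min(tpp, m) + 1L, m) else integer()
  prot_minus <- if (tpp > 0) seq_len(min(tpp, m)) else integer()
  rc <- seq_chars(revcomp(paste(pc, collapse = "")))
  purrr::map_dfr(seq_len(nrow(g)), function(i) {
    tc <- seq_chars(g$sequence[i])
    plus <- scan_one_strand(tc, pc, params, prot_plus)
    minus <- scan_one_strand(tc, rc, params, prot_minus)
    dplyr::bind_rows(
      dplyr::mutate(plus, strand = "+"),
      dplyr::mutate(minus, strand = "-")
    ) |>
      dplyr::mutate(seq_id = g$seq_id[i]) |>
      dplyr::select("seq_id", "strand", "start", "end", "mismatches", "gaps")
  }) |>
    dplyr::arrange(.data$seq_id, .data$start, .data$strand)
}

#' Enumerate in-silico PCR products from binding sites
#'
#' Pairs convergent sites — a forward-primer site and a reverse-primer site
#' facing each other on opposite strands, in either arrangement — whose
#' implied product deviates from the expected size by strictly less than
#' `params$size_deviation` bases. Sites may not overlap each other, so the
#' minimum product is the sum of the primer lengths.
#'
#' @param sites_f,sites_r Site tibbles from [find_binding_sites()] for the
#'   forward and reverse primer of one pair, same genome.
#' @param expected_size Expected product size, bases.
#' @param params See [epcr_params()].
#' @return Amplicon tibble: `seq_id`, `start`, `end`, `size`,
#'   `f_start`, `f_strand`, `f_mismatches`, `r_start`, `r_mismatches`,
#'   sorted by (`seq_id`, `start`).
#' @export
enumerate_amplicons <- function(sites_f, sites_r, expected_size,
                                params = epcr_params()) {
  empty <- tibble::tibble(
    seq_id = character(), start = integer(), end = integer(),
    size = integer(), f_start = integer(), f_strand = character(),
    f_mismatches = integer(), r_start = integer(), r_mismatches = integer())
  if (nrow(sites_f) == 0 || nrow(sites_r) == 0) return(empty)
  pair_up <- function(up, dn, up_is_f) {
    # `up` on + strand extends right; `dn` on - strand extends left
    grid <- tidyr::expand_grid(ui = seq_len(nrow(up)), di = seq_len(nrow(dn)))
    grid <- grid[up$seq_id[grid$ui] == dn$seq_id[grid$di], , drop = FALSE]
    if (nrow(grid) == 0) return(empty)
    size <- dn$end[grid$di] - up$start[grid$ui]
    ok <- dn$start[grid$di] >= up$end[grid$ui] &
      abs(size - expected_size) < params$size_deviation
    grid <- grid[ok, , drop = FALSE]; size <- size[ok]
    if (nrow(grid) == 0) return(empty)
    tibble::tibble(
      seq_id = up$seq_id[grid$ui],
      start = up$start[grid$ui],
      end = dn$end[grid$di],
      size = as.integer(size),
      f_start = if (up_is_f) up$start[grid$ui] else dn$start[grid$di],
      f_strand = if (up_is_f) "+" else "-",
      f_mismatches = if (up_is_f) up$mismatches[grid$ui] else dn$mismatches[grid$di],
      r_start = if (up_is_f) dn$start[grid$di] else up$start[grid$ui],
      r_mismatches = if (up_is_f) dn$mismatches[grid$di] else up$mismatches[grid$ui])
  }
  out <- dplyr::bind_rows(
    pair_up(sites_f[sites_f$strand == "+", ], sites_r[sites_r$strand == "-", ],
            up_is_f = TRUE),
    pair_up(sites_r[sites_r$strand == "+", ], sites_f[sites_f$strand == "-", ],
            up_is_f = FALSE)
  )
  dplyr::arrange(out, .data$seq_id, .data$start)
}

#' Classify marker copy number from a product count
#'
#' @param n_amplicons Integer vector of in-silico product counts.
#' @return Character vector: `"1"`, `"2"`, `"3"`, `">3"`; `NA` for zero
#'   products (no-product markers fall outside the classes).
#' @export
#' @examples
#' classify_copy_number(c(0, 1, 4, 57))
classify_copy_number <- function(n_amplicons) {
  if (any(n_amplicons < 0)) stop("negative product count", call. = FALSE)
  dplyr::case_when(
    n_amplicons == 0 ~ NA_character_,
    n_amplicons == 1 ~ "1",
    n_amplicons == 2 ~ "2",
    n_amplicons == 3 ~ "3",
    TRUE ~ ">3"
  )
}

#' Run electronic PCR for a primer table against a genome
#'
#' @param genome Genome tibble or named character vector.
#' @param primer_table Tibble with `marker_id`, `forward_seq`, `reverse_seq`,
#'   `expected_product_size` (as produced by [design_primers()], designed
#'   rows only).
#' @param params See [epcr_params()].
#' @return A list of two tibbles: `amplicons` (per product, with
#'   `marker_id`) and `markers` (per primer pair: `n_products`,
#'   `copy_number_class`, `best_size_deviation`).
#' @export
run_epcr <- function(genome, primer_table, params = epcr_params()) {
  g <- as_genome(genome)
  stopifnot(all(c("marker_id", "forward_seq", "reverse_seq",
                  "expected_product_size") %in% names(primer_table)))
  amp <- purrr::map_dfr(seq_len(nrow(primer_table)), function(i) {
    row <- primer_table[i, ]
    sf <- find_binding_sites(g, row$forward_seq, params)
    sr <- find_binding_sites(g, row$reverse_seq, params)
    a <- enumerate_amplicons(sf, sr, row$expected_product_size, params)
    if (nrow(a) == 0) return(NULL)
    a$marker_id <- row$marker_id
    a
  })
  per_marker <- tibble::tibble(marker_id = primer_table$marker_id,
                               expected_product_size = primer_table$expected_product_size)
  if (!is.null(amp) && nrow(amp) > 0) {
    counts <- amp |>
      dplyr::left_join(per_marker, by = "marker_id") |>
      dplyr::group_by(.data$marker_id) |>
      dplyr::summarise(
        n_products = dplyr::n(),
        best_size_deviation = min(abs(.data$size - .data$expected_product_size)),
        .groups = "drop")
  } else {
    amp <- tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), size = integer(),
                          f_start = integer(), f_strand = character(),
                          f_mismatches = integer(), r_start = integer(),
                          r_mismatches = integer(), marker_id = character())
    counts <- tibble::tibble(marker_id = character(), n_products = integer(),
                             best_size_deviation = numeric())
  }
  markers <- per_marker |>
    dplyr::left_join(counts, by = "marker_id") |>
    dplyr::mutate(n_products = dplyr::coalesce(.data$n_products, 0L),
                  copy_number_class = classify_copy_number(.data$n_products)) |>
    dplyr::select("marker_id", "n_products", "copy_number_class",
                  "best_size_deviation")
  list(amplicons = amp, markers = markers)
}
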