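## Detection of maximal perfect mono- to hexanucleotide tandem repeats.
##
## A locus is a maximal periodic run: the stretch cannot be extended by one
## repeat unit on either side, the recorded unit is the rotation starting at
## the run's leftmost base, and only the smallest primitive unit is reported
## (so (AT)4 is never also reported as (ATAT)2). Runs are broken by N and by
## sequence boundaries (maximality is vacuous at a contig end).

#' Default minimum repeat counts per unit length
#'
#' Twelve repeats for mononucleotides, four for di- through hexanucleotides.
#'
#' @return Named integer vector, names `"1"`..`"6"`.
#' @export
default_thresholds <- function() {
  c(`1` = 12L, `2` = 4L, `3` = 4L, `4` = 4L, `5` = 4L, `6` = 4L)
}

check_thresholds <- function(thresholds) {
  stopifnot(length(thresholds) == 6L,
            identical(names(thresholds), as.character(1:6)),
            all(thresholds >= 2))
  as.integer(thresholds)
}

#' Is a repeat unit primitive?
#'
#' A unit is primitive when it is not a whole-number concatenation of a
#' shorter unit (`"atat"` is two copies of `"at"`, hence not primitive).
#'
#' @param unit Character vector of DNA units, each of length 1--6.
#' @return Logical vector.
#' @export
#' @examples
#' is_primitive(c("atat", "aat"))  # FALSE TRUE
is_primitive <- function(unit) {
  if (any(!nzchar(unit))) stop("empty repeat unit", call. = FALSE)
  len <- nchar(unit)
  if (any(len > 6)) stop("unit length must be 1-6", call. = FALSE)
  vapply(unit, function(u) {
    n <- nchar(u)
    for (d in seq_len(n - 1)) {
      if (n %% d == 0 && strrep(substr(u, 1, d), n / d) == u) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Motif class label of a repeat unit
#'
#' Pairs the unit, in the rotational phase in which it was scanned, with its
#' reverse complement (`"tc"` -> `"tc/ga"`). Rotations are deliberately not
#' merged -- `"ca/tg"` and `"gt/ac"` are distinct classes -- and a
#' self-reverse-complementary unit keeps a single-part label (`"at"`).
#'
#' @param unit Character vector of primitive DNA units.
#' @return Character vector of class labels, lower-case.
#' @export
#' @examples
#' canonicalize_motif(c("tc", "at", "ca"))
canonicalize_motif <- function(unit) {
  if (!all(is_primitive(unit))) {
    stop("motif class is defined for primitive units only", call. = FALSE)
  }
  u <- tolower(unit)
  rc <- tolower(revcomp(u))
  ifelse(u == rc, u, paste0(u, "/", rc))
}

## Scan one character vector for maximal runs of period k.
## Returns a data.frame of 0-based half-open loci (unit lower-case).
scan_period <- function(ch, k, min_rep) {
  n <- length(ch)
  out0 <- data.frame(start = integer(), end = integer(), unit = character(),
                     repeat_count = integer())
  if (n < k * min_rep) return(out0)
  left <- ch[seq_len(n - k)]
  m <- left == ch[seq.int(k + 1L, n)] & left != "N"
  r <- rle(m)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L        # 1-based index into m
  keep <- r$values & (r$lengths + k) >= k * min_rep
  if (!any(keep)) return(out0)
  starts0 <- run_start[keep] - 1L              # 0-based locus start
  span <- r$lengths[keep] + k                  # periodic stretch, bases
  count <- span %/% k
  unit <- vapply(starts0, function(s) {
    paste(ch[(s + 1L):(s + k)], collapse = "")
  }, character(1))
  prim <- is_primitive(unit)
  data.frame(start = starts0[prim], end = starts0[prim] + k * count[prim],
             unit = tolower(unit[prim]), repeat_count = count[prim])
}

#' Find all perfect microsatellites in a genome
#'
#' Detects every maximal run of a primitive 1--6 bp unit meeting the minimum
#' repeat count for its unit length. Scanning is case-insensitive; N breaks
#' a run (a repeat spanning unknown bases is not perfect).
#'
#' @param genome Genome tibble (see [read_genome()]) or named character
#'   vector of sequences.
#' @param thresholds Named integer vector of minimum repeat counts for unit
#'   lengths 1--6; see [default_thresholds()].
#' @return A tibble of loci sorted by (`seq_id`, `start`): `seq_id`,
#'   `start` (0-based), `end` (exclusive), `unit` (lower-case, phase as
#'   scanned), `unit_length`, `repeat_count`, `motif_class`, `length`.
#' @export
#' @examples
#' find_ssrs(c(chr = "GGCATATATATGG"))
find_ssrs <- function(genome, thresholds = default_thresholds()) {
  g <- as_genome(genome)
  if (nrow(g) == 0 || all(g$length == 0)) stop("empty genome", call. = FALSE)
  thresholds <- check_thresholds(thresholds)
  res <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    ch <- seq_chars(g$sequence[i], what = sprintf("sequence '%s'", g$seq_id[i]))
    hits <- purrr::map_dfr(1:6, function(k) {
      scan_period(ch, k, thresholds[[k]])
    })
    if (nrow(hits) == 0) return(NULL)
    hits$seq_id <- g$seq_id[i]
    hits
  })
  if (is.null(res) || nrow(res) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), unit = character(),
                          unit_length = integer(), repeat_count = integer(),
                          motif_class = character(), length = integer()))
  }
  res <- tibble::as_tibble(res)
  res$unit_length <- nchar(res$unit)
  res$motif_class <- canonicalize_motif(res$unit)
  res$length <- res$end - res$start
  dplyr::arrange(
    dplyr::select(res, "seq_id", "start", "end", "unit", "unit_length",
                  "repeat_count", "motif_class", "length"),
    .data$seq_id, .data$start, .data$unit_length
  )
}

TIER_NAMES <- c("mono", "di", "tri", "tetra", "penta", "hexa")

#' Percentage of a total
#'
#' The rounding-free percentage used throughout the summary and reporting
#' code: `100 * n / total`.
#'
#' @param n Numerator count(s).
#' @param total Denominator.
#' @return Numeric percentage(s).
#' @export
percentage <- function(n, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  100 * n / total
}

#' Summarize a locus table by unit-length tier and motif class
#'
#' Produces the per-tier and per-class statistics conventionally reported for
#' genome-wide SSR surveys: counts, percentage of all loci, percentage within
#' the unit-length tier, repeat-count range and mean, and total repeat
#' length, plus overall density when the genome length is supplied.
#'
#' @param loci Locus tibble from [find_ssrs()].
#' @param genome_length Total assembly length in bases (optional; enables
#'   the density columns of the `total` row).
#' @return A tibble with a `level` column (`"total"`, `"tier"`, `"class"`);
#'   class rows are nested within tiers. Columns: `tier`, `motif_class`,
#'   `n`, `pct_total`, `pct_tier`, `min_repeats`, `max_repeats`,
#'   `mean_repeats`, `total_length_bp`, `density_per_mb`, `kb_per_ssr`.
#' @export
summarize_ssrs <- function(loci, genome_length = NA_real_) {
  empty_stats <- tibble::tibble(
    level = "total", tier = NA_character_, motif_class = NA_character_,
    n = 0L, pct_total = NA_real_, pct_tier = NA_real_,
    min_repeats = NA_integer_, max_repeats = NA_integer_,
    mean_repeats = NA_real_, total_length_bp = 0,
    density_per_mb = 0, kb_per_ssr = NA_real_
  )
  if (nrow(loci) == 0) return(empty_stats)
  total_n <- nrow(loci)
  dens <- if (is.na(genome_length)) {
    tibble::tibble(per_mb = NA_real_, kb_per_locus = NA_real_)
  } else {
    ssr_density(total_n, genome_length)
  }
  tot <- tibble::tibble(
    level = "total", tier = NA_character_, motif_class = NA_character_,
    n = total_n, pct_total = 100, pct_tier = NA_real_,
    min_repeats = min(loci$repeat_count), max_repeats = max(loci$repeat_count),
    mean_repeats = mean(loci$repeat_count),
    total_length_bp = sum(loci$length),
    density_per_mb = dens$per_mb, kb_per_ssr = dens$kb_per_locus
  )
  tiers <- loci |>
    dplyr::mutate(tier = TIER_NAMES[.data$unit_length]) |>
    dplyr::group_by(.data$tier) |>
    dplyr::summarise(
      n = dplyr::n(),
      min_repeats = min(.data$repeat_count),
      max_repeats = max(.data$repeat_count),
      mean_repeats = mean(.data$repeat_count),
      total_length_bp = sum(.data$length), .groups = "drop"
    ) |>
    dplyr::mutate(level = "tier", motif_class = NA_character_,
                  pct_total = percentage(.data$n, total_n),
                  pct_tier = NA_real_,
                  density_per_mb = NA_real_, kb_per_ssr = NA_real_)
  classes <- loci |>
    dplyr::mutate(tier = TIER_NAMES[.data$unit_length]) |>
    dplyr::group_by(.data$tier, .data$motif_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      min_repeats = min(.data$repeat_count),
      max_repeats = max(.data$repeat_count),
      mean_repeats = mean(.data$repeat_count),
      total_length_bp = sum(.data$length), .groups = "drop"
    ) |>
    dplyr::left_join(dplyr::select(tiers, "tier", tier_n = "n"), by = "tier") |>
    dplyr::mutate(level = "class",
                  pct_total = percentage(.data$n, total_n),
                  pct_tier = percentage(.data$n, .data$tier_n),
                  density_per_mb = NA_real_, kb_per_ssr = NA_real_) |>
    dplyr::select(-"tier_n")
  cols <- names(empty_stats)
  out <- dplyr::bind_rows(tot[cols], tiers[cols], classes[cols])
  out$tier <- factor(out$tier, levels = TIER_NAMES)
  dplyr::arrange(out, !is.na(.data$tier), .data$tier,
                 .data$level == "class", dplyr::desc(.data$n)) |>
    dplyr::mutate(tier = as.character(.data$tier))
}

#' SSR density and spacing
#'
#' @param n_loci Number of loci.
#' @param genome_length Assembly length in bases.
#' @return One-row tibble: `per_mb` (loci per megabase) and `kb_per_locus`
#'   (mean spacing in kilobases; `NA` when `n_loci` is zero).
#' @export
#' @examples
#' ssr_density(1, 1e6)  # 1 per Mb, 1000 kb spacing
ssr_density <- function(n_loci, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive", call. = FALSE)
  tibble::tibble(
    per_mb = if (n_loci == 0) 0 else n_loci / (genome_length / 1e6),
    kb_per_locus = if (n_loci == 0) NA_real_ else (genome_length / 1e3) / n_loci
  )
}
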