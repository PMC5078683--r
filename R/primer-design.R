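## Primer design under fixed physico-chemical constraints: Tm 58-62 C,
## length 18-24 bp, GC 45-55 %, product 100-250 bp, primers strictly flanking
## (never overlapping) the SSR. The candidate search is exhaustive over
## (window, length) combinations and fully deterministic.

#' Default primer design constraints
#'
#' @return A list: `tm` (°C), `len` (bases), `gc` (%), `product` (bases),
#'   each a `c(min, max)` pair.
#' @export
default_primer_constraints <- function() {
  list(tm = c(58, 62), len = c(18L, 24L), gc = c(45, 55),
       product = c(100L, 250L))
}

check_constraints <- function(constraints) {
  stopifnot(all(c("tm", "len", "gc", "product") %in% names(constraints)))
  for (nm in c("tm", "len", "gc", "product")) {
    r <- constraints[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop(sprintf("constraint '%s' must be c(min, max) with min <= max", nm),
           call. = FALSE)
    }
  }
  constraints
}

#' GC content of DNA strings
#'
#' @param seq Character vector of unambiguous DNA strings.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' gc_content("GCGC")  # 100
gc_content <- function(seq) {
  vapply(seq, function(s) {
    ch <- assert_unambiguous(s, "primer")
    percentage(sum(ch %in% c("G", "C")), length(ch))
  }, numeric(1), USE.NAMES = FALSE)
}

## Unified nearest-neighbor stack parameters (dH kcal/mol, dS cal/mol/K),
## duplex-symmetric entries filled in for both strand readings.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
GAS_CONSTANT <- 1.987   # cal / (K mol)

tm_nearest_neighbor <- function(ch, na_molar, ct_molar) {
  n <- length(ch)
  stacks <- paste0(ch[-n], ch[-1])
  dh <- sum(NN_DH[stacks])
  ds <- sum(NN_DS[stacks])
  for (term in ch[c(1, n)]) {        # duplex initiation at each terminus
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_molar)   # entropic salt correction
  1000 * dh / (ds + GAS_CONSTANT * log(ct_molar / 4)) - 273.15
}

#' Oligonucleotide melting temperature
#'
#' Nearest-neighbor thermodynamics with the unified duplex parameter set
#' (entropic salt correction, total-strand-concentration/4 term; the primer
#' is assumed in excess over template, so no self-complementarity
#' correction), or the Wallace 2(A+T)+4(G+C) rule.
#'
#' @param seq Character vector of unambiguous DNA strings (length >= 8 for
#'   the nearest-neighbor method).
#' @param method `"nearest_neighbor"` (default; used for constraint
#'   checking) or `"wallace"`.
#' @param na_mM Monovalent cation concentration, mM.
#' @param oligo_nM Total oligonucleotide concentration, nM.
#' @return Numeric vector of melting temperatures in °C.
#' @export
#' @examples
#' melting_temp("AAAAAAAAAA", method = "wallace")  # 20
melting_temp <- function(seq, method = c("nearest_neighbor", "wallace"),
                         na_mM = 50, oligo_nM = 50) {
  method <- match.arg(method)
  vapply(seq, function(s) {
    ch <- assert_unambiguous(s, "primer")
    if (method == "wallace") {
      2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
    } else {
      if (length(ch) < 8) {
        stop("nearest-neighbor Tm needs length >= 8", call. = FALSE)
      }
      tm_nearest_neighbor(ch, na_mM / 1e3, oligo_nM / 1e9)
    }
  }, numeric(1), USE.NAMES = FALSE)
}

## Enumerate candidate primers on one side of a locus. `starts` are 0-based
## window starts; returns tibble with per-candidate Tm/GC and pass flags.
candidate_windows <- function(ch, starts, lens, reverse, constraints,
                              na_mM, oligo_nM) {
  grid <- tidyr::expand_grid(start = starts, len = lens)
  grid <- grid[grid$start >= 0 & grid$start + grid$len <= length(ch), ]
  if (nrow(grid) == 0) return(grid)
  grid$seq <- vapply(seq_len(nrow(grid)), function(i) {
    paste(ch[(grid$start[i] + 1):(grid$start[i] + grid$len[i])], collapse = "")
  }, character(1))
  if (reverse) grid$seq <- revcomp(grid$seq)
  has_n <- grepl("N", grid$seq, fixed = TRUE)
  grid$gc <- NA_real_
  grid$tm <- NA_real_
  ok <- !has_n
  grid$gc[ok] <- gc_content(grid$seq[ok])
  grid$gc_pass <- ok & grid$gc >= constraints$gc[1] & grid$gc <= constraints$gc[2]
  # Tm only where GC already passes: identical result, far fewer evaluations
  grid$tm[grid$gc_pass] <- melting_temp(grid$seq[grid$gc_pass],
                                        na_mM = na_mM, oligo_nM = oligo_nM)
  grid$tm_pass <- grid$gc_pass & grid$tm >= constraints$tm[1] &
    grid$tm <= constraints$tm[2]
  grid$ambiguous <- has_n
  grid
}

failure_row <- function(locus, reason) {
  tibble::tibble(
    marker_id = locus$marker_id, seq_id = locus$seq_id,
    locus_start = locus$start, locus_end = locus$end, unit = locus$unit,
    motif_class = locus$motif_class, repeat_count = locus$repeat_count,
    status = reason,
    forward_seq = NA_character_, reverse_seq = NA_character_,
    forward_start = NA_integer_, forward_len = NA_integer_,
    reverse_start = NA_integer_, reverse_len = NA_integer_,
    forward_tm = NA_real_, reverse_tm = NA_real_,
    forward_gc = NA_real_, reverse_gc = NA_real_,
    expected_product_size = NA_integer_,
    product_start = NA_integer_, product_end = NA_integer_
  )
}

design_one <- function(ch, locus, constraints, na_mM, oligo_nM) {
  n <- length(ch)
  len_min <- constraints$len[1]; len_max <- constraints$len[2]
  prod_min <- constraints$product[1]; prod_max <- constraints$product[2]
  locus_len <- locus$end - locus$start
  if (locus$start < len_min || n - locus$end < len_min) {
    return(failure_row(locus, "insufficient_flank"))
  }
  if (locus_len + 2 * len_min > prod_max) {
    return(failure_row(locus, "product_size"))
  }
  lens <- seq.int(len_min, len_max)
  f_starts <- seq.int(max(0L, locus$end - prod_max),
                      locus$start - len_min)
  r_starts <- seq.int(locus$end,
                      min(n - len_min, locus$start + prod_max - len_min))
  fw <- candidate_windows(ch, f_starts, lens, FALSE, constraints, na_mM, oligo_nM)
  rv <- candidate_windows(ch, r_starts, lens, TRUE, constraints, na_mM, oligo_nM)
  # forward primer must not cross into the SSR
  fw <- fw[fw$start + fw$len <= locus$start, ]
  vf <- fw[fw$tm_pass, ]
  vr <- rv[rv$tm_pass, ]
  if (nrow(vf) == 0 || nrow(vr) == 0) {
    fails <- dplyr::bind_rows(fw[!fw$tm_pass, ], rv[!rv$tm_pass, ])
    n_amb <- sum(fails$ambiguous)
    n_gc <- sum(!fails$ambiguous & !fails$gc_pass)
    n_tm <- sum(fails$gc_pass & !fails$tm_pass)
    reason <- c("ambiguous_bases", "gc_out_of_range", "tm_out_of_range")[
      which.max(c(n_amb, n_gc, n_tm))]
    return(failure_row(locus, reason))
  }
  pairs <- tidyr::expand_grid(fi = seq_len(nrow(vf)), ri = seq_len(nrow(vr)))
  product <- (vr$start[pairs$ri] + vr$len[pairs$ri]) - vf$start[pairs$fi]
  keep <- product >= prod_min & product <= prod_max
  if (!any(keep)) return(failure_row(locus, "product_size"))
  pairs <- pairs[keep, ]; product <- product[keep]
  f <- vf[pairs$fi, ]; r <- vr[pairs$ri, ]
  half <- function(rng) max((rng[2] - rng[1]) / 2, .Machine$double.eps)
  score <- abs(f$tm - mean(constraints$tm)) / half(constraints$tm) +
    abs(r$tm - mean(constraints$tm)) / half(constraints$tm) +
    abs(f$gc - mean(constraints$gc)) / half(constraints$gc) +
    abs(r$gc - mean(constraints$gc)) / half(constraints$gc) +
    abs(product - mean(constraints$product)) / half(constraints$product)
  ord <- order(score, product, f$start, f$len + r$len, r$start)
  b <- ord[1]
  tibble::tibble(
    marker_id = locus$marker_id, seq_id = locus$seq_id,
    locus_start = locus$start, locus_end = locus$end, unit = locus$unit,
    motif_class = locus$motif_class, repeat_count = locus$repeat_count,
    status = "designed",
    forward_seq = f$seq[b], reverse_seq = r$seq[b],
    forward_start = f$start[b], forward_len = f$len[b],
    reverse_start = r$start[b], reverse_len = r$len[b],
    forward_tm = f$tm[b], reverse_tm = r$tm[b],
    forward_gc = f$gc[b], reverse_gc = r$gc[b],
    expected_product_size = as.integer(product[b]),
    product_start = f$start[b],
    product_end = r$start[b] + r$len[b]
  )
}

#' Design flanking primer pairs for SSR loci
#'
#' For each locus, searches every (window, length) combination of forward
#' primers left of the SSR and reverse primers right of it (primers never
#' overlap the repeat), keeps combinations satisfying all Tm/length/GC
#' constraints whose product falls in the allowed size range and contains
#' the locus, and returns the best-scoring pair — score is the sum of
#' half-range-normalized distances of both primers' Tm and GC and of the
#' product size from their range midpoints, with deterministic tie-breaking
#' (smaller product, then leftmost forward start, then shortest primers).
#' Undesignable loci get a failure `status` naming the dominant blocking
#' constraint (`insufficient_flank`, `gc_out_of_range`, `tm_out_of_range`,
#' `product_size`, `ambiguous_bases`).
#'
#' @param genome Genome tibble or named character vector.
#' @param loci Locus tibble from [find_ssrs()] (any subset of rows).
#' @param constraints See [default_primer_constraints()].
#' @param na_mM,oligo_nM Tm model conditions passed to [melting_temp()].
#' @return A tibble with one row per locus: locus fields, `status`, primer
#'   sequences (reverse given 5'→3' on the minus strand), positions, Tm, GC,
#'   and `expected_product_size`.
#' @export
design_primers <- function(genome, loci,
                           constraints = default_primer_constraints(),
                           na_mM = 50, oligo_nM = 50) {
  g <- as_genome(genome)
  constraints <- check_constraints(constraints)
  if (nrow(loci) == 0) return(failure_row(
    tibble::tibble(marker_id = character(), seq_id = character(),
                   start = integer(), end = integer(), unit = character(),
                   motif_class = character(), repeat_count = integer()),
    character(0)))
  loci <- dplyr::mutate(
    loci,
    marker_id = sprintf("%s_%d_%d", .data$seq_id, .data$start, .data$end))
  bad <- !loci$seq_id %in% g$seq_id
  if (any(bad)) {
    stop(sprintf("locus seq_id '%s' not in genome", loci$seq_id[which(bad)[1]]),
         call. = FALSE)
  }
  chars <- stats::setNames(lapply(g$sequence, seq_chars), g$seq_id)
  out <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    ch <- chars[[locus$seq_id]]
    if (locus$start < 0 || locus$end > length(ch)) {
      stop("locus outside sequence bounds", call. = FALSE)
    }
    design_one(ch, locus, constraints, na_mM, oligo_nM)
  })
  out
}
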