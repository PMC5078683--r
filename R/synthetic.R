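## Seed-controlled synthetic genomes with planted SSR loci and planted
## primer target sites, plus a divergence operator (substitutions + small
## indels) with a full mutation ledger. All randomness flows through the
## explicit `seed` argument (withr::with_seed; the caller's RNG state is
## untouched).

random_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## Deterministically pick a base differing from every base in `avoid`.
other_base <- function(avoid) {
  DNA_BASES[!DNA_BASES %in% avoid][1]
}

#' Generate a synthetic genome with planted features
#'
#' Background is i.i.d. DNA at the requested GC fraction. Planted SSRs are
#' perfect repeats whose immediate flanking bases are chosen to break the
#' periodicity, so each planted locus is recovered exactly as planted
#' (background elsewhere may still contain chance SSRs, which is realistic
#' and intended). Planted primer targets are forward-primer site + spacer +
#' reverse-complemented reverse-primer site spanning `product_size` bases,
#' inserted `copies` times. Features are placed uniformly at random without
#' overlap (margin 30 bases); supplying `pos` pins a feature.
#'
#' @param n_sequences Number of sequences.
#' @param length Length of each sequence, bases (recycled).
#' @param gc Background GC fraction.
#' @param planted_ssrs Tibble with columns `unit`, `repeat_count` and
#'   optionally `seq` (sequence index) and `pos` (0-based start), or `NULL`.
#' @param planted_primer_targets Tibble with columns `forward`, `reverse`,
#'   `product_size`, `copies` and optionally `seq`, or `NULL`.
#' @param seed Integer seed; same seed, same genome, byte for byte.
#' @return A list: `genome` (tibble), `ssr_truth` (tibble `seq_id`, `start`,
#'   `end`, `unit`, `repeat_count`), `primer_truth` (tibble `target_id`,
#'   `seq_id`, `start`, `end`, `forward`, `reverse`, `product_size`,
#'   `copy`).
#' @export
generate_genome <- function(n_sequences = 1, length = 10000, gc = 0.5,
                            planted_ssrs = NULL,
                            planted_primer_targets = NULL,
                            seed = 1) {
  stopifnot(n_sequences >= 1, all(length >= 1), gc >= 0, gc <= 1)
  lens <- rep_len(length, n_sequences)
  withr::with_seed(seed, {
    seqs <- lapply(lens, random_bases, gc = gc)
    occupied <- lapply(lens, function(l) integer(0))  # taken positions
    place <- function(si, flen, pos = NA, margin = 30L) {
      l <- lens[si]
      if (!is.na(pos)) {                     # pinned: 0-based start
        p <- pos + 1L
        if (p < 1 || p + flen - 1L > l) stop("infeasible packing", call. = FALSE)
        occupied[[si]] <<- c(occupied[[si]], p:(p + flen - 1L))
        return(p)
      }
      if (flen + 2 * margin >= l) stop("infeasible packing", call. = FALSE)
      for (try in 1:200) {
        p <- sample.int(l - flen - 2 * margin, 1) + margin
        span <- (p - margin):(p + flen + margin)
        if (!any(span %in% occupied[[si]])) {
          occupied[[si]] <<- c(occupied[[si]], p:(p + flen - 1L))
          return(p)
        }
      }
      stop("infeasible packing", call. = FALSE)
    }
    ssr_truth <- tibble::tibble(seq_id = character(), start = integer(),
                                end = integer(), unit = character(),
                                repeat_count = integer())
    if (!is.null(planted_ssrs) && nrow(planted_ssrs) > 0) {
      for (i in seq_len(nrow(planted_ssrs))) {
        unit <- tolower(planted_ssrs$unit[i])
        if (!is_primitive(unit)) stop("planted unit must be primitive", call. = FALSE)
        count <- planted_ssrs$repeat_count[i]
        k <- nchar(unit)
        si <- if ("seq" %in% names(planted_ssrs) && !is.na(planted_ssrs$seq[i]))
          planted_ssrs$seq[i] else sample.int(n_sequences, 1)
        pos <- if ("pos" %in% names(planted_ssrs)) planted_ssrs$pos[i] else NA
        rep_ch <- seq_chars(strrep(unit, count))
        # `p` is a 1-based index; the repeat occupies p..p+len-1
        p <- place(si, base::length(rep_ch), pos)
        seqs[[si]][p:(p + base::length(rep_ch) - 1L)] <- rep_ch
        # break periodicity at both edges (character-level maximality)
        left_i <- p - 1L
        if (left_i >= 1) {
          seqs[[si]][left_i] <- other_base(c(seqs[[si]][left_i + k],
                                             seqs[[si]][left_i + 1L]))
        }
        right_i <- p + base::length(rep_ch)
        if (right_i <= lens[si]) {
          seqs[[si]][right_i] <- other_base(c(seqs[[si]][right_i - k],
                                              seqs[[si]][right_i - 1L]))
        }
        ssr_truth <- dplyr::bind_rows(ssr_truth, tibble::tibble(
          seq_id = paste0("synth", si), start = p - 1L,
          end = p - 1L + base::length(rep_ch), unit = unit,
          repeat_count = as.integer(count)))
      }
    }
    primer_truth <- tibble::tibble(target_id = character(), seq_id = character(),
                                   start = integer(), end = integer(),
                                   forward = character(), reverse = character(),
                                   product_size = integer(), copy = integer())
    if (!is.null(planted_primer_targets) && nrow(planted_primer_targets) > 0) {
      for (i in seq_len(nrow(planted_primer_targets))) {
        fw <- toupper(planted_primer_targets$forward[i])
        rv <- toupper(planted_primer_targets$reverse[i])
        size <- planted_primer_targets$product_size[i]
        copies <- planted_primer_targets$copies[i] %||% 1L
        if (size < nchar(fw) + nchar(rv)) stop("product shorter than primers", call. = FALSE)
        for (cp in seq_len(copies)) {
          si <- if ("seq" %in% names(planted_primer_targets) &&
                    !is.na(planted_primer_targets$seq[i]))
            planted_primer_targets$seq[i] else sample.int(n_sequences, 1)
          spacer <- random_bases(size - nchar(fw) - nchar(rv), gc)
          block <- c(seq_chars(fw), spacer, seq_chars(revcomp(rv)))
          p <- place(si, base::length(block))
          seqs[[si]][p:(p + base::length(block) - 1L)] <- block
          primer_truth <- dplyr::bind_rows(primer_truth, tibble::tibble(
            target_id = sprintf("target%02d", i),
            seq_id = paste0("synth", si), start = p - 1L,
            end = p - 1L + base::length(block),
            forward = fw, reverse = rv,
            product_size = as.integer(size), copy = cp))
        }
      }
    }
    genome <- tibble::tibble(
      seq_id = paste0("synth", seq_len(n_sequences)),
      sequence = vapply(seqs, paste, character(1), collapse = ""))
    list(genome = as_genome(genome), ssr_truth = ssr_truth,
         primer_truth = primer_truth)
  })
}

#' Diverge a genome by point mutations and small indels
#'
#' Per-base independent substitutions at `substitution_rate`; indel events
#' initiate at `indel_rate` per base, each equally likely an insertion or a
#' deletion with length 1 + Geometric (mean `indel_mean`). Every event is
#' recorded in a ledger carrying both original and derived coordinates, so
#' the fate of any planted feature is computable.
#'
#' @param genome Genome tibble or named character vector.
#' @param substitution_rate,indel_rate Per-base event probabilities in
#'   \[0, 1).
#' @param indel_mean Mean indel length, bases.
#' @param seed Integer seed.
#' @return A list: `genome` (diverged), `ledger` (tibble `seq_id`, `type`
#'   (`sub`/`ins`/`del`), `old_pos` (0-based, original coordinates),
#'   `new_pos` (0-based, derived coordinates), `length`, `ref`, `alt`).
#' @export
diverge_genome <- function(genome, substitution_rate = 0.01,
                           indel_rate = 0, indel_mean = 3, seed = 1) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1, indel_mean >= 1)
  g <- as_genome(genome)
  withr::with_seed(seed, {
    res <- purrr::map(seq_len(nrow(g)), function(i) {
      ch <- seq_chars(g$sequence[i])
      n <- base::length(ch)
      ledger <- list()
      # substitutions on original coordinates
      subs <- which(stats::runif(n) < substitution_rate & ch != "N")
      for (p in subs) {
        old <- ch[p]
        ch[p] <- sample(setdiff(DNA_BASES, old), 1)
        ledger[[base::length(ledger) + 1]] <- tibble::tibble(
          type = "sub", old_pos = p - 1L, length = 1L, ref = old, alt = ch[p])
      }
      # indel events, applied right-to-left so earlier old-coords are stable
      ev <- which(stats::runif(n) < indel_rate)
      for (p in rev(ev)) {
        len <- 1L + stats::rgeom(1, 1 / indel_mean)
        if (stats::runif(1) < 0.5) {          # insertion after position p
          ins <- random_bases(len, 0.5)
          ch <- append(ch, ins, after = p)
          ledger[[base::length(ledger) + 1]] <- tibble::tibble(
            type = "ins", old_pos = p - 1L, length = len,
            ref = "", alt = paste(ins, collapse = ""))
        } else {                              # deletion starting at p
          len <- min(len, base::length(ch) - p + 1L)
          ledger[[base::length(ledger) + 1]] <- tibble::tibble(
            type = "del", old_pos = p - 1L, length = len,
            ref = paste(ch[p:(p + len - 1L)], collapse = ""), alt = "")
          ch <- ch[-(p:(p + len - 1L))]
        }
      }
      led <- if (base::length(ledger)) dplyr::bind_rows(ledger) else
        tibble::tibble(type = character(), old_pos = integer(),
                       length = integer(), ref = character(), alt = character())
      led$seq_id <- g$seq_id[i]
      led <- dplyr::arrange(led, .data$old_pos)
      # derived coordinate of each event: cumulative shift of earlier indels
      shift <- ifelse(led$type == "ins", led$length,
                      ifelse(led$type == "del", -led$length, 0L))
      led$new_pos <- led$old_pos + dplyr::lag(cumsum(shift), default = 0L)
      list(seq = paste(ch, collapse = ""), ledger = led)
    })
    genome_out <- as_genome(tibble::tibble(
      seq_id = g$seq_id,
      sequence = vapply(res, function(x) x$seq, character(1))))
    ledger <- dplyr::bind_rows(lapply(res, function(x) x$ledger))
    list(genome = genome_out,
         ledger = dplyr::select(ledger, "seq_id", "type", "old_pos",
                                "new_pos", "length", "ref", "alt"))
  })
}
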