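flank <- function(core, left = "GGCGC", right = "GCGTC") {
  stats::setNames(paste0(left, core, right), "chr")
}

test_that("mononucleotide threshold of 12 is exact", {
  hit <- find_ssrs(flank(strrep("A", 12)))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit, "a")
  expect_equal(hit$repeat_count, 12L)
  expect_equal(hit$start, 5L)
  expect_equal(hit$end, 17L)
  expect_equal(nrow(find_ssrs(flank(strrep("A", 11)))), 0L)
})

test_that("a dinucleotide run is reported once, at its smallest primitive unit", {
  hit <- find_ssrs(stats::setNames(paste0("CCCCC", "ATATATAT", "CCCCC"), "chr"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit, "at")
  expect_equal(hit$repeat_count, 4L)
  # never additionally reported as (atat)2
  expect_false(any(hit$unit_length == 4))
})

test_that("runs are maximal and N splits a run", {
  # 13 A's: count 13, not a 12 inside
  hit <- find_ssrs(flank(strrep("A", 13)))
  expect_equal(hit$repeat_count, 13L)
  # N in the middle kills both halves (11 each, below threshold)
  hit2 <- find_ssrs(flank(paste0(strrep("A", 11), "N", strrep("A", 11))))
  expect_equal(nrow(hit2), 0L)
  # but 12+N+12 yields two loci
  hit3 <- find_ssrs(flank(paste0(strrep("A", 12), "N", strrep("A", 12))))
  expect_equal(nrow(hit3), 2L)
  expect_equal(hit3$repeat_count, c(12L, 12L))
})

test_that("scan is case-insensitive and boundaries satisfy maximality vacuously", {
  hit <- find_ssrs(c(chr = strrep("at", 4)))   # the entire sequence
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 0L)
  expect_equal(hit$end, 8L)
})

test_that("non-IUPAC characters are rejected with a position", {
  expect_error(find_ssrs(c(chr = "ACGTXACGT")), "position 5")
})

test_that("abutting different-unit runs are all reported, unmerged", {
  hit <- find_ssrs(flank(paste0(strrep("A", 12), strrep("T", 12))))
  expect_equal(nrow(hit), 2L)
  expect_equal(sort(hit$unit), c("a", "t"))
  expect_equal(hit$end[1], hit$start[2])
})

test_that("primitivity agrees with rotation brute force on all hexamers", {
  hexamers <- do.call(paste0, expand.grid(rep(list(c("a", "c", "g", "t")), 6)))
  expect_equal(is_primitive(hexamers),
               vapply(hexamers, oracle_primitive, logical(1),
                      USE.NAMES = FALSE))
  expect_error(is_primitive(""), "empty")
})

test_that("motif classes pair phase with reverse complement, rotations kept apart", {
  expect_equal(canonicalize_motif("tc"), "tc/ga")
  expect_equal(canonicalize_motif("at"), "at")
  expect_equal(canonicalize_motif("cg"), "cg")
  expect_equal(canonicalize_motif("ca"), "ca/tg")
  expect_equal(canonicalize_motif("gt"), "gt/ac")
  expect_false(canonicalize_motif("ca") == canonicalize_motif("gt"))
  expect_equal(canonicalize_motif("att"), "att/aat")
  expect_error(canonicalize_motif("atat"), "primitive")
})

test_that("finder matches the brute-force oracle on seeded random sequences", {
  for (s in 1:40) {
    n <- withr::with_seed(1000 + s, sample(500:3000, 1))
    seq <- rand_dna(n, gc = 0.5, seed = 2000 + s)
    found <- find_ssrs(c(chr = seq))
    expect_same_loci(found, oracle_find_ssrs(seq))
  }
})

test_that("found loci are maximal and not contained in one another", {
  for (s in 1:10) {
    seq <- rand_dna(4000, gc = 0.35, seed = 3000 + s)  # AT-rich: more repeats
    loci <- find_ssrs(c(chr = seq))
    if (nrow(loci) == 0) next
    ch <- strsplit(seq, "")[[1]]
    for (i in seq_len(nrow(loci))) {
      k <- loci$unit_length[i]; st <- loci$start[i]; en <- loci$end[i]
      unit <- toupper(loci$unit[i])
      # extending one unit left or right must break the repeat
      if (st - k >= 0) {
        expect_false(paste(ch[(st - k + 1):st], collapse = "") == unit &&
                       ch[st] == ch[st + k])
      }
      if (en + k <= nchar(seq)) {
        expect_false(paste(ch[(en + 1):(en + k)], collapse = "") ==
                       paste(ch[(en - k + 1):en], collapse = ""))
      }
    }
    # no locus is a sub-interval of another with rotation/multiple unit
    for (i in seq_len(nrow(loci))) {
      inside <- loci$start >= loci$start[i] & loci$end <= loci$end[i] &
        seq_len(nrow(loci)) != i
      for (j in which(inside)) {
        rot <- rotations_of(loci$unit[i])
        expect_false(loci$unit[j] %in% rot ||
                       loci$unit[i] %in% rotations_of(loci$unit[j]))
      }
    }
  }
})

test_that("summary table conserves counts, lengths and percentages", {
  syn <- generate_genome(
    n_sequences = 1, length = 8000, gc = 0.5,
    planted_ssrs = tibble::tibble(
      unit = c("a", "at", "ag", "aac", "aggc"),
      repeat_count = c(14, 6, 5, 4, 4)),
    seed = 11)
  loci <- find_ssrs(syn$genome)
  sm <- summarize_ssrs(loci, genome_length = sum(syn$genome$length))
  tot <- sm[sm$level == "total", ]
  tiers <- sm[sm$level == "tier", ]
  classes <- sm[sm$level == "class", ]
  expect_equal(sum(tiers$n), tot$n)
  expect_equal(sum(classes$n), tot$n)
  expect_equal(sum(tiers$total_length_bp), sum(loci$length))
  expect_equal(sum(tiers$pct_total), 100)
  expect_equal(sum(classes$pct_total), 100)
  # mean_repeats * unit_length * count == total_length, tier by tier
  unit_len <- match(tiers$tier, c("mono", "di", "tri", "tetra", "penta",
                                  "hexa"))
  expect_equal(tiers$mean_repeats * unit_len * tiers$n,
               as.numeric(tiers$total_length_bp))
  # density columns mirror ssr_density()
  d <- ssr_density(nrow(loci), sum(syn$genome$length))
  expect_equal(tot$density_per_mb, d$per_mb)
  expect_equal(tot$kb_per_ssr, d$kb_per_locus)
})

test_that("one-locus summary and empty summary behave", {
  loci <- find_ssrs(flank(strrep("AT", 5)))
  sm <- summarize_ssrs(loci)
  cls <- sm[sm$level == "class", ]
  expect_equal(cls$total_length_bp, 10)
  expect_equal(cls$mean_repeats, 5)
  empty <- summarize_ssrs(loci[0, ])
  expect_equal(empty$n, 0L)
  expect_equal(empty$density_per_mb, 0)
})

test_that("density arithmetic and degenerate cases", {
  d <- ssr_density(1, 1e6)
  expect_equal(d$per_mb, 1)
  expect_equal(d$kb_per_locus, 1000)
  d0 <- ssr_density(0, 1e6)
  expect_equal(d0$per_mb, 0)
  expect_true(is.na(d0$kb_per_locus))
  expect_error(ssr_density(5, 0), "positive")
})
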