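plant_in <- function(insert, at, n = 600, seed = 1, gc = 0.5) {
  bg <- strsplit(rand_dna(n, gc = gc, seed = seed), "")[[1]]
  ins <- strsplit(toupper(insert), "")[[1]]
  bg[(at + 1):(at + length(ins))] <- ins
  c(chr = paste(bg, collapse = ""))
}

test_that("a verbatim planted primer gives exactly one plus-strand site", {
  primer <- "ACGGATTACCAGGCATCAAG"
  g <- plant_in(primer, at = 200, seed = 21)
  sites <- find_binding_sites(g, primer, epcr_params())
  plus <- sites[sites$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 200L)
  expect_equal(plus$end, 220L)
  expect_equal(plus$mismatches, 0L)
})

test_that("two substitutions exceed the stringent one-mismatch budget", {
  primer <- "ACGGATTACCAGGCATCAAG"
  mut <- primer
  substr(mut, 3, 3) <- "T"; substr(mut, 11, 11) <- "C"
  g <- plant_in(mut, at = 200, seed = 22)
  sites <- find_binding_sites(g, primer, epcr_params())
  expect_equal(nrow(sites[sites$start == 200, ]), 0L)
  # one substitution is tolerated
  one <- primer; substr(one, 3, 3) <- "T"
  g1 <- plant_in(one, at = 200, seed = 22)
  s1 <- find_binding_sites(g1, primer, epcr_params())
  expect_equal(s1$mismatches[s1$start == 200], 1L)
})

test_that("site finding matches the sliding-Hamming oracle on random cases", {
  for (s in 1:60) {
    n <- withr::with_seed(4000 + s, sample(300:1200, 1))
    seq <- rand_dna(n, gc = 0.4, seed = 5000 + s)
    m <- withr::with_seed(6000 + s, sample(12:24, 1))
    # half the cases use a primer cut from the sequence (guaranteed hits)
    primer <- if (s %% 2 == 0) {
      at <- withr::with_seed(7000 + s, sample(n - m, 1))
      substr(seq, at, at + m - 1)
    } else {
      rand_dna(m, seed = 7000 + s)
    }
    mm <- s %% 3  # budgets 0, 1, 2
    got <- find_binding_sites(
      c(chr = seq), primer,
      modifyList(epcr_params(), list(max_mismatch = mm)))
    want <- oracle_binding_sites(seq, primer, mm)
    got_df <- as.data.frame(got[order(got$start, got$strand),
                                c("strand", "start", "end", "mismatches")])
    rownames(got_df) <- rownames(want) <- NULL
    expect_equal(got_df, want)
  }
})

test_that("site and amplicon sets grow monotonically with the mismatch budget", {
  seq <- rand_dna(2000, gc = 0.45, seed = 81)
  primer <- substr(seq, 501, 520)
  key <- function(df) paste(df$strand, df$start, df$end)
  prev <- NULL
  for (mm in 0:2) {
    cur <- find_binding_sites(c(chr = seq), primer,
                              modifyList(epcr_params(),
                                         list(max_mismatch = mm)))
    if (!is.null(prev)) expect_true(all(key(prev) %in% key(cur)))
    prev <- cur
  }
})

test_that("strand symmetry: ePCR of the reverse-complemented genome mirrors sites", {
  seq <- rand_dna(1500, seed = 83)
  primer <- substr(seq, 301, 322)
  n <- nchar(seq)
  a <- find_binding_sites(c(chr = seq), primer, epcr_params())
  b <- find_binding_sites(c(chr = revcomp(seq)), primer, epcr_params())
  # a + site [s, e) maps to a - site [n-e, n-s) on the reverse complement
  mirrored <- data.frame(strand = ifelse(a$strand == "+", "-", "+"),
                         start = n - a$end, end = n - a$start,
                         mismatches = a$mismatches)
  got <- as.data.frame(b[c("strand", "start", "end", "mismatches")])
  o1 <- order(mirrored$start, mirrored$strand)
  o2 <- order(got$start, got$strand)
  expect_equal(got[o2, ], mirrored[o1, ], ignore_attr = TRUE)
})

test_that("amplicons pair convergent sites inside a strict size window", {
  fwd <- "ACGGATTACCAGGCATCAAG"
  rev <- "TGCCTGAGTCAGTCCGATCA"
  make_g <- function(product) {
    spacer <- rand_dna(product - 40, seed = 90)
    plant_in(paste0(fwd, spacer, revcomp(rev)), at = 100, n = 600, seed = 91)
  }
  p <- epcr_params()
  g <- make_g(150)
  sf <- find_binding_sites(g, fwd, p)
  sr <- find_binding_sites(g, rev, p)
  amp <- enumerate_amplicons(sf, sr, expected_size = 150, params = p)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$size, 150L)
  expect_equal(amp$start, 100L)
  expect_equal(amp$end, 250L)
  # mirrored arrangement: reverse primer upstream on +, forward on -
  gm <- plant_in(paste0(rev, rand_dna(110, seed = 92), revcomp(fwd)),
                 at = 100, n = 600, seed = 93)
  ampm <- enumerate_amplicons(find_binding_sites(gm, fwd, p),
                              find_binding_sites(gm, rev, p), 150, p)
  expect_equal(nrow(ampm), 1L)
  expect_equal(ampm$f_strand, "-")
  expect_equal(ampm$size, 150L)
  # deviation of exactly 100 is rejected (strict <), 99 is kept
  g2 <- make_g(250)
  sf2 <- find_binding_sites(g2, fwd, p)
  sr2 <- find_binding_sites(g2, rev, p)
  expect_equal(nrow(enumerate_amplicons(sf2, sr2, 150, p)), 0L)
  expect_equal(nrow(enumerate_amplicons(sf2, sr2, 151, p)), 1L)
})

test_that("a primer pair planted at three loci yields three products, class 3", {
  fwd <- "ACGGATTACCAGGCATCAAG"
  rev <- "TGCCTGAGTCAGTCCGATCA"
  syn <- generate_genome(
    n_sequences = 2, length = 3000, gc = 0.5,
    planted_primer_targets = tibble::tibble(
      forward = fwd, reverse = rev, product_size = 180, copies = 3),
    seed = 13)
  res <- run_epcr(syn$genome, tibble::tibble(
    marker_id = "m1", forward_seq = fwd, reverse_seq = rev,
    expected_product_size = 180L))
  expect_equal(res$markers$n_products, 3L)
  expect_equal(res$markers$copy_number_class, "3")
  expect_equal(sort(res$amplicons$start),
               sort(syn$primer_truth$start))
})

test_that("copy-number classes follow the 1/2/3/>3 convention", {
  expect_equal(classify_copy_number(c(0, 1, 2, 3, 4, 57)),
               c(NA, "1", "2", "3", ">3", ">3"))
  expect_error(classify_copy_number(-1), "negative")
})

test_that("gapped permissive mode finds a one-deletion site that stringent mode misses", {
  primer <- "ACGGATTACCAGGCATCAAG"
  deleted <- paste0(substr(primer, 1, 9), substr(primer, 11, 20))
  g <- plant_in(deleted, at = 250, seed = 95)
  stringent <- find_binding_sites(g, primer, epcr_params())
  expect_equal(nrow(stringent[stringent$start >= 240 & stringent$start <= 260, ]), 0L)
  permissive <- find_binding_sites(g, primer, epcr_params(stringent = FALSE))
  hit <- permissive[permissive$start == 250 & permissive$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$gaps, 1L)
  expect_equal(hit$end, 269L)
})

test_that("self-recovery: every designed pair re-amplifies its own genome at size", {
  syn <- generate_genome(
    n_sequences = 1, length = 12000, gc = 0.5,
    planted_ssrs = tibble::tibble(unit = c("at", "ag", "ct", "aac"),
                                  repeat_count = c(7, 9, 6, 5)),
    seed = 31)
  loci <- find_ssrs(syn$genome)
  des <- design_primers(syn$genome, loci)
  des <- des[des$status == "designed", ]
  expect_gt(nrow(des), 0)
  p0 <- modifyList(epcr_params(), list(max_mismatch = 0L))
  res <- run_epcr(syn$genome, des, p0)
  expect_true(all(res$markers$n_products >= 1))
  exact <- dplyr::inner_join(res$amplicons, des, by = "marker_id") |>
    dplyr::group_by(marker_id) |>
    dplyr::summarise(hit = any(size == expected_product_size))
  expect_true(all(exact$hit))
})
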