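# Brute-force reference implementations, deliberately written with
# different algorithms than the package (unit-table DP + pairwise dedup
# here vs. period-match run scanning there; per-window text loop here vs.
# per-pattern-position vector accumulation there).

rand_dna <- function(n, gc = 0.5, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                           (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# primitive iff no rotation by 1..k-1 maps the unit onto itself
oracle_primitive <- function(u) {
  k <- nchar(u)
  if (k == 1) return(TRUE)
  uu <- paste0(u, u)
  for (d in seq_len(k - 1)) {
    if (substr(uu, d + 1, d + k) == u) return(FALSE)
  }
  TRUE
}

rotations_of <- function(u) {
  k <- nchar(u)
  uu <- paste0(u, u)
  unique(substring(uu, 1:k, k:(2 * k - 1)))
}

# All maximal primitive-unit repeats meeting the thresholds, labelled at the
# leftmost phase of each maximal periodic run.
oracle_find_ssrs <- function(seq, thresholds = palmsat::default_thresholds()) {
  s <- toupper(seq)
  n <- nchar(s)
  out <- list()
  for (k in 1:6) {
    thr <- thresholds[[as.character(k)]]
    if (n < k * thr) next
    nu <- n - k + 1
    units <- substring(s, 1:nu, k:n)
    cnt <- integer(nu)
    for (i in nu:1) {
      j <- i + k
      cnt[i] <- if (j <= nu && units[j] == units[i]) cnt[j] + 1L else 1L
    }
    cand <- which(cnt >= thr)
    cand <- cand[!grepl("N", units[cand], fixed = TRUE)]
    # cannot be extended left by one full unit
    ok_left <- vapply(cand, function(i) {
      i - k < 1 || units[i - k] != units[i]
    }, logical(1))
    cand <- cand[ok_left]
    cand <- cand[vapply(units[cand], oracle_primitive, logical(1))]
    if (length(cand) == 0) next
    df <- data.frame(start = cand - 1L, k = k,
                     end = cand - 1L + k * cnt[cand],
                     unit = tolower(units[cand]),
                     repeat_count = cnt[cand])
    # phase convention: a candidate whose start lies inside an
    # earlier-starting candidate of the same run (same k, rotated unit)
    # is the same locus scanned out of phase -- keep the leftmost
    keep <- rep(TRUE, nrow(df))
    for (a in seq_len(nrow(df))) {
      for (b in seq_len(nrow(df))) {
        if (a == b || !keep[b]) next
        if (df$start[a] < df$start[b] && df$start[b] < df$end[a] &&
            df$unit[b] %in% rotations_of(df$unit[a])) {
          keep[b] <- FALSE
        }
      }
    }
    out[[length(out) + 1]] <- df[keep, c("start", "end", "unit",
                                         "repeat_count")]
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      unit = character(), repeat_count = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end - res$start), , drop = FALSE]
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "")[[1]]),
        collapse = "")
}

# sliding-window Hamming scan, one window at a time
oracle_binding_sites <- function(seq, primer, max_mismatch) {
  s <- toupper(seq)
  n <- nchar(s)
  hits <- list()
  for (pat in list(c(toupper(primer), "+"),
                   c(oracle_revcomp(primer), "-"))) {
    pc <- strsplit(pat[1], "")[[1]]
    m <- length(pc)
    if (n < m) next
    for (i in 1:(n - m + 1)) {
      win <- strsplit(substr(s, i, i + m - 1), "")[[1]]
      mm <- sum(win != pc | win == "N")
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1]] <- data.frame(
          strand = pat[2], start = i - 1L, end = i - 1L + m,
          mismatches = mm)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), mismatches = integer()))
  }
  res <- do.call(rbind, hits)
  res[order(res$start, res$strand), , drop = FALSE]
}

# two-pass textbook Pearson
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# set comparison of locus tables on the identifying columns
expect_same_loci <- function(found, truth) {
  cols <- c("start", "end", "unit", "repeat_count")
  f <- as.data.frame(found[order(found$start, found$end), cols])
  t2 <- as.data.frame(truth[order(truth$start, truth$end), cols])
  rownames(f) <- rownames(t2) <- NULL
  expect_equal(f, t2)
}
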