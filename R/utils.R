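## Shared low-level sequence helpers. All coordinates inside the package are
## 0-based half-open; conversion to/from 1-based inclusive happens only at the
## GFF3/BED boundary (see io.R).

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' IUPAC-aware for the characters this package handles (A/C/G/T/N,
#' case-insensitive); the result is upper-case.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("tc")   # "GA"
#' revcomp("AT")   # "AT"
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

## Split a sequence into an upper-case character vector, validating the
## alphabet. `what` names the offending input in error messages.
seq_chars <- function(seq, what = "sequence") {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c(DNA_BASES, "N"))
  if (length(bad) > 0) {
    stop(sprintf("non-IUPAC character '%s' in %s at position %d",
                 ch[bad[1]], what, bad[1]), call. = FALSE)
  }
  ch
}

## Assert a DNA string contains no N (primer/GC contexts).
assert_unambiguous <- function(seq, what = "sequence") {
  ch <- seq_chars(seq, what)
  if (any(ch == "N")) {
    stop(sprintf("ambiguous base N in %s at position %d",
                 what, which(ch == "N")[1]), call. = FALSE)
  }
  invisible(ch)
}

## Coerce genome input to the canonical tibble (seq_id, sequence, length).
## Accepts a named character vector, a Biostrings::DNAStringSet, or a tibble
## already in that shape.
as_genome <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    x <- tibble::tibble(seq_id = ids, sequence = unname(x))
  }
  stopifnot(is.data.frame(x), all(c("seq_id", "sequence") %in% names(x)))
  tibble::tibble(
    seq_id = as.character(x$seq_id),
    sequence = toupper(x$sequence),
    length = nchar(x$sequence)
  )
}

## Sequence lengths tibble from a genome.
seq_lengths <- function(genome) {
  g <- as_genome(genome)
  dplyr::select(g, "seq_id", "length")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
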