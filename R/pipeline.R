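## The cross-genus workflow: mine genome A -> design primers -> self-screen
## by e-PCR on A (keep pairs with at least one product) -> cross-amplify
## genome B -> conserved markers are those with a qualifying product in both
## genomes. Copy-number classes in B are reported, never filtered on.

#' Run the conserved-marker discovery pipeline
#'
#' Stage order: mine A, design primers, self-ePCR on A, ePCR on B,
#' intersect. Survivor counts are checked to be monotone non-increasing
#' along the funnel. The run is fully deterministic given its inputs.
#'
#' @param genome_a,genome_b Genome tibbles or named character vectors.
#' @param thresholds Minimum repeat counts, see [default_thresholds()].
#' @param constraints Primer constraints, see [default_primer_constraints()].
#' @param params e-PCR parameters, see [epcr_params()]; the same stringent
#'   mismatch and size window are applied to the self-screen and the
#'   cross-genome screen.
#' @param verbose Log per-stage counts with `message()`.
#' @return An object of class `palmsat_pipeline`: a list with
#'   `markers` (per designed primer pair: primers, product counts and
#'   copy-number class in A and B, best size deviation in B, `conserved`
#'   flag), `conserved` (the conserved subset), `amplicons_b`, and `report`
#'   (stage counts, copy-number histograms, both conservation rates, total
#'   in-silico fragment counts). Use [generics::tidy()] / [generics::glance()].
#' @export
run_pipeline <- function(genome_a, genome_b,
                         thresholds = default_thresholds(),
                         constraints = default_primer_constraints(),
                         params = epcr_params(),
                         verbose = FALSE) {
  ga <- as_genome(genome_a)
  gb <- as_genome(genome_b)
  if (nrow(ga) == 0 || nrow(gb) == 0) stop("empty genome", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  loci <- find_ssrs(ga, thresholds)
  say("mined %d SSR loci in genome A", nrow(loci))

  design <- design_primers(ga, loci, constraints)
  designed <- dplyr::filter(design, .data$status == "designed")
  say("designed %d primer pairs (%d loci undesignable)",
      nrow(designed), nrow(design) - nrow(designed))
  if (nrow(designed) == 0) warning("no designable loci", call. = FALSE)

  self_res <- run_epcr(ga, designed, params)
  markers <- designed |>
    dplyr::left_join(
      dplyr::rename(self_res$markers, n_products_a = "n_products",
                    copy_class_a = "copy_number_class") |>
        dplyr::select("marker_id", "n_products_a", "copy_class_a"),
      by = "marker_id")
  self_amp <- dplyr::filter(markers, .data$n_products_a >= 1)
  say("%d primer pairs self-amplify genome A", nrow(self_amp))
  if (nrow(designed) > 0 && nrow(self_amp) == 0) {
    warning("no self-amplifying primer pairs", call. = FALSE)
  }

  if (nrow(self_amp) > 0) {
    cross_res <- run_epcr(gb, self_amp, params)
    cross <- dplyr::rename(cross_res$markers, n_products_b = "n_products",
                           copy_class_b = "copy_number_class",
                           best_b_size_deviation = "best_size_deviation")
    amplicons_b <- cross_res$amplicons
  } else {
    cross <- tibble::tibble(marker_id = character(),
                            n_products_b = integer(),
                            copy_class_b = character(),
                            best_b_size_deviation = numeric())
    amplicons_b <- NULL
  }
  markers <- markers |>
    dplyr::left_join(cross, by = "marker_id") |>
    dplyr::mutate(
      n_products_b = dplyr::coalesce(.data$n_products_b, 0L),
      conserved = .data$n_products_a >= 1 & .data$n_products_b >= 1)
  conserved <- dplyr::filter(markers, .data$conserved)
  say("%d conserved markers", nrow(conserved))
  if (nrow(self_amp) > 0 && nrow(conserved) == 0) {
    warning("no conserved markers", call. = FALSE)
  }

  hist_of <- function(cls) {
    tibble::tibble(copy_number_class = factor(cls, levels = c("1", "2", "3", ">3"))) |>
      dplyr::filter(!is.na(.data$copy_number_class)) |>
      dplyr::count(.data$copy_number_class, .drop = FALSE, name = "n")
  }
  report <- list(
    n_loci_mined = nrow(loci),
    n_primers_designed = nrow(designed),
    n_with_self_products = nrow(self_amp),
    n_conserved = nrow(conserved),
    conservation_rate_vs_designed = if (nrow(designed) > 0)
      conservation_rate(nrow(conserved), nrow(designed)) else NA_real_,
    conservation_rate_vs_self = if (nrow(self_amp) > 0)
      conservation_rate(nrow(conserved), nrow(self_amp)) else NA_real_,
    copy_number_a = hist_of(markers$copy_class_a),
    copy_number_b = hist_of(conserved$copy_class_b),
    total_fragments_a = sum(markers$n_products_a, na.rm = TRUE),
    total_fragments_b = sum(markers$n_products_b, na.rm = TRUE)
  )
  with(report, stopifnot(
    n_conserved <= n_with_self_products,
    n_with_self_products <= n_primers_designed,
    n_primers_designed <= n_loci_mined))
  structure(list(markers = markers, conserved = conserved,
                 amplicons_b = amplicons_b, report = report),
            class = "palmsat_pipeline")
}

#' Conservation rate
#'
#' Percentage of primer pairs with qualifying products in both genomes.
#'
#' @param n_conserved Number of conserved markers.
#' @param n_designed Denominator (designed or self-amplifying pair count).
#' @return Percentage.
#' @export
#' @examples
#' conservation_rate(7265, 734509)  # ~0.99
conservation_rate <- function(n_conserved, n_designed) {
  if (n_designed <= 0) stop("denominator must be positive", call. = FALSE)
  percentage(n_conserved, n_designed)
}

#' Cross-species transferability rates from a wet-lab score matrix
#'
#' Computes, from a 0/1 marker-by-species amplification matrix (as scored
#' from gels), the per-marker percentage of species amplified and the
#' min/mean/max over markers. Missing entries are allowed and excluded from
#' a marker's denominator.
#'
#' @param scores A data frame whose first column is the marker id and
#'   remaining columns are species scores in \{0, 1, NA\}, or a path to such
#'   a TSV.
#' @return An object of class `palmsat_transferability` with elements
#'   `per_marker` (tibble: `marker_id`, `n_amplified`, `n_tested`,
#'   `rate_pct`) and `summary` (tibble: `min`, `mean`, `max`).
#' @export
transferability_rate <- function(scores) {
  if (is.character(scores) && length(scores) == 1) {
    scores <- read_tsv_table(scores)
  }
  stopifnot(is.data.frame(scores), ncol(scores) >= 2)
  ids <- as.character(scores[[1]])
  mat <- as.matrix(scores[, -1, drop = FALSE])
  storage.mode(mat) <- "numeric"
  if (!all(mat %in% c(0, 1) | is.na(mat))) {
    stop("score matrix entries must be 0, 1 or missing", call. = FALSE)
  }
  per_marker <- tibble::tibble(
    marker_id = ids,
    n_amplified = rowSums(mat == 1, na.rm = TRUE),
    n_tested = rowSums(!is.na(mat))
  )
  if (any(per_marker$n_tested == 0)) {
    stop("marker with no scored species", call. = FALSE)
  }
  per_marker$rate_pct <- percentage(per_marker$n_amplified,
                                    per_marker$n_tested)
  structure(list(
    per_marker = per_marker,
    summary = tibble::tibble(min = min(per_marker$rate_pct),
                             mean = mean(per_marker$rate_pct),
                             max = max(per_marker$rate_pct))
  ), class = "palmsat_transferability")
}

#' @export
print.palmsat_pipeline <- function(x, ...) {
  r <- x$report
  cat("palmsat conserved-marker pipeline\n")
  cat(sprintf("  loci mined:            %d\n", r$n_loci_mined))
  cat(sprintf("  primer pairs designed: %d\n", r$n_primers_designed))
  cat(sprintf("  self-amplifying in A:  %d\n", r$n_with_self_products))
  cat(sprintf("  conserved in B:        %d\n", r$n_conserved))
  if (!is.na(r$conservation_rate_vs_designed)) {
    cat(sprintf("  conservation rate:     %.2f%% of designed (%.2f%% of self-amplifying)\n",
                r$conservation_rate_vs_designed, r$conservation_rate_vs_self))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-marker results of a pipeline run
#'
#' @param x A `palmsat_pipeline` object.
#' @param ... Unused.
#' @return The per-marker tibble (one row per designed primer pair).
#' @export
tidy.palmsat_pipeline <- function(x, ...) x$markers

#' One-row summary of a pipeline run
#'
#' @param x A `palmsat_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble of funnel counts, conservation rates and total
#'   fragment counts.
#' @export
glance.palmsat_pipeline <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_loci_mined = r$n_loci_mined,
    n_primers_designed = r$n_primers_designed,
    n_with_self_products = r$n_with_self_products,
    n_conserved = r$n_conserved,
    conservation_rate_vs_designed = r$conservation_rate_vs_designed,
    conservation_rate_vs_self = r$conservation_rate_vs_self,
    total_fragments_a = r$total_fragments_a,
    total_fragments_b = r$total_fragments_b
  )
}

#' @export
tidy.palmsat_transferability <- function(x, ...) x$per_marker

#' @export
glance.palmsat_transferability <- function(x, ...) x$summary

#' @export
print.palmsat_transferability <- function(x, ...) {
  cat(sprintf("transferability over %d markers: min %.1f%%, mean %.1f%%, max %.1f%%\n",
              nrow(x$per_marker), x$summary$min, x$summary$mean,
              x$summary$max))
  invisible(x)
}
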