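## ggplot2 figures for the three result types users actually look at:
## the motif spectrum, chromosome window densities, and the pipeline funnel.

#' Motif-spectrum bar chart
#'
#' Tier-level counts (mono..hexa) from an SSR summary table, the standard
#' first figure of a genome-wide repeat survey.
#'
#' @param summary Output of [summarize_ssrs()].
#' @return A ggplot object.
#' @export
plot_motif_spectrum <- function(summary) {
  tiers <- dplyr::filter(summary, .data$level == "tier") |>
    dplyr::mutate(tier = factor(.data$tier, levels = TIER_NAMES))
  ggplot2::ggplot(tiers, ggplot2::aes(x = .data$tier, y = .data$pct_total)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = "motif length", y = "% of all SSRs") +
    ggplot2::theme_minimal()
}

#' Windowed feature-density profile
#'
#' Per-window SSR, gene and TE counts along each sequence, one facet per
#' sequence — the view in which peri-telomeric SSR enrichment and SSR/TE
#' anti-correlation are visible.
#'
#' @param windows Output of [window_densities()].
#' @return A ggplot object.
#' @export
plot_window_densities <- function(windows) {
  long <- windows |>
    tidyr::pivot_longer(cols = c("ssr_count", "gene_count", "te_count"),
                        names_to = "feature", values_to = "count") |>
    dplyr::mutate(feature = sub("_count$", "", .data$feature))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_start / 1e6,
                                     y = .data$count,
                                     fill = .data$feature)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~seq_id, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(ssr = "black", te = "blue",
                                          gene = "red")) +
    ggplot2::labs(x = "position (Mb)", y = "features per window") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Funnel plot of a pipeline run
#'
#' Survivor counts through mine / design / self-amplify / conserve.
#'
#' @param object A `palmsat_pipeline` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.palmsat_pipeline <- function(object, ...) {
  r <- object$report
  df <- tibble::tibble(
    stage = factor(c("mined", "designed", "self-amplifying", "conserved"),
                   levels = c("mined", "designed", "self-amplifying",
                              "conserved")),
    n = c(r$n_loci_mined, r$n_primers_designed, r$n_with_self_products,
          r$n_conserved))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "primer pairs / loci") +
    ggplot2::theme_minimal()
}
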