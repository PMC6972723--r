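#' Plot a severity heatmap
#'
#' Tile plot of the thresholded variants-by-categories score matrix, rows
#' ordered by total score.
#'
#' @param x A `crl4_heatmap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(x, ...) {
  stopifnot(inherits(x, "crl4_heatmap"))
  long <- tidy(x)
  long$vid <- factor(long$vid, levels = rev(x$matrix$vid))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$category, y = .data$vid, fill = .data$points)
  ) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::scale_fill_gradient(
      low = "#fff7bc", high = "#d7301f", limits = c(0, NA)
    ) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "points",
      title = paste0("Variants scoring ≥ ", x$threshold)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.crl4_heatmap <- function(object, ...) {
  plot_score_heatmap(object, ...)
}

#' Plot a per-gene genotype heatmap
#'
#' Variants by individuals, coloured the conventional way: yellow for
#' Ref/Ref (variant absent), orange for heterozygous, red for homozygous
#' alternate.
#'
#' @param gh Output of [genotype_heatmap()].
#' @return A ggplot object.
#' @export
plot_genotype_heatmap <- function(gh) {
  long <- gh$matrix |>
    tidyr::pivot_longer(
      -"vid", names_to = "individual", values_to = "genotype"
    )
  long$vid <- factor(long$vid, levels = rev(gh$matrix$vid))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$individual, y = .data$vid, fill = .data$genotype)
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(
        "Ref/Ref" = "#ffe44d", "Ref/Alt" = "#fd8d3c", "Alt/Alt" = "#e31a1c"
      ),
      na.value = "grey80"
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6)
    )
}

#' Plot burden distributions by group
#'
#' Boxplots of per-individual burden (score sum or variant count) for each
#' phenotype group.
#'
#' @param profiles Output of [individual_burden()].
#' @param phenotypes Phenotype tibble.
#' @param by `"score"` or `"count"`.
#' @return A ggplot object.
#' @export
plot_burden <- function(profiles, phenotypes, by = c("score", "count")) {
  by <- match.arg(by)
  col <- if (by == "score") "score_sum" else "variant_count"
  df <- total_burden(profiles) |>
    inner_join(phenotypes, by = "individual") |>
    mutate(
      group = if_else(
        .data$cohort == "reference", "reference", .data$endophenotype
      )
    )
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$group, y = .data[[col]], fill = .data$group)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::labs(
      x = NULL,
      y = if (by == "score") "score sum" else "variant count"
    ) +
    ggplot2::theme_minimal()
}

#' Plot sample vs reference location distributions
#'
#' Side-by-side bars of the percentage of variants per genomic location in
#' the study sample and a reference panel.
#'
#' @param sample_counts,reference_counts Tibbles with `location`, `n`.
#' @return A ggplot object.
#' @export
plot_location_distribution <- function(sample_counts, reference_counts) {
  df <- bind_rows(
    mutate(sample_counts, sample = "cohort"),
    mutate(reference_counts, sample = "reference")
  ) |>
    group_by(.data$sample) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup()
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$location, y = .data$pct, fill = .data$sample)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of variants", fill = NULL) +
    ggplot2::theme_minimal()
}
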