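#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-codon occupancy ratios
#'
#' Bar plot of observed/expected A-site occupancy per sense codon. With
#' replicate libraries (a `sample` column) bars show the mean ratio with SEM
#' error bars; the pause codon is highlighted.
#'
#' @param object an `"occupancy_tbl"` from [codon_occupancy()].
#' @param highlight codon identity to colour (default `"AGA"`).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot occupancy_tbl
#' @export
autoplot.occupancy_tbl <- function(object, highlight = "AGA", ...) {
  df <- if ("sample" %in% names(object)) {
    summarize_occupancy(object)
  } else {
    dplyr::transmute(as_tibble(object), codon = .data$codon,
                     mean_ratio = .data$ratio, sem = NA_real_)
  }
  df$highlight <- df$codon == highlight
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$mean_ratio,
                                   fill = .data$highlight)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_ratio - .data$sem,
                   ymax = .data$mean_ratio + .data$sem),
      width = 0.3, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "ribosome occupancy (observed/expected)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 5))
}

#' Volcano plot of a differential-TE fit
#'
#' @param object a `"te_fit"` from [differential_te()].
#' @param q_threshold genes at or below this BH-adjusted cutoff are coloured.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot te_fit
#' @export
autoplot.te_fit <- function(object, q_threshold = 0.05, ...) {
  df <- as_tibble(object) |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::mutate(altered = .data$q_value <= q_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_log2_te,
                                   y = -log10(.data$p_value),
                                   colour = .data$altered)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = sprintf("q <= %g", q_threshold)) +
    ggplot2::labs(x = expression(Delta ~ log[2] ~ "TE (alt - ref)"),
                  y = expression(-log[10] ~ "p")) +
    ggplot2::theme_minimal()
}

#' Plot pairwise pause-gene overlap fractions
#'
#' Bar plot of the shared fractions |A∩B|/|A| and |A∩B|/|B| for every pair
#' of replicate pause-gene sets; under stochastic per-replicate pausing with
#' per-gene probability p these fractions centre on p.
#'
#' @param overlap result of [intersect_pause_sets()].
#' @return a ggplot.
#' @export
plot_pause_overlap <- function(overlap) {
  df <- overlap$pairwise |>
    tidyr::pivot_longer(c("frac_a", "frac_b"), names_to = "direction",
                        values_to = "fraction") |>
    dplyr::mutate(pair = paste(.data$set_a, "vs", .data$set_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$fraction,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge", na.rm = TRUE) +
    ggplot2::scale_fill_grey(start = 0.35, end = 0.65,
                             labels = c("of first set", "of second set"),
                             name = "shared fraction") +
    ggplot2::labs(x = NULL, y = "shared pause-gene fraction") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
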