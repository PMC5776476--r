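#' Stacked-bar plot of core-community composition
#'
#' One bar per grain sample, stacked by core family share of total reads,
#' with pooled minor core families and the non-core remainder.
#'
#' @param breakdown A tibble from [core_family_breakdown()].
#' @return A ggplot object.
#' @export
plot_core_composition <- function(breakdown) {
  lev <- breakdown |>
    dplyr::filter(!.data$family %in% c("other core community", "non-core")) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(m = mean(.data$share), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m))
  breakdown$family <- factor(breakdown$family,
                             levels = c(lev$family, "other core community", "non-core"))
  ggplot2::ggplot(breakdown,
                  ggplot2::aes(x = .data$sample_id, y = .data$share,
                               fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of total reads", fill = "family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
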