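#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the identity ranking of a homolog database
#'
#' Percent identity (and similarity) against rank; donors selected by a
#' design can be highlighted by passing the design.
#'
#' @param ranked Output of [rank_homologs()].
#' @param design Optional `variant_design` whose donors are highlighted.
#' @return A ggplot object.
#' @export
plot_homolog_ranking <- function(ranked, design = NULL) {
  long <- tidyr::pivot_longer(
    dplyr::select(ranked, "rank", "hit_id", "identity_pct",
                  "similarity_pct"),
    cols = c("identity_pct", "similarity_pct"),
    names_to = "measure", values_to = "pct"
  )
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$rank, y = .data$pct,
                                    colour = .data$measure)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_colour_manual(
      values = c(identity_pct = "#1b6ca8", similarity_pct = "#999999"),
      labels = c(identity_pct = "identity", similarity_pct = "similarity"),
      name = NULL) +
    ggplot2::labs(x = "homolog rank (closest first)",
                  y = "percent of alignment columns") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if (!is.null(design)) {
    donors <- unique(stats::na.omit(design$substitutions$donor_id))
    hl <- ranked[ranked$hit_id %in% donors, , drop = FALSE]
    p <- p + ggplot2::geom_point(
      data = tibble(rank = hl$rank, pct = hl$identity_pct,
                    measure = "identity_pct"),
      shape = 21, size = 3, stroke = 1, colour = "#c0392b")
  }
  p
}

#' @rdname plot_homolog_ranking
#' @param object A `variant_design`.
#' @param ... Unused.
#' @export
autoplot.variant_design <- function(object, ...) {
  plot_homolog_ranking(object$ranked, design = object) +
    ggplot2::labs(title = sprintf(
      "%s: donors for eliminating '%s'",
      object$query$id[1], object$target$forbidden_residue))
}

#' Plot a per-position variation profile
#'
#' Residues carried by each ranked homolog at each requested position:
#' one tile per (homolog, position), lettered by residue, gaps and
#' uncovered positions shown as '-' and '.'.
#'
#' @param object A `variation_profile` from [variation_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variation_profile <- function(object, ...) {
  df <- dplyr::mutate(
    as_tibble(object),
    shown = dplyr::case_when(.data$status == "gap" ~ "-",
                             .data$status == "outside" ~ ".",
                             TRUE ~ .data$residue)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = stats::reorder(.data$source_id,
                                                      -.data$rank))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$shown),
                       colour = "white", show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$shown), size = 3) +
    ggplot2::labs(x = "query position", y = "homolog (closest on top)") +
    ggplot2::theme_minimal()
}
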