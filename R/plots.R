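#' Plot a weighted network as a signed edge heatmap
#'
#' @param object An `mgm_network`.
#' @param ... Unused.
#' @return A ggplot object: node-by-node tiles shaded by signed magnitude
#'   (unsigned edges, i.e. those involving a categorical variable, in grey).
#' @export
autoplot.mgm_network <- function(object, ...) {
  edges <- tidy(object, all = TRUE)
  edges <- dplyr::mutate(
    edges,
    from = factor(.data$from, levels = object$nodes),
    to = factor(.data$to, levels = object$nodes),
    value = .data$sign * .data$magnitude
  )
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$from, y = .data$to)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(
      data = dplyr::filter(edges, .data$involves_categorical,
                           .data$magnitude > 0),
      ggplot2::aes(size = .data$magnitude), colour = "grey40"
    ) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "forestgreen", name = "weight") +
    ggplot2::scale_size_continuous(range = c(0.5, 3), guide = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot bootstrap stability per edge
#'
#' @param object An `mgm_boot`.
#' @param ... Unused.
#' @return A ggplot object: edges ordered by full-data magnitude with their
#'   bootstrap quantile intervals, coloured by stability class.
#' @export
autoplot.mgm_boot <- function(object, ...) {
  tbl <- dplyr::filter(object$table, .data$in_full_network)
  tbl <- dplyr::mutate(tbl,
                       edge = stats::reorder(paste(.data$from, .data$to,
                                                   sep = "--"),
                                             .data$estimate))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$estimate, y = .data$edge)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stability_class)) +
    ggplot2::labs(x = "edge magnitude", y = NULL, colour = "stability") +
    ggplot2::theme_minimal()
}

#' Plot ratio and entropy indicators over the threshold grid
#'
#' @param object A [threshold_grid()] result.
#' @param ... Unused.
#' @return A ggplot object with one panel per indicator, lines per clique
#'   size; the ratio panel marks the crossing value 2.
#' @export
autoplot.threshold_grid <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object),
                  ratio = ifelse(is.finite(.data$ratio), .data$ratio, NA)),
    cols = c("ratio", "entropy_bits"),
    names_to = "indicator", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$I, y = .data$value,
                                     colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::geom_hline(
      data = tibble::tibble(indicator = "ratio", y = 2),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed"
    ) +
    ggplot2::labs(x = "intensity threshold I", y = NULL,
                  colour = "clique size k") +
    ggplot2::theme_minimal()
}

#' Plot community membership
#'
#' @param object A `community_solution`.
#' @param ... Unused.
#' @return A ggplot object: nodes by communities, cross-loading nodes
#'   appearing in several columns.
#' @export
autoplot.community_solution <- function(object, ...) {
  tbl <- tidy(object)
  tbl <- dplyr::mutate(
    tbl,
    community = factor(ifelse(is.na(.data$community), "isolated",
                              paste0("C", .data$community)))
  )
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$community, y = .data$node)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$community),
                       show.legend = FALSE) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}
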