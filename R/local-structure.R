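#' Stabilizing and communicating indices
#'
#' For every node v and every community c containing it, the stabilizing
#' index sums the absolute edge magnitudes between v and its co-members in
#' c, and the communicating index sums the absolute magnitudes between v and
#' nodes belonging to at least one *other* community. Edges to isolated
#' nodes count toward neither index. Nodes that cross-load receive one row
#' per community. Within each community the top two stabilizers and
#' communicators are flagged, extended to three when the third value lies
#' within `tie_window` of the second.
#'
#' @param network An `mgm_network`.
#' @param solution A [percolate()] or [select_solution()] community
#'   solution derived from this network.
#' @param signed If `TRUE`, sum signed weights (`sign * magnitude`) instead
#'   of absolute magnitudes.
#' @param tie_window Tie tolerance for extending the top-2 flag to a third
#'   node (default 0.05).
#' @return A tibble of class `local_index_table` with columns `node`,
#'   `community`, `stabilizing`, `communicating`, `top_stabilizer`,
#'   `top_communicator`.
#' @export
local_indices <- function(network, solution, signed = FALSE,
                          tie_window = 0.05) {
  stopifnot(inherits(network, "mgm_network"),
            inherits(solution, "community_solution"))
  sol_nodes <- c(unlist(solution$communities), solution$isolated)
  if (!setequal(unique(sol_nodes), network$nodes)) {
    stop("community solution and network cover different node sets")
  }
  W <- if (signed) network$sign * network$magnitude else network$magnitude
  in_any <- unique(unlist(solution$communities))
  rows <- list()
  for (ci in seq_along(solution$communities)) {
    comm <- solution$communities[[ci]]
    external <- setdiff(in_any, comm)
    for (v in comm) {
      co <- setdiff(comm, v)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        node = v, community = ci,
        stabilizing = sum(W[v, co]),
        communicating = sum(W[v, external])
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$community)
  out <- dplyr::mutate(
    out,
    top_stabilizer = top_flag(.data$stabilizing, tie_window),
    top_communicator = top_flag(.data$communicating, tie_window)
  )
  out <- dplyr::ungroup(out)
  class(out) <- c("local_index_table", class(out))
  out
}

# Flag the two largest values, or three when the third is within `window`
# of the second.
top_flag <- function(values, window) {
  ord <- order(values, decreasing = TRUE)
  n_top <- min(2L, length(values))
  if (length(values) >= 3 &&
      values[ord[2]] - values[ord[3]] <= window &&
      values[ord[3]] > 0) {
    n_top <- 3L
  }
  flag <- rep(FALSE, length(values))
  flag[ord[seq_len(n_top)]] <- values[ord[seq_len(n_top)]] > 0
  flag
}

#' Community network at subscale resolution
#'
#' Re-estimates a mixed graphical model for one community, with
#' multi-dimensional constructs replaced by their subscale columns: every
#' community node mapped in `subscale_map` contributes its subscale columns
#' instead of the construct column, unmapped nodes enter unchanged. Edges
#' whose magnitude does not exceed `display_threshold` are suppressed from
#' the exported view ([display_edges()]) while remaining in the full edge
#' table; community-restricted networks change with the variable set and do
#' not exactly reproduce the full network's weights.
#'
#' @param x A [mixed_data()] containing both the construct and the subscale
#'   columns.
#' @param community_nodes Character vector of the community's construct
#'   nodes.
#' @param subscale_map Named list `construct -> character vector of subscale
#'   column names`.
#' @param display_threshold Magnitude below or at which an edge is hidden
#'   from the exported view (default 0.05).
#' @inheritParams fit_mgm
#' @return An `mgm_network` over the community's (subscale-resolved)
#'   variables, carrying the display threshold as an attribute.
#' @export
subscale_network <- function(x, community_nodes, subscale_map = list(),
                             display_threshold = 0.05, gamma = 0.25,
                             rule = c("AND", "OR"), nlambda = 50,
                             lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  stopifnot(inherits(x, "mixed_data"))
  if (!length(community_nodes)) stop("empty community node set")
  cols <- unlist(lapply(community_nodes, function(nm) {
    subscale_map[[nm]] %||% nm
  }))
  missing_cols <- setdiff(cols, x$spec$name)
  if (length(missing_cols)) {
    stop("subscale column(s) absent from the dataset: ",
         paste(missing_cols, collapse = ", "))
  }
  spec <- x$spec[match(cols, x$spec$name), ]
  sub <- mixed_data(x$data[cols], spec)
  fit <- fit_mgm(sub, gamma = gamma, rule = rule, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio)
  net <- fit$network
  attr(net, "display_threshold") <- display_threshold
  attr(net, "subscale_map") <- subscale_map
  net
}

#' @rdname subscale_network
#' @param network An `mgm_network` with a display threshold attribute.
#' @return `display_edges()` returns the edge tibble restricted to edges
#'   strictly stronger than the display threshold.
#' @export
display_edges <- function(network, display_threshold = NULL) {
  thr <- display_threshold %||% attr(network, "display_threshold") %||% 0.05
  dplyr::filter(tidy(network), .data$magnitude > thr)
}
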