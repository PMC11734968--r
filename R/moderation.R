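#' Fit a moderated mixed graphical model
#'
#' Augments every nodewise regression with product terms `x_j * x_m` for a
#' single user-named continuous moderator `m` and all candidate predictors
#' `j` outside the node/moderator pair, so three-way interactions
#' (node, j, m) can enter the model. Selection is by EBIC exactly as in
#' [fit_nodewise()]. The pairwise (base) terms are aggregated into the usual
#' signed network; the product terms are aggregated into a symmetric
#' moderation-magnitude matrix by the same mean-of-absolute-values and AND
#' convention: the pair (i, j) carries a three-way term with the moderator
#' only when both i's and j's regressions retain the corresponding product.
#'
#' @inheritParams fit_mgm
#' @param moderator Name of a continuous variable with positive variance.
#' @return An object of class `moderated_network` with elements `base` (an
#'   `mgm_network`), `moderator`, `moderation_magnitude` (symmetric matrix)
#'   and `fits`.
#' @export
fit_moderated <- function(x, moderator, gamma = 0.25, rule = c("AND", "OR"),
                          nlambda = 50, lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  stopifnot(inherits(x, "mixed_data"))
  i <- match(moderator, x$spec$name)
  if (is.na(i)) stop("unknown moderator: ", moderator)
  if (x$spec$domain[i] == "categorical") {
    stop("categorical moderators are not supported")
  }
  xs <- standardize_continuous(x)   # errors on a constant moderator column
  fits <- lapply(xs$spec$name, function(nm) {
    fit_nodewise(xs, nm, gamma = gamma, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio, moderator = moderator)
  })
  names(fits) <- xs$spec$name
  base <- aggregate_network(fits, rule = rule)
  nodes <- xs$spec$name
  p <- length(nodes)
  dm <- directed_magnitudes(fits, nodes, kind = "product")
  mod_mag <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      if (nodes[a] == moderator || nodes[b] == moderator) next
      u <- dm$magnitude[a, b]
      v <- dm$magnitude[b, a]
      nz <- c(u, v)[c(u, v) > 0]
      mod_mag[a, b] <- mod_mag[b, a] <- if (rule == "AND") {
        if (u > 0 && v > 0) mean(c(u, v)) else 0
      } else {
        if (length(nz)) mean(nz) else 0
      }
    }
  }
  structure(list(base = base, moderator = moderator,
                 moderation_magnitude = mod_mag, fits = fits,
                 gamma = gamma, rule = rule, data = xs),
            class = "moderated_network")
}

#' @export
print.moderated_network <- function(x, ...) {
  nm <- sum(x$moderation_magnitude[upper.tri(x$moderation_magnitude)] > 0)
  cat(sprintf("<moderated_network> moderator '%s', %d moderated pair(s)\n",
              x$moderator, nm))
  print(x$base)
  invisible(x)
}

#' @export
tidy.moderated_network <- function(x, all = FALSE, ...) {
  nodes <- x$base$nodes
  idx <- upper_pairs(length(nodes))
  out <- tibble::tibble(
    from = nodes[idx[, 1]],
    to = nodes[idx[, 2]],
    moderator = x$moderator,
    base_magnitude = x$base$magnitude[idx],
    moderation_magnitude = x$moderation_magnitude[idx]
  )
  if (!all) {
    out <- dplyr::filter(out, .data$base_magnitude > 0 |
                           .data$moderation_magnitude > 0)
  }
  out
}
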