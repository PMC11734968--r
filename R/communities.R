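#' Intensity of a weighted clique
#'
#' The intensity of a k-clique is the geometric mean of its
#' `k * (k - 1) / 2` edge magnitudes; the intensity threshold `I` of the
#' percolation algorithm admits a clique only when its intensity reaches
#' `I`. Signs play no role: percolation operates on association strength.
#'
#' @param edge_magnitudes Positive numeric vector whose length is
#'   `k * (k - 1) / 2` for some integer `k >= 3`.
#' @return The geometric mean of the magnitudes.
#' @export
#' @examples
#' clique_intensity(c(0.1, 0.2, 0.4))  # 0.2
clique_intensity <- function(edge_magnitudes) {
  m <- length(edge_magnitudes)
  k <- (1 + sqrt(1 + 8 * m)) / 2
  if (m < 3 || abs(k - round(k)) > 1e-9) {
    stop("edge count must be k*(k-1)/2 for some k >= 3")
  }
  if (any(edge_magnitudes <= 0)) {
    stop("a clique has strictly positive edge magnitudes only")
  }
  exp(mean(log(edge_magnitudes)))
}

# Enumerate all k-cliques of the unsigned magnitude graph, with their
# intensities. Returns list(members = list of integer vectors, intensity).
clique_table <- function(network, k) {
  A <- network$magnitude > 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::cliques(g, min = k, max = k)
  if (!length(cl)) {
    return(list(members = list(), intensity = numeric(0)))
  }
  members <- lapply(cl, as.integer)
  intensity <- vapply(members, function(ii) {
    w <- network$magnitude[ii, ii]
    clique_intensity(w[upper.tri(w)])
  }, numeric(1))
  list(members = members, intensity = intensity)
}

# Percolate pre-enumerated cliques at threshold I: keep cliques with
# intensity >= I, join cliques sharing k - 1 nodes, communities are the node
# unions of the connected components of that clique graph.
percolate_cliques <- function(members, intensity, I, k, nodes) {
  keep <- intensity >= I
  members <- members[keep]
  p <- length(nodes)
  if (!length(members)) {
    return(new_community_solution(k, I, list(), nodes, p))
  }
  ncl <- length(members)
  M <- matrix(FALSE, ncl, p)
  for (q in seq_len(ncl)) M[q, members[[q]]] <- TRUE
  shared <- tcrossprod(M * 1)
  adj <- shared >= (k - 1)
  diag(adj) <- FALSE
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  )$membership
  communities <- lapply(seq_len(max(comp)), function(cid) {
    sort(nodes[unique(unlist(members[comp == cid]))])
  })
  covered <- unique(unlist(communities))
  isolated <- setdiff(nodes, covered)
  new_community_solution(k, I, communities, isolated, p)
}

new_community_solution <- function(k, I, communities, isolated, p_total) {
  sizes <- vapply(communities, length, integer(1))
  ord <- order(sizes, decreasing = TRUE)
  ratio <- if (length(sizes) == 0) {
    NA_real_
  } else if (length(sizes) == 1) {
    Inf
  } else {
    s <- sort(sizes, decreasing = TRUE)
    s[1] / s[2]
  }
  sol <- structure(
    list(k = k, I = I,
         communities = communities[ord],
         isolated = sort(isolated),
         sizes = sizes[ord],
         ratio = ratio,
         entropy_bits = NA_real_,
         p_total = p_total),
    class = "community_solution"
  )
  sol$entropy_bits <- partition_entropy(sol, p_total)
  sol
}

#' Detect overlapping communities by weighted clique percolation
#'
#' Enumerates all k-cliques of the unsigned magnitude graph whose intensity
#' (geometric mean of edge magnitudes) is at least `I`, declares two
#' k-cliques adjacent when they share `k - 1` nodes, and returns the node
#' unions of the connected components of that clique graph as communities.
#' Nodes may belong to several communities (cross-loading); nodes in none
#' are isolated.
#'
#' @param network An `mgm_network`.
#' @param k Clique size, at least 3.
#' @param I Nonnegative intensity threshold.
#' @return An object of class `community_solution` with fields `k`, `I`,
#'   `communities` (list of node-name vectors, largest first), `isolated`,
#'   `sizes`, `ratio` (largest to second-largest size; `Inf` with a single
#'   community) and `entropy_bits`.
#' @export
percolate <- function(network, k, I) {
  stopifnot(inherits(network, "mgm_network"), k >= 3, I >= 0)
  ct <- clique_table(network, k)
  percolate_cliques(ct$members, ct$intensity, I, k, network$nodes)
}

#' @export
print.community_solution <- function(x, ...) {
  cat(sprintf("<community_solution> k = %d, I = %.3f: %d community(ies), %d isolated, ratio %.3g, entropy %.3f bits\n",
              x$k, x$I, length(x$communities), length(x$isolated),
              x$ratio, x$entropy_bits))
  for (i in seq_along(x$communities)) {
    cat(sprintf("  [%d] (%d) %s\n", i, x$sizes[i],
                paste(x$communities[[i]], collapse = " ")))
  }
  if (length(x$isolated)) {
    cat("  isolated:", paste(x$isolated, collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
tidy.community_solution <- function(x, ...) {
  rows <- lapply(seq_along(x$communities), function(i) {
    tibble::tibble(node = x$communities[[i]], community = i)
  })
  dplyr::bind_rows(
    dplyr::bind_rows(rows),
    tibble::tibble(node = x$isolated, community = NA_integer_)
  )
}

#' Shannon entropy of a community partition
#'
#' Effective community sizes split shared nodes equally among the
#' communities they belong to; all isolated nodes are pooled into a single
#' pseudo-community of their full count. The entropy (in bits) is
#' `H = -sum_c (s_c / p) log2(s_c / p)` over communities with positive
#' effective size. Equal effective sizes with no isolated nodes maximize H
#' at `log2` of the community count.
#'
#' @param solution A [percolate()] result.
#' @param p_total Total node count of the network.
#' @return Entropy in bits (nonnegative).
#' @export
partition_entropy <- function(solution, p_total = solution$p_total) {
  members <- unlist(solution$communities)
  n_nodes <- length(unique(members)) + length(solution$isolated)
  if (n_nodes != p_total) {
    stop(sprintf("solution covers %d nodes but p_total = %d", n_nodes, p_total))
  }
  if (!length(solution$communities) && !length(solution$isolated)) return(0)
  n_memberships <- table(members)
  sizes <- vapply(solution$communities, function(comm) {
    sum(1 / as.numeric(n_memberships[comm]))
  }, numeric(1))
  sizes <- c(sizes, length(solution$isolated))
  pr <- sizes[sizes > 0] / p_total
  -sum(pr * log2(pr))
}

#' Evaluate percolation over a (k, I) grid
#'
#' Runs [percolate()] at every combination of clique size `k` and intensity
#' threshold on the grid `I in {0, I_step, 2 I_step, ..., max magnitude}`,
#' recording community count, isolated count, ratio and entropy per row.
#' The default step 0.005 resolves optima reported to three decimals.
#'
#' @param network An `mgm_network`.
#' @param k_values Integer clique sizes (default `c(3, 4)`).
#' @param I_step Positive grid step (default 0.005).
#' @return A tibble of class `threshold_grid` with columns `k`, `I`,
#'   `n_communities`, `n_isolated`, `ratio`, `entropy_bits`; the network is
#'   attached as an attribute for downstream selection.
#' @export
threshold_grid <- function(network, k_values = c(3, 4), I_step = 0.005) {
  stopifnot(inherits(network, "mgm_network"), all(k_values >= 3), I_step > 0)
  k_values <- sort(unique(as.integer(k_values)))
  max_mag <- max(network$magnitude)
  I_grid <- seq(0, max(max_mag, 0), by = I_step)
  rows <- lapply(k_values, function(k) {
    ct <- clique_table(network, k)
    dplyr::bind_rows(lapply(I_grid, function(I) {
      sol <- percolate_cliques(ct$members, ct$intensity, I, k, network$nodes)
      tibble::tibble(k = k, I = I,
                     n_communities = length(sol$communities),
                     n_isolated = length(sol$isolated),
                     ratio = sol$ratio,
                     entropy_bits = sol$entropy_bits)
    }))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "network") <- network
  class(out) <- c("threshold_grid", class(out))
  out
}

#' Permutation null band for the entropy indicator
#'
#' Each permutation reassigns the observed edge magnitudes uniformly at
#' random over all node pairs (preserving the number of edges and the
#' weight multiset, not the degree sequence), re-evaluates the entropy over
#' the full I grid, and records the maximal entropy per clique size. The
#' 95% upper confidence bound per `k` is the 97.5th percentile of those
#' maxima; an observed entropy is higher than chance when it exceeds this
#' bound.
#'
#' @inheritParams threshold_grid
#' @param n_perm Number of permutations (study default 100).
#' @param seed Integer seed.
#' @return A tibble of class `entropy_null` with columns `k`, `n_perm`,
#'   `upper_95`; the per-permutation maxima are attached as an attribute.
#' @export
permute_entropy_null <- function(network, k_values = c(3, 4), I_step = 0.005,
                                 n_perm = 100, seed = 1) {
  stopifnot(inherits(network, "mgm_network"), n_perm >= 1)
  k_values <- sort(unique(as.integer(k_values)))
  p <- length(network$nodes)
  idx <- upper_pairs(p)
  weights <- network$magnitude[idx]
  weights <- weights[weights > 0]
  max_mag <- max(network$magnitude)
  I_grid <- seq(0, max(max_mag, 0), by = I_step)
  set.seed(derive_seed(seed, 211L))
  maxima <- matrix(NA_real_, n_perm, length(k_values),
                   dimnames = list(NULL, paste0("k", k_values)))
  for (perm in seq_len(n_perm)) {
    pos <- sample.int(nrow(idx), length(weights))
    mag <- matrix(0, p, p, dimnames = dimnames(network$magnitude))
    mag[idx[pos, , drop = FALSE]] <- weights
    mag <- mag + t(mag)
    pnet <- network
    pnet$magnitude <- mag
    for (ki in seq_along(k_values)) {
      k <- k_values[ki]
      ct <- clique_table(pnet, k)
      ent <- vapply(I_grid, function(I) {
        percolate_cliques(ct$members, ct$intensity, I, k,
                          pnet$nodes)$entropy_bits
      }, numeric(1))
      maxima[perm, ki] <- max(ent)
    }
  }
  out <- tibble::tibble(
    k = k_values,
    n_perm = n_perm,
    upper_95 = apply(maxima, 2, stats::quantile, probs = 0.975, names = FALSE)
  )
  attr(out, "maxima") <- maxima
  class(out) <- c("entropy_null", class(out))
  out
}

#' Select the community solution from the threshold grid
#'
#' Codifies the study's solution-selection procedure deterministically. The
#' ratio candidate operationalizes "the threshold just above the emergence
#' of the giant component": scanning thresholds upward, it is the smallest
#' grid threshold at which a multi-community solution first attains a
#' largest-to-second-largest size ratio of at most 2 (single-community rows
#' are giant components by definition and are skipped), taken at the
#' smallest clique size having such a row. The
#' entropy candidate is the grid row maximizing the partition entropy,
#' flagged against the permutation null band when one is supplied. The
#' chosen solution is the candidate preferred by, in order: (1) largest
#' community at most 50% of the non-isolated nodes, (2) fewer isolated
#' nodes, (3) more communities, (4) higher entropy; remaining ties go to
#' the ratio candidate. Every comparison is recorded in the rationale.
#'
#' @param grid A [threshold_grid()] result.
#' @param null Optional [permute_entropy_null()] result.
#' @return An object of class `community_selection` with elements
#'   `ratio_candidate`, `entropy_candidate`, `chosen` (all
#'   `community_solution`s), `entropy_significant` and `rationale`.
#' @export
select_solution <- function(grid, null = NULL) {
  stopifnot(inherits(grid, "threshold_grid"), nrow(grid) > 0)
  network <- attr(grid, "network")
  rationale <- character()
  ratio_rows <- dplyr::filter(grid, .data$n_communities >= 2, .data$ratio <= 2)
  ratio_cand <- NULL
  if (nrow(ratio_rows)) {
    k0 <- min(ratio_rows$k)
    I0 <- min(ratio_rows$I[ratio_rows$k == k0])
    ratio_cand <- percolate(network, k0, I0)
    rationale <- c(rationale, sprintf(
      "ratio candidate: k = %d, I = %.3f (smallest I where the ratio first reaches 2 at the smallest such k)",
      k0, I0))
  } else {
    rationale <- c(rationale, "ratio candidate: none (no multi-community row reaches ratio 2)")
  }
  ent_rows <- dplyr::filter(grid, .data$n_communities >= 1)
  ent_cand <- NULL
  ent_sig <- NA
  if (nrow(ent_rows)) {
    best <- ent_rows[which.max(ent_rows$entropy_bits), ]
    ent_cand <- percolate(network, best$k, best$I)
    rationale <- c(rationale, sprintf(
      "entropy candidate: k = %d, I = %.3f (maximal entropy %.3f bits)",
      best$k, best$I, best$entropy_bits))
    if (!is.null(null)) {
      bound <- null$upper_95[null$k == best$k]
      if (length(bound)) {
        ent_sig <- best$entropy_bits > bound
        rationale <- c(rationale, sprintf(
          "entropy %.3f bits %s the 95%% permutation bound %.3f for k = %d",
          best$entropy_bits, if (ent_sig) "exceeds" else "does not exceed",
          bound, best$k))
      }
    }
  } else {
    rationale <- c(rationale, "entropy candidate: none (no row has a community)")
  }
  if (is.null(ratio_cand) && is.null(ent_cand)) {
    stop("no candidate solution on the grid; use a finer I_step or more clique sizes")
  }
  if (is.null(ratio_cand) || is.null(ent_cand)) {
    chosen <- ratio_cand %||% ent_cand
    rationale <- c(rationale, "single candidate available; chosen by default")
  } else {
    cmp <- compare_candidates(ratio_cand, ent_cand)
    chosen <- if (cmp$winner == "ratio") ratio_cand else ent_cand
    rationale <- c(rationale, cmp$rationale)
  }
  structure(list(ratio_candidate = ratio_cand,
                 entropy_candidate = ent_cand,
                 chosen = chosen,
                 entropy_significant = ent_sig,
                 rationale = rationale),
            class = "community_selection")
}

# Lexicographic candidate comparison: giant-component rule, isolated count,
# community count, entropy; final tie to the ratio candidate.
compare_candidates <- function(ratio_cand, ent_cand) {
  rationale <- character()
  giant_ok <- function(s) {
    non_isolated <- s$p_total - length(s$isolated)
    length(s$sizes) > 0 && max(s$sizes) <= 0.5 * non_isolated
  }
  g_r <- giant_ok(ratio_cand)
  g_e <- giant_ok(ent_cand)
  rationale <- c(rationale, sprintf(
    "giant-component rule (largest community <= 50%% of non-isolated nodes): ratio %s, entropy %s",
    if (g_r) "pass" else "fail", if (g_e) "pass" else "fail"))
  if (g_r != g_e) {
    winner <- if (g_r) "ratio" else "entropy"
    return(list(winner = winner,
                rationale = c(rationale,
                              sprintf("chosen: %s candidate (giant-component rule)", winner))))
  }
  iso_r <- length(ratio_cand$isolated)
  iso_e <- length(ent_cand$isolated)
  rationale <- c(rationale, sprintf("isolated nodes: ratio %d, entropy %d",
                                    iso_r, iso_e))
  if (iso_r != iso_e) {
    winner <- if (iso_r < iso_e) "ratio" else "entropy"
    return(list(winner = winner,
                rationale = c(rationale,
                              sprintf("chosen: %s candidate (fewer isolated nodes)", winner))))
  }
  nc_r <- length(ratio_cand$communities)
  nc_e <- length(ent_cand$communities)
  rationale <- c(rationale, sprintf("communities: ratio %d, entropy %d",
                                    nc_r, nc_e))
  if (nc_r != nc_e) {
    winner <- if (nc_r > nc_e) "ratio" else "entropy"
    return(list(winner = winner,
                rationale = c(rationale,
                              sprintf("chosen: %s candidate (more communities)", winner))))
  }
  rationale <- c(rationale, sprintf("entropy: ratio %.3f, entropy %.3f bits",
                                    ratio_cand$entropy_bits, ent_cand$entropy_bits))
  if (ratio_cand$entropy_bits != ent_cand$entropy_bits) {
    winner <- if (ratio_cand$entropy_bits > ent_cand$entropy_bits) "ratio" else "entropy"
    return(list(winner = winner,
                rationale = c(rationale,
                              sprintf("chosen: %s candidate (higher entropy)", winner))))
  }
  list(winner = "ratio",
       rationale = c(rationale, "chosen: ratio candidate (complete tie)"))
}

#' @export
print.community_selection <- function(x, ...) {
  cat("<community_selection>\n")
  for (line in x$rationale) cat(" -", line, "\n")
  cat("chosen:\n")
  print(x$chosen)
  invisible(x)
}
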