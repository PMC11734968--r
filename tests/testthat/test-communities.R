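# Two weight-0.3 triangles {1,2,3} and {3,4,5} sharing node 3, plus node 6
# attached to node 5 by a 0.01 edge.
two_triangle_net <- function() {
  mag <- matrix(0, 6, 6)
  tri <- list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(3, 5), c(4, 5))
  for (e in tri) mag[e[1], e[2]] <- 0.3
  mag[5, 6] <- 0.01
  mag <- mag + t(mag)
  dimnames(mag) <- list(paste0("N", 1:6), paste0("N", 1:6))
  net_from_matrix(mag)
}

test_that("clique intensity is the geometric mean of edge magnitudes", {
  expect_equal(clique_intensity(c(0.1, 0.2, 0.4)), 0.2)
  expect_equal(clique_intensity(rep(0.37, 6)), 0.37)
  for (s in 1:15) {
    set.seed(s)
    w <- runif(3, 0.01, 1)
    expect_lte(clique_intensity(w), mean(w))  # AM-GM
  }
  expect_error(clique_intensity(c(0.1, 0, 0.4)), "positive")
  expect_error(clique_intensity(c(0.1, 0.2)), "k >= 3")
})

test_that("percolation resolves shared nodes, weak attachments and merging", {
  sol <- percolate(two_triangle_net(), k = 3, I = 0.2)
  expect_equal(canonical_cover(sol$communities),
               c("N1,N2,N3", "N3,N4,N5"))
  expect_equal(sol$isolated, "N6")
  expect_equal(sol$ratio, 1.0)

  # complete graph on 4 nodes: all four triangles share two nodes pairwise
  mag <- matrix(0.5, 4, 4); diag(mag) <- 0
  sol4 <- percolate(net_from_matrix(mag), k = 3, I = 0.4)
  expect_length(sol4$communities, 1)
  expect_equal(sol4$sizes, 4)
  expect_equal(sol4$ratio, Inf)

  # threshold above every clique intensity: everything isolated
  sol_hi <- percolate(two_triangle_net(), k = 3, I = 0.5)
  expect_length(sol_hi$communities, 0)
  expect_length(sol_hi$isolated, 6)
  expect_true(is.na(sol_hi$ratio))
})

test_that("percolation agrees with brute-force subset enumeration", {
  cases <- 0
  for (s in 1:34) {
    p <- 5 + (s %% 6)
    net <- random_network(p, density = 0.45, seed = s)
    w <- net$magnitude[upper.tri(net$magnitude)]
    w <- w[w > 0]
    if (!length(w)) next
    thresholds <- stats::quantile(w, c(0.1, 0.5, 0.9), names = FALSE)
    for (k in c(3, 4)) {
      for (I in thresholds) {
        sol <- percolate(net, k, I)
        oracle <- brute_percolate(net$magnitude, k, I)
        expect_equal(canonical_cover(sol$communities),
                     canonical_cover(oracle$communities))
        expect_equal(sol$isolated, oracle$isolated)
        cases <- cases + 1
      }
    }
  }
  expect_gte(cases, 100)
})

test_that("raising the threshold only refines the community cover", {
  for (s in 1:8) {
    net <- random_network(8, density = 0.5, seed = 100 + s)
    lo <- percolate(net, 3, 0.1)
    hi <- percolate(net, 3, 0.3)
    cover_lo <- unique(unlist(lo$communities))
    for (comm in hi$communities) {
      expect_true(all(comm %in% cover_lo))
      # each high-threshold community sits inside one low-threshold community
      expect_true(any(vapply(lo$communities,
                             function(c0) all(comm %in% c0), logical(1))))
    }
  }
})

test_that("partition entropy follows the equal-splitting definition", {
  # two disjoint communities of 15 over 30 nodes: exactly 1 bit
  mag <- matrix(0, 30, 30)
  for (b in list(1:15, 16:30)) {
    mag[b, b] <- 0.3
  }
  diag(mag) <- 0
  sol <- percolate(net_from_matrix(mag), 3, 0.1)
  expect_equal(sol$entropy_bits, 1.0)

  # communities {A,B,C} and {C,D,E}: effective sizes 2.5/2.5, 1 bit
  mag2 <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(3, 5), c(4, 5))) {
    mag2[e[1], e[2]] <- mag2[e[2], e[1]] <- 0.3
  }
  sol2 <- percolate(net_from_matrix(mag2), 3, 0.1)
  expect_length(sol2$communities, 2)
  expect_equal(sol2$entropy_bits, 1.0)

  # one community of 3 plus one isolated node over 4 nodes
  mag3 <- matrix(0, 4, 4)
  mag3[1:3, 1:3] <- 0.4
  diag(mag3) <- 0
  sol3 <- percolate(net_from_matrix(mag3), 3, 0.1)
  expect_equal(sol3$entropy_bits, 0.8112781, tolerance = 1e-6)

  expect_error(partition_entropy(sol3, p_total = 9), "p_total")
})

test_that("effective sizes plus isolated count conserve the node total", {
  for (s in 1:10) {
    net <- random_network(9, density = 0.5, seed = 200 + s)
    sol <- percolate(net, 3, 0.15)
    memberships <- table(unlist(sol$communities))
    eff <- vapply(sol$communities, function(comm) {
      sum(1 / as.numeric(memberships[comm]))
    }, numeric(1))
    expect_equal(sum(eff) + length(sol$isolated), 9)
  }
})

test_that("entropy is maximal exactly for equal sizes with no isolation", {
  mag <- matrix(0, 12, 12)
  for (b in list(1:4, 5:8, 9:12)) mag[b, b] <- 0.3
  diag(mag) <- 0
  sol <- percolate(net_from_matrix(mag), 3, 0.1)
  expect_equal(sol$entropy_bits, log2(3))
})

test_that("the threshold grid enumerates ordered (k, I) combinations", {
  grid <- threshold_grid(two_triangle_net(), k_values = c(3, 4), I_step = 0.05)
  expect_true(all(diff(grid$I[grid$k == 3]) > 0))
  expect_equal(sort(unique(grid$k)), c(3, 4))
  expect_equal(max(grid$I[grid$k == 3]) <= max(two_triangle_net()$magnitude),
               TRUE)
  # the grid stops at the maximum magnitude
  expect_length(grid$n_communities[grid$k == 3 & grid$I > 0.3], 0)
  top <- grid[grid$k == 4, ]
  expect_true(all(top$n_communities == 0))  # no 4-clique exists

  empty <- net_from_matrix(matrix(0, 4, 4))
  g0 <- threshold_grid(empty, I_step = 0.01)
  expect_true(all(g0$n_communities == 0))
})

test_that("the permutation null band is deterministic and exchangeable", {
  net <- two_triangle_net()
  n1 <- permute_entropy_null(net, n_perm = 30, seed = 5)
  n2 <- permute_entropy_null(net, n_perm = 30, seed = 5)
  expect_identical(n1$upper_95, n2$upper_95)

  # equal weights everywhere: permutation leaves the graph distribution
  # unchanged, so the observed maximum falls inside the null band
  mag <- matrix(0.3, 8, 8); diag(mag) <- 0
  eq <- net_from_matrix(mag)
  grid <- threshold_grid(eq, k_values = 3, I_step = 0.05)
  nul <- permute_entropy_null(eq, k_values = 3, I_step = 0.05,
                              n_perm = 40, seed = 6)
  expect_lte(max(grid$entropy_bits), nul$upper_95[nul$k == 3])
})

test_that("solution selection prefers balanced covers and records why", {
  # planted disjoint blocks (12, 6, 6, 4, 4): ratio exactly 2 at the crossing
  m <- make_planted_model(n_continuous = 32,
                          community_sizes = c(12, 6, 6, 4, 4),
                          within_weight = 0.3, seed = 1, random_sign = FALSE)
  net <- net_from_matrix(abs(m$pair_params))
  grid <- threshold_grid(net, k_values = 3, I_step = 0.05)
  sel <- select_solution(grid)
  expect_equal(sel$ratio_candidate$ratio, 2.0)
  expect_equal(canonical_cover(sel$chosen$communities),
               canonical_cover(m$blocks))
  expect_true(any(grepl("ratio candidate", sel$rationale)))
  expect_true(any(grepl("entropy candidate", sel$rationale)))

  # a single giant community fails the giant-component rule; with no
  # multi-community row the entropy candidate is chosen by default
  mag <- matrix(0.5, 5, 5); diag(mag) <- 0
  giant <- net_from_matrix(mag)
  sel2 <- select_solution(threshold_grid(giant, k_values = 3, I_step = 0.1))
  expect_length(sel2$chosen$communities, 1)
  expect_true(any(grepl("single candidate", sel2$rationale)))

  # no triangles anywhere: no candidate at all
  path_net <- net_from_matrix({
    m0 <- matrix(0, 4, 4)
    m0[1, 2] <- m0[2, 3] <- m0[3, 4] <- 0.3
    m0 + t(m0)
  })
  expect_error(select_solution(threshold_grid(path_net, k_values = 3,
                                              I_step = 0.1)),
               "finer")
})
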