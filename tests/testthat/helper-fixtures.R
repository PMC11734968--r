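# Shared fixtures: all data is generated in code, no stored files.

# Tiny mixed dataset: two continuous + one 2-level categorical column.
toy_mixed <- function(n = 10, seed = 1) {
  set.seed(seed)
  spec <- variable_spec(
    name = c("a", "b", "g"),
    domain = c("continuous", "continuous", "categorical"),
    levels = list(character(), character(), c("lo", "hi"))
  )
  mixed_data(
    data.frame(a = rnorm(n), b = rnorm(n),
               g = sample(c("lo", "hi"), n, replace = TRUE)),
    spec
  )
}

# Wrap a symmetric magnitude matrix into an mgm_network (all-continuous).
net_from_matrix <- function(mag, sign = NULL) {
  p <- nrow(mag)
  nodes <- rownames(mag)
  if (is.null(nodes)) {
    nodes <- paste0("N", seq_len(p))
    dimnames(mag) <- list(nodes, nodes)
  }
  if (is.null(sign)) {
    sign <- (mag > 0) * 1
    dimnames(sign) <- dimnames(mag)
  }
  inv <- matrix(FALSE, p, p, dimnames = dimnames(mag))
  wellnet:::new_mgm_network(nodes, mag, sign, inv,
                            rep("continuous", p))
}

# Random sparse weighted network on p nodes.
random_network <- function(p, density = 0.4, seed = 1) {
  set.seed(seed)
  mag <- matrix(0, p, p)
  pairs <- which(upper.tri(mag), arr.ind = TRUE)
  on <- runif(nrow(pairs)) < density
  w <- round(runif(sum(on), 0.05, 0.5), 3)
  mag[pairs[on, , drop = FALSE]] <- w
  mag <- mag + t(mag)
  net_from_matrix(mag)
}

# Independent clique-percolation oracle: enumerate k-subsets by brute force,
# test cliquehood and intensity by definition, and merge cliques sharing
# k - 1 nodes by breadth-first closure. No igraph involved.
brute_percolate <- function(mag, k, I) {
  p <- nrow(mag)
  nodes <- rownames(mag)
  if (is.null(nodes)) nodes <- paste0("N", seq_len(p))
  subsets <- utils::combn(p, k, simplify = FALSE)
  is_admissible <- function(ii) {
    w <- mag[ii, ii][upper.tri(matrix(0, k, k))]
    all(w > 0) && exp(mean(log(w))) >= I
  }
  cls <- Filter(is_admissible, subsets)
  if (!length(cls)) {
    return(list(communities = list(), isolated = sort(nodes)))
  }
  nc <- length(cls)
  comp <- rep(NA_integer_, nc)
  cid <- 0L
  for (s in seq_len(nc)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in seq_len(nc)) {
        if (is.na(comp[u]) &&
            length(intersect(cls[[v]], cls[[u]])) == k - 1) {
          comp[u] <- cid
          queue <- c(queue, u)
        }
      }
    }
  }
  communities <- lapply(seq_len(cid), function(ci) {
    sort(nodes[unique(unlist(cls[comp == ci]))])
  })
  covered <- unique(unlist(communities))
  list(communities = communities, isolated = sort(setdiff(nodes, covered)))
}

# Canonical form of a community cover for set comparison.
canonical_cover <- function(communities) {
  sort(unname(vapply(communities, function(x) paste(sort(x), collapse = ","),
                     character(1))))
}

# Toy participant-flow dataset mirroring the published exclusion counts:
# 2886 completers of which 176 carry an unreliable-record flag and, of the
# remainder, 217 are physical-activity outliers.
exclusion_flow_data <- function() {
  n <- 2886
  unreliable <- c(rep(TRUE, 176), rep(FALSE, n - 176))
  outlier <- rep(FALSE, n)
  outlier[177:(176 + 217)] <- TRUE
  spec <- variable_spec(
    name = c("unreliable_record", "phy_outlier", "score"),
    domain = c("categorical", "categorical", "continuous"),
    levels = list(c("no", "yes"), c("no", "yes"), character())
  )
  mixed_data(
    data.frame(unreliable_record = ifelse(unreliable, "yes", "no"),
               phy_outlier = ifelse(outlier, "yes", "no"),
               score = seq_len(n)),
    spec
  )
}
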