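#' Build a planted pairwise model with community structure
#'
#' Constructs a ground-truth pairwise model over `p` nodes organised into
#' blocks (communities): every within-community pair receives an interaction
#' of magnitude `within_weight`, a sparse set of between-community pairs
#' (one randomly chosen pair per community pair) receives `between_weight`,
#' and isolated nodes receive no interactions. A fixed proportion of planted
#' edges (default 25%) is given a negative sign, mirroring the mixed-sign
#' networks typical of psychometric data.
#'
#' For all-continuous models the implied precision matrix is
#' `I - theta` with `theta` the (possibly repaired) interaction matrix. When
#' the requested interaction matrix is too strong to be positive definite --
#' equal partial correlations within a block of size m cannot exceed
#' 1/(m-1) -- the matrix is repaired by uniform diagonal loading, which
#' shrinks all interactions by a common factor (`repair_factor`) and thereby
#' preserves the within/between contrast exactly. When no repair is needed
#' the realized partial correlations equal the requested weights.
#'
#' @param n_continuous Number of continuous nodes.
#' @param categorical_specs Integer vector of level counts, one per
#'   categorical node; categorical nodes occupy the last positions.
#' @param community_sizes Integer vector of disjoint block sizes.
#' @param within_weight Magnitude of within-community interactions.
#' @param between_weight Magnitude of the sparse between-community
#'   interactions; must satisfy `abs(within_weight) > abs(between_weight)`.
#' @param n_isolated Number of nodes in no community;
#'   `sum(community_sizes) + n_isolated` must equal `p`.
#' @param seed Integer seed fixing signs and between-edge placement.
#' @param neg_prop Proportion of planted edges given a negative sign.
#' @param random_sign If `FALSE`, all planted edges are positive.
#' @param moderation Optional list `list(moderator = <node name>, triples =
#'   data.frame(a, b, strength))` planting three-way product terms.
#'
#' @return An object of class `planted_model`.
#' @export
make_planted_model <- function(n_continuous, categorical_specs = integer(),
                               community_sizes, within_weight,
                               between_weight = 0, n_isolated = 0,
                               seed = 1, neg_prop = 0.25, random_sign = TRUE,
                               moderation = NULL) {
  p <- n_continuous + length(categorical_specs)
  if (sum(community_sizes) + n_isolated != p) {
    stop(sprintf("infeasible sizes: sum(community_sizes) + n_isolated = %d but p = %d",
                 sum(community_sizes) + n_isolated, p))
  }
  if (abs(within_weight) > 0 && abs(within_weight) <= abs(between_weight)) {
    stop("need |within_weight| > |between_weight|")
  }
  nodes <- paste0("V", seq_len(p))
  membership <- vector("list", p)
  names(membership) <- nodes
  idx <- 1L
  blocks <- vector("list", length(community_sizes))
  for (b in seq_along(community_sizes)) {
    blocks[[b]] <- nodes[idx:(idx + community_sizes[b] - 1L)]
    idx <- idx + community_sizes[b]
  }
  build_planted_model(
    nodes = nodes,
    n_continuous = n_continuous,
    categorical_specs = categorical_specs,
    blocks = blocks,
    within_weight = within_weight,
    between_weight = between_weight,
    seed = seed, neg_prop = neg_prop, random_sign = random_sign,
    moderation = moderation
  )
}

# Shared builder: blocks may overlap (shared nodes cross-load).
build_planted_model <- function(nodes, n_continuous, categorical_specs,
                                blocks, within_weight, between_weight,
                                seed, neg_prop, random_sign,
                                moderation = NULL,
                                cont_means = NULL, cont_sds = NULL,
                                categorical_probs = NULL) {
  p <- length(nodes)
  set.seed(derive_seed(seed, 11L))
  P <- matrix(0, p, p, dimnames = list(nodes, nodes))
  draw_sign <- function(m) {
    if (!random_sign) rep(1, m) else ifelse(stats::runif(m) < neg_prop, -1, 1)
  }
  for (blk in blocks) {
    ii <- match(blk, nodes)
    pairs <- utils::combn(ii, 2)
    s <- draw_sign(ncol(pairs))
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1, q]; j <- pairs[2, q]
      if (P[i, j] == 0) {
        P[i, j] <- P[j, i] <- s[q] * within_weight
      }
    }
  }
  if (between_weight != 0 && length(blocks) >= 2) {
    combs <- utils::combn(length(blocks), 2)
    for (q in seq_len(ncol(combs))) {
      a <- setdiff(blocks[[combs[1, q]]], blocks[[combs[2, q]]])
      b <- setdiff(blocks[[combs[2, q]]], blocks[[combs[1, q]]])
      if (!length(a) || !length(b)) next
      i <- match(sample(a, 1), nodes)
      j <- match(sample(b, 1), nodes)
      if (P[i, j] == 0) {
        P[i, j] <- P[j, i] <- draw_sign(1) * between_weight
      }
    }
  }
  # Positive-definiteness repair by uniform diagonal loading (expressed as a
  # uniform shrink of the interactions): keeps min eigenvalue of I - theta
  # at or above 0.05 and preserves the within/between weight ratio.
  lam_max <- if (all(P == 0)) 0 else max(eigen(P, symmetric = TRUE,
                                               only.values = TRUE)$values)
  repair_factor <- max(1, lam_max / 0.95)
  theta <- P / repair_factor
  membership <- lapply(nodes, function(v) {
    which(vapply(blocks, function(blk) v %in% blk, logical(1)))
  })
  names(membership) <- nodes
  domain <- c(rep("continuous", n_continuous),
              rep("categorical", length(categorical_specs)))
  levels <- c(rep(list(character()), n_continuous),
              lapply(categorical_specs, function(L) as.character(seq_len(L) - 1L)))
  spec <- variable_spec(nodes, domain, levels)
  if (is.null(cont_means)) cont_means <- stats::setNames(rep(0, n_continuous),
                                                         nodes[seq_len(n_continuous)])
  if (is.null(cont_sds)) cont_sds <- stats::setNames(rep(1, n_continuous),
                                                     nodes[seq_len(n_continuous)])
  structure(
    list(spec = spec, nodes = nodes,
         pair_params = P, theta = theta, repair_factor = repair_factor,
         blocks = lapply(blocks, sort),
         community_labels = membership,
         cont_means = cont_means, cont_sds = cont_sds,
         categorical_probs = categorical_probs,
         moderation = moderation),
    class = "planted_model"
  )
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf("<planted_model> %d nodes (%d categorical), %d planted communities, %d isolated\n",
              length(x$nodes), sum(x$spec$domain == "categorical"),
              length(x$blocks),
              sum(vapply(x$community_labels, length, integer(1)) == 0)))
  if (x$repair_factor > 1) {
    cat(sprintf("  interactions shrunk by %.3f for positive definiteness\n",
                x$repair_factor))
  }
  invisible(x)
}

#' True partial correlations of an all-continuous planted model
#'
#' Returns the partial-correlation matrix implied by the model's precision
#' matrix `Theta = I - theta`:
#' `rho_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)`, with unit diagonal.
#' These are the population edge weights a consistent estimator should
#' recover.
#'
#' @param model A [make_planted_model()] result with continuous nodes only.
#' @return A symmetric p x p matrix with unit diagonal.
#' @export
true_partial_correlations <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  if (any(model$spec$domain == "categorical")) {
    stop("true_partial_correlations is defined for all-continuous models only")
  }
  Theta <- diag(length(model$nodes)) - model$theta
  d <- sqrt(diag(Theta))
  rho <- -Theta / outer(d, d)
  diag(rho) <- 1
  dimnames(rho) <- list(model$nodes, model$nodes)
  rho
}

model_precision <- function(model) {
  diag(length(model$nodes)) - model$theta
}

# Centered, unit-variance scores for the levels of a categorical node; used
# to let categorical nodes enter the pairwise potentials on a single score
# dimension.
level_scores <- function(L) {
  s <- seq_len(L)
  as.numeric(scale(s))
}

#' Sample observations from a planted model
#'
#' All-continuous models without moderation are sampled exactly from the
#' zero-mean Gaussian with precision `I - theta`, then de-standardized by the
#' model's per-variable means/SDs. Models with categorical nodes or planted
#' moderation are sampled by a vectorized Gibbs sweep over the full
#' conditionals (linear-Gaussian with unit conditional variance for
#' continuous nodes, multinomial-logistic over centered level scores for
#' categorical nodes), run in parallel over observations with `burn_in`
#' sequential sweeps. Gibbs states are clamped to +/- 8 standard deviations
#' as a numerical guard against runaway moderation feedback.
#'
#' @param model A [make_planted_model()] result.
#' @param n Number of observations.
#' @param seed Integer seed.
#' @param burn_in Number of Gibbs sweeps before the state is taken as the
#'   sample (default 200).
#' @param thinning Extra sweeps appended after burn-in (kept for
#'   compatibility with sequential-chain samplers; chains here are parallel
#'   over observations).
#'
#' @return A [mixed_data()] with `n` rows.
#' @export
sample_mgm <- function(model, n, seed = 1, burn_in = 200, thinning = 1) {
  stopifnot(inherits(model, "planted_model"), n >= 1)
  set.seed(derive_seed(seed, 23L))
  p <- length(model$nodes)
  cat_idx <- which(model$spec$domain == "categorical")
  cont_idx <- which(model$spec$domain == "continuous")
  all_cont <- length(cat_idx) == 0
  if (all_cont && is.null(model$moderation)) {
    Theta <- model_precision(model)
    ev <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("implied precision matrix is not positive definite")
    R <- chol(Theta)
    Z <- matrix(stats::rnorm(n * p), n, p)
    X <- t(backsolve(R, t(Z)))   # rows ~ N(0, Theta^-1)
    # rescale to unit marginal variances so cont_sds are the actual SDs
    # (partial correlations are invariant under this diagonal scaling)
    X <- sweep(X, 2, sqrt(diag(solve(Theta))), "/")
    colnames(X) <- model$nodes
  } else {
    X <- gibbs_sample(model, n, burn_in = burn_in, thinning = thinning)
  }
  values <- tibble::as_tibble(as.data.frame(X))
  for (i in cont_idx) {
    nm <- model$nodes[i]
    values[[nm]] <- values[[nm]] * model$cont_sds[[nm]] + model$cont_means[[nm]]
  }
  for (i in cat_idx) {
    nm <- model$nodes[i]
    lev <- model$spec$levels[[match(nm, model$spec$name)]]
    values[[nm]] <- lev[as.integer(values[[nm]])]
  }
  mixed_data(values, model$spec)
}

# Vectorized Gibbs sampler: one chain per observation, sequential node
# updates within each sweep. Continuous state is kept on the standardized
# scale; categorical state is the integer level index, entering the
# conditionals through centered level scores.
gibbs_sample <- function(model, n, burn_in = 200, thinning = 1) {
  p <- length(model$nodes)
  theta <- model$theta
  cat_idx <- which(model$spec$domain == "categorical")
  scores <- vector("list", p)
  for (i in cat_idx) {
    L <- length(model$spec$levels[[i]])
    scores[[i]] <- level_scores(L)
  }
  # initial state
  state <- matrix(stats::rnorm(n * p), n, p)
  z <- state
  for (i in cat_idx) {
    L <- length(scores[[i]])
    state[, i] <- sample.int(L, n, replace = TRUE)
    z[, i] <- scores[[i]][state[, i]]
  }
  mod <- model$moderation
  mod_triples <- NULL
  if (!is.null(mod)) {
    m_idx <- match(mod$moderator, model$nodes)
    mod_triples <- data.frame(a = match(mod$triples$a, model$nodes),
                              b = match(mod$triples$b, model$nodes),
                              m = m_idx,
                              w = mod$triples$strength)
  }
  n_sweeps <- burn_in + thinning
  message(sprintf("Gibbs sampler: %d chains, %d burn-in sweeps, thinning %d",
                  n, burn_in, thinning))
  # sequential node order; an exogenous moderator is updated first so the
  # final state of its dependents is conditioned on the current value
  node_order <- seq_len(p)
  if (!is.null(mod_triples)) {
    node_order <- c(mod_triples$m[1], setdiff(node_order, mod_triples$m[1]))
  }
  for (sweep in seq_len(n_sweeps)) {
    for (i in node_order) {
      eta <- z %*% theta[, i]
      if (!is.null(mod_triples)) {
        # the moderator is exogenous: its own conditional carries no product
        # term, keeping the three-way chain proper (a symmetric cubic
        # potential is unnormalizable)
        for (t in seq_len(nrow(mod_triples))) {
          tr <- mod_triples[t, ]
          if (i == tr$a) eta <- eta + tr$w * z[, tr$b] * z[, tr$m]
          if (i == tr$b) eta <- eta + tr$w * z[, tr$a] * z[, tr$m]
        }
      }
      if (i %in% cat_idx) {
        sc <- scores[[i]]
        # multinomial logit over levels: P(l) propto exp(score_l * eta)
        lp <- outer(as.vector(eta), sc)
        lp <- lp - apply(lp, 1, max)
        pr <- exp(lp)
        pr <- pr / rowSums(pr)
        u <- stats::runif(n)
        cum <- t(apply(pr, 1, cumsum))
        state[, i] <- 1L + rowSums(u > cum)
        state[, i] <- pmin(state[, i], length(sc))
        z[, i] <- sc[state[, i]]
      } else {
        draw <- stats::rnorm(n, mean = as.vector(eta), sd = 1)
        draw <- pmin(pmax(draw, -8), 8)
        state[, i] <- draw
        z[, i] <- draw
      }
    }
  }
  colnames(state) <- model$nodes
  state
}

# Table-1 calibration of the 30-variable study mimic: 28 continuous
# constructs with their published means/SDs plus two categorical history
# variables (physical/neurological diseases, 8 levels; mental health
# disorders, 3 levels).
mimic_roster <- function() {
  tibble::tribble(
    ~name, ~mean, ~sd, ~group,
    "MWB",  55.6,    5.88,  "outcomes",
    "QoL",  94.7,    9.46,  "outcomes",
    "SES",  85.0,   10.3,   "demographics",
    "URB",  2859.0, 2665.0, "demographics",
    "CON",  168.8,  73.9,   "lifestyle",
    "HEA",  82.8,   13.6,   "lifestyle",
    "SQ",   5.3,    3.22,   "lifestyle",
    "PHY",  3619.1, 2098.2, "lifestyle",
    "AU",   3.35,   2.15,   "lifestyle",
    "PRM",  24.5,   4.8,    "lifestyle",
    "HAP",  7.80,   1.02,   "mental_health",
    "DEP",  15.9,   4.59,   "mental_health",
    "ANX",  11.0,   3.32,   "mental_health",
    "LON",  2.76,   3.07,   "mental_health",
    "SSD",  15.0,   4.43,   "mental_health",
    "BOR",  1.74,   0.74,   "mental_health",
    "PS",   10.5,   5.42,   "stress",
    "MLE",  7.13,   6.42,   "stress",
    "SI",   70.2,   8.52,   "stress",
    "BRS",  21.3,   3.88,   "coping",
    "PAS",  0.04,   0.6,    "coping",
    "BC",   21.5,   3.66,   "coping",
    "GSE",  32.6,   4.14,   "coping",
    "SE",   33.0,   4.17,   "coping",
    "SMA",  69.4,   11.5,   "coping",
    "SPoA", 51.8,   9.18,   "ageism",
    "PNA",  7.39,   2.61,   "ageism",
    "PPA",  9.56,   2.28,   "ageism"
  )
}

# Planted overlapping community template of the mimic: five blocks of sizes
# (12, 6, 6, 4, 4) chained by single shared (cross-loading) nodes; the two
# categorical nodes are isolated.
mimic_blocks <- function() {
  list(
    psycho_social = c("HAP", "MWB", "DEP", "QoL", "ANX", "PS",
                      "SQ", "CON", "SSD", "LON", "SMA", "HEA"),
    aging_identity = c("HEA", "SPoA", "PNA", "SE", "PPA", "PRM"),
    life_context = c("PRM", "SES", "URB", "PHY", "AU", "MLE"),
    external_load = c("MLE", "BOR", "SI", "GSE"),
    positive_outlook = c("GSE", "BRS", "PAS", "BC")
  )
}

#' Generate the 30-node study mimic
#'
#' Builds a planted model over the 30 study variables -- 28 continuous
#' constructs calibrated to the published descriptive statistics (e.g.
#' mental well-being mean 55.6, SD 5.88; quality of life mean 94.7, SD 9.46)
#' plus one 8-level and one 3-level categorical variable -- and draws a
#' sample of `n` observations. The planted dependence structure follows the
#' published community-size template: five overlapping communities of sizes
#' 12, 6, 6, 4 and 4, chained by four single cross-loading nodes, with the
#' two categorical variables isolated. Categorical variables are drawn from
#' fixed marginal frequencies (independent of the rest, consistent with
#' their isolated status).
#'
#' @param seed Integer seed.
#' @param n Sample size (default 2000).
#' @param within_weight Requested within-community interaction magnitude
#'   (default 0.3; shrunk by the positive-definiteness repair).
#' @param between_weight Requested between-community interaction magnitude
#'   (default 0.05).
#'
#' @return A list with elements `model` (the `planted_model`) and `data`
#'   (a [mixed_data()] of `n` rows).
#' @export
study_mimic <- function(seed = 1, n = 2000, within_weight = 0.3,
                        between_weight = 0.05) {
  roster <- mimic_roster()
  nodes <- c(roster$name, "PND", "MHD")
  pnd_probs <- c(0.35, 0.15, 0.12, 0.10, 0.09, 0.08, 0.06, 0.05)
  mhd_probs <- c(0.60, 0.25, 0.15)
  model <- build_planted_model(
    nodes = nodes,
    n_continuous = nrow(roster),
    categorical_specs = c(8L, 3L),
    blocks = mimic_blocks(),
    within_weight = within_weight,
    between_weight = between_weight,
    seed = seed, neg_prop = 0.25, random_sign = TRUE,
    cont_means = stats::setNames(roster$mean, roster$name),
    cont_sds = stats::setNames(roster$sd, roster$name),
    categorical_probs = list(PND = pnd_probs, MHD = mhd_probs)
  )
  model$spec$display_group <- c(roster$group, "health", "health")
  set.seed(derive_seed(seed, 37L))
  # continuous part: exact Gaussian sampling from the repaired precision
  cont_nodes <- roster$name
  Theta <- model_precision(model)[cont_nodes, cont_nodes]
  R <- chol(Theta)
  Z <- matrix(stats::rnorm(n * length(cont_nodes)), n, length(cont_nodes))
  X <- t(backsolve(R, t(Z)))
  X <- sweep(X, 2, sqrt(diag(solve(Theta))), "/")
  colnames(X) <- cont_nodes
  values <- tibble::as_tibble(as.data.frame(X))
  for (nm in cont_nodes) {
    values[[nm]] <- values[[nm]] * roster$sd[roster$name == nm] +
      roster$mean[roster$name == nm]
  }
  values$PND <- as.character(sample(0:7, n, replace = TRUE, prob = pnd_probs))
  values$MHD <- as.character(sample(0:2, n, replace = TRUE, prob = mhd_probs))
  list(model = model, data = mixed_data(values, model$spec))
}

#' Write a planted model as structured text
#'
#' Serializes the planted interaction matrix and community labels so test
#' oracles can be stored or inspected outside R.
#'
#' @param model A `planted_model`.
#' @param path Output YAML path.
#' @export
write_planted_model <- function(model, path) {
  yaml::write_yaml(list(
    nodes = as.list(model$nodes),
    repair_factor = model$repair_factor,
    blocks = lapply(model$blocks, as.list),
    pair_params = apply(model$pair_params, 1, as.list)
  ), path)
  invisible(model)
}
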