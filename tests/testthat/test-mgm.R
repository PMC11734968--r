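test_that("EBIC formula and its limits", {
  # -2(-150) + 3 ln(100) + 2(0.25)(3) ln(29) = 318.8665
  expect_equal(ebic_score(-150, df = 3, n = 100, q = 29, gamma = 0.25),
               318.866455, tolerance = 1e-6)
  expect_equal(ebic_score(-10, df = 2, n = 50, q = 5, gamma = 0),
               -2 * (-10) + 2 * log(50))
  expect_equal(ebic_score(-123.4, df = 0, n = 100, q = 10, gamma = 0.25),
               246.8)
})

test_that("nodewise regression selects the empty model on independent data", {
  m0 <- make_planted_model(n_continuous = 5, community_sizes = 5,
                           within_weight = 0, seed = 1)
  d <- sample_mgm(m0, 2000, seed = 11)
  xs <- standardize_continuous(d)
  f <- fit_nodewise(xs, "V1")
  expect_equal(f$df, 0)
  # the largest penalty always gives an all-zero fit
  expect_equal(f$path$df[1], 0L)
  expect_true(f$selected_lambda %in% f$lambda_grid)
  expect_equal(f$ebic, min(f$path$ebic))
})

test_that("nodewise coefficient recovers the standardized partial", {
  m <- make_planted_model(n_continuous = 2, community_sizes = 2,
                          within_weight = 0.5, seed = 1, random_sign = FALSE)
  d <- sample_mgm(m, 5000, seed = 12)
  xs <- standardize_continuous(d)
  f <- fit_nodewise(xs, "V1")
  expect_equal(unname(f$coefficients["V2"]), 0.5, tolerance = 0.03 / 0.5)
})

test_that("aggregation follows the stated AND/OR and sign conventions", {
  fake_fit <- function(node, coefs, domain = "continuous") {
    structure(list(node = node, domain = domain,
                   coefficients = coefs,
                   term_targets = stats::setNames(names(coefs), names(coefs)),
                   term_kinds = stats::setNames(rep("base", length(coefs)),
                                                names(coefs))),
              class = "nodewise_fit")
  }
  fits <- list(fake_fit("A", c(B = 0.20)), fake_fit("B", c(A = 0.30)))
  net <- aggregate_network(fits, rule = "AND")
  expect_equal(net$magnitude["A", "B"], 0.25)
  expect_equal(net$sign["A", "B"], 1)

  fits2 <- list(fake_fit("A", c(B = 0.20)), fake_fit("B", c(A = 0)))
  expect_equal(aggregate_network(fits2, "AND")$magnitude["A", "B"], 0)
  expect_equal(aggregate_network(fits2, "OR")$magnitude["A", "B"], 0.20)

  # disagreeing directions lose their sign
  fits3 <- list(fake_fit("A", c(B = 0.20)), fake_fit("B", c(A = -0.30)))
  net3 <- aggregate_network(fits3, "AND")
  expect_equal(net3$magnitude["A", "B"], 0.25)
  expect_equal(net3$sign["A", "B"], 0)

  # categorical-involving pairs are unsigned regardless of coefficients
  fits4 <- list(
    fake_fit("A", c(`G.1` = 0.4), domain = "continuous"),
    structure(list(node = "G", domain = "categorical",
                   coefficients = c(`1~A` = 0.2, `2~A` = -0.6),
                   term_targets = c(`1~A` = "A", `2~A` = "A"),
                   term_kinds = c(`1~A` = "base", `2~A` = "base")),
              class = "nodewise_fit")
  )
  fits4[[1]]$term_targets <- c(`G.1` = "G")
  net4 <- aggregate_network(fits4, "AND")
  expect_equal(net4$sign["A", "G"], 0)
  expect_true(net4$involves_categorical["A", "G"])
  # mean of absolute level coefficients, then mean across directions
  expect_equal(net4$magnitude["A", "G"], mean(c(0.4, mean(c(0.2, 0.6)))))

  expect_error(aggregate_network(list(fake_fit("A", c(Z = 0.2)),
                                      fake_fit("B", c(A = 0.2)))),
               "mismatched")
})

test_that("every emitted network is symmetric with zero diagonal", {
  d <- study_mimic(seed = 2, n = 300)$data
  fit <- fit_mgm(d)
  expect_true(isSymmetric(unname(fit$network$magnitude)))
  expect_equal(diag(fit$network$magnitude), rep(0, 30), ignore_attr = TRUE)
  expect_true(all(fit$network$sign[fit$network$involves_categorical] == 0))
  expect_true(all(fit$network$sign[fit$network$magnitude == 0] == 0))
})

test_that("AND-rule networks are edge subsets of OR-rule networks", {
  m <- make_planted_model(n_continuous = 6, community_sizes = c(3, 3),
                          within_weight = 0.3, seed = 3)
  d <- sample_mgm(m, 800, seed = 13)
  xs <- standardize_continuous(d)
  fits <- lapply(xs$spec$name, function(nm) fit_nodewise(xs, nm))
  and_net <- aggregate_network(fits, "AND")
  or_net <- aggregate_network(fits, "OR")
  expect_true(all(or_net$magnitude[and_net$magnitude > 0] > 0))
})

test_that("increasing gamma never increases the selected edge count", {
  m <- make_planted_model(n_continuous = 6, community_sizes = c(4, 2),
                          within_weight = 0.25, seed = 4)
  d <- sample_mgm(m, 600, seed = 14)
  counts <- vapply(c(0, 0.25, 0.5, 1), function(g) {
    net <- fit_mgm(d, gamma = g)$network
    sum(net$magnitude[upper.tri(net$magnitude)] > 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("permuting dataset columns permutes the network identically", {
  m <- make_planted_model(n_continuous = 5, community_sizes = c(3, 2),
                          within_weight = 0.35, seed = 5)
  d <- sample_mgm(m, 700, seed = 15)
  fit1 <- fit_mgm(d)
  perm <- c(3, 1, 5, 2, 4)
  d2 <- mixed_data(d$data[perm], d$spec[perm, ])
  fit2 <- fit_mgm(d2)
  nodes <- fit1$network$nodes
  # identical sparsity pattern; weights equal up to solver tolerance
  perm_mag <- fit2$network$magnitude[nodes, nodes]
  expect_identical(perm_mag > 0, fit1$network$magnitude > 0)
  expect_lt(max(abs(perm_mag - fit1$network$magnitude)), 1e-4)
})

test_that("near-unpenalized magnitudes approach true partial correlations", {
  m <- make_planted_model(n_continuous = 6, community_sizes = c(3, 3),
                          within_weight = 0.35, seed = 6)
  d <- sample_mgm(m, 4000, seed = 16)
  net <- fit_mgm(d, select = "min_lambda")$network
  truth <- abs(true_partial_correlations(m))
  diag(truth) <- 0
  expect_lt(max(abs(net$magnitude - truth)), 0.05)
})

test_that("predictability reports R-squared and accuracy with baselines", {
  # isolated node: no signal to explain
  m <- make_planted_model(n_continuous = 4, community_sizes = 3,
                          n_isolated = 1, within_weight = 0.4, seed = 7,
                          random_sign = FALSE)
  d <- sample_mgm(m, 2000, seed = 17)
  fit <- fit_mgm(d)
  pr <- predictability(fit)
  expect_lte(pr$r_squared[pr$node == "V4"], 0.02)
  expect_gt(pr$r_squared[pr$node == "V1"], 0.1)
  expect_true(all(pr$r_squared >= 0 & pr$r_squared <= 1, na.rm = TRUE))

  # categorical node with an empty neighborhood predicts the marginal mode
  m2 <- make_planted_model(n_continuous = 2, categorical_specs = 3L,
                           community_sizes = 3, within_weight = 0, seed = 2)
  d2 <- suppressMessages(sample_mgm(m2, 500, seed = 18))
  fit2 <- fit_mgm(d2)
  pr2 <- predictability(fit2)
  cat_row <- pr2[pr2$domain == "categorical", ]
  expect_equal(cat_row$accuracy, cat_row$baseline)
})
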