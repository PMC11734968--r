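test_that("planted models are deterministic and respect the size layout", {
  m1 <- make_planted_model(n_continuous = 32, community_sizes = c(12, 6, 6, 4, 4),
                           within_weight = 0.3, between_weight = 0.05, seed = 9)
  m2 <- make_planted_model(n_continuous = 32, community_sizes = c(12, 6, 6, 4, 4),
                           within_weight = 0.3, between_weight = 0.05, seed = 9)
  expect_identical(m1$pair_params, m2$pair_params)
  expect_length(m1$blocks, 5)
  expect_equal(sort(vapply(m1$blocks, length, integer(1)), decreasing = TRUE),
               c(12, 6, 6, 4, 4))
  # ~25% of planted edges carry a negative sign
  w <- m1$pair_params[upper.tri(m1$pair_params)]
  expect_gt(mean(w[w != 0] < 0), 0.12)
  expect_lt(mean(w[w != 0] < 0), 0.40)

  expect_error(make_planted_model(n_continuous = 5, community_sizes = c(3, 3),
                                  within_weight = 0.3),
               "infeasible")

  m0 <- make_planted_model(n_continuous = 6, community_sizes = 6,
                           within_weight = 0, seed = 1)
  expect_true(all(m0$theta == 0))
})

test_that("true partial correlations match the precision-matrix formula", {
  m <- make_planted_model(n_continuous = 2, community_sizes = 2,
                          within_weight = 0.3, seed = 1, random_sign = FALSE)
  rho <- true_partial_correlations(m)
  expect_equal(rho[1, 2], 0.3, tolerance = 1e-12)
  expect_equal(diag(rho), rep(1, 2), ignore_attr = TRUE)

  # chain 1-2-3: the unlinked pair has partial exactly 0
  chain <- make_planted_model(n_continuous = 3, community_sizes = c(2, 1),
                              within_weight = 0.4, seed = 1,
                              random_sign = FALSE)
  chain$theta[1, 3] <- chain$theta[3, 1] <- 0
  chain$theta[2, 3] <- chain$theta[3, 2] <- 0.4
  expect_equal(true_partial_correlations(chain)[1, 3], 0)

  # two-route oracle: partials via a second inversion through the covariance
  m5 <- make_planted_model(n_continuous = 5, community_sizes = c(3, 2),
                           within_weight = 0.35, between_weight = 0.1,
                           seed = 4)
  rho5 <- true_partial_correlations(m5)
  Sigma <- solve(diag(5) - m5$theta)
  K <- solve(Sigma)
  rho_alt <- -K / sqrt(outer(diag(K), diag(K)))
  diag(rho_alt) <- 1
  expect_equal(unname(rho5), unname(rho_alt), tolerance = 1e-10)

  cat_model <- make_planted_model(n_continuous = 1, categorical_specs = 2L,
                                  community_sizes = 2, within_weight = 0.2,
                                  seed = 1)
  expect_error(true_partial_correlations(cat_model), "continuous")
})

test_that("exact Gaussian sampling reproduces planted dependence", {
  # p = 2: the partial equals the marginal correlation
  m <- make_planted_model(n_continuous = 2, community_sizes = 2,
                          within_weight = 0.3, seed = 1, random_sign = FALSE)
  d <- sample_mgm(m, 50000, seed = 2)
  expect_equal(stats::cor(d$data$V1, d$data$V2), 0.3, tolerance = 0.01)

  # empty model: no pairwise correlation beyond Monte-Carlo noise
  m0 <- make_planted_model(n_continuous = 4, community_sizes = 4,
                           within_weight = 0, seed = 1)
  d0 <- sample_mgm(m0, 5000, seed = 3)
  C <- stats::cor(as.matrix(d0$data))
  expect_lt(max(abs(C[upper.tri(C)])), 3 / sqrt(5000))
})

test_that("sample partial correlations recover the planted model", {
  m <- make_planted_model(n_continuous = 6, community_sizes = c(3, 2),
                          n_isolated = 1, within_weight = 0.35,
                          between_weight = 0.1, seed = 7)
  d <- sample_mgm(m, 50000, seed = 8)
  K <- solve(stats::cov(as.matrix(d$data)))
  sample_rho <- -K / sqrt(outer(diag(K), diag(K)))
  diag(sample_rho) <- 1
  truth <- true_partial_correlations(m)
  expect_lt(max(abs(sample_rho - truth)), 0.02)
  # planted-zero pairs stay near zero
  zeros <- which(m$theta == 0 & upper.tri(m$theta), arr.ind = TRUE)
  expect_lt(max(abs(sample_rho[zeros])), 4 / sqrt(50000))
})

test_that("Gibbs sampling handles categorical nodes sensibly", {
  # symmetric potentials, no interactions: level frequencies ~ uniform
  m <- make_planted_model(n_continuous = 2, categorical_specs = 3L,
                          community_sizes = 3, within_weight = 0, seed = 1)
  d <- suppressMessages(sample_mgm(m, 4000, seed = 2))
  freq <- table(d$data$V3) / 4000
  expect_true(all(abs(freq - 1 / 3) < 0.04))

  # a positive continuous-categorical coupling separates level means
  m2 <- make_planted_model(n_continuous = 2, categorical_specs = 3L,
                           community_sizes = 3, within_weight = 0.4,
                           seed = 2, random_sign = FALSE)
  d2 <- suppressMessages(sample_mgm(m2, 4000, seed = 3))
  means <- tapply(d2$data$V1, d2$data$V3, mean)
  expect_gt(means[3] - means[1], 0.2)
})

test_that("doubling the Gibbs burn-in leaves summary statistics unchanged", {
  m <- make_planted_model(n_continuous = 3, categorical_specs = 3L,
                          community_sizes = 4, within_weight = 0.25, seed = 3)
  d1 <- suppressMessages(sample_mgm(m, 4000, seed = 5, burn_in = 100))
  d2 <- suppressMessages(sample_mgm(m, 4000, seed = 5, burn_in = 200))
  c1 <- stats::cor(as.matrix(d1$data[1:3]))
  c2 <- stats::cor(as.matrix(d2$data[1:3]))
  expect_lt(max(abs(c1 - c2)), 0.06)
})

test_that("the study mimic is calibrated to the published descriptives", {
  sim <- study_mimic(seed = 1, n = 2000)
  d <- sim$data
  expect_equal(dim(d), c(2000L, 30L))
  expect_equal(mean(d$data$MWB), 55.6, tolerance = 0.4 / 55.6)
  expect_equal(stats::sd(d$data$QoL), 9.46, tolerance = 0.5 / 9.46)
  expect_equal(length(levels(d$data$PND)), 8)
  expect_equal(length(levels(d$data$MHD)), 3)
  # planted cover: five blocks sized (12, 6, 6, 4, 4), categoricals isolated
  expect_equal(unname(sort(vapply(sim$model$blocks, length, integer(1)),
                           decreasing = TRUE)), c(12, 6, 6, 4, 4))
  expect_length(sim$model$community_labels[["PND"]], 0)

  sim2 <- study_mimic(seed = 1, n = 2000)
  expect_identical(sim$data$data, sim2$data$data)
})

test_that("planted models serialize to structured text", {
  m <- make_planted_model(n_continuous = 4, community_sizes = 4,
                          within_weight = 0.2, seed = 1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_planted_model(m, path)
  raw <- yaml::read_yaml(path)
  expect_equal(unlist(raw$nodes), m$nodes)
  expect_equal(raw$repair_factor, m$repair_factor, tolerance = 1e-6)
})
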