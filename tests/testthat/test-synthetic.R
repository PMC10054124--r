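test_that("default scenario encodes the four-source, six-element design", {
  sc <- default_scenario()
  expect_equal(sc$n, 101L)
  expect_equal(sc$elements, c("Cu", "Zn", "Pb", "Cd", "Cr", "Ni"))
  expect_equal(sc$k, 4L)
  expect_equal(sum(sc$shares), 1)
  expect_equal(unname(sc$shares), c(0.35, 0.30, 0.21, 0.14))
  expect_equal(unname(rowSums(sc$profiles)), rep(1, 4), tolerance = 1e-12)
  expect_gte(sc$profiles["natural", "Cr"], 0.79)
  expect_equal(sc$theta, 0.10)
  expect_error(scenario_config(10, c("A", "B"), matrix(0.5, 2, 2),
                               c(0.5, 0.5), 100, 0.3, outlier_frac = 0.5),
               "outlier fraction")
})

test_that("simulation is exact at zero noise and reproducible", {
  sc <- default_scenario(n = 30, theta = 0, seed = 5)
  sim <- simulate_scenario(sc)
  expect_equal(sim$table$values,
               unname(sim$truth$g_true %*% sim$truth$f_true),
               ignore_attr = TRUE)
  sim2 <- simulate_scenario(default_scenario(n = 30, theta = 0, seed = 5))
  expect_identical(sim$table$values, sim2$table$values)
  expect_true(all(sim$table$values > 0))
  expect_equal(sum(sim$truth$shares_true), 100)
})

test_that("generator moments match the configuration at large n", {
  sc <- default_scenario(n = 10000L, seed = 99)
  sim <- simulate_scenario(sc)
  # empirical mean source shares within one percentage point of targets
  expect_lt(max(abs(sim$truth$shares_true - 100 * sc$shares)), 1)
  # mean total load within 2% of the log-normal expectation
  expected_total <- sc$total_median * exp(sc$total_sigma^2 / 2)
  expect_equal(mean(rowSums(sim$truth$g_true)), expected_total,
               tolerance = 0.02)
})

test_that("outlier injection flags match the perturbed cells", {
  sc <- default_scenario(n = 50, seed = 21, outlier_frac = 0.1)
  sim <- simulate_scenario(sc)
  expect_equal(length(sim$truth$outlier_samples), 5L)
  expect_true(all(rowSums(sim$truth$outlier_mask) > 0) ||
                all(rowSums(sim$truth$outlier_mask[sim$truth$outlier_samples, ]) > 0))
  # unmasked cells agree with the noise-only surface reconstruction
  clean <- sim$table$values / ifelse(sim$truth$outlier_mask,
                                     sc$outlier_multiplier, 1)
  expect_true(all(clean > 0))
})

test_that("recovery scoring is exact on identity and permuted estimates", {
  sim <- simulate_scenario(default_scenario(n = 20, seed = 2))
  tr <- sim$truth
  rec <- score_recovery(tr$f_true, tr$shares_true, tr)
  expect_equal(rec$cosine, rep(1, 4), tolerance = 1e-12)
  expect_equal(rec$max_share_error, 0, tolerance = 1e-9)
  perm <- c(3, 1, 4, 2)
  rec2 <- score_recovery(tr$f_true[perm, ], tr$shares_true[perm], tr)
  expect_equal(rec2$assignment, order(perm))
  expect_equal(rec2$cosine, rep(1, 4), tolerance = 1e-12)
  expect_equal(rec2$max_share_error, 0, tolerance = 1e-9)
})

test_that("assignment agrees with the brute-force permutation oracle", {
  set.seed(17)
  sim <- simulate_scenario(default_scenario(n = 20, seed = 3))
  for (rep in 1:5) {
    Fe <- matrix(stats::runif(24), 4, 6)
    rec <- score_recovery(Fe, rep(25, 4), sim$truth)
    oracle <- oracle_best_assignment(sim$truth$f_true, Fe)
    expect_equal(rec$assignment, oracle$perm)
    expect_equal(sum(rec$cosine), oracle$total)
  }
})

test_that("recovery metrics are symmetric under joint permutation", {
  sim <- simulate_scenario(default_scenario(n = 20, seed = 4))
  tr <- sim$truth
  set.seed(6)
  Fe <- tr$f_true * matrix(stats::runif(24, 0.8, 1.2), 4, 6)
  she <- c(30, 28, 22, 20)
  rec <- score_recovery(Fe, she, tr)
  perm <- c(2, 4, 1, 3)
  tr2 <- tr
  tr2$f_true <- tr$f_true[perm, ]
  tr2$shares_true <- tr$shares_true[perm]
  rec2 <- score_recovery(Fe[perm, ], she[perm], tr2)
  expect_equal(sort(rec$cosine), sort(rec2$cosine))
  expect_equal(sort(rec$share_error), sort(rec2$share_error))
})
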