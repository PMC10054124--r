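test_that("uncertainty follows the error-fraction model", {
  X <- cbind(Cu = c(10, 5), Zn = c(10, 5))
  tab <- conc_table(X)
  refs <- ref_table(data.frame(element = c("Cu", "Zn"),
                               background = c(1, 1), screening = c(1, 1),
                               toxicity = c(1, 1),
                               mdl = c(1, 0), theta = c(0, 0.2)))
  U <- uncertainty(tab, refs)
  expect_equal(unname(U[, "Cu"]), c(1, 1))            # theta 0, MDL 1
  expect_equal(unname(U[1, "Zn"]), 2)                 # 0.2 * 10, MDL 0
  expect_equal(unname(U[2, "Zn"]), 1)                 # 0.2 * 5
  refs2 <- ref_table(data.frame(element = c("Cu", "Zn"),
                                background = c(1, 1), screening = c(1, 1),
                                toxicity = c(1, 1),
                                mdl = c(1, NA), theta = c(0.1, NA)))
  U2 <- uncertainty(tab, refs2)
  expect_equal(unname(U2[1, "Cu"]), sqrt((0.1 * 10)^2 + 1))
  # defaults fill the NA element: theta 0.10, MDL 5% of the element mean
  expect_equal(unname(U2[1, "Zn"]), sqrt(1^2 + (0.05 * 7.5)^2))
})

test_that("signal-to-noise uses the positive excess over uncertainty", {
  X <- cbind(a = c(2, 2), b = c(6, 6)); U <- X
  expect_equal(signal_to_noise(X, U)$sn, c(0, 0))
  expect_equal(signal_to_noise(3 * U, U)$sn, c(2, 2))
  X2 <- matrix(c(1, 3), 2, 1); U2 <- matrix(1, 2, 1)
  expect_equal(signal_to_noise(X2, U2)$sn, 1)   # mean of {0, 2}
  expect_equal(signal_to_noise(3 * U, U)$category, c("weak", "weak"))
  expect_equal(signal_to_noise(4 * U, U)$category, c("strong", "strong"))
})

test_that("q_values match naive summation and the Huber form", {
  set.seed(3)
  X <- matrix(stats::rlnorm(20), 5, 4)
  G <- matrix(stats::runif(10), 5, 2)
  F <- matrix(stats::runif(8), 2, 4)
  U <- matrix(stats::runif(20, 0.5, 2), 5, 4)
  qv <- q_values(X, U, G, F, robust_alpha = 4)
  q_naive <- 0
  for (i in 1:5) for (j in 1:4)
    q_naive <- q_naive + ((X[i, j] - sum(G[i, ] * F[, j])) / U[i, j])^2
  expect_equal(qv$q_true, q_naive)
  # all residuals within the cutoff: robust equals true
  Xs <- G %*% F + 0.1 * U
  qv2 <- q_values(Xs, U, G, F, robust_alpha = 4)
  expect_equal(qv2$q_robust, qv2$q_true)
  # a single residual at 2*alpha contributes 3 alpha^2 instead of 4 alpha^2
  a <- 4
  X1 <- matrix(2 * a, 1, 1); U1 <- matrix(1, 1, 1)
  qv3 <- q_values(X1, U1, matrix(0, 1, 1), matrix(0, 1, 1), robust_alpha = a)
  expect_equal(qv3$q_true, 4 * a^2)
  expect_equal(qv3$q_robust, 3 * a^2)
  # scaled residuals all equal to 1 give Q = n*m
  qv4 <- q_values(G %*% F + U, U, G, F)
  expect_equal(qv4$q_true, 20)
})

test_that("an exact factorization is recovered to near-zero Q", {
  set.seed(6)
  G0 <- matrix(stats::runif(30, 0.5, 2), 15, 2)
  F0 <- matrix(stats::runif(8, 0.1, 1), 2, 4)
  X <- G0 %*% F0
  U <- matrix(1, 15, 4)
  fit <- suppressWarnings(pmf_fit(X, U, 2, pmf_config(n_runs = 5, seed = 2,
                                                      max_iter = 5000)))
  expect_lt(fit$q_true, 1e-6 * 15 * 4)
  expect_true(all(fit$g >= 0))
  expect_true(all(fit$f >= 0))
  expect_equal(unname(rowSums(fit$f)), c(1, 1))
  expect_lte(fit$q_robust, fit$q_true)
})

test_that("Q never increases within a run across many seeds", {
  set.seed(77)
  X <- matrix(stats::rlnorm(60, 1), 15, 4)
  U <- 0.1 * X + 0.05
  for (s in 1:10) {
    fit <- suppressWarnings(
      pmf_fit(X, U, 2, pmf_config(n_runs = 1, seed = s, max_iter = 300)))
    expect_true(all(diff(fit$q_trace) <= 1e-8 * fit$q_trace[-length(fit$q_trace)] + 1e-12))
  }
})

test_that("rank-1 weighted factorization matches a generic optimizer", {
  set.seed(4)
  X <- matrix(stats::rlnorm(9, 1), 3, 3)
  U <- matrix(1, 3, 3)
  fit <- suppressWarnings(pmf_fit(X, U, 1, pmf_config(n_runs = 10, seed = 5,
                                                      max_iter = 10000,
                                                      tol = 1e-14)))
  # oracle: direct numeric minimization over the 6 free parameters
  obj <- function(par) {
    g <- par[1:3]; f <- par[4:6]
    sum((X - outer(g, f))^2)
  }
  best <- Inf
  for (s in 1:5) {
    set.seed(s)
    o <- stats::optim(stats::runif(6, 0.1, 2), obj, method = "L-BFGS-B",
                      lower = 1e-9, control = list(maxit = 500))
    best <- min(best, o$value)
  }
  expect_equal(fit$q_true, best, tolerance = 1e-6)
})

test_that("fits are deterministic given the seed", {
  sim <- simulate_scenario(default_scenario(n = 40, seed = 10))
  U <- uncertainty(sim$table)
  f1 <- suppressWarnings(pmf_fit(sim$table, U, 3, pmf_config(n_runs = 3, seed = 9)))
  f2 <- suppressWarnings(pmf_fit(sim$table, U, 3, pmf_config(n_runs = 3, seed = 9)))
  expect_identical(f1$g, f2$g)
  expect_identical(f1$f, f2$f)
})

test_that("species_fit matches the closed-form Pearson on a toy case", {
  G <- matrix(c(1, 2, 3, 4), 4, 1)
  F <- matrix(c(1, 2), 1, 2)
  X <- G %*% F
  expect_equal(unname(species_fit(X, G, F)), c(1, 1))
  # reconstruction equal to the column mean carries no association
  Xobs <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  Gm <- matrix(1, 4, 1); Fm <- matrix(c(2.5, 5), 1, 2)
  expect_equal(unname(species_fit(Xobs, Gm, Fm)), c(0, 0))
  # toy numeric check against cor()
  set.seed(8)
  Xn <- X + matrix(stats::runif(8), 4, 2)
  r2 <- species_fit(Xn, G, F)
  expect_equal(unname(r2[1]), stats::cor(Xn[, 1], (G %*% F)[, 1])^2)
})

test_that("outlier removal deletes injected outliers and helps profiles", {
  sim <- simulate_scenario(default_scenario(n = 80, seed = 31,
                                            outlier_frac = 5 / 80))
  U <- uncertainty(sim$table)
  cfg <- pmf_config(n_runs = 8, seed = 42, max_removals = 10)
  before <- suppressWarnings(pmf_fit(sim$table, U, 4, cfg))
  res <- suppressWarnings(remove_outliers(sim$table, k = 4, config = cfg, U = U))
  expect_gt(length(res$fit$removed_samples), 0)
  hits <- mean(res$fit$removed_samples %in% sim$truth$outlier_samples)
  expect_gt(hits, 0.5)   # removals concentrate on true outliers
  rec_b <- score_recovery(before$f, pmf_shares(before), sim$truth)
  rec_a <- score_recovery(res$fit$f, pmf_shares(res$fit), sim$truth)
  expect_gt(rec_a$mean_cosine, rec_b$mean_cosine - 0.01)
  # clean data: no removals at the default tolerance
  simc <- simulate_scenario(default_scenario(n = 60, seed = 13))
  Uc <- uncertainty(simc$table)
  resc <- suppressWarnings(remove_outliers(simc$table, k = 4,
                                           config = pmf_config(n_runs = 5, seed = 3),
                                           U = Uc))
  expect_equal(length(resc$fit$removed_samples), 0L)
  # max_removals = 0 returns the full-data fit unchanged
  res0 <- suppressWarnings(remove_outliers(sim$table, k = 4,
                                           config = pmf_config(n_runs = 8, seed = 42,
                                                               max_removals = 0),
                                           U = U))
  expect_identical(res0$fit$g, before$g)
})

test_that("factor scan shows the rank-4 elbow and the Qexpected formula", {
  expect_equal(q_expected(101, 6, 4), 178)
  sim <- simulate_scenario(default_scenario(n = 60, seed = 19))
  U <- uncertainty(sim$table)
  cfg <- pmf_config(k_min = 2, k_max = 5, n_runs = 5, seed = 7)
  scan <- suppressWarnings(scan_factors(sim$table, U, cfg))
  expect_equal(scan$k, 2:5)
  expect_true(all(diff(scan$q_true) < 0))
  # the steepest drop lands on the true rank
  ratios <- scan$q_true[-nrow(scan)] / scan$q_true[-1]
  expect_gt(scan$q_true[scan$k == 3] / scan$q_true[scan$k == 4],
            scan$q_true[scan$k == 4] / scan$q_true[scan$k == 5])
  expect_equal(scan$k[scan$elbow], 4)
  expect_equal(scan$q_expected, 60 * 6 - (2:5) * 66)
})
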