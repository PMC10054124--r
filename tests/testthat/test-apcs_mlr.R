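test_that("standardization matches hand arithmetic and is idempotent", {
  tab <- tiny_table()  # Cu = {1,2,3}
  std <- standardize(tab)
  expect_equal(unname(std$z[, "Cu"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(std$z)), c(0, 0))
  expect_equal(unname(apply(std$z, 2, sd)), c(1, 1))
  # a sample equal to the column means standardizes to the zero row
  X <- rbind(c(10, 100), c(30, 300), c(20, 200))
  colnames(X) <- c("Cu", "Zn")
  std2 <- standardize(conc_table(X))
  expect_equal(unname(std2$z[3, ]), c(0, 0))
  # standardizing an already standardized matrix changes nothing
  z2 <- scale(std$z)[, ]
  expect_equal(unname(z2), unname(std$z))
  expect_error(standardize(conc_table(cbind(A = c(1, 1, 1), B = 1:3))),
               "zero-variance")
})

test_that("retained components agree with a direct eigendecomposition", {
  # 4 independent drivers spread over 8 elements; eigenvalue rule keeps 4
  set.seed(5)
  n <- 200
  drivers <- matrix(rnorm(n * 4), n, 4)
  X <- exp(drivers[, rep(1:4, each = 2)] * 0.5 +
             matrix(rnorm(n * 8, sd = 0.05), n, 8) + 3)
  colnames(X) <- paste0("E", 1:8)
  std <- standardize(conc_table(X))
  comp <- fit_components(std$z, retention = "eigen", rotate = "none")
  expect_equal(comp$p, 4L)
  eig <- eigen(cor(std$z), symmetric = TRUE)
  expect_equal(abs(comp$loadings),
               abs(eig$vectors[, 1:4] %*% diag(sqrt(eig$values[1:4]))),
               ignore_attr = TRUE)
  expect_equal(comp$explained, 100 * eig$values[1:4] / 8, ignore_attr = TRUE)
  # two perfectly correlated variables: one component carries everything
  z2 <- scale(cbind(a = 1:10, b = 2 * (1:10) + 3))[, ]
  c2 <- fit_components(z2, retention = 1, rotate = "none")
  expect_equal(unname(c2$explained), 100)
})

test_that("absolute scores equal the append-zero-row oracle", {
  set.seed(9)
  X <- matrix(stats::rlnorm(10, meanlog = 2), 5, 2,
              dimnames = list(NULL, c("Cu", "Zn")))
  tab <- conc_table(X)
  std <- standardize(tab)
  comp <- fit_components(std$z, retention = 1, rotate = "none")
  apcs <- absolute_scores(comp, std$z, std$means, std$sds)
  # oracle: explicitly append the zero-concentration row, standardize it
  # with the sample means/sds, score all rows, subtract the zero row score
  z_aug <- sweep(sweep(rbind(X, 0), 2, std$means, "-"), 2, std$sds, "/")
  scores_aug <- z_aug %*% comp$score_coef
  oracle <- sweep(scores_aug[1:5, , drop = FALSE], 2,
                  scores_aug[6, ], "-")
  expect_lt(max(abs(apcs - oracle)), 1e-10)
  # the zero-concentration sample itself scores to an all-zero APCS row
  z0 <- matrix(-std$means / std$sds, 1)
  apcs0 <- absolute_scores(comp, z0, std$means, std$sds)
  expect_equal(unname(apcs0[1, ]), rep(0, comp$p))
})

test_that("noise-free regression recovers coefficients with r2 = 1", {
  set.seed(21)
  apcs <- matrix(stats::runif(60, 0, 5), 20, 3)
  b0 <- c(10, 20)
  b <- matrix(c(2, 1, 0.5, 3, 0.2, 1.5), nrow = 3)
  X <- sweep(apcs %*% b, 2, b0, "+")
  colnames(X) <- c("Cu", "Zn")
  res <- regress_and_apportion(apcs, conc_table(X))
  expect_equal(unname(res$r2), c(1, 1))
  expect_equal(unname(res$intercepts), b0)
  expect_equal(unname(res$coefficients), unname(t(b)))
  expect_equal(unname(colSums(res$percent)), c(100, 100))
})

test_that("single-factor regression matches the normal-equations oracle", {
  set.seed(2)
  a <- matrix(stats::runif(6, 1, 4), 6, 1)
  y <- 5 + 2 * a[, 1] + stats::rnorm(6, sd = 0.1)
  X <- cbind(Cu = y, Zn = y * 2 + 1)
  res <- regress_and_apportion(a, conc_table(X))
  slope <- sum((a - mean(a)) * (y - mean(y))) / sum((a - mean(a))^2)
  expect_equal(res$coefficients["Cu", 1], slope)
  expect_equal(unname(res$intercepts["Cu"]), mean(y) - slope * mean(a))
})

test_that("fit quality is invariant to factor relabeling", {
  sim <- simulate_scenario(default_scenario(n = 60, seed = 4))
  std <- standardize(sim$table)
  comp <- fit_components(std$z, retention = 4, rotate = "varimax")
  apcs <- absolute_scores(comp, std$z, std$means, std$sds)
  r2a <- regress_and_apportion(apcs, sim$table)$r2
  r2b <- regress_and_apportion(apcs[, c(3, 1, 4, 2)], sim$table)$r2
  expect_equal(r2a, r2b)
})

test_that("all components with no rotation reconstruct Z exactly", {
  sim <- simulate_scenario(default_scenario(n = 40, seed = 8))
  std <- standardize(sim$table)
  comp <- fit_components(std$z, retention = ncol(std$z), rotate = "none")
  scores <- std$z %*% comp$score_coef
  expect_equal(scores %*% t(comp$loadings), std$z, ignore_attr = TRUE)
})

test_that("percent tables renormalize with an unidentified remainder", {
  sim <- simulate_scenario(default_scenario(seed = 14))
  res <- apcs_mlr(sim$table, retention = 4)
  expect_equal(unname(colSums(res$percent)), rep(100, 6))
  expect_equal(sum(res$shares), 100)
  expect_true(all(res$percent >= 0))
  expect_true("unidentified" %in% names(res$shares))
})
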