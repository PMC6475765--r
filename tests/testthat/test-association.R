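test_that("partial correlations match the residualize-then-correlate oracle", {
  set.seed(51)
  n <- 30
  X <- matrix(rnorm(n * 5), n, 5)
  Y <- matrix(rnorm(n * 4), n, 4)
  cov <- cbind(age = runif(n, 50, 80), sex = rbinom(n, 1, 0.5))
  res <- partial_correlation_matrix(X, Y, cov)
  expect_equal(res$r, oracle_partial_cor(X, Y, cov),
               tolerance = 1e-12, ignore_attr = TRUE)
  # no covariates: plain Pearson correlation
  res0 <- partial_correlation_matrix(X, Y)
  expect_equal(res0$r, stats::cor(X, Y), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(res$r) <= 1 + 1e-12))
})

test_that("self- and anti-correlation diagonals are exact", {
  set.seed(52)
  X <- matrix(rnorm(20 * 6), 20, 6)
  expect_equal(diag(partial_correlation_matrix(X, X)$r), rep(1, 6))
  expect_equal(diag(partial_correlation_matrix(X, -X)$r), rep(-1, 6))
})

test_that("constant columns are flagged NA, not silently zeroed", {
  set.seed(53)
  X <- matrix(rnorm(20 * 3), 20, 3)
  Y <- cbind(rnorm(20), rep(2, 20))
  expect_warning(res <- partial_correlation_matrix(X, Y), "constant")
  expect_true(all(is.na(res$r[, 2])))
  expect_false(anyNA(res$r[, 1]))
})

test_that("too few subjects for the covariate set is an error", {
  X <- matrix(rnorm(4 * 2), 4, 2)
  expect_error(partial_correlation_matrix(X, X, cbind(rnorm(4), rnorm(4))),
               "k \\+ 3")
})

test_that("maxT adjusted p-values have the permutation floor and", {
  # monotonicity over unadjusted p-values
  set.seed(54)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4)
  Y <- cbind(X[, 2], matrix(rnorm(n * 2), n, 2))  # one planted signal
  res <- permutation_fwe(X, Y, n_permutations = 200L, seed = 5L,
                         return_unadjusted = TRUE)
  expect_equal(res$p_adjusted[2, 1], 1 / 201)  # attainable minimum
  expect_true(all(res$p_adjusted >= res$p_unadjusted))
  expect_true(all(res$p_adjusted >= 1 / 201 & res$p_adjusted <= 1))
  expect_error(permutation_fwe(X, Y, n_permutations = 50L), ">= 100")
  expect_error(permutation_fwe(X[1:2, ], Y[1:2, ],
                               n_permutations = 100L), "too few")
})

test_that("maxT permutation distribution is deterministic in the seed", {
  set.seed(55)
  X <- matrix(rnorm(25 * 3), 25, 3)
  Y <- matrix(rnorm(25 * 3), 25, 3)
  a <- permutation_fwe(X, Y, n_permutations = 150L, seed = 9L)
  b <- permutation_fwe(X, Y, n_permutations = 150L, seed = 9L)
  expect_identical(a$p_adjusted, b$p_adjusted)
})

test_that("unpenalized SCCA equals the leading singular vectors", {
  set.seed(56)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6)
  Y <- matrix(rnorm(n * 5), n, 5)
  fit <- scca(X, Y, penalty_x = 1, penalty_y = 1, n_components = 1L)
  Z <- crossprod(scale(X), scale(Y)) / (n - 1)
  sv <- svd(Z, nu = 1, nv = 1)
  u <- sv$u[, 1]; v <- sv$v[, 1]
  if (sign(u[which.max(abs(u))]) < 0) { u <- -u; v <- -v }
  expect_equal(unname(fit[[1]]$u), u, tolerance = 1e-8)
  expect_equal(unname(fit[[1]]$v), v, tolerance = 1e-8)
  expect_equal(fit[[1]]$d, sv$d[1], tolerance = 1e-8)
  # reported correlation equals cor of the projected scores
  expect_equal(fit[[1]]$correlation,
               stats::cor(scale(X) %*% u, scale(Y) %*% v)[1],
               tolerance = 1e-8)
})

test_that("SCCA recovers a sparse rank-1 cross-covariance exactly", {
  a <- c(1, -2, 0, 0, 0, 0)
  b <- c(0, 0, 3, 1, 0)
  n <- 500
  set.seed(57)
  s <- rnorm(n)
  X <- s %*% t(a) + matrix(rnorm(n * 6, sd = 1e-3), n, 6)
  Y <- s %*% t(b) + matrix(rnorm(n * 5, sd = 1e-3), n, 5)
  fit <- scca(X, Y, penalty_x = 0.9, penalty_y = 0.9)
  u <- fit[[1]]$u
  v <- fit[[1]]$v
  # support recovery: dominant weights on the planted coordinates
  expect_gt(sum(abs(u[1:2])), 0.99)
  expect_gt(sum(abs(v[3:4])), 0.99)
})

test_that("SCCA constraints hold post hoc and sparsity is monotone", {
  set.seed(58)
  n <- 50
  X <- matrix(rnorm(n * 12), n, 12)
  Y <- matrix(rnorm(n * 12), n, 12)
  nz <- c()
  for (pen in c(1, 0.8, 0.6, 0.45, 0.3)) {
    fit <- scca(X, Y, penalty_x = pen, penalty_y = pen)[[1]]
    expect_lte(sum(fit$u^2), 1 + 1e-8)
    expect_lte(sum(fit$v^2), 1 + 1e-8)
    expect_lte(sum(abs(fit$u)), pen * sqrt(12) + 1e-8)
    expect_lte(sum(abs(fit$v)), pen * sqrt(12) + 1e-8)
    expect_gt(sum(fit$u != 0), 0)
    expect_gt(sum(fit$v != 0), 0)
    nz <- c(nz, sum(fit$u != 0))
  }
  # decreasing penalty never increases the number of nonzero weights
  expect_true(all(diff(nz) <= 0))
  # penalties below the feasibility floor 1/sqrt(p) are rejected
  expect_error(scca(X, Y, penalty_x = 0.2, penalty_y = 0.2),
               "feasibility floor")
  # sign convention: largest-|u| entry is positive
  fit <- scca(X, Y, penalty_x = 0.4, penalty_y = 0.4)[[1]]
  expect_gt(fit$u[which.max(abs(fit$u))], 0)
})

test_that("deflation yields a second component orthogonal in effect", {
  set.seed(59)
  n <- 200
  s1 <- rnorm(n); s2 <- rnorm(n)
  X <- cbind(s1, s1, s2, s2) + matrix(rnorm(n * 4, sd = 0.1), n, 4)
  Y <- cbind(s1, s2, rnorm(n)) + matrix(rnorm(n * 3, sd = 0.1), n, 3)
  fit <- scca(X, Y, penalty_x = 1, penalty_y = 1, n_components = 2L)
  expect_length(fit, 2L)
  expect_gt(abs(fit[[1]]$correlation), abs(fit[[2]]$correlation) - 0.1)
  expect_gt(abs(fit[[2]]$correlation), 0.5)
})

test_that("canonical weight tables key every ROI and component", {
  set.seed(60)
  X <- matrix(rnorm(40 * 3), 40, 3)
  Y <- matrix(rnorm(40 * 4), 40, 4)
  fit <- scca(X, Y, penalty_x = 1, penalty_y = 1, n_components = 2L)
  tab <- canonical_weight_table(fit, roi_ids_x = paste0("x", 1:3),
                                roi_ids_y = paste0("y", 1:4))
  expect_identical(nrow(tab), 2L * (3L + 4L))
  expect_setequal(unique(tab$dataset), c("x", "y"))
})
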