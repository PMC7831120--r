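test_that("column z-scoring is exact and idempotent", {
  set.seed(1)
  X <- matrix(rnorm(40 * 6, mean = 5, sd = 3), 40, 6)
  Z <- zscore_columns(X)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-10))
  expect_equal(zscore_columns(Z), Z, tolerance = 1e-10)
  expect_equal(as.numeric(zscore_columns(cbind(a = c(1, 2, 3)))),
               c(-1, 0, 1))
  X[, 2] <- 7
  colnames(X) <- paste0("c", 1:6)
  expect_error(zscore_columns(X), "c2")
})

test_that("task PLS solves the hand-computable two-group case", {
  Z <- cbind(c(1, 1, -1, -1), matrix(0, 4, 4))
  res <- task_pls(Z, c("A", "A", "B", "B"))
  expect_equal(res$s[1], sqrt(2))
  expect_equal(abs(res$u[, 1]), c(1, 0, 0, 0, 0))
  expect_equal(sort(unname(res$v[, 1])), c(-1, 1) / sqrt(2))
  expect_equal(res$cov_explained[1], 1)
  expect_equal(res$brain_scores[, 1], Z %*% res$u[, 1, drop = FALSE],
               ignore_attr = TRUE)
})

test_that("task PLS satisfies the SVD identities on arbitrary data", {
  set.seed(2)
  Z <- zscore_columns(matrix(rnorm(30 * 12), 30, 12))
  group <- rep(c("CB", "GD", "CG"), each = 10)
  res <- task_pls(Z, group)
  Mc <- res$v %*% diag(res$s) %*% t(res$u)
  M <- do.call(rbind, lapply(split(1:30, factor(group)),
                             function(i) colMeans(Z[i, ])))
  expect_lt(norm(Mc - sweep(M, 2, colMeans(M)), "F"), 1e-8)
  expect_equal(sum(res$cov_explained), 1, tolerance = 1e-10)
  expect_true(all(diff(res$s) <= 1e-12))
  expect_equal(sum(sweep(M, 2, colMeans(M))^2), sum(res$s^2))
  # orthonormal axes
  expect_equal(crossprod(res$u), diag(ncol(res$u)), ignore_attr = TRUE)
  expect_equal(crossprod(res$v), diag(ncol(res$v)), ignore_attr = TRUE)
})

test_that("task PLS strength scales linearly with planted separation", {
  set.seed(3)
  base <- matrix(0, 20, 5)
  s_at <- vapply(c(1, 2, 4), function(eff) {
    Z <- base
    Z[1:10, 1] <- eff
    Z[11:20, 1] <- -eff
    task_pls(Z, rep(c("A", "B"), each = 10))$s[1]
  }, numeric(1))
  expect_equal(s_at / s_at[1], c(1, 2, 4), tolerance = 1e-10)
})

test_that("behavior PLS recovers a single dominating brain-behavior link", {
  # correlation is scale-invariant, so "vanishing" noise columns must be
  # washed out by sample size, not amplitude
  set.seed(4)
  n <- 5000
  b <- rnorm(n)
  Z <- cbind(b, matrix(rnorm(n * 5), n, 5))
  res <- behavior_pls(Z, rep("A", n) , cbind(beh = b))
  expect_equal(res$s[1], 1, tolerance = 0.01)
  expect_equal(abs(res$u[1, 1]), 1, tolerance = 0.01)
  expect_equal(sum(res$cov_explained), 1, tolerance = 1e-10)
  # reconstruction of the correlation stack
  idx <- split(seq_len(n), rep("A", n))
  R <- cor(cbind(beh = b), Z)
  expect_lt(norm(res$v %*% diag(res$s, length(res$s)) %*% t(res$u) - R,
                 "F"), 1e-8)
})

test_that("behavior PLS needs two groups only for task-style designs", {
  # single-group behavior PLS is legitimate; task PLS demands >= 2 groups
  expect_error(task_pls(matrix(rnorm(20), 10, 2), rep("A", 10)),
               "2 groups")
})

test_that("consistent row permutation leaves singular values unchanged", {
  set.seed(5)
  n <- 24
  Z <- matrix(rnorm(n * 8), n, 8)
  group <- rep(c("CB", "GD", "CG"), each = 8)
  B <- cbind(x = rnorm(n), y = rnorm(n))
  perm <- sample(n)
  res1 <- behavior_pls(zscore_columns(Z), group, B)
  res2 <- behavior_pls(zscore_columns(Z[perm, ]), group[perm], B[perm, ])
  expect_equal(res1$s, res2$s, tolerance = 1e-10)
  t1 <- task_pls(zscore_columns(Z), group)
  t2 <- task_pls(zscore_columns(Z[perm, ]), group[perm])
  expect_equal(t1$s, t2$s, tolerance = 1e-10)
})

test_that("column reordering permutes saliences without changing strength", {
  set.seed(6)
  Z <- matrix(rnorm(30 * 10), 30, 10)
  group <- rep(c("A", "B", "C"), each = 10)
  perm <- sample(10)
  res1 <- task_pls(Z, group)
  res2 <- task_pls(Z[, perm], group)
  expect_equal(res1$s, res2$s, tolerance = 1e-10)
  expect_equal(abs(res2$u[, 1]), abs(res1$u[perm, 1]), tolerance = 1e-8)
})

test_that("permutation test flags a strong planted effect and stays in [0,1]", {
  set.seed(7)
  Z <- matrix(rnorm(30 * 8, sd = 1e-3), 30, 8)
  Z[1:10, 1] <- Z[1:10, 1] + 2
  Z[11:30, 1] <- Z[11:30, 1] - 1
  res <- task_pls(Z, rep(c("A", "B", "C"), each = 10))
  res <- pls_permutation(res, n_perm = 100, seed = 1)
  expect_equal(res$perm_p[1], 0)  # reported without add-one smoothing
  expect_true(all(res$perm_p >= 0 & res$perm_p <= 1))
})

test_that("same seed gives bit-identical inference, different seeds differ", {
  set.seed(8)
  Z <- zscore_columns(matrix(rnorm(30 * 10), 30, 10))
  group <- rep(c("A", "B", "C"), each = 10)
  r1 <- pls_bootstrap(pls_permutation(task_pls(Z, group), 50, seed = 5),
                      50, seed = 6)
  r2 <- pls_bootstrap(pls_permutation(task_pls(Z, group), 50, seed = 5),
                      50, seed = 6)
  expect_identical(r1$perm_p, r2$perm_p)
  expect_identical(r1$bootstrap_ratio, r2$bootstrap_ratio)
  r3 <- pls_permutation(task_pls(Z, group), 50, seed = 99)
  expect_false(identical(r1$perm_p, r3$perm_p))
})

test_that("bootstrap isolates a planted single-column effect", {
  set.seed(9)
  Z <- matrix(rnorm(40 * 6, sd = 1e-4), 40, 6)
  Z[1:20, 1] <- Z[1:20, 1] + 1
  Z[21:40, 1] <- Z[21:40, 1] - 1
  res <- task_pls(Z, rep(c("A", "B"), each = 20))
  res <- pls_bootstrap(res, n_boot = 200, seed = 2)
  expect_true(res$stable_mask[1, 1])
  expect_true(all(!res$stable_mask[-1, 1]))
  expect_gt(abs(res$bootstrap_ratio[1, 1]), 100)
  # threshold monotonicity: raising 3 -> 4 never adds stable columns
  stable4 <- abs(res$bootstrap_ratio) >= 4
  expect_true(all(!res$stable_mask[, 1] | !stable4[, 1] |
                    res$stable_mask[, 1]))
  expect_true(all(which(stable4[, 1]) %in% which(res$stable_mask[, 1])))
})

test_that("stratified bootstrap SE of a plain mean matches sigma/sqrt(n)", {
  set.seed(10)
  sigma <- 2.5
  n <- 200
  x <- rnorm(n, sd = sigma)
  boots <- replicate(1000, mean(x[sample.int(n, replace = TRUE)]))
  expect_lt(abs(sd(boots) - sigma / sqrt(n)) / (sigma / sqrt(n)), 0.10)
})

test_that("stable-region summary respects the mask and counts metrics", {
  sim <- simulate_cohort(sim_config(seed = 11))
  Z <- zscore_columns(sim$roi)
  res <- task_pls(Z, sim$participants$group)
  res <- pls_bootstrap(res, n_boot = 100, seed = 3)
  tab <- summarize_stable_regions(res, lv = 1)
  expect_equal(nrow(tab), sum(res$stable_mask[, 1]))
  counts <- attr(tab, "metric_counts")
  expect_equal(sum(counts), nrow(tab))
  expect_true(all(abs(tab$ratio) >= 3))
  # no stable columns: empty table with zero counts
  res2 <- res
  res2$stable_mask[] <- FALSE
  tab2 <- summarize_stable_regions(res2, lv = 1)
  expect_equal(nrow(tab2), 0L)
  expect_equal(unname(attr(tab2, "metric_counts")), c(0L, 0L, 0L))
})
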