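test_that("dense-penalty sparse CCA matches the classical CCA oracle", {
  set.seed(5)
  n <- 60
  X <- qr.Q(qr(scale(matrix(rnorm(n * 3), n))))
  Y0 <- scale(matrix(rnorm(n * 3), n))
  Y0[, 1] <- Y0[, 1] + 2 * X[, 1]
  Y <- qr.Q(qr(scale(Y0)))
  # orthonormal within-block columns: the diagonal-covariance solution is
  # exactly classical CCA
  fit <- scca_fit(X, Y, 10, 10, n_dims = 2, seed = 1)
  cc <- stats::cancor(X, Y, xcenter = FALSE, ycenter = FALSE)
  expect_lt(abs(fit$cors[1] - cc$cor[1]), 1e-6)
  # l2 norm is 1 when the l1 penalty is inactive
  expect_equal(sum(fit$u[, 1]^2), 1, tolerance = 1e-9)
  expect_equal(sum(fit$v[, 1]^2), 1, tolerance = 1e-9)
})

test_that("weight vectors respect the l1/l2 constraints and deflation", {
  sim <- simulate_crossblock(100, 12, 10, c(4, 4), 0.7, seed = 2)
  fit <- scca_fit(sim$X, sim$Y, 2, 2, n_dims = 3, seed = 1)
  for (d in 1:3) {
    expect_lte(sum(abs(fit$u[, d])), 2 + 1e-6)
    expect_lte(sum(abs(fit$v[, d])), 2 + 1e-6)
    expect_lte(sum(fit$u[, d]^2), 1 + 1e-9)
  }
  expect_error(scca_fit(sim$X, sim$Y, 2, 2, n_dims = 5),
               class = "netdax_error_argument")
  Xz <- sim$X; Xz[, 3] <- 5
  expect_error(scca_fit(Xz, sim$Y, 2, 2), class = "netdax_error_degenerate")
})

test_that("planted sparse latent is recovered with sign-consistent supports", {
  sim <- simulate_crossblock(500, 20, 15, c(5, 5), 0.8, seed = 3)
  fit <- scca_fit(sim$X, sim$Y, 2.5, 2.5, n_dims = 1, seed = 2)
  u <- fit$u[, 1]
  v <- fit$v[, 1]
  expect_true(all(sim$truth$support_x %in% which(u != 0)))
  expect_true(all(sim$truth$support_y %in% which(v != 0)))
  # spurious mass <= 20%
  expect_lte(sum(abs(u[-sim$truth$support_x])) / sum(abs(u)), 0.2)
  expect_lte(sum(abs(v[-sim$truth$support_y])) / sum(abs(v)), 0.2)
  # sign-consistent within each block
  expect_true(all(sign(u[sim$truth$support_x]) == sign(u[sim$truth$support_x][1])))
  expect_true(all(sign(v[sim$truth$support_y]) == sign(v[sim$truth$support_y][1])))
  expect_gte(fit$cors[1], 0.7)
})

test_that("penalty selection lands on the planted support and is deterministic", {
  sim <- simulate_crossblock(300, 12, 10, c(4, 4), 0.8, seed = 4)
  sel <- select_penalties(sim$X, sim$Y, n_perm = 30, seed = 5)
  fit <- scca_fit(sim$X, sim$Y, sel$c_x, sel$c_y, seed = 5)
  expect_true(all(which(fit$u[, 1] != 0) %in% sim$truth$support_x))
  expect_true(all(which(fit$v[, 1] != 0) %in% sim$truth$support_y))
  sel2 <- select_penalties(sim$X, sim$Y, n_perm = 30, seed = 5)
  expect_identical(sel$table, sel2$table)
  # pure noise: selection completes and downstream p values behave like a
  # null (median over draws well away from significance; full calibration is
  # tested separately with fixed penalties)
  null_ps <- vapply(1:5, function(i) {
    null <- simulate_crossblock(120, 8, 8, c(3, 3), 0, seed = 100 + i)
    seln <- select_penalties(null$X, null$Y, n_perm = 30, seed = 7,
                             test_mode = TRUE)
    scca_permutation_test(null$X, null$Y, seln$c_x, seln$c_y,
                          n_perm = 199, seed = 8)$p
  }, numeric(1))
  expect_gte(stats::median(null_ps), 0.1)
  expect_error(select_penalties(sim$X, sim$Y, n_perm = 5),
               class = "netdax_error_argument")
})

test_that("permutation test is powerful on planted signal with bounded p", {
  sim <- simulate_crossblock(300, 12, 10, c(4, 4), 0.8, seed = 9)
  pt <- scca_permutation_test(sim$X, sim$Y, 2, 2, n_perm = 499, seed = 10)
  expect_lte(pt$p, 0.01)
  expect_gte(pt$p, 1 / 500)
})

test_that("subdomain pairwise sCCA applies BH-FDR over all pairs", {
  set.seed(11)
  n <- 150
  blocks <- list(
    integrity = matrix(rnorm(n * 5), n, 5,
                       dimnames = list(NULL, paste0("i", 1:5))),
    integration = matrix(rnorm(n * 5), n, 5,
                         dimnames = list(NULL, paste0("k", 1:5))),
    cognition = matrix(rnorm(n * 4), n, 4,
                       dimnames = list(NULL, paste0("c", 1:4))),
    clinical = matrix(rnorm(n * 4), n, 4,
                      dimnames = list(NULL, paste0("d", 1:4)))
  )
  # plant one associated pair: integrity <-> cognition
  z <- rnorm(n)
  blocks$integrity[, 1:2] <- z + matrix(rnorm(n * 2), n) * 0.4
  blocks$cognition[, 1:2] <- z + matrix(rnorm(n * 2), n) * 0.4
  out <- subdomain_scca(blocks, n_perm = 199, seed = 12, test_mode = TRUE)
  expect_equal(nrow(out), 6)
  planted <- out$block_a == "integrity" & out$block_b == "cognition"
  expect_true(out$significant[planted])
  expect_equal(out$p_adj, p.adjust(out$p, "BH"))
  # overlapping names across blocks are rejected
  bad <- blocks
  colnames(bad$clinical)[1] <- "i1"
  expect_error(subdomain_scca(bad), class = "netdax_error_argument")
})

test_that("cognition PC1 follows the stated conventions", {
  set.seed(13)
  # two perfectly correlated tests: PC1 explains everything
  t1 <- rnorm(80)
  perfect <- cbind(a = t1, b = 2 * t1 + 5)
  p1 <- cognition_pc1(perfect)
  expect_equal(p1$variance_explained, 1)
  # uncorrelated equal-variance tests: variance explained ~ 1/k
  k <- 5
  big <- matrix(rnorm(4000 * k), 4000, k)
  pk <- cognition_pc1(big)
  expect_lt(abs(pk$variance_explained - 1 / k), 0.02)
  # sign convention: positive mean loading
  expect_gte(mean(p1$loadings), 0)
  # column scaling after standardization changes nothing
  p2 <- cognition_pc1(sweep(perfect, 2, c(10, 0.1), "*"))
  expect_equal(abs(p1$scores$pc1), abs(p2$scores$pc1), tolerance = 1e-9)
  # missingness rules: > 30% missing drops the subject, less is imputed
  m <- cbind(perfect, c = rnorm(80), d = rnorm(80))
  m[1, ] <- NA
  m[2, 1] <- NA
  pm <- cognition_pc1(m)
  expect_equal(pm$dropped, 1)
  expect_false(2 %in% pm$dropped)
  expect_error(cognition_pc1(cbind(a = rep(1, 10), b = rep(2, 10))),
               class = "netdax_error_degenerate")
})
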