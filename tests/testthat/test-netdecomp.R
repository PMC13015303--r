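test_that("block bootstrap keeps frame membership, length, and autocorrelation", {
  g <- toy_geom(80, 8, 2)
  sim <- plant_networks_and_bold(g, 2, 0.2, 100, tr = 2, ar1 = 0.5, seed = 1)
  bb <- block_bootstrap(sim$ts, 20, 60, seed = 3)
  expect_equal(nrow(bb$data), 100)
  # every output frame is some original frame
  orig_keys <- apply(sim$ts$data, 1, function(r) paste(signif(r[1:5], 12), collapse = "|"))
  boot_keys <- apply(bb$data, 1, function(r) paste(signif(r[1:5], 12), collapse = "|"))
  expect_true(all(boot_keys %in% orig_keys))
  # a block as long as the scan reproduces the series
  ident <- block_bootstrap(sim$ts, 200, 200, seed = 5)
  expect_equal(ident$data, sim$ts$data)
  expect_error(block_bootstrap(sim$ts, 500, 600), class = "netdax_error_argument")
  expect_error(block_bootstrap(sim$ts, 1, 60), class = "netdax_error_argument")
  # autocorrelation preservation over resamples
  v <- which(g$gm_mask)[1]
  ac_orig <- stats::acf(sim$ts$data[, v], plot = FALSE, lag.max = 1)$acf[2]
  ac_boot <- vapply(1:200, function(b) {
    x <- block_bootstrap(sim$ts, 20, 60, seed = b)$data[, v]
    stats::acf(x, plot = FALSE, lag.max = 1)$acf[2]
  }, numeric(1))
  expect_lt(abs(mean(ac_boot) - ac_orig), 0.1)
})

test_that("sparse decomposition respects constraints and recovers rank-1 data", {
  set.seed(2)
  tc <- rnorm(60)
  map <- runif(30)
  X <- tc %o% map
  fit <- sparse_decompose(X, 1, sparsity = 1, seed = 1)
  expl <- 1 - sum((X - fit$dictionary %*% fit$coefficients)^2) / sum(X^2)
  expect_gte(expl, 0.99)
  expect_equal(unname(sqrt(colSums(fit$dictionary^2))), 1, tolerance = 1e-9)
  # per-vertex cardinality never exceeds the sparsity budget
  g <- toy_geom(200, 10, 3)
  sim <- plant_networks_and_bold(g, 3, 0.2, 80, seed = 4)
  fit3 <- sparse_decompose(sim$ts, 5, sparsity = 2, seed = 2)
  expect_lte(max(colSums(abs(fit3$coefficients) > 1e-8)), 2)
  # reconstruction error is non-increasing across iterations
  expect_true(all(diff(fit3$error) <= 1e-6 * max(fit3$error[1], 1)))
  expect_error(sparse_decompose(matrix(0, 20, 10), 3),
               class = "netdax_error_degenerate")
  expect_error(sparse_decompose(X, 100), class = "netdax_error_argument")
})

test_that("planted networks are recovered with high support Dice", {
  g <- toy_geom()
  sim <- plant_networks_and_bold(g, 3, 0.2, 150, snr = 4, seed = 6)
  fit <- sparse_decompose(sim$ts, 3, seed = 2)
  m <- netdax:::match_atoms(abs(fit$coefficients) > 1e-8, sim$truth$planted_supports)
  expect_true(all(m$dice >= 0.9))
})

test_that("model-order selection finds the planted order and reports the curve", {
  g <- toy_geom()
  sim <- plant_networks_and_bold(g, 3, 0, 150, snr = 5, seed = 2)
  K <- select_model_order(sim$ts, 2, 8, 1, seed = 1)
  expect_equal(as.integer(K), 3)
  curve <- attr(K, "criterion")
  expect_equal(curve$K, 2:8)
  expect_true(all(is.finite(curve$criterion)))
  # degenerate range returns immediately
  K1 <- select_model_order(sim$ts, 5, 5, seed = 1)
  expect_equal(as.integer(K1), 5)
  expect_error(select_model_order(sim$ts, 2, 200), class = "netdax_error_argument")
})

test_that("consensus clustering applies the reproducibility threshold", {
  set.seed(5)
  atoms <- matrix(rnorm(3 * 50), 3, 50)
  # B identical resamples: reproducibility 1 for all clusters
  boots <- replicate(10, atoms, simplify = FALSE)
  nets <- consensus_cluster(boots, 3, reproducibility_threshold = 0.5, seed = 1)
  expect_equal(nrow(nets$loadings), 3)
  expect_equal(nets$reproducibility, rep(1, 3))
  # an atom present in 1 of 10 resamples is dropped at threshold 0.5
  rare <- rnorm(50) * 10
  boots2 <- boots
  boots2[[1]] <- rbind(atoms, rare)
  nets2 <- consensus_cluster(boots2, 4, reproducibility_threshold = 0.5, seed = 1)
  expect_equal(nrow(nets2$loadings), 3)
  expect_error(consensus_cluster(list(), 3), class = "netdax_error_argument")
})

test_that("end-to-end network estimation is deterministic and bounded by K", {
  g <- toy_geom(200, 10, 3)
  sim <- plant_networks_and_bold(g, 3, 0.2, 100, seed = 4)
  cfg <- decomp_config(k_min = 3, k_max = 3, n_boot = 6, n_iter = 8)
  n1 <- estimate_networks(sim$ts, cfg, seed = 11)
  n2 <- estimate_networks(sim$ts, cfg, seed = 11)
  expect_identical(n1$loadings, n2$loadings)
  expect_identical(n1$reproducibility, n2$reproducibility)
  expect_lte(nrow(n1$loadings), 3)
  expect_true(all(n1$reproducibility >= 0 & n1$reproducibility <= 1))
  # supports equal thresholded loadings
  expect_identical(n1$supports, abs(n1$loadings) > n1$epsilon)
})

test_that("noise atoms are flagged by gray-matter mass", {
  g <- toy_geom(200, 10, 3)
  inside <- matrix(0, 1, 200); inside[1, which(g$gm_mask)[1:20]] <- 1
  outside <- matrix(0, 1, 200); outside[1, which(!g$gm_mask)[1:5]] <- 1
  nets <- structure(list(loadings = rbind(inside, outside),
                         supports = rbind(inside, outside) != 0,
                         reproducibility = c(1, 1), model_order = 2,
                         epsilon = 1e-8),
                    class = "subject_networks")
  flags <- flag_noise_atoms(nets, g)
  expect_identical(flags, c(FALSE, TRUE))
})
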