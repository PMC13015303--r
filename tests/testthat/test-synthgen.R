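test_that("toy geometry satisfies its structural invariants", {
  g <- toy_geom()
  expect_equal(unname(sqrt(rowSums(g$coords^2))), rep(1, 400), tolerance = 1e-9)
  expect_setequal(unique(g$parcel_id), 1:20)
  # parcels never span hemispheres
  for (p in 1:20) {
    expect_length(unique(g$hemisphere[g$parcel_id == p]), 1)
  }
  expect_true(all(sort(unique(g$subcortical_id)) == 0:14))
  # seven subcortical regions per hemisphere
  for (r in 1:7) expect_true(all(g$hemisphere[g$subcortical_id == r] == "L"))
  for (r in 8:14) expect_true(all(g$hemisphere[g$subcortical_id == r] == "R"))
})

test_that("geometry is seed-deterministic and seed-sensitive", {
  g1 <- make_geometry(400, 20, seed = 1)
  g2 <- make_geometry(400, 20, seed = 1)
  g3 <- make_geometry(400, 20, seed = 2)
  expect_identical(g1, g2)
  expect_false(identical(g1$parcel_id, g3$parcel_id))
  expect_error(make_geometry(0, 5, 1), class = "netdax_error_argument")
  expect_error(make_geometry(400, 150, 1), class = "netdax_error_argument")
})

test_that("label atlases partition vertices and component atlases may overlap", {
  g <- toy_geom()
  atl <- make_atlases(g, label_specs = c(7, 17), component_specs = 10, seed = 1)
  expect_length(atl, 3)
  expect_equal(vapply(atl, `[[`, numeric(1), "M"), c(7, 17, 10))
  for (a in atl[1:2]) {
    # no vertex carries two labels; union of supports within the vertex set
    expect_lte(max(colSums(a$supports)), 1)
    expect_true(all(a$labels %in% 0:a$M))
    expect_true(all(1:a$M %in% a$labels))
  }
  comp <- atl[[3]]
  expect_true(any(colSums(comp$supports) > 1))  # overlap allowed
  # weight outside every component's support is exactly zero
  expect_true(all(comp$weights[!comp$supports] == 0))
  expect_error(make_atlases(g, label_specs = 25), class = "netdax_error_argument")
  expect_error(make_atlases(g, label_specs = 1), class = "netdax_error_argument")
})

test_that("planted BOLD honors overlap fraction and records exact ground truth", {
  g <- toy_geom()
  sim <- plant_networks_and_bold(g, K = 4, overlap_frac = 0.3, T_frames = 150,
                                 seed = 5)
  expect_identical(sim$truth$planted_k, colSums(sim$truth$planted_supports))
  frac <- mean(sim$truth$planted_k[g$gm_mask] >= 2)
  expect_equal(frac, 0.3, tolerance = 0.01)
  # zero overlap: k in {0, 1}
  s0 <- plant_networks_and_bold(g, 4, 0, 150, seed = 5)
  expect_true(all(s0$truth$planted_k %in% 0:1))
  # noiseless: data is the exact product of timecourses and supports
  sn <- plant_networks_and_bold(g, 4, 0.3, 150, snr = Inf, seed = 5)
  expect_equal(sn$ts$data,
               sn$truth$planted_timecourses %*% (sn$truth$planted_supports * 1))
  expect_error(plant_networks_and_bold(g, 4, 0.3, 7), class = "netdax_error_argument")
  expect_error(plant_networks_and_bold(g, 4, 1.0, 150), class = "netdax_error_argument")
})

test_that("cohort generator plants group deviations and is reproducible", {
  sim <- simulate_cohort_features(600, 600, 5,
                                  deviation_spec = c(f3 = -1.5),
                                  noise_sd = 1, seed = 3)
  hp <- sim$cohort$group == "HP"
  diff3 <- mean(sim$features[!hp, "f3"]) - mean(sim$features[hp, "f3"])
  expect_equal(diff3, -1.5, tolerance = 0.2)
  # other features are undistorted in expectation
  diff1 <- mean(sim$features[!hp, "f1"]) - mean(sim$features[hp, "f1"])
  expect_lt(abs(diff1), 0.2)
  sim2 <- simulate_cohort_features(600, 600, 5,
                                   deviation_spec = c(f3 = -1.5),
                                   noise_sd = 1, seed = 3)
  expect_identical(sim$features, sim2$features)
  expect_identical(sim$cohort, sim2$cohort)
  expect_error(
    simulate_cohort_features(50, 10, 3, deviation_spec = c(f9 = 1)),
    class = "netdax_error_argument"
  )
})

test_that("progression generator follows the waypoint trajectories", {
  n_f <- 4
  ord <- c(t(outer(1:n_f, 1:3, function(f, w) (f - 1) * 3 + w)))
  sim <- simulate_progression(3000, n_f, 1, orderings = list(ord),
                              sigma = 0.2, seed = 2)
  E <- stage_expected_z(ord, n_f)
  for (st in c(0, 4, 8, 12)) {
    idx <- sim$truth$stage == st
    expect_equal(unname(colMeans(sim$z[idx, , drop = FALSE])),
                 unname(E[st + 1, ]), tolerance = 0.05)
  }
  # stage 0 expects all zeros, final stage all at/above waypoint 3
  expect_true(all(E[1, ] == 0))
  expect_true(all(E[nrow(E), ] >= 3))
  bad <- ord
  bad[1:2] <- bad[2:1]  # z=2 before z=1 for feature 1
  expect_error(simulate_progression(10, n_f, 1, orderings = list(bad)),
               class = "netdax_error_ordering")
})

test_that("cross-block generator plants the stated latent correlation", {
  sim <- simulate_crossblock(500, 20, 15, support_sizes = c(5, 5),
                             latent_r = 0.8, seed = 9)
  xs <- rowMeans(sim$X[, sim$truth$support_x])
  ys <- rowMeans(sim$Y[, sim$truth$support_y])
  expect_equal(cor(xs, ys), 0.8, tolerance = 0.05)
  # latent_r = 0: blocks independent by construction
  s0 <- simulate_crossblock(2000, 6, 6, c(3, 3), latent_r = 0, seed = 4)
  expect_lt(abs(cor(rowMeans(s0$X[, 1:3]), rowMeans(s0$Y[, 1:3]))), 0.07)
  expect_identical(sim$X, simulate_crossblock(500, 20, 15, c(5, 5), 0.8, seed = 9)$X)
  expect_error(simulate_crossblock(100, 5, 5, c(3, 3), latent_r = 1),
               class = "netdax_error_argument")
})
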