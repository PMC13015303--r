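test_that("Dice matrix matches the stated arithmetic and set oracle", {
  a <- matrix(FALSE, 1, 5); a[1, 1:3] <- TRUE
  b <- matrix(FALSE, 1, 5); b[1, 2:4] <- TRUE
  expect_equal(dice_matrix(a, b)[1, 1], 2 * 2 / (3 + 3))
  expect_equal(dice_matrix(a, a)[1, 1], 1)
  disj <- matrix(FALSE, 1, 5); disj[1, 5] <- TRUE
  expect_equal(dice_matrix(a, disj)[1, 1], 0)
  # empty-vs-empty is defined as 0
  e <- matrix(FALSE, 1, 5)
  expect_equal(dice_matrix(e, e)[1, 1], 0)
  # brute-force oracle over random masks
  set.seed(7)
  for (i in 1:50) {
    A <- random_support_matrix(3, 10)
    B <- random_support_matrix(4, 10)
    D <- dice_matrix(A, B)
    for (k in 1:3) for (m in 1:4) {
      expect_identical(D[k, m], dice_oracle(A[k, ], B[m, ]))
    }
  }
  expect_error(dice_matrix(a, matrix(TRUE, 1, 4)), class = "netdax_error_shape")
})

test_that("correspondence metrics match forced arithmetic and the loop oracle", {
  D <- matrix(c(0.8, 0.3, 0.1, 0.6), 2, 2)
  pr <- correspondence_profile(D)
  expect_equal(unname(pr$cnr), c(0.8, 0.6))
  expect_equal(pr$normativity, 0.7)
  expect_equal(pr$non_normativity, ((1 - 0.8) + (1 - 0.6)) / 2)
  # identity case: nets identical to atlas networks
  sup <- random_support_matrix(4, 30)
  pid <- correspondence_profile(dice_matrix(sup, sup))
  expect_equal(pid$normativity, 1)
  expect_equal(pid$non_normativity, 0)
  # all-zero Dice
  p0 <- correspondence_profile(matrix(0, 3, 5))
  expect_equal(p0$normativity, 0)
  expect_equal(p0$non_normativity, 1)
  # loop-oracle equivalence on 100 random matrices (exact)
  set.seed(11)
  for (i in 1:100) {
    K <- sample(2:8, 1); M <- sample(2:9, 1)
    Dm <- matrix(runif(K * M), K, M)
    pr <- correspondence_profile(Dm)
    or <- profile_oracle(Dm)
    expect_identical(unname(pr$cnr), or$cnr)
    # means agree up to the last-bit rounding of independent summation orders
    expect_equal(pr$normativity, or$normativity, tolerance = 1e-14)
    expect_equal(pr$non_normativity, or$non_normativity, tolerance = 1e-14)
  }
  # ties break to the lowest atom index
  Dt <- matrix(c(0.5, 0.5, 0.2, 0.1), 2, 2)
  expect_equal(correspondence_profile(Dt)$best_atom[1], 1L)
})

test_that("atom duplication leaves normativity unchanged; duplicating the best atom cannot raise non-normativity", {
  set.seed(3)
  for (i in 1:20) {
    sup <- random_support_matrix(4, 40)
    atl <- random_support_matrix(5, 40)
    D1 <- dice_matrix(sup, atl)
    p1 <- correspondence_profile(D1)
    # any duplicate: column maxima (hence normativity) unchanged
    sup_any <- rbind(sup, sup[sample(4, 1), ])
    expect_equal(correspondence_profile(dice_matrix(sup_any, atl))$normativity,
                 p1$normativity)
    # duplicating the best-matching atom adds the smallest (1 - max) term,
    # so the mean cannot increase
    best <- which.max(apply(D1, 1, max))
    p2 <- correspondence_profile(dice_matrix(rbind(sup, sup[best, ]), atl))
    expect_lte(p2$non_normativity, p1$non_normativity + 1e-12)
    expect_true(p1$normativity >= 0 && p1$normativity <= 1)
    expect_true(p1$non_normativity >= 0 && p1$non_normativity <= 1)
  }
})

test_that("parcel projection follows the label weighting and component coverage rules", {
  g <- toy_geom(120, 6, 4)
  # label atlas: craft a profile, verify the weighted-average rule by oracle
  atl <- make_atlases(g, label_specs = 4, seed = 2)[[1]]
  cnr <- c(0.8, 0.4, 0.2, 0.6)
  pr <- structure(list(cnr = cnr, best_atom = rep(1L, 4),
                       normativity = mean(cnr), non_normativity = 0.1),
                  class = "correspondence_profile")
  pp <- map_to_parcels(pr, atl, g)
  for (p in 1:6) {
    idx <- which(g$parcel_id == p)
    expected <- 0
    for (m in 1:4) {
      expected <- expected + cnr[m] * sum(atl$labels[idx] == m) / length(idx)
    }
    expect_equal(pp$value[p], expected)
  }
  # component atlas: mean CNR over covering components; uncovered parcels -> 0
  catl <- make_atlases(g, component_specs = 3, seed = 5)[[1]]
  cnr3 <- c(0.2, 0.6, 0.9)
  pr3 <- structure(list(cnr = cnr3, best_atom = rep(1L, 3),
                        normativity = mean(cnr3), non_normativity = 0.1),
                   class = "correspondence_profile")
  pp3 <- map_to_parcels(pr3, catl, g)
  for (p in 1:6) {
    idx <- which(g$parcel_id == p)
    covering <- which(rowSums(catl$supports[, idx, drop = FALSE]) > 0)
    if (length(covering) == 0) {
      expect_false(pp3$covered[p])
      expect_equal(pp3$value[p], 0)
    } else {
      expect_true(pp3$covered[p])
      expect_equal(pp3$value[p], mean(cnr3[covering]))
    }
  }
})

test_that("consensus map averages over covering atlases only", {
  g <- toy_geom(120, 6, 4)
  mk <- function(vals, cov) tibble::tibble(parcel = 1:6, value = vals, covered = cov)
  p1 <- mk(rep(0.3, 6), rep(TRUE, 6))
  p2 <- mk(rep(0.5, 6), rep(TRUE, 6))
  p3 <- mk(rep(0.9, 6), c(FALSE, rep(TRUE, 5)))
  cm <- consensus_map(list(p1, p2, p3), g)
  expect_equal(cm$parcels$value[1], 0.4)                 # 0.9 not covering
  expect_equal(cm$parcels$value[2], mean(c(0.3, 0.5, 0.9)))
  # single atlas: identity
  cm1 <- consensus_map(list(p1), g)
  expect_equal(cm1$parcels$value, p1$value)
  # uncovered-everywhere parcel flagged missing and excluded from network means
  p4 <- mk(rep(0.2, 6), c(FALSE, rep(TRUE, 5)))
  cm2 <- consensus_map(list(p4), g)
  expect_true(cm2$parcels$missing[1])
  expect_false(1 %in% (cm2$networks$network[is.na(cm2$networks$value)]))
  # consensus values bounded by contributing atlas values
  set.seed(8)
  profs <- lapply(1:3, function(i) mk(runif(6), runif(6) > 0.3))
  cmr <- consensus_map(profs, g)
  for (p in 1:6) {
    vals <- vapply(profs, function(x) x$value[p], numeric(1))
    cov <- vapply(profs, function(x) x$covered[p], logical(1))
    if (any(cov)) {
      expect_gte(cmr$parcels$value[p], min(vals[cov]) - 1e-12)
      expect_lte(cmr$parcels$value[p], max(vals[cov]) + 1e-12)
    }
  }
  # network mean arithmetic
  expect_equal(mean(c(0.2, 0.4, 0.6)), 0.4)
})

test_that("spin permutations are valid relabelings with correct p-value bounds", {
  g <- toy_geom(200, 10, 6)
  atl <- make_atlases(g, label_specs = 5, seed = 3)[[1]]
  # a spin is a relabeling: the multiset of atlas labels is preserved up to
  # neighbor multiplicity; check the p-value formula bounds instead plus an
  # identity-rotation sanity
  sup <- atl$supports[1:2, , drop = FALSE]
  p <- spin_significance(sup, atl, g, n_perm = 99, seed = 2)
  expect_true(all(p >= 1 / 100 & p <= 1))
  # perfectly matching atom should be extreme: p at the floor
  expect_equal(p[1, 1], 1 / 100)
  expect_error(
    spin_significance(sup, atl,
                      structure(list(coords = matrix(rnorm(600), 200, 3)),
                                class = "toy_geometry"),
                      n_perm = 9, seed = 1),
    class = "netdax_error_geometry"
  )
})

test_that("spin null p-values are uniform under random atlas placement", {
  g <- toy_geom(200, 10, 9)
  atl <- make_atlases(g, label_specs = 2, seed = 3)[[1]]
  d <- colSums((t(g$coords) - g$coords[5, ])^2)
  sup <- matrix(d < quantile(d, 0.35), 1)
  set.seed(21)
  pvals <- vapply(1:200, function(i) {
    # random placement: spin the atlas relative to the atom with the same
    # relabeling mechanism the null uses (exchangeable by construction)
    perm <- netdax:::spin_nearest(g$coords, netdax:::random_rotation())
    atl_obs <- atl
    atl_obs$supports <- atl$supports[, perm, drop = FALSE]
    atl_obs$labels <- atl$labels[perm]
    spin_significance(sup, atl_obs, g, n_perm = 49, seed = i)[1, 1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a spin is an exact relabeling (label multiset preserved)", {
  g <- toy_geom(200, 10, 9)
  set.seed(4)
  for (i in 1:5) {
    perm <- netdax:::spin_nearest(g$coords, netdax:::random_rotation())
    expect_setequal(perm, seq_len(nrow(g$coords)))
  }
})

test_that("subcortical correspondence yields 14 region and 7 bilateral values", {
  g <- toy_geom()
  sup <- t(vapply(1:3, function(r) g$subcortical_id %in% c(r, r + 7),
                  logical(nrow(g$coords))))
  sc <- subcortical_dice(sup, g)
  expect_length(sc$cnr, 14)
  expect_length(sc$cnr_bilateral, 7)
  expect_equal(dim(sc$dice), c(3, 14))
  # atoms built from bilateral regions 1..3 correspond most to those regions
  expect_true(all(sc$cnr_bilateral[1:3] > sc$cnr_bilateral[4:7 ][1]))
})
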