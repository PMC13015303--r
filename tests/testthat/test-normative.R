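test_that("design matrix has the right spline block and catches degenerate input", {
  set.seed(1)
  d <- tibble::tibble(age = runif(100, 20, 60), motion = runif(100, 0, 0.3),
                      n_atoms = sample(18:40, 100, TRUE),
                      sex = sample(c("F", "M"), 100, TRUE))
  X <- build_design(d)
  # cubic spline with 4 interior knots: 4 + 3 = 7 columns per covariate
  expect_equal(sum(grepl("^age_bs", colnames(X))), 7)
  expect_equal(ncol(X), 1 + 3 * 7 + 1)
  # identical covariate values give identical rows
  d2 <- d[c(1, 1), ]
  X2 <- build_design(d2, spec = attr(X, "spec"))
  expect_equal(X2[1, ], X2[2, ])
  # row at a knot matches a direct basis evaluation
  spec <- attr(X, "spec")
  x_at_knot <- spec$knots$age[2]
  d3 <- d[1, ]; d3$age <- x_at_knot
  X3 <- build_design(d3, spec = spec)
  direct <- splines::bs(x_at_knot, knots = spec$knots$age, degree = 3,
                        Boundary.knots = spec$boundary$age)
  expect_equal(unname(X3[1, grepl("^age_bs", colnames(X3))]), as.numeric(direct))
  # constant covariate rejected
  dc <- d; dc$age <- 42
  expect_error(build_design(dc), class = "netdax_error_degenerate")
  # out-of-range covariates flagged
  d4 <- d[1, ]; d4$age <- 200
  X4 <- build_design(d4, spec = spec)
  expect_true(attr(X4, "out_of_range")[1])
})

test_that("normative fit recovers a linear age effect and the noiseless limit", {
  set.seed(7)
  n <- 500
  d <- tibble::tibble(age = runif(n, 20, 60), motion = runif(n, 0, 0.3),
                      n_atoms = sample(18:40, n, TRUE),
                      sex = sample(c("F", "M"), n, TRUE))
  y <- 2 * d$age + rnorm(n)
  X <- build_design(d)
  fit <- fit_normative(matrix(y, ncol = 1, dimnames = list(NULL, "y")), X)
  # recovered marginal age effect: finite-difference slope of the predictor
  d_lo <- d[1, ]; d_lo$age <- 30; d_hi <- d_lo; d_hi$age <- 50
  X_pred <- build_design(rbind(d_lo, d_hi), spec = fit$spec)
  mu <- predict_normative(fit, X_pred, rbind(d_lo, d_hi))$mean
  slope <- (mu[2, 1] - mu[1, 1]) / 20
  expect_gte(slope, 1.9)
  expect_lte(slope, 2.1)
  # zero-noise data reproduced to numerical tolerance
  y0 <- 1.5 * d$age - 0.5
  f0 <- fit_normative(matrix(y0, ncol = 1, dimnames = list(NULL, "y")), X)
  mu0 <- predict_normative(f0, X)$mean
  expect_lt(max(abs(mu0 - y0)), 1e-3)
  expect_error(fit_normative(matrix(y[1:10], ncol = 1), X[1:10, ]),
               class = "netdax_error_argument")
})

test_that("w-scores follow their definition", {
  set.seed(3)
  n <- 200
  d <- tibble::tibble(age = runif(n, 20, 60), motion = runif(n, 0, 0.3),
                      n_atoms = sample(18:40, n, TRUE),
                      sex = sample(c("F", "M"), n, TRUE))
  y <- 0.5 * d$age + rnorm(n)
  X <- build_design(d)
  fit <- fit_normative(matrix(y, ncol = 1, dimnames = list(NULL, "y")), X)
  pred <- predict_normative(fit, X)
  # subject exactly at the predicted mean -> w = 0
  w0 <- compute_wscores(fit, matrix(pred$mean[1, 1], 1, 1,
                                    dimnames = list(NULL, "y")),
                        X[1, , drop = FALSE])
  expect_equal(unname(w0[1, 1]), 0)
  # subject 2 healthy-sd above the mean -> w = 2
  w2 <- compute_wscores(fit, matrix(pred$mean[1, 1] + 2 * fit$models[[1]]$sigma,
                                    1, 1, dimnames = list(NULL, "y")),
                        X[1, , drop = FALSE])
  expect_equal(unname(w2[1, 1]), 2)
  expect_error(
    compute_wscores(fit, matrix(1, 1, 1, dimnames = list(NULL, "zz")),
                    X[1, , drop = FALSE]),
    class = "netdax_error_untrained"
  )
})

test_that("held-out healthy w-scores are calibrated and patients never touch the fit", {
  sim <- simulate_cohort_features(2500, 0, 3, noise_sd = 1, seed = 21)
  train <- 1:500
  test <- 501:2500
  d_train <- build_design(sim$cohort[train, ])
  fit <- fit_normative(sim$features[train, ], d_train)
  d_test <- build_design(sim$cohort[test, ], spec = fit$spec)
  w <- compute_wscores(fit, sim$features[test, ], d_test)
  for (j in 1:3) {
    expect_gte(mean(w[, j]), -0.1)
    expect_lte(mean(w[, j]), 0.1)
    expect_gte(sd(w[, j]), 0.9)
    expect_lte(sd(w[, j]), 1.1)
  }
  # patient rows never influence the fit
  sim2 <- simulate_cohort_features(100, 80, 2,
                                   deviation_spec = c(f1 = -3), seed = 5)
  res_all <- normative_wscores(sim2$features, sim2$cohort)
  hp_only <- sim2$cohort$group == "HP"
  d_hp <- build_design(sim2$cohort[hp_only, ])
  fit_hp <- fit_normative(sim2$features[hp_only, ], d_hp)
  expect_equal(res_all$fit$models[[1]]$beta, fit_hp$models[[1]]$beta)
})

test_that("heteroskedastic fits recover an sd ratio doubling over the age range", {
  sim <- simulate_cohort_features(1000, 0, 2, noise_sd = 1, hetero_ratio = 2,
                                  seed = 13)
  res <- normative_wscores(sim$features, sim$cohort, heteroskedastic = TRUE)
  # predicted sd at the ends of the age range
  ends <- sim$cohort[c(which.min(sim$cohort$age), which.max(sim$cohort$age)), ]
  d_ends <- build_design(ends, spec = res$fit$spec)
  pr <- predict_normative(res$fit, d_ends, ends)
  ratio <- pr$sd[2, ] / pr$sd[1, ]
  expect_true(all(ratio >= 1.6 & ratio <= 2.4))
  # held-out calibration also holds under heteroskedastic noise
  w_hp <- res$w
  expect_true(all(abs(colMeans(w_hp)) < 0.1))
  expect_true(all(apply(w_hp, 2, sd) > 0.85 & apply(w_hp, 2, sd) < 1.15))
})

test_that("w-scores are invariant to positive affine rescaling of the feature", {
  sim <- simulate_cohort_features(300, 0, 1, noise_sd = 1, seed = 9)
  res1 <- normative_wscores(sim$features, sim$cohort)
  res2 <- normative_wscores(sim$features * 3.7 + 11, sim$cohort)
  expect_equal(res1$w, res2$w, tolerance = 1e-8)
})
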