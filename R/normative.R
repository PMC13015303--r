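#' Build a normative design matrix (cubic B-splines + coded categoricals)
#'
#' Expands each continuous covariate with a cubic B-spline whose four interior
#' knots sit at quantiles of the training (healthy) values, adds dummy-coded
#' categorical covariates and an intercept. When `spec` is `NULL` the knot
#' positions and ranges are learned from `data` (the healthy training rows)
#' and attached to the result; passing that spec back evaluates the same basis
#' for new subjects. Subjects whose continuous covariates fall outside the
#' training range (beyond a small tolerance) are flagged, and their values are
#' clamped to the range for basis evaluation.
#'
#' @param data Tibble/data frame of covariates.
#' @param continuous,categorical Character vectors of column names.
#' @param spec Optional design spec from a previous call (its `continuous`
#'   and `categorical` settings take precedence).
#' @param n_knots Number of interior knots (default 4).
#' @param degree Spline degree (default 3, cubic).
#' @param range_tol Out-of-range tolerance as a fraction of the training
#'   range (default 0.05).
#' @return A numeric design matrix with attributes `spec` (reusable) and
#'   `out_of_range` (logical per row).
#' @export
build_design <- function(data, continuous = c("age", "motion", "n_atoms"),
                         categorical = "sex", spec = NULL,
                         n_knots = 4L, degree = 3L, range_tol = 0.05) {
  data <- as.data.frame(data)
  if (!is.null(spec)) {
    continuous <- spec$continuous
    categorical <- spec$categorical
    n_knots <- spec$n_knots
    degree <- spec$degree
  }
  missing_cols <- setdiff(c(continuous, categorical), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing covariate columns: %s", paste(missing_cols, collapse = ", ")),
          class = "netdax_error_missing_covariate")
  }
  learn <- is.null(spec)
  if (learn) {
    spec <- list(continuous = continuous, categorical = categorical,
                 n_knots = n_knots, degree = degree,
                 knots = list(), boundary = list(), levels = list())
    for (v in continuous) {
      x <- data[[v]]
      if (!is.numeric(x)) abort(sprintf("Covariate `%s` must be numeric.", v),
                                class = "netdax_error_argument")
      if (diff(range(x)) <= 0) {
        abort(sprintf("Covariate `%s` is constant (degenerate design).", v),
              class = "netdax_error_degenerate")
      }
      probs <- seq_len(n_knots) / (n_knots + 1)
      spec$knots[[v]] <- as.numeric(quantile(x, probs))
      spec$boundary[[v]] <- range(x)
    }
    for (v in categorical) {
      spec$levels[[v]] <- sort(unique(as.character(data[[v]])))
    }
  }
  out_of_range <- rep(FALSE, nrow(data))
  blocks <- list(`(Intercept)` = matrix(1, nrow(data), 1))
  for (v in continuous) {
    b <- spec$boundary[[v]]
    tol <- range_tol * diff(b)
    x <- data[[v]]
    out_of_range <- out_of_range | x < b[1] - tol | x > b[2] + tol
    x <- pmin(pmax(x, b[1]), b[2])
    basis <- splines::bs(x, knots = spec$knots[[v]], degree = spec$degree,
                         Boundary.knots = b, intercept = FALSE)
    colnames(basis) <- paste0(v, "_bs", seq_len(ncol(basis)))
    blocks[[v]] <- basis
  }
  for (v in categorical) {
    lv <- spec$levels[[v]]
    if (length(lv) < 2) {
      abort(sprintf("Categorical covariate `%s` has a single level.", v),
            class = "netdax_error_degenerate")
    }
    dm <- vapply(lv[-1], function(l) as.numeric(as.character(data[[v]]) == l),
                 numeric(nrow(data)))
    dm <- matrix(dm, nrow(data), length(lv) - 1L,
                 dimnames = list(NULL, paste0(v, lv[-1])))
    blocks[[v]] <- dm
  }
  X <- do.call(cbind, blocks)
  attr(X, "spec") <- spec
  attr(X, "out_of_range") <- out_of_range
  X
}

# Evidence-based ridge: empirical-Bayes choice of the prior precision ratio
# on a log-spaced grid, conjugate Gaussian model, intercept unpenalized.
bayes_ridge <- function(X, y, lambda_grid = 10^seq(-6, 4, length.out = 30),
                        weights = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    abort("Singular design matrix.", class = "netdax_error_singular")
  }
  w <- if (is.null(weights)) rep(1, n) else weights
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  XtX <- crossprod(Xw)
  Xty <- crossprod(Xw, yw)
  pen <- diag(p)
  pen[1, 1] <- 0  # intercept unpenalized
  best <- NULL
  for (lam in lambda_grid) {
    A <- XtX + lam * pen
    beta <- solve(A, Xty)
    resid <- yw - Xw %*% beta
    sigma2 <- max(sum(resid^2) / max(n - 1, 1), 1e-12)
    # Gaussian evidence (up to constants), sigma2 plugged in
    logdet <- determinant(A, logarithm = TRUE)$modulus
    ev <- -0.5 * (n * log(sigma2) + sum(resid^2) / sigma2 +
                    logdet - (p - 1) * log(lam + 1e-300))
    if (is.null(best) || ev > best$evidence) {
      best <- list(beta = as.numeric(beta), lambda = lam, sigma2 = sigma2,
                   evidence = as.numeric(ev), cov = solve(A) * sigma2)
    }
  }
  best
}

#' Fit normative models on healthy participants
#'
#' For each feature column, fits a Bayesian linear regression with a
#' ridge-type conjugate Gaussian prior (prior scale chosen by
#' marginal-likelihood grid search) on the healthy design. With
#' `heteroskedastic = TRUE`, the log squared residuals are regressed on the
#' linear continuous covariates and the mean model is refit once with the
#' implied inverse-variance weights, yielding a covariate-dependent predictive
#' standard deviation.
#'
#' @param features Healthy-participant feature matrix (subjects x features).
#' @param design Healthy design matrix from [build_design()] (spec attached).
#' @param heteroskedastic Model log-linear residual variance in the continuous
#'   covariates (default `FALSE`).
#' @param data Covariate table for the healthy rows; required when
#'   `heteroskedastic = TRUE`.
#' @return An object of class `normative_fit`: per-feature models (posterior
#'   mean coefficients, homoskedastic residual sd, optional log-variance
#'   coefficients) plus the design spec.
#' @export
fit_normative <- function(features, design, heteroskedastic = FALSE, data = NULL) {
  features <- as.matrix(features)
  if (nrow(features) != nrow(design)) {
    abort("Features and design have different row counts.",
          class = "netdax_error_shape")
  }
  if (nrow(design) < ncol(design) + 5) {
    abort("Too few healthy participants for the design size.",
          class = "netdax_error_argument")
  }
  spec <- attr(design, "spec")
  if (heteroskedastic && is.null(data)) {
    abort("Heteroskedastic fits need the covariate table.", class = "netdax_error_argument")
  }
  var_design <- if (heteroskedastic) linear_var_design(data, spec) else NULL
  models <- lapply(seq_len(ncol(features)), function(j) {
    y <- features[, j]
    fit <- bayes_ridge(design, y)
    resid <- y - as.numeric(design %*% fit$beta)
    model <- list(beta = fit$beta, lambda = fit$lambda,
                  sigma = sd(resid), heteroskedastic = heteroskedastic)
    if (heteroskedastic) {
      # two-stage: log squared residuals ~ linear covariates, one refit
      ly <- log(pmax(resid^2, 1e-12))
      gamma <- qr.solve(var_design, ly)
      # E[log chi^2_1] = digamma(1/2) + log 2; correct the bias
      gamma[1] <- gamma[1] - (digamma(0.5) + log(2))
      sd_hat <- exp(0.5 * as.numeric(var_design %*% gamma))
      refit <- bayes_ridge(design, y, weights = 1 / sd_hat^2)
      resid2 <- y - as.numeric(design %*% refit$beta)
      # rescale so standardized healthy residuals have unit variance
      scale_adj <- sd(resid2 / sd_hat)
      model$beta <- refit$beta
      model$lambda <- refit$lambda
      model$var_gamma <- gamma
      model$var_scale <- scale_adj
      model$sigma <- sd(resid2)
    }
    model
  })
  names(models) <- colnames(features)
  structure(list(models = models, spec = spec,
                 feature_names = colnames(features)),
            class = "normative_fit")
}

linear_var_design <- function(data, spec) {
  data <- as.data.frame(data)
  cbind(`(Intercept)` = 1,
        vapply(spec$continuous, function(v) as.numeric(data[[v]]),
               numeric(nrow(data))))
}

#' @export
print.normative_fit <- function(x, ...) {
  cat(sprintf("<normative_fit> %d features, %s noise\n", length(x$models),
              if (x$models[[1]]$heteroskedastic) "heteroskedastic" else "homoskedastic"))
  invisible(x)
}

#' Predictive mean and sd of a normative fit
#'
#' @param fit A [fit_normative()] object.
#' @param design Design matrix for the subjects to predict (built with the
#'   fit's spec).
#' @param data Covariate table (needed for heteroskedastic sd).
#' @return A list with `mean` and `sd`, each subjects x features.
#' @export
predict_normative <- function(fit, design, data = NULL) {
  stopifnot(inherits(fit, "normative_fit"))
  mu <- vapply(fit$models, function(m) as.numeric(design %*% m$beta),
               numeric(nrow(design)))
  mu <- matrix(mu, nrow(design), dimnames = list(NULL, fit$feature_names))
  if (fit$models[[1]]$heteroskedastic) {
    if (is.null(data)) abort("Heteroskedastic prediction needs covariates.",
                             class = "netdax_error_argument")
    vd <- linear_var_design(data, fit$spec)
    sdm <- vapply(fit$models, function(m) {
      m$var_scale * exp(0.5 * as.numeric(vd %*% m$var_gamma))
    }, numeric(nrow(design)))
  } else {
    sdm <- vapply(fit$models, function(m) rep(m$sigma, nrow(design)),
                  numeric(nrow(design)))
  }
  sdm <- matrix(sdm, nrow(design), dimnames = list(NULL, fit$feature_names))
  list(mean = mu, sd = sdm)
}

#' Covariate-adjusted deviation scores (w-scores)
#'
#' Expresses each subject's feature as its residual from the healthy
#' predictive mean, scaled by the healthy residual variability:
#' `w = (y - mean) / sd`, with the predictive sd covariate-dependent under
#' the heteroskedastic model and equal to the healthy residual sd otherwise.
#' The sign of the deviation is preserved.
#'
#' @param fit A [fit_normative()] object.
#' @param features Feature matrix for all subjects (same columns as training).
#' @param design Their design matrix (built with the fit's spec).
#' @param data Covariate table (heteroskedastic sd).
#' @return A subjects x features matrix of w-scores, with attribute
#'   `out_of_range` copied from the design.
#' @export
compute_wscores <- function(fit, features, design, data = NULL) {
  features <- as.matrix(features)
  missing_f <- setdiff(colnames(features), fit$feature_names)
  if (length(missing_f) > 0) {
    abort(sprintf("No trained model for features: %s", paste(missing_f, collapse = ", ")),
          class = "netdax_error_untrained")
  }
  features <- features[, fit$feature_names, drop = FALSE]
  pred <- predict_normative(fit, design, data)
  w <- (features - pred$mean) / pred$sd
  attr(w, "out_of_range") <- attr(design, "out_of_range")
  w
}

#' One-call normative w-scores for a cohort
#'
#' Trains on the healthy rows only (verifiably: patient rows never enter the
#' fit), then scores every subject.
#'
#' @param features Subjects x features matrix (all subjects).
#' @param cohort Cohort tibble with a `group` column ("HP" marks healthy).
#' @param continuous,categorical Covariate columns.
#' @param heteroskedastic Passed to [fit_normative()].
#' @return A list with `w` (subjects x features w-score matrix) and `fit`.
#' @export
normative_wscores <- function(features, cohort,
                              continuous = c("age", "motion", "n_atoms"),
                              categorical = "sex", heteroskedastic = FALSE,
                              n_knots = 4L) {
  hp <- cohort$group == "HP"
  d_hp <- build_design(cohort[hp, ], continuous, categorical,
                       n_knots = n_knots)
  fit <- fit_normative(as.matrix(features)[hp, , drop = FALSE], d_hp,
                       heteroskedastic = heteroskedastic,
                       data = cohort[hp, ])
  d_all <- build_design(cohort, spec = fit$spec)
  w <- compute_wscores(fit, features, d_all, data = cohort)
  list(w = w, fit = fit)
}
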