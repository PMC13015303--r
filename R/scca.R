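# Soft-threshold a vector and rescale to unit l2 norm, with the threshold
# delta chosen (closed form over the sorted segments) so the l1 norm equals
# the bound `c` when it would otherwise exceed it.
l1_unit_project <- function(a, c_bound) {
  if (all(a == 0)) return(a)
  w <- a / sqrt(sum(a^2))
  if (sum(abs(w)) <= c_bound) return(w)
  b <- sort(abs(a), decreasing = TRUE)
  p <- length(b)
  S <- cumsum(b)
  Q <- cumsum(b^2)
  c2 <- c_bound^2
  delta <- NULL
  for (k in seq_len(p)) {
    if (k <= c2) next  # within this support size the ratio cannot reach c
    # solve (S_k - k d)^2 = c^2 (Q_k - 2 d S_k + k d^2) for d
    A <- k * (k - c2)
    B <- 2 * S[k] * (c2 - k)
    Cc <- S[k]^2 - c2 * Q[k]
    disc <- B^2 - 4 * A * Cc
    if (disc < 0) next
    roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    lo <- if (k < p) b[k + 1] else 0
    for (d in roots) {
      if (d >= lo - 1e-12 && d <= b[k] + 1e-12 && d >= 0) {
        delta <- d
        break
      }
    }
    if (!is.null(delta)) break
  }
  if (is.null(delta)) delta <- b[2]  # fall back to the sparsest solution
  s <- sign(a) * pmax(abs(a) - delta, 0)
  if (all(s == 0)) {
    s <- numeric(length(a))
    j <- which.max(abs(a))
    s[j] <- a[j]
  }
  s / sqrt(sum(s^2))
}

standardize_cols <- function(X, label) {
  X <- as.matrix(X)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("Zero-variance column(s) in %s: %s", label,
                  paste(which(sds == 0), collapse = ", ")),
          class = "netdax_error_degenerate")
  }
  scale(X)
}

#' Sparse canonical correlation via penalized matrix decomposition
#'
#' Finds up to `n_dims` pairs of sparse weight vectors (u, v) maximizing
#' `u' X' Y v` subject to unit l2 norms and l1 bounds `c_x`, `c_y` per side,
#' by alternating soft-thresholded power iterations on the cross-product
#' matrix; subsequent dimensions deflate the rank-1 term of the previous
#' solution. Columns are standardized internally (zero-variance columns are
#' an error).
#'
#' @param X,Y Data blocks (n x p, n x q).
#' @param c_x,c_y l1 bounds, in `[1, sqrt(p)]` / `[1, sqrt(q)]`.
#' @param n_dims Number of canonical dimensions, capped at 4.
#' @param seed Integer seed (initialization).
#' @param tol,max_iter Convergence controls (weight change below `tol`, or
#'   `max_iter` alternations).
#' @return An object of class `scca_model`: `u` (p x d), `v` (q x d),
#'   `cors` (canonical correlations), `d` (cross-product values),
#'   `penalties`, `iterations`.
#' @export
scca_fit <- function(X, Y, c_x, c_y, n_dims = 1L, seed = 1L,
                     tol = 1e-6, max_iter = 200L) {
  n_dims <- assert_positive_int(n_dims, "n_dims")
  if (n_dims > 4) abort("Canonical dimensions are capped at four.",
                        class = "netdax_error_argument")
  Xs <- standardize_cols(X, "X")
  Ys <- standardize_cols(Y, "Y")
  n <- nrow(Xs)
  if (n < 10) abort("Need at least 10 observations.", class = "netdax_error_argument")
  Z <- crossprod(Xs, Ys)
  p <- ncol(Xs); q <- ncol(Ys)
  U <- matrix(0, p, n_dims)
  V <- matrix(0, q, n_dims)
  cors <- numeric(n_dims)
  dvals <- numeric(n_dims)
  iters <- integer(n_dims)
  with_seed(seed, {
    for (dim in seq_len(n_dims)) {
      sv <- svd(Z, nu = 1, nv = 1)
      v <- sv$v[, 1]
      u <- numeric(p)
      for (it in seq_len(max_iter)) {
        u_new <- l1_unit_project(as.numeric(Z %*% v), c_x)
        v_new <- l1_unit_project(as.numeric(crossprod(Z, u_new)), c_y)
        delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
        u <- u_new
        v <- v_new
        if (delta < tol) break
      }
      iters[dim] <- it
      d <- as.numeric(crossprod(u, Z %*% v))
      xu <- Xs %*% u
      yv <- Ys %*% v
      cors[dim] <- if (sd(xu) > 0 && sd(yv) > 0) cor(xu, yv) else 0
      U[, dim] <- u
      V[, dim] <- v
      dvals[dim] <- d
      Z <- Z - d * tcrossprod(u, v)
    }
  })
  rownames(U) <- colnames(X)
  rownames(V) <- colnames(Y)
  structure(
    list(u = U, v = V, cors = cors, d = dvals,
         penalties = c(c_x = c_x, c_y = c_y), iterations = iters,
         n = n),
    class = "scca_model"
  )
}

#' @export
print.scca_model <- function(x, ...) {
  cat(sprintf("<scca_model> %d dimension(s), canonical r = %s; penalties (%.2f, %.2f)\n",
              length(x$cors), paste(sprintf("%.3f", x$cors), collapse = ", "),
              x$penalties[1], x$penalties[2]))
  invisible(x)
}

#' Permutation-based selection of sparsity penalties
#'
#' For each candidate penalty pair, fits the first sparse canonical dimension
#' on the observed data and on row-permuted copies of Y, and scores the
#' candidate by the z-statistic of the Fisher-transformed observed
#' correlation against the permuted null. The pair with the largest z wins.
#'
#' @param X,Y Data blocks.
#' @param grid Data frame / tibble with columns `c_x`, `c_y`; `NULL` builds
#'   10 evenly spaced bounds per side between 1 and sqrt(dim), paired
#'   diagonally.
#' @param n_perm Permutations per candidate (default 200; fewer than 20 is
#'   refused outside test mode).
#' @param seed Integer seed.
#' @param test_mode Allow tiny permutation counts for unit tests.
#' @return A list with `c_x`, `c_y`, and `table` (per-candidate tibble of
#'   observed correlation and z-statistic).
#' @export
select_penalties <- function(X, Y, grid = NULL, n_perm = 200L, seed = 1L,
                             test_mode = FALSE) {
  if (n_perm < 20 && !test_mode) {
    abort("Fewer than 20 permutations is only allowed in test mode.",
          class = "netdax_error_argument")
  }
  if (is.null(grid)) {
    grid <- tibble(c_x = seq(1, sqrt(ncol(X)), length.out = 10),
                   c_y = seq(1, sqrt(ncol(Y)), length.out = 10))
  }
  if (nrow(grid) == 0) abort("Empty penalty grid.", class = "netdax_error_argument")
  n <- nrow(X)
  seeds <- derive_seeds(seed, n_perm + 1L)
  perms <- with_seed(seeds[1], {
    replicate(n_perm, sample.int(n), simplify = FALSE)
  })
  fisher <- function(r) atanh(pmin(pmax(r, -0.999999), 0.999999))
  zstat <- vapply(seq_len(nrow(grid)), function(g) {
    fit <- scca_fit(X, Y, grid$c_x[g], grid$c_y[g], n_dims = 1L, seed = seeds[2])
    obs <- fisher(fit$cors[1])
    null <- vapply(perms, function(pm) {
      f <- scca_fit(X, Y[pm, , drop = FALSE], grid$c_x[g], grid$c_y[g],
                    n_dims = 1L, seed = seeds[2])
      fisher(f$cors[1])
    }, numeric(1))
    s <- sd(null)
    if (s == 0) 0 else (obs - mean(null)) / s
  }, numeric(1))
  obs_r <- vapply(seq_len(nrow(grid)), function(g) {
    scca_fit(X, Y, grid$c_x[g], grid$c_y[g], n_dims = 1L, seed = seeds[2])$cors[1]
  }, numeric(1))
  best <- which.max(zstat)
  list(c_x = grid$c_x[best], c_y = grid$c_y[best],
       table = tibble(c_x = grid$c_x, c_y = grid$c_y, r = obs_r, z = zstat))
}

#' Overall permutation p-value of a sparse CCA fit
#'
#' Permutes the rows of Y, refits the first canonical dimension at the stated
#' penalties, and returns the add-one permutation p-value on the first
#' canonical correlation.
#'
#' @param X,Y Data blocks.
#' @param c_x,c_y Penalties used for the final fit.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A one-row tibble: `r` (observed first canonical correlation),
#'   `p`, `n_perm`.
#' @export
scca_permutation_test <- function(X, Y, c_x, c_y, n_perm = 1000L, seed = 1L) {
  n <- nrow(X)
  seeds <- derive_seeds(seed, 2L)
  fit <- scca_fit(X, Y, c_x, c_y, n_dims = 1L, seed = seeds[2])
  null <- with_seed(seeds[1], {
    vapply(seq_len(n_perm), function(i) {
      pm <- sample.int(n)
      scca_fit(X, Y[pm, , drop = FALSE], c_x, c_y, n_dims = 1L,
               seed = seeds[2])$cors[1]
    }, numeric(1))
  })
  tibble(r = fit$cors[1], p = perm_pvalue(fit$cors[1], null),
         n_perm = as.integer(n_perm))
}

#' Pairwise sparse CCA across feature subdomains
#'
#' Partitions the feature space into named blocks (e.g. system integrity,
#' system integration, cognition, clinical), runs penalty selection, fitting
#' and permutation testing for every block pair, and applies BH-FDR across
#' the pair family; `significant` marks pairs surviving correction (solid
#' vs dashed edges in the usual subdomain graph).
#'
#' @param blocks Named list of data blocks sharing rows; feature names must
#'   not overlap across blocks.
#' @param pairs Optional 2-column matrix/data frame of block-name pairs;
#'   `NULL` tests all pairs.
#' @param n_perm Permutations for the p-value (and, divided by 5 with a floor
#'   of 20, for penalty selection).
#' @param q FDR level (default 0.05).
#' @param seed Integer seed.
#' @param test_mode Passed to [select_penalties()].
#' @return A tibble: `block_a`, `block_b`, `c_x`, `c_y`, `r`, `p`, `p_adj`,
#'   `significant`.
#' @export
subdomain_scca <- function(blocks, pairs = NULL, n_perm = 1000L, q = 0.05,
                           seed = 1L, test_mode = FALSE) {
  if (length(blocks) < 2) abort("Need at least two blocks.",
                                class = "netdax_error_argument")
  all_names <- unlist(lapply(blocks, colnames))
  if (anyDuplicated(all_names)) {
    abort("Feature names overlap across blocks.", class = "netdax_error_argument")
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(names(blocks), 2))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs) <- c("block_a", "block_b")
  seeds <- derive_seeds(seed, nrow(pairs))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    X <- blocks[[pairs$block_a[i]]]
    Y <- blocks[[pairs$block_b[i]]]
    sel <- select_penalties(X, Y, n_perm = max(20L, n_perm %/% 5L),
                            seed = seeds[i], test_mode = test_mode)
    pt <- scca_permutation_test(X, Y, sel$c_x, sel$c_y, n_perm = n_perm,
                                seed = seeds[i])
    tibble(block_a = pairs$block_a[i], block_b = pairs$block_b[i],
           c_x = sel$c_x, c_y = sel$c_y, r = pt$r, p = pt$p)
  })
  out <- bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < q
  out
}

#' First principal component of cognitive scores
#'
#' Standardizes the test columns, extracts the first principal component,
#' fixes its sign so that a higher PC1 means better performance (positive
#' mean loading), and reports variance explained. Subjects missing more than
#' 30% of tests are dropped (flagged); remaining missing values are
#' mean-imputed before standardization.
#'
#' @param scores Subjects x tests matrix or data frame (at least 2 tests).
#' @return A list with `scores` (tibble: subject row index, pc1), `loadings`,
#'   `variance_explained` (fraction), and `dropped` (row indices removed for
#'   missingness).
#' @export
cognition_pc1 <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) abort("Need at least two tests.",
                              class = "netdax_error_argument")
  miss_frac <- rowMeans(is.na(scores))
  dropped <- which(miss_frac > 0.3)
  keep <- setdiff(seq_len(nrow(scores)), dropped)
  s <- scores[keep, , drop = FALSE]
  for (j in seq_len(ncol(s))) {
    nas <- is.na(s[, j])
    if (any(nas)) s[nas, j] <- mean(s[, j], na.rm = TRUE)
  }
  sds <- apply(s, 2, sd)
  if (all(sds == 0)) abort("All tests are constant.",
                           class = "netdax_error_degenerate")
  s <- s[, sds > 0, drop = FALSE]
  s <- scale(s)
  pc <- stats::prcomp(s, center = FALSE, scale. = FALSE)
  load <- pc$rotation[, 1]
  sgn <- if (mean(load) < 0) -1 else 1
  list(
    scores = tibble(subject = keep, pc1 = sgn * pc$x[, 1]),
    loadings = sgn * load,
    variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
    dropped = dropped
  )
}
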