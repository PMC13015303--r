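#' Configuration for subject-level network estimation
#'
#' Collects the tunable parameters of the bootstrap sparse-decomposition
#' stage. Defaults mirror the full-scale analysis (B = 200 bootstraps, model
#' order searched 18..40 in steps of two, 20-60 s blocks); tests and toy runs
#' pass smaller values.
#'
#' @param k_min,k_max,k_step Model-order search range and step.
#' @param n_boot Number of block-bootstrap resamples B.
#' @param block_min_s,block_max_s Bootstrap block length bounds (seconds).
#' @param sparsity Maximum atoms per vertex in the sparse code.
#' @param n_iter Maximum alternating-minimization iterations.
#' @param min_explained Minimum fraction of residual variance an atom must
#'   explain to enter a vertex's sparse code (guards supports against chance
#'   selections on noise-only vertices).
#' @param n_restarts Decomposition restarts per resample (lowest-coherence
#'   dictionary kept).
#' @param reproducibility_threshold Minimum fraction of resamples that must
#'   contribute to a consensus cluster for it to be retained.
#' @param epsilon Nonzero-loading tolerance shared with k-hubness.
#' @return A named list of class `decomp_config`.
#' @export
decomp_config <- function(k_min = 18L, k_max = 40L, k_step = 2L,
                          n_boot = 200L, block_min_s = 20, block_max_s = 60,
                          sparsity = 3L, n_iter = 20L, min_explained = 0.2,
                          n_restarts = 6L,
                          reproducibility_threshold = 0.5, epsilon = 1e-8) {
  structure(
    list(k_min = as.integer(k_min), k_max = as.integer(k_max),
         k_step = as.integer(k_step), n_boot = as.integer(n_boot),
         block_min_s = block_min_s, block_max_s = block_max_s,
         sparsity = as.integer(sparsity), n_iter = as.integer(n_iter),
         min_explained = min_explained, n_restarts = as.integer(n_restarts),
         reproducibility_threshold = reproducibility_threshold,
         epsilon = epsilon),
    class = "decomp_config"
  )
}

#' Block-bootstrap resample of a BOLD time series
#'
#' Resamples the series as contiguous temporal blocks drawn with replacement;
#' each block's length is drawn uniformly from the stated range (converted to
#' frames), and the last block is truncated so the output has exactly the
#' original number of frames. Blockwise resampling preserves low-frequency
#' structure and autocorrelation within blocks.
#'
#' @param ts A [bold_ts()].
#' @param block_min_s,block_max_s Block length bounds in seconds.
#' @param seed Integer seed.
#' @return A [bold_ts()] with the same dimensions.
#' @export
block_bootstrap <- function(ts, block_min_s = 20, block_max_s = 60, seed = 1L) {
  stopifnot(inherits(ts, "bold_ts"))
  t_frames <- nrow(ts$data)
  if (block_min_s < ts$tr) {
    abort("Minimum block length must be at least one TR.",
          class = "netdax_error_argument")
  }
  if (block_min_s > t_frames * ts$tr) {
    abort("Minimum block length exceeds the scan duration.",
          class = "netdax_error_argument")
  }
  min_f <- max(1L, round(block_min_s / ts$tr))
  max_f <- max(min_f, min(t_frames, round(block_max_s / ts$tr)))
  idx <- with_seed(seed, {
    out <- integer(0)
    while (length(out) < t_frames) {
      # sample() on a length-1 vector would resample 1:n
      len <- if (min_f == max_f) min_f else sample(min_f:max_f, 1L)
      start <- sample.int(t_frames - len + 1L, 1L)
      out <- c(out, start:(start + len - 1L))
    }
    out[seq_len(t_frames)]
  })
  out <- bold_ts(ts$data[idx, , drop = FALSE], tr = ts$tr, mask = ts$mask)
  attr(out, "frames") <- idx
  out
}

# Batch orthogonal matching pursuit: sparse-code every vertex against the
# dictionary with per-vertex cardinality <= sparsity. An atom enters a
# vertex's code only if it explains at least `min_explained` of the current
# residual sum of squares; after selection, atoms whose unique contribution
# (partial R^2 against the vertex's total energy) falls below the same
# fraction are pruned and the code refit. The backward step stops a pure atom
# from compensating another atom's impurity. Vertices are grouped by active
# set so least-squares refits are batched.
omp_code <- function(D, X, sparsity, min_explained = 0, prune = FALSE) {
  K <- ncol(D)
  V <- ncol(X)
  C <- matrix(0, K, V)
  active <- matrix(0L, sparsity, V)
  n_active <- integer(V)
  R <- X
  alive <- rep(TRUE, V)
  for (s in seq_len(sparsity)) {
    if (!any(alive)) break
    corr <- crossprod(D, R[, alive, drop = FALSE])
    # mask atoms already selected
    if (s > 1) {
      av <- which(alive)
      for (j in seq_along(av)) {
        corr[active[seq_len(n_active[av[j]]), av[j]], j] <- 0
      }
    }
    pick <- max.col(t(abs(corr)), ties.method = "first")
    gain <- corr[cbind(pick, seq_along(pick))]^2
    rss <- colSums(R[, alive, drop = FALSE]^2)
    ok <- rss > 0 & gain >= min_explained * rss
    av <- which(alive)
    sel <- av[ok]
    alive[av[!ok]] <- FALSE
    if (length(sel) == 0) break
    n_active[sel] <- s
    active[s, sel] <- pick[ok]
    # batch LS refit per unique active set
    keys <- vapply(sel, function(v) {
      paste(sort(active[seq_len(s), v]), collapse = ",")
    }, character(1))
    for (key in unique(keys)) {
      vs <- sel[keys == key]
      atoms <- sort(active[seq_len(s), vs[1]])
      Dsub <- D[, atoms, drop = FALSE]
      # ridge-stabilized LS (near-duplicate atoms can make Dsub singular)
      coef <- solve(crossprod(Dsub) + diag(1e-10, length(atoms)),
                    crossprod(Dsub, X[, vs, drop = FALSE]))
      C[atoms, vs] <- coef
      R[, vs] <- X[, vs, drop = FALSE] - Dsub %*% coef
    }
  }
  if (prune && min_explained > 0) C <- prune_by_unique_r2(D, X, C, min_explained)
  C
}

# Backward elimination: repeatedly drop, per vertex, the active atom whose
# unique contribution is smallest if it explains less than `min_explained` of
# the vertex's total sum of squares, refitting after each drop.
prune_by_unique_r2 <- function(D, X, C, min_explained) {
  total <- colSums(X^2)
  repeat {
    act <- C != 0
    n_act <- colSums(act)
    cand <- which(n_act >= 2 & total > 0)
    if (length(cand) == 0) break
    keys <- vapply(cand, function(v) paste(which(act[, v]), collapse = ","),
                   character(1))
    changed <- FALSE
    for (key in unique(keys)) {
      vs <- cand[keys == key]
      atoms <- as.integer(strsplit(key, ",")[[1]])
      Dsub <- D[, atoms, drop = FALSE]
      G <- crossprod(Dsub) + diag(1e-10, length(atoms))
      full_fit <- solve(G, crossprod(Dsub, X[, vs, drop = FALSE]))
      rss_full <- total[vs] - colSums(full_fit * crossprod(Dsub, X[, vs, drop = FALSE]))
      # unique contribution of each atom = RSS(without it) - RSS(full)
      uniq <- vapply(seq_along(atoms), function(j) {
        Dm <- Dsub[, -j, drop = FALSE]
        cm <- solve(crossprod(Dm) + diag(1e-10, ncol(Dm)),
                    crossprod(Dm, X[, vs, drop = FALSE]))
        rss_m <- total[vs] - colSums(cm * crossprod(Dm, X[, vs, drop = FALSE]))
        rss_m - rss_full
      }, numeric(length(vs)))
      uniq <- matrix(uniq, nrow = length(vs))
      worst <- max.col(-uniq, ties.method = "first")
      worst_val <- uniq[cbind(seq_along(vs), worst)]
      drop_vs <- worst_val < min_explained * total[vs]
      if (any(drop_vs)) {
        changed <- TRUE
        for (i in which(drop_vs)) {
          v <- vs[i]
          keep <- atoms[-worst[i]]
          C[, v] <- 0
          Dk <- D[, keep, drop = FALSE]
          C[keep, v] <- solve(crossprod(Dk) + diag(1e-10, length(keep)),
                              crossprod(Dk, X[, v]))
        }
      }
    }
    if (!changed) break
  }
  C
}

#' Sparse dictionary decomposition of a BOLD series
#'
#' Represents each vertex's time series as a sparse linear combination of at
#' most `sparsity` temporal atoms, by alternating batch orthogonal matching
#' pursuit (sparse coding) with an atom-wise rank-1 dictionary update
#' (columns kept unit-norm). The per-iteration reconstruction error is
#' recorded and is non-increasing: after each dictionary update, a vertex's
#' new code is kept only if it beats its previous one. Several restarts from
#' different k-means initializations are run and the dictionary with the
#' lowest mutual coherence (maximum absolute inter-atom correlation) is kept
#' — alternating minimization has local optima in which one atom absorbs a
#' mixture of two sources, and such solutions are recognizably coherent with
#' the pure atom they overlap.
#'
#' @param ts A [bold_ts()] or a T x V matrix.
#' @param K Number of atoms; must be below the frame count.
#' @param sparsity Maximum atoms per vertex (at most K).
#' @param n_iter Maximum iterations per restart.
#' @param min_explained Residual-variance entry threshold (see
#'   [decomp_config()]).
#' @param n_restarts Number of initializations (default 6).
#' @param d_init Optional T x K dictionary used as the (single) warm-start
#'   initialization, e.g. the original-data solution when decomposing
#'   bootstrap resamples.
#' @param seed Integer seed (initializations).
#' @return A list with `dictionary` (T x K, unit-norm columns),
#'   `coefficients` (K x V), `error` (per-iteration reconstruction SSE of the
#'   kept restart) and `coherence`.
#' @export
sparse_decompose <- function(ts, K, sparsity = 3L, n_iter = 20L,
                             min_explained = 0.2, n_restarts = 6L,
                             d_init = NULL, seed = 1L) {
  X <- if (inherits(ts, "bold_ts")) ts$data else as.matrix(ts)
  K <- assert_positive_int(K, "K")
  if (K >= nrow(X)) abort("`K` must be below the frame count.",
                          class = "netdax_error_argument")
  if (sparsity > K) abort("`sparsity` cannot exceed K.",
                          class = "netdax_error_argument")
  if (all(X == 0)) abort("All-zero data cannot be decomposed.",
                         class = "netdax_error_degenerate")
  if (!is.null(d_init)) n_restarts <- 1L
  seeds <- derive_seeds(seed, n_restarts)
  mask <- if (inherits(ts, "bold_ts")) ts$mask else rep(TRUE, ncol(X))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # alternate between two initialization families to diversify basins
    style <- if (r %% 2 == 0) "overcluster" else "kmeans"
    fit <- decompose_once(X, K, sparsity, n_iter, min_explained, seeds[r],
                          d_init = d_init, init_style = style, mask = mask)
    if (is.null(best) ||
        fit$coherence < best$coherence - 1e-12 ||
        (abs(fit$coherence - best$coherence) <= 1e-12 &&
         utils::tail(fit$error, 1) < utils::tail(best$error, 1))) {
      best <- fit
    }
  }
  best
}

decompose_once <- function(X, K, sparsity, n_iter, min_explained, seed,
                           d_init = NULL, init_style = "kmeans",
                           mask = rep(TRUE, ncol(X))) {
  with_seed(seed, {
    # init: warm start if given, otherwise centroids of the standardized
    # vertex time series — either plain k-means with K centers, or an
    # over-clustered (2K) solution reduced by greedy max-min selection,
    # which skips centroids sitting between two network cores
    cand <- which(apply(X, 2, sd) > 0 & mask)
    if (length(cand) < K) cand <- which(apply(X, 2, sd) > 0)
    D <- if (!is.null(d_init)) {
      d_init
    } else {
      tryCatch({
        if (init_style == "overcluster" && length(cand) >= 4 * K) {
          km <- suppressWarnings(
            stats::kmeans(t(scale(X[, cand, drop = FALSE])),
                          centers = 2L * K, nstart = 2, iter.max = 30))
          cen <- t(km$centers)
          cc <- abs(suppressWarnings(stats::cor(cen)))
          cc[!is.finite(cc)] <- 1
          sel <- which.max(tabulate(km$cluster, 2L * K))
          while (length(sel) < K) {
            candc <- setdiff(seq_len(2L * K), sel)
            mind <- vapply(candc, function(j) {
              min(1 - cc[j, sel])
            }, numeric(1))
            sel <- c(sel, candc[which.max(mind)])
          }
          cen[, sel, drop = FALSE]
        } else {
          km <- suppressWarnings(
            stats::kmeans(t(scale(X[, cand, drop = FALSE])),
                          centers = min(K, length(cand)), nstart = 2,
                          iter.max = 30))
          t(km$centers)
        }
      }, error = function(e) {
        X[, sample(cand, min(K, length(cand)), replace = length(cand) < K),
          drop = FALSE]
      })
    }
    if (ncol(D) < K) D <- cbind(D, matrix(rnorm(nrow(X) * (K - ncol(D))), nrow(X)))
    D <- sweep(D, 2, pmax(sqrt(colSums(D^2)), 1e-12), "/")
    C <- matrix(0, K, ncol(X))
    errors <- numeric(0)
    prev_err <- Inf
    for (it in seq_len(n_iter)) {
      C_new <- omp_code(D, X, sparsity, min_explained)
      # keep the better code per vertex (guarantees monotone error)
      err_new <- colSums((X - D %*% C_new)^2)
      err_old <- colSums((X - D %*% C)^2)
      worse <- err_new > err_old
      if (any(worse)) C_new[, worse] <- C[, worse]
      C <- C_new
      # atom-wise (K-SVD style) dictionary update: each atom is refit as the
      # rank-1 least-squares direction of its users' residual, with its
      # coefficients refreshed; unused atoms re-seed from the worst vertex
      R_full <- X - D %*% C
      for (k in seq_len(K)) {
        users <- which(C[k, ] != 0)
        if (length(users) == 0) {
          resid <- colSums(R_full^2)
          worst <- which.max(resid)
          d_new <- X[, worst]
          D[, k] <- d_new / max(sqrt(sum(d_new^2)), 1e-12)
          next
        }
        E <- R_full[, users, drop = FALSE] +
          D[, k, drop = FALSE] %*% C[k, users, drop = FALSE]
        d_new <- E %*% C[k, users]
        nrm <- sqrt(sum(d_new^2))
        if (nrm < 1e-12) next
        d_new <- d_new / nrm
        c_new <- as.numeric(crossprod(d_new, E))
        R_full[, users] <- E - d_new %*% t(c_new)
        D[, k] <- d_new
        C[k, users] <- c_new
      }
      err <- sum((X - D %*% C)^2)
      errors <- c(errors, err)
      if (is.finite(prev_err) && (prev_err - err) <= 1e-9 * max(prev_err, 1)) break
      prev_err <- err
    }
    # final coding with backward pruning of atoms whose unique contribution
    # is negligible (applied once the dictionary has converged)
    C <- omp_code(D, X, sparsity, min_explained, prune = TRUE)
    coherence <- if (K > 1) {
      cors <- suppressWarnings(stats::cor(D))
      cors[!is.finite(cors)] <- 0
      max(abs(cors[upper.tri(cors)]))
    } else {
      0
    }
    list(dictionary = D, coefficients = C, error = errors,
         coherence = coherence)
  })
}

#' Select the model order by penalized reconstruction error
#'
#' Fits the sparse decomposition on the original (non-bootstrapped) data for
#' each candidate order and scores it with a BIC-style criterion,
#' `T*V*log(MSE) + lambda * K * (T + V_active) * log(T*V)`, where `V_active`
#' is the mean support size per atom. The candidate minimizing the criterion
#' is returned; the full criterion curve is attached.
#'
#' @param ts A [bold_ts()].
#' @param k_min,k_max,k_step Search range (k_min >= 2) and increment.
#' @param lambda Penalty multiplier (default 1).
#' @param sparsity,n_iter,min_explained Decomposition settings.
#' @param seed Integer seed.
#' @return The selected integer K, with attribute `criterion`, a tibble of
#'   candidate K and criterion values.
#' @export
select_model_order <- function(ts, k_min, k_max, k_step = 2L, lambda = 1,
                               sparsity = 3L, n_iter = 15L,
                               min_explained = 0.2, n_restarts = 2L,
                               seed = 1L) {
  stopifnot(inherits(ts, "bold_ts"))
  k_min <- assert_positive_int(k_min, "k_min")
  k_max <- assert_positive_int(k_max, "k_max")
  if (k_min < 2) abort("`k_min` must be at least 2.", class = "netdax_error_argument")
  if (k_max >= nrow(ts$data)) {
    abort("`k_max` must be below the frame count.", class = "netdax_error_argument")
  }
  candidates <- seq(k_min, k_max, by = k_step)
  if (length(candidates) == 1L) {
    out <- candidates[1]
    attr(out, "criterion") <- tibble(K = candidates, criterion = NA_real_)
    return(out)
  }
  tv <- length(ts$data)
  crit <- vapply(seq_along(candidates), function(i) {
    k <- candidates[i]
    fit <- sparse_decompose(ts, k, sparsity = min(sparsity, k), n_iter = n_iter,
                            min_explained = min_explained,
                            n_restarts = n_restarts, seed = seed + i)
    mse <- sum((ts$data - fit$dictionary %*% fit$coefficients)^2) / tv
    v_active <- mean(rowSums(abs(fit$coefficients) > 1e-8))
    tv * log(max(mse, 1e-300)) + lambda * k * (nrow(ts$data) + v_active) * log(tv)
  }, numeric(1))
  out <- candidates[which.min(crit)]
  attr(out, "criterion") <- tibble(K = candidates, criterion = crit)
  out
}

#' Consensus clustering of bootstrap atoms
#'
#' Pools the spatial maps from all bootstrap decompositions, sign-aligns and
#' correlation-normalizes them, clusters them into K groups (k-means, 10
#' restarts), and summarizes each cluster: the consensus loading is the
#' cluster centroid of the raw maps, the consensus support keeps vertices
#' present in at least half the cluster members, and reproducibility is the
#' fraction of resamples contributing at least one atom to the cluster.
#' Clusters below the reproducibility threshold are dropped.
#'
#' @param bootstrap_atoms List (one element per resample) of K_b x V loading
#'   matrices.
#' @param K Number of consensus clusters.
#' @param reproducibility_threshold Retention threshold in `[0, 1]`.
#' @param epsilon Nonzero tolerance for supports.
#' @param seed Integer seed for k-means restarts.
#' @return An object of class `subject_networks` (without timecourses; see
#'   [estimate_networks()]).
#' @export
consensus_cluster <- function(bootstrap_atoms, K, reproducibility_threshold = 0.5,
                              epsilon = 1e-8, seed = 1L) {
  if (length(bootstrap_atoms) < 2) {
    abort("Need at least 2 bootstrap resamples.", class = "netdax_error_argument")
  }
  maps <- do.call(rbind, bootstrap_atoms)
  if (is.null(maps) || nrow(maps) == 0) {
    abort("Empty atom list.", class = "netdax_error_argument")
  }
  resample_id <- rep(seq_along(bootstrap_atoms),
                     vapply(bootstrap_atoms, nrow, integer(1)))
  # sign-align (dictionary sign ambiguity), then center/scale rows so k-means
  # distance behaves like correlation distance
  flip <- sign(rowSums(maps))
  flip[flip == 0] <- 1
  maps <- maps * flip
  norm <- maps - rowMeans(maps)
  rs <- sqrt(rowSums(norm^2))
  norm <- norm / pmax(rs, 1e-12)
  km <- with_seed(seed, stats::kmeans(norm, centers = min(K, nrow(norm)),
                                      nstart = 10, iter.max = 50))
  B <- length(bootstrap_atoms)
  keep <- list()
  for (cl in seq_len(max(km$cluster))) {
    members <- which(km$cluster == cl)
    if (length(members) == 0) next
    repro <- length(unique(resample_id[members])) / B
    if (repro < reproducibility_threshold) next
    centroid <- colMeans(maps[members, , drop = FALSE])
    presence <- colMeans(abs(maps[members, , drop = FALSE]) > epsilon)
    support <- presence >= 0.5
    loading <- centroid
    loading[!support] <- 0
    keep[[length(keep) + 1L]] <- list(loading = loading, support = support,
                                      repro = repro)
  }
  if (length(keep) == 0) {
    abort("No cluster met the reproducibility threshold.",
          class = "netdax_error_degenerate")
  }
  structure(
    list(
      loadings = do.call(rbind, lapply(keep, `[[`, "loading")),
      supports = do.call(rbind, lapply(keep, `[[`, "support")),
      reproducibility = vapply(keep, `[[`, numeric(1), "repro"),
      model_order = K,
      timecourses = NULL,
      epsilon = epsilon
    ),
    class = "subject_networks"
  )
}

#' @export
print.subject_networks <- function(x, ...) {
  cat(sprintf("<subject_networks> %d retained atoms (model order %d), %d vertices\n",
              nrow(x$loadings), x$model_order, ncol(x$loadings)))
  invisible(x)
}

#' Estimate reliable overlapping networks for one subject
#'
#' Runs the full single-subject pipeline: model-order selection on the
#' original series, B block-bootstrap resamples each decomposed into sparse
#' atoms, consensus clustering with reproducibility filtering, and a final
#' least-squares fit of the consensus timecourses on the original data. All
#' stage seeds are derived from the master seed.
#'
#' @param ts A [bold_ts()].
#' @param config A [decomp_config()].
#' @param seed Master integer seed.
#' @return A `subject_networks` object: `loadings` (atoms x vertices),
#'   `supports`, per-atom `reproducibility`, `model_order`, `timecourses`
#'   (T x atoms), `epsilon`.
#' @export
estimate_networks <- function(ts, config = decomp_config(), seed = 1L) {
  stopifnot(inherits(ts, "bold_ts"))
  seeds <- derive_seeds(seed, config$n_boot + 2L)
  K <- select_model_order(ts, config$k_min, config$k_max, config$k_step,
                          sparsity = config$sparsity, n_iter = config$n_iter,
                          min_explained = config$min_explained,
                          seed = seeds[1])
  # original-data fit: the reference solution whose stability the
  # bootstraps assess (and the warm start for each resample's decomposition)
  fit0 <- sparse_decompose(ts, K, sparsity = config$sparsity,
                           n_iter = config$n_iter,
                           min_explained = config$min_explained,
                           n_restarts = config$n_restarts,
                           seed = seeds[1])
  atoms <- vector("list", config$n_boot)
  for (b in seq_len(config$n_boot)) {
    bts <- block_bootstrap(ts, config$block_min_s, config$block_max_s,
                           seed = seeds[b + 1L])
    # warm start in the resample's time basis: the dictionary is a temporal
    # pattern, so it is resampled with the same frame indices
    d_init <- fit0$dictionary[attr(bts, "frames"), , drop = FALSE]
    d_init <- sweep(d_init, 2, pmax(sqrt(colSums(d_init^2)), 1e-12), "/")
    fit <- sparse_decompose(bts, K, sparsity = config$sparsity,
                            n_iter = config$n_iter,
                            min_explained = config$min_explained,
                            d_init = d_init,
                            seed = seeds[b + 1L])
    atoms[[b]] <- fit$coefficients
  }
  nets <- consensus_cluster(atoms, K, config$reproducibility_threshold,
                            epsilon = config$epsilon, seed = seeds[config$n_boot + 2L])
  # dictionary refit on the original series given consensus loadings
  L <- nets$loadings
  G <- tcrossprod(L) + diag(1e-10, nrow(L))
  nets$timecourses <- t(qr.solve(G, L %*% t(ts$data)))
  nets$order_criterion <- attr(K, "criterion")
  nets
}

#' Flag likely-noise atoms by gray-matter overlap
#'
#' An atom is flagged when more than half of its absolute loading mass lies
#' outside the gray-matter mask (boundary shell / out-of-brain zone).
#' Downstream stages accept the flag as an include/exclude switch; the default
#' analyses use the full atom set.
#'
#' @param nets A `subject_networks`.
#' @param geom A `toy_geometry` providing the gray-matter mask.
#' @return Logical vector, one flag per atom.
#' @export
flag_noise_atoms <- function(nets, geom) {
  stopifnot(inherits(nets, "subject_networks"), inherits(geom, "toy_geometry"))
  mass <- abs(nets$loadings)
  total <- rowSums(mass)
  outside <- rowSums(mass[, !geom$gm_mask, drop = FALSE])
  ifelse(total > 0, outside / total > 0.5, FALSE)
}

# Best one-to-one matching of atoms to reference networks by Dice; exhaustive
# over permutations for small K, greedy otherwise. Used by tests and recovery
# summaries.
match_atoms <- function(supports, reference) {
  d <- dice_matrix(supports, reference)
  k <- nrow(d)
  m <- ncol(d)
  if (m <= 7 && k >= m) {
    perms <- permutations_of(seq_len(k), m)
    scores <- vapply(perms, function(p) sum(d[cbind(p, seq_len(m))]), numeric(1))
    best <- perms[[which.max(scores)]]
    return(tibble(reference = seq_len(m), atom = best,
                  dice = d[cbind(best, seq_len(m))]))
  }
  # greedy fallback
  used <- integer(0)
  out <- integer(m)
  for (j in order(apply(d, 2, max), decreasing = TRUE)) {
    cand <- setdiff(order(d[, j], decreasing = TRUE), used)
    out[j] <- cand[1]
    used <- c(used, cand[1])
  }
  tibble(reference = seq_len(m), atom = out, dice = d[cbind(out, seq_len(m))])
}

permutations_of <- function(x, m) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i], m - 1L)
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}
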