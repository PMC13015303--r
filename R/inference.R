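#' One-sample tests of global deviation metrics with BH-FDR
#'
#' Two-sided one-sample t tests of each w-score column against zero (the
#' normative reference), with Benjamini-Hochberg false-discovery-rate
#' correction across the tested family. Zero-variance features get an
#' undefined p and are flagged rather than dropped silently.
#'
#' @param w Subjects x features matrix of w-scores (or tibble of numerics).
#' @param alpha FDR level (default 0.05).
#' @return A tibble: `feature`, `estimate` (mean w), `t`, `df`, `p`,
#'   `p_adj`, `significant`, `flag`.
#' @export
test_global_metrics <- function(w, alpha = 0.05) {
  w <- as.matrix(w)
  if (nrow(w) < 3) abort("Need at least 3 subjects.", class = "netdax_error_argument")
  feats <- colnames(w)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(w)))
  n <- nrow(w)
  m <- colMeans(w)
  s <- apply(w, 2, sd)
  tstat <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  p <- 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- p.adjust(p[ok], method = "BH")
  tibble(
    feature = feats, estimate = unname(m), t = unname(tstat), df = n - 1,
    p = unname(p), p_adj = unname(p_adj),
    significant = !is.na(p_adj) & p_adj < alpha,
    flag = ifelse(is.na(p), "zero_variance", NA_character_),
    method = "one_sample_t_BH"
  )
}

#' Max-T permutation tests across regions
#'
#' Family-wise-error-controlled tests of regional deviations. For the default
#' one-sample family the null is built by random sign flips of subject rows
#' (exchangeable under a symmetric null); for each permutation the maximum
#' absolute t across regions is recorded, and the corrected p of region r is
#' the add-one formula on that max-null distribution. A two-sample variant
#' (group-label shuffles) and a correlation variant (covariate shuffles)
#' reuse the same max-T machinery for subgroup contrasts and stage
#' associations. Constant columns are excluded with a flag.
#'
#' @param w Subjects x regions matrix.
#' @param n_perm Number of permutations (at least 100).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @param statistic "one_sample" (default), "two_sample", or "correlation".
#' @param group Factor/vector of two group labels (two-sample variant).
#' @param x Numeric covariate (correlation variant; the statistic is the
#'   Fisher-stabilized correlation).
#' @return A tibble: `region`, `estimate`, `t`, `p_raw`, `p_corrected`,
#'   `significant`, `flag`, plus `n_perm` and `seed` provenance columns.
#' @export
test_regional_maxT <- function(w, n_perm = 10000L, alpha = 0.05, seed = 1L,
                               statistic = c("one_sample", "two_sample", "correlation"),
                               group = NULL, x = NULL) {
  statistic <- match.arg(statistic)
  w <- as.matrix(w)
  n_perm <- assert_positive_int(n_perm, "n_perm")
  if (n_perm < 100) abort("Need at least 100 permutations.",
                          class = "netdax_error_argument")
  regions <- colnames(w)
  if (is.null(regions)) regions <- paste0("r", seq_len(ncol(w)))
  n <- nrow(w)
  constant <- apply(w, 2, function(v) sd(v) == 0 || !all(is.finite(v)))
  wt <- w[, !constant, drop = FALSE]
  r_use <- sum(!constant)

  stat_fun <- switch(statistic,
    one_sample = function(mat) {
      m <- colMeans(mat)
      s2 <- (colSums(mat^2) - n * m^2) / (n - 1)
      m / sqrt(s2 / n)
    },
    two_sample = function(mat, g) {
      i1 <- g == levels(factor(g))[1]
      n1 <- sum(i1); n2 <- sum(!i1)
      m1 <- colMeans(mat[i1, , drop = FALSE])
      m2 <- colMeans(mat[!i1, , drop = FALSE])
      v1 <- apply(mat[i1, , drop = FALSE], 2, var)
      v2 <- apply(mat[!i1, , drop = FALSE], 2, var)
      sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
    },
    correlation = function(mat, xv) {
      r <- as.numeric(cor(xv, mat))
      atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) * sqrt(n - 3)
    }
  )

  if (statistic == "one_sample") {
    t_obs <- stat_fun(wt)
    sumsq <- colSums(wt^2)
    null_abs <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
      M <- crossprod(signs, wt) / n          # n_perm x R means under flips
      S2 <- sweep(-n * M^2, 2, sumsq, "+") / (n - 1)
      abs(M / sqrt(S2 / n))
    })
  } else if (statistic == "two_sample") {
    if (is.null(group)) abort("two_sample needs `group`.", class = "netdax_error_argument")
    t_obs <- stat_fun(wt, group)
    null_abs <- with_seed(seed, {
      t(vapply(seq_len(n_perm), function(i) abs(stat_fun(wt, sample(group))),
               numeric(r_use)))
    })
  } else {
    if (is.null(x)) abort("correlation needs `x`.", class = "netdax_error_argument")
    t_obs <- stat_fun(wt, x)
    null_abs <- with_seed(seed, {
      t(vapply(seq_len(n_perm), function(i) abs(stat_fun(wt, sample(x))),
               numeric(r_use)))
    })
  }
  null_abs <- matrix(null_abs, n_perm, r_use)
  max_null <- apply(null_abs, 1, max)
  p_corr <- vapply(abs(t_obs), function(t0) (1 + sum(max_null >= t0)) / (1 + n_perm),
                   numeric(1))
  p_raw <- vapply(seq_along(t_obs), function(j) {
    (1 + sum(null_abs[, j] >= abs(t_obs[j]))) / (1 + n_perm)
  }, numeric(1))

  est <- rep(NA_real_, ncol(w)); tv <- rep(NA_real_, ncol(w))
  pr <- rep(NA_real_, ncol(w)); pc <- rep(NA_real_, ncol(w))
  est[!constant] <- if (statistic == "correlation") {
    as.numeric(cor(x, wt))
  } else {
    colMeans(wt)
  }
  tv[!constant] <- t_obs
  pr[!constant] <- p_raw
  pc[!constant] <- p_corr
  tibble(
    region = regions, estimate = unname(est), t = unname(tv),
    p_raw = unname(pr), p_corrected = unname(pc),
    significant = unname(!is.na(pc) & pc < alpha),
    flag = unname(ifelse(constant, "constant", NA_character_)),
    statistic = statistic, n_perm = n_perm, seed = as.integer(seed)
  )
}

#' Spin-corrected spatial similarity of two maps
#'
#' Pearson correlation between two parcel-indexed (or vertex-indexed) maps,
#' with a spatial null built by rotating the second map's positions on the
#' sphere and reassigning values by nearest rotated neighbor. The p-value is
#' two-sided on |r| with the add-one permutation formula.
#'
#' @param map_a,map_b Numeric vectors over the same parcels/vertices.
#' @param geom The shared `toy_geometry`; length-P maps use parcel centroids,
#'   length-V maps use vertex coordinates.
#' @param n_spins Number of rotations (default 1000).
#' @param seed Integer seed.
#' @return A one-row tibble: `r`, `p_spin`, `n_spins`.
#' @export
spatial_similarity <- function(map_a, map_b, geom, n_spins = 1000L, seed = 1L) {
  stopifnot(inherits(geom, "toy_geometry"))
  if (length(map_a) != length(map_b)) {
    abort("Maps have different lengths.", class = "netdax_error_shape")
  }
  if (sd(map_a) == 0 || sd(map_b) == 0) {
    abort("Correlation undefined for a constant map.",
          class = "netdax_error_degenerate")
  }
  coords <- if (length(map_a) == geom$n_parcels) {
    parcel_centroids(geom)
  } else if (length(map_a) == nrow(geom$coords)) {
    geom$coords
  } else {
    abort("Map length matches neither parcels nor vertices.",
          class = "netdax_error_shape")
  }
  coords <- coords / sqrt(rowSums(coords^2))
  r_obs <- cor(map_a, map_b)
  null_r <- with_seed(seed, {
    vapply(seq_len(n_spins), function(i) {
      nn <- spin_nearest(coords, random_rotation())
      cor(map_a, map_b[nn])
    }, numeric(1))
  })
  tibble(r = r_obs, p_spin = (1 + sum(abs(null_r) >= abs(r_obs))) / (1 + n_spins),
         n_spins = as.integer(n_spins))
}

parcel_centroids <- function(geom) {
  t(vapply(seq_len(geom$n_parcels), function(p) {
    colMeans(geom$coords[geom$parcel_id == p, , drop = FALSE])
  }, numeric(3)))
}

#' Similarity space of group feature vectors against a reference
#'
#' Places each group in a two-dimensional similarity space relative to a
#' reference profile (e.g., focal epilepsy): spatial pattern similarity
#' (Pearson r with the reference) on one axis and magnitude deviation (mean
#' absolute difference from the reference) on the other. When a `family`
#' vector is supplied, the two coordinates are computed separately per
#' feature family (e.g., correspondence vs k-hubness).
#'
#' @param groups Named list of numeric feature vectors (or a matrix with one
#'   column per group).
#' @param reference Numeric reference vector in the same feature order.
#' @param family Optional grouping vector over features.
#' @return A tibble: `group`, (`family`,) `r`, `mean_abs_diff`.
#' @export
similarity_space <- function(groups, reference, family = NULL) {
  if (is.matrix(groups)) {
    groups <- as.list(as.data.frame(groups))
  }
  rows <- imap(groups, function(g, nm) {
    if (length(g) != length(reference)) {
      abort("Group vector length differs from the reference.",
            class = "netdax_error_shape")
    }
    fam <- if (is.null(family)) rep("all", length(g)) else family
    map(unique(fam), function(f) {
      idx <- fam == f
      tibble(group = nm, family = f,
             r = cor(g[idx], reference[idx]),
             mean_abs_diff = mean(abs(g[idx] - reference[idx])))
    }) |> bind_rows()
  })
  out <- bind_rows(rows)
  if (is.null(family)) out$family <- NULL
  out
}

#' Spearman correlation with a two-variable variance inflation factor
#'
#' Convenience helper for comparing two staging variables: Spearman's rho,
#' its test p-value, and the VIF `1 / (1 - rho^2)` quantifying redundancy.
#'
#' @param x,y Numeric vectors.
#' @return A one-row tibble: `rho`, `p`, `vif`.
#' @export
spearman_vif <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  rho <- unname(ct$estimate)
  tibble(rho = rho, p = ct$p.value, vif = 1 / (1 - rho^2))
}
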