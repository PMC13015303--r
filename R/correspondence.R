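#' Dice similarity matrix between individualized and canonical networks
#'
#' Computes the K x M matrix of Dice coefficients
#' `D(k, m) = 2|A_k ∩ B_m| / (|A_k| + |B_m|)` between binary supports of an
#' individual's K networks and a canonical atlas's M networks. An
#' empty-vs-empty pair is defined as 0.
#'
#' @param nets A `subject_networks` object (see [estimate_networks()]) or a
#'   K x V logical support matrix.
#' @param atlas A `canonical_atlas` object or an M x V logical support matrix.
#'
#' @return A K x M numeric matrix with values in `[0, 1]`.
#' @export
dice_matrix <- function(nets, atlas) {
  a <- get_supports(nets)
  b <- get_supports(atlas)
  if (ncol(a) != ncol(b)) {
    abort("Networks and atlas live on different vertex spaces.",
          class = "netdax_error_shape")
  }
  inter <- tcrossprod(a * 1, b * 1)
  sizes <- outer(rowSums(a), rowSums(b), "+")
  d <- ifelse(sizes > 0, 2 * inter / sizes, 0)
  dimnames(d) <- list(rownames(a), rownames(b))
  d
}

get_supports <- function(x) {
  if (inherits(x, "subject_networks")) return(x$supports)
  if (inherits(x, "canonical_atlas")) return(x$supports)
  if (is.matrix(x) && is.logical(x)) return(x)
  if (is.matrix(x)) return(x != 0)
  abort("Expected a support matrix, subject_networks, or canonical_atlas.",
        class = "netdax_error_argument")
}

#' Summarize a Dice matrix into correspondence metrics
#'
#' Derives the three subject-level system-integrity metrics from a K x M Dice
#' matrix: canonical network representation (CNR, the column-wise maximum Dice
#' for each canonical network), normativity (the mean CNR across canonical
#' networks), and non-normativity (one minus the row-wise maximum, averaged
#' over the K individualized networks). Column-max ties are broken toward the
#' lowest atom index, which is recorded.
#'
#' @param D A K x M Dice matrix.
#' @return An object of class `correspondence_profile`: list with `cnr`
#'   (length M), `best_atom` (argmax atom per canonical network),
#'   `normativity` and `non_normativity` scalars.
#' @export
correspondence_profile <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 1 || ncol(D) < 1) {
    abort("Dice matrix must have at least one row and column.",
          class = "netdax_error_argument")
  }
  cnr <- apply(D, 2, max)
  best_atom <- apply(D, 2, which.max)  # lowest index on ties
  structure(
    list(
      cnr = cnr,
      best_atom = as.integer(best_atom),
      normativity = mean(cnr),
      non_normativity = mean(1 - apply(D, 1, max))
    ),
    class = "correspondence_profile"
  )
}

#' @export
print.correspondence_profile <- function(x, ...) {
  cat(sprintf("<correspondence_profile> M = %d, normativity = %.3f, non-normativity = %.3f\n",
              length(x$cnr), x$normativity, x$non_normativity))
  invisible(x)
}

#' Spin-based significance of network-atlas correspondences
#'
#' Builds a spatial null by applying random 3D rotations to the spherical
#' vertex cloud and reassigning atlas values by nearest rotated neighbor; each
#' rotation is a relabeling, so the null preserves the multiset of atlas
#' labels and their spatial autocorrelation. For every (atom, canonical
#' network) pair, the p-value is the add-one permutation formula on the Dice
#' overlap.
#'
#' @param nets Subject networks or K x V support matrix.
#' @param atlas Canonical atlas.
#' @param geom Toy geometry (vertices must lie on the unit sphere).
#' @param n_perm Number of rotations (default 1000).
#' @param seed Integer seed.
#'
#' @return A K x M matrix of p-values in `[1/(n_perm+1), 1]`.
#' @export
spin_significance <- function(nets, atlas, geom, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(geom, "toy_geometry"))
  if (max(abs(rowSums(geom$coords^2) - 1)) > 1e-6) {
    abort("Spin permutations require a spherical geometry.",
          class = "netdax_error_geometry")
  }
  obs <- dice_matrix(nets, atlas)
  a <- get_supports(nets)
  b <- get_supports(atlas)
  count <- matrix(0L, nrow(obs), ncol(obs))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      rot <- random_rotation()
      nn <- spin_nearest(geom$coords, rot)
      null_d <- dice_matrix(a, b[, nn, drop = FALSE])
      count <- count + (null_d >= obs)
    }
  })
  p <- (1 + count) / (1 + n_perm)
  dimnames(p) <- dimnames(obs)
  p
}

# One-to-one spin assignment: vertex i receives the value of the unclaimed
# vertex whose rotated position is nearest (greedy, most-constrained first).
# Because the assignment is a permutation, a spin is an exact relabeling —
# the multiset of atlas labels is preserved.
spin_nearest <- function(coords, rotation) {
  rotated <- coords %*% t(rotation)
  sim <- tcrossprod(coords, rotated)  # dot product = closeness on the sphere
  v <- nrow(coords)
  perm <- integer(v)
  taken <- rep(FALSE, v)
  # process receivers whose best match is tightest first
  order_i <- order(apply(sim, 1, max), decreasing = TRUE)
  for (i in order_i) {
    row <- sim[i, ]
    row[taken] <- -Inf
    j <- which.max(row)
    perm[i] <- j
    taken[j] <- TRUE
  }
  perm
}

#' Project an atlas-specific CNR profile into parcel space
#'
#' Distributes a per-canonical-network CNR vector over the geometry's parcels.
#' For label atlases, parcel value = sum over networks of CNR_m times the
#' fraction of the parcel's vertices carrying label m (unlabeled vertices
#' deflate the weights, consistent with normalizing by total parcel size).
#' For component atlases, a parcel is covered by a component if any of its
#' vertices lies in the component's positive-weight mask; the parcel value is
#' the mean CNR over covering components, and uncovered parcels get value 0
#' with `covered = FALSE`.
#'
#' @param profile A [correspondence_profile()] for this atlas.
#' @param atlas The `canonical_atlas` the profile was computed against.
#' @param geom The shared `toy_geometry`.
#'
#' @return A tibble with one row per parcel: `parcel`, `value`, `covered`.
#' @export
map_to_parcels <- function(profile, atlas, geom) {
  stopifnot(inherits(profile, "correspondence_profile"),
            inherits(atlas, "canonical_atlas"),
            inherits(geom, "toy_geometry"))
  if (length(profile$cnr) != atlas$M) {
    abort("Profile length does not match the atlas network count.",
          class = "netdax_error_shape")
  }
  p_sizes <- tabulate(geom$parcel_id, geom$n_parcels)
  if (any(p_sizes == 0)) {
    abort("Geometry contains an empty parcel.", class = "netdax_error_geometry")
  }
  if (atlas$kind == "label") {
    # W(m, p) = |network m ∩ parcel p| / |parcel p|
    counts <- table(factor(atlas$labels, levels = 0:atlas$M),
                    factor(geom$parcel_id, levels = seq_len(geom$n_parcels)))
    W <- sweep(unclass(counts)[-1, , drop = FALSE], 2, p_sizes, "/")
    value <- as.numeric(crossprod(W, profile$cnr))
    covered <- colSums(W) > 0
  } else {
    covers <- vapply(seq_len(geom$n_parcels), function(p) {
      idx <- geom$parcel_id == p
      rowSums(atlas$supports[, idx, drop = FALSE]) > 0
    }, logical(atlas$M))
    n_cov <- colSums(covers)
    value <- ifelse(n_cov > 0,
                    as.numeric(crossprod(covers, profile$cnr)) / pmax(n_cov, 1),
                    0)
    covered <- n_cov > 0
  }
  tibble(parcel = seq_len(geom$n_parcels), value = value, covered = covered)
}

#' Cross-atlas consensus correspondence map
#'
#' Averages parcel-wise correspondence values across atlases, for each parcel
#' using only the atlases that cover it, and summarizes the consensus profile
#' at the level of the geometry's 17-network partition (parcels with no
#' coverage are flagged missing and excluded from network means).
#'
#' @param parcel_profiles List of [map_to_parcels()] tibbles, one per atlas.
#' @param geom The shared `toy_geometry`.
#'
#' @return An object of class `consensus_map`: list with `parcels` (tibble:
#'   parcel, value, n_atlases, missing) and `networks` (tibble: network,
#'   value).
#' @export
consensus_map <- function(parcel_profiles, geom) {
  stopifnot(inherits(geom, "toy_geometry"))
  if (length(parcel_profiles) < 1) {
    abort("Need at least one atlas profile.", class = "netdax_error_argument")
  }
  vals <- vapply(parcel_profiles, function(x) x$value, numeric(geom$n_parcels))
  cov <- vapply(parcel_profiles, function(x) x$covered, logical(geom$n_parcels))
  vals <- matrix(vals, nrow = geom$n_parcels)
  cov <- matrix(cov, nrow = geom$n_parcels)
  n_atlases <- rowSums(cov)
  value <- ifelse(n_atlases > 0, rowSums(vals * cov) / pmax(n_atlases, 1), NA_real_)
  parcels <- tibble(
    parcel = seq_len(geom$n_parcels),
    value = value,
    n_atlases = as.integer(n_atlases),
    missing = n_atlases == 0
  )
  networks <- parcels |>
    mutate(network = geom$network17_id[.data$parcel]) |>
    filter(!.data$missing) |>
    group_by(.data$network) |>
    summarise(value = mean(.data$value), n_parcels = dplyr::n(), .groups = "drop")
  structure(list(parcels = parcels, networks = networks), class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("<consensus_map> %d parcels (%d missing), %d networks summarized\n",
              nrow(x$parcels), sum(x$parcels$missing), nrow(x$networks)))
  invisible(x)
}

#' Subcortical correspondence (volumetric Dice, no spin inference)
#'
#' Dice overlap of each atom with the 14 emulated subcortical regions, plus
#' the per-region CNR (best Dice across atoms) and its bilateral-pair mean
#' (seven features). Spatial rotation nulls do not apply to volumetric
#' subcortex, so no significance is attached.
#'
#' @param nets Subject networks or K x V support matrix.
#' @param geom Toy geometry carrying `subcortical_id`.
#' @return A list with `dice` (K x 14), `cnr` (length 14) and `cnr_bilateral`
#'   (length 7, left/right pair means).
#' @export
subcortical_dice <- function(nets, geom) {
  stopifnot(inherits(geom, "toy_geometry"))
  masks <- t(vapply(1:14, function(r) geom$subcortical_id == r,
                    logical(length(geom$subcortical_id))))
  d <- dice_matrix(nets, masks)
  cnr <- apply(d, 2, max)
  list(
    dice = d,
    cnr = cnr,
    cnr_bilateral = (cnr[1:7] + cnr[8:14]) / 2
  )
}
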