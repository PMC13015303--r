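#' Build a toy spherical geometry with parcels, hemispheres and subcortical labels
#'
#' Constructs a unit-sphere point cloud standing in for a cortical surface:
#' vertices are partitioned into spatially contiguous parcels (nearest-centroid
#' patches, never spanning hemispheres), each parcel is assigned to one of 17
#' canonical networks, a gray-matter mask marks a boundary shell as non-GM, and
#' a reserved polar band emulates 14 subcortical regions (seven per
#' hemisphere). One geometry serves the whole pipeline: spin permutations,
#' parcel aggregation, and synthetic BOLD all share the same vertex space.
#'
#' @param n_vertices Number of vertices (points on the unit sphere).
#' @param n_parcels Number of parcels; must not exceed `n_vertices / 4`.
#' @param seed Integer seed; the geometry is deterministic given the seed.
#'
#' @return An object of class `toy_geometry`: a list with `coords` (n x 3 unit
#'   vectors), `parcel_id` (1..P per vertex), `network17_id` (length-P map of
#'   parcels to 17 networks), `hemisphere` ("L"/"R" per vertex, split at x = 0),
#'   `gm_mask` (logical per vertex), and `subcortical_id` (0..14 per vertex,
#'   0 = cortical).
#' @export
make_geometry <- function(n_vertices, n_parcels, seed) {
  n_vertices <- assert_positive_int(n_vertices, "n_vertices")
  n_parcels <- assert_positive_int(n_parcels, "n_parcels")
  if (n_parcels > n_vertices / 4) {
    abort("`n_parcels` must be at most n_vertices / 4.",
          class = "netdax_error_argument")
  }
  if (n_vertices < 60) {
    abort("Need at least 60 vertices to carve out hemispheres and subcortical bands.",
          class = "netdax_error_argument")
  }
  with_seed(seed, {
    coords <- matrix(rnorm(n_vertices * 3), ncol = 3)
    coords <- coords / sqrt(rowSums(coords^2))
    # avoid vertices exactly on the hemisphere boundary
    coords[abs(coords[, 1]) < 1e-6, 1] <- 1e-6
    hemisphere <- ifelse(coords[, 1] < 0, "L", "R")

    # Subcortical band: the vertices closest to the north pole, split by
    # hemisphere into seven slabs each (ids 1-7 left, 8-14 right).
    subcortical_id <- integer(n_vertices)
    n_sub_per_hemi <- max(7L, round(0.04 * n_vertices))
    for (h in c("L", "R")) {
      idx <- which(hemisphere == h)
      if (length(idx) < n_sub_per_hemi) {
        abort("Hemisphere too small to host subcortical band.",
              class = "netdax_error_argument")
      }
      band <- idx[order(coords[idx, 3], decreasing = TRUE)[seq_len(n_sub_per_hemi)]]
      # slice the band by azimuthal angle into 7 contiguous regions
      ang <- atan2(coords[band, 2], coords[band, 1])
      grp <- cut(rank(ang, ties.method = "first"), breaks = 7, labels = FALSE)
      subcortical_id[band] <- grp + ifelse(h == "L", 0L, 7L)
    }

    # Gray-matter mask: a southern cap stands in for the boundary shell /
    # out-of-brain zone; subcortical vertices are gray matter.
    gm_mask <- coords[, 3] > -0.85 | subcortical_id > 0

    # Parcels: nearest-centroid patches within hemisphere. Allocate parcel
    # counts proportionally to hemisphere sizes (at least one each).
    n_left <- sum(hemisphere == "L")
    p_left <- min(max(1L, round(n_parcels * n_left / n_vertices)), n_parcels - 1L)
    p_count <- c(L = p_left, R = n_parcels - p_left)
    parcel_id <- integer(n_vertices)
    offset <- 0L
    for (h in c("L", "R")) {
      idx <- which(hemisphere == h)
      centers <- sample(idx, p_count[[h]])
      d <- cross_dist(coords[idx, , drop = FALSE], coords[centers, , drop = FALSE])
      parcel_id[idx] <- as.integer(max.col(-d, ties.method = "first") + offset)
      offset <- offset + as.integer(p_count[[h]])
    }

    # Parcel -> 17-network assignment, cycling so all ids 1..17 are used when
    # P >= 17; homotopic pairing is approximated by cycling within hemisphere.
    network17_id <- ((seq_len(n_parcels) - 1L) %% 17L) + 1L

    structure(
      list(
        coords = coords,
        parcel_id = parcel_id,
        network17_id = network17_id,
        hemisphere = hemisphere,
        gm_mask = gm_mask,
        subcortical_id = subcortical_id,
        n_parcels = n_parcels
      ),
      class = "toy_geometry"
    )
  })
}

#' @export
print.toy_geometry <- function(x, ...) {
  cat(sprintf(
    "<toy_geometry> %d vertices, %d parcels, %d/%d L/R, %d gm, %d subcortical\n",
    nrow(x$coords), x$n_parcels, sum(x$hemisphere == "L"),
    sum(x$hemisphere == "R"), sum(x$gm_mask), sum(x$subcortical_id > 0)
  ))
  invisible(x)
}

#' Generate canonical atlases on a toy geometry
#'
#' Emulates the two families of canonical intrinsic-connectivity-network
#' atlases the correspondence stage supports: label atlases, which partition
#' (a subset of) vertices into M non-overlapping networks, and component
#' atlases, whose M spatial weight maps may overlap; a component's support is
#' the set of vertices with weight > 0.
#'
#' @param geom A [make_geometry()] object.
#' @param label_specs Integer vector: one label atlas per element, with that
#'   many networks. Each must be at least 2 and at most the parcel count.
#' @param component_specs Integer vector: one component atlas per element.
#' @param seed Integer seed.
#'
#' @return A list of `canonical_atlas` objects. Each has `name`, `kind`
#'   ("label" or "component"), `M`, and either `labels` (0..M per vertex,
#'   0 = unlabeled) or `weights` (M x V, non-negative) plus `supports`
#'   (M x V logical).
#' @export
make_atlases <- function(geom, label_specs = integer(), component_specs = integer(), seed = 1L) {
  stopifnot(inherits(geom, "toy_geometry"))
  if (any(c(label_specs, component_specs) < 2)) {
    abort("Every atlas must have at least 2 networks.", class = "netdax_error_argument")
  }
  if (any(label_specs > geom$n_parcels)) {
    abort("Label atlas network count cannot exceed the parcel count.",
          class = "netdax_error_argument")
  }
  v <- nrow(geom$coords)
  seeds <- derive_seeds(seed, length(label_specs) + length(component_specs))
  atlases <- list()
  i_seed <- 1L
  for (m in label_specs) {
    atlases[[length(atlases) + 1L]] <- with_seed(seeds[i_seed], {
      # group parcels into M networks by nearest network-seed parcel centroid
      centroids <- t(vapply(seq_len(geom$n_parcels), function(p) {
        colMeans(geom$coords[geom$parcel_id == p, , drop = FALSE])
      }, numeric(3)))
      seeds_p <- sample(geom$n_parcels, m)
      assign_p <- max.col(-cross_dist(centroids, centroids[seeds_p, , drop = FALSE]),
                          ties.method = "first")
      labels <- assign_p[geom$parcel_id]
      labels[!geom$gm_mask] <- 0L  # unlabeled vertices belong to no network
      supports <- t(vapply(seq_len(m), function(k) labels == k, logical(v)))
      structure(
        list(name = sprintf("label%d", m), kind = "label", M = m,
             labels = labels, supports = supports),
        class = "canonical_atlas"
      )
    })
    i_seed <- i_seed + 1L
  }
  for (m in component_specs) {
    atlases[[length(atlases) + 1L]] <- with_seed(seeds[i_seed], {
      centers <- geom$coords[sample(which(geom$gm_mask), m), , drop = FALSE]
      # smooth radial bumps truncated at a radius; components may overlap
      d <- cross_dist(centers, geom$coords)
      radius <- runif(m, 0.6, 1.1)
      weights <- 1 - sweep(d, 1, radius, "/")
      weights[weights < 0] <- 0
      weights[, !geom$gm_mask] <- 0
      structure(
        list(name = sprintf("comp%d", m), kind = "component", M = m,
             weights = weights, supports = weights > 0),
        class = "canonical_atlas"
      )
    })
    i_seed <- i_seed + 1L
  }
  atlases
}

#' @export
print.canonical_atlas <- function(x, ...) {
  cat(sprintf("<canonical_atlas> %s (%s), M = %d\n", x$name, x$kind, x$M))
  invisible(x)
}
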