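#' Voxel-wise k-hubness from overlapping networks
#'
#' k-hubness counts, per vertex, the retained consensus atoms with loading
#' magnitude above the nonzero tolerance. A vertex with k = 1 belongs to a
#' single network; k >= 2 marks multi-network participation — a connector
#' hub linking distinct functional systems.
#'
#' @param nets A `subject_networks` or a loadings matrix (atoms x vertices).
#' @param epsilon Nonzero tolerance; defaults to the tolerance stored in
#'   `nets`.
#' @return An object of class `khubness_map`: list with `k` (integer per
#'   vertex) and `epsilon`.
#' @export
compute_khubness_map <- function(nets, epsilon = NULL) {
  loadings <- if (inherits(nets, "subject_networks")) nets$loadings else as.matrix(nets)
  if (is.null(dim(loadings)) || nrow(loadings) < 1) {
    abort("Need at least one atom.", class = "netdax_error_argument")
  }
  if (is.null(epsilon)) {
    epsilon <- if (inherits(nets, "subject_networks")) nets$epsilon else 1e-8
  }
  structure(
    list(k = as.integer(colSums(abs(loadings) > epsilon)), epsilon = epsilon),
    class = "khubness_map"
  )
}

#' @export
print.khubness_map <- function(x, ...) {
  cat(sprintf("<khubness_map> %d vertices, k range %d..%d, %.1f%% connector (k>=2)\n",
              length(x$k), min(x$k), max(x$k), 100 * mean(x$k >= 2)))
  invisible(x)
}

#' Region and network summaries of a k-hubness map
#'
#' Averages voxel-wise k over gray-matter member vertices of each region. Two
#' region families are summarized: the 34 hemisphere-split cortical networks
#' (the 17-network partition split into left/right homologues) and the 14
#' subcortical regions. Regions with no gray-matter vertices are reported as
#' missing (`NA`), not zero.
#'
#' @param kmap A [compute_khubness_map()] result.
#' @param geom The shared `toy_geometry`.
#' @return A tibble with `region` (e.g. `"net03_L"`, `"subcortical_05"`),
#'   `family` ("cortical" or "subcortical"), `mean_k`, `n_vertices`.
#' @export
summarize_khubness <- function(kmap, geom) {
  stopifnot(inherits(kmap, "khubness_map"), inherits(geom, "toy_geometry"))
  if (length(kmap$k) != nrow(geom$coords)) {
    abort("k map and geometry live on different vertex spaces.",
          class = "netdax_error_shape")
  }
  k <- kmap$k
  gm <- geom$gm_mask
  cortical <- geom$subcortical_id == 0
  net_of_vertex <- geom$network17_id[geom$parcel_id]
  rows <- list()
  for (net in 1:17) {
    for (h in c("L", "R")) {
      idx <- which(gm & cortical & net_of_vertex == net & geom$hemisphere == h)
      rows[[length(rows) + 1L]] <- tibble(
        region = sprintf("net%02d_%s", net, h), family = "cortical",
        mean_k = if (length(idx)) mean(k[idx]) else NA_real_,
        n_vertices = length(idx)
      )
    }
  }
  for (r in 1:14) {
    idx <- which(gm & geom$subcortical_id == r)
    rows[[length(rows) + 1L]] <- tibble(
      region = sprintf("subcortical_%02d", r), family = "subcortical",
      mean_k = if (length(idx)) mean(k[idx]) else NA_real_,
      n_vertices = length(idx)
    )
  }
  bind_rows(rows)
}
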