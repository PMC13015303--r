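# Vertex clouds are embedded into a cubic voxel grid (raster order) so maps
# and BOLD series can round-trip through NIfTI; the sidecar JSON records the
# true vertex count and TR.

grid_side <- function(n_vertices) as.integer(ceiling(n_vertices^(1 / 3)))

vertex_to_grid <- function(values, n_vertices) {
  side <- grid_side(n_vertices)
  arr <- array(0, dim = c(side, side, side))
  arr[seq_len(n_vertices)] <- values
  arr
}

grid_to_vertex <- function(arr, n_vertices) {
  as.numeric(arr)[seq_len(n_vertices)]
}

#' Write / read a BOLD series as 4D NIfTI with a JSON sidecar
#'
#' @param ts A [bold_ts()].
#' @param path Output path (`.nii.gz`); the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(ts, path) {
  stopifnot(inherits(ts, "bold_ts"))
  v <- ncol(ts$data)
  side <- grid_side(v)
  arr <- array(0, dim = c(side, side, side, nrow(ts$data)))
  for (t in seq_len(nrow(ts$data))) {
    arr[, , , t][seq_len(v)] <- ts$data[t, ]
  }
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(1, 1, 1, ts$tr)), path)
  meta <- list(n_vertices = v, tr = ts$tr, mask = which(ts$mask))
  if (!is.null(ts$fd)) meta$fd <- ts$fd
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- RNifti::readNifti(path)
  v <- meta$n_vertices
  t_frames <- dim(arr)[4]
  data <- t(vapply(seq_len(t_frames), function(t) {
    as.numeric(arr[, , , t])[seq_len(v)]
  }, numeric(v)))
  mask <- rep(FALSE, v)
  mask[meta$mask] <- TRUE
  bold_ts(data, tr = meta$tr, mask = mask, fd = meta$fd)
}

#' Write / read a per-vertex map as 3D NIfTI
#'
#' @param values Numeric/integer vector over vertices.
#' @param n_vertices Vertex count (read side).
#' @param path File path (`.nii.gz`).
#' @return `path` / numeric vector.
#' @export
write_map_nifti <- function(values, path) {
  arr <- vertex_to_grid(values, length(values))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path, n_vertices) {
  grid_to_vertex(RNifti::readNifti(path), n_vertices)
}

#' Write / read a toy geometry as TSV + JSON
#'
#' The per-vertex table goes to `<stem>.tsv`, the parcel-level network map to
#' `<stem>.json`; round-trips losslessly.
#'
#' @param geom A `toy_geometry`.
#' @param stem Path stem (without extension).
#' @return `stem` / a `toy_geometry`.
#' @export
write_geometry <- function(geom, stem) {
  tbl <- tibble(
    x = geom$coords[, 1], y = geom$coords[, 2], z = geom$coords[, 3],
    parcel_id = geom$parcel_id, hemisphere = geom$hemisphere,
    gm_mask = geom$gm_mask, subcortical_id = geom$subcortical_id
  )
  readr::write_tsv(tbl, paste0(stem, ".tsv"))
  jsonlite::write_json(list(n_parcels = geom$n_parcels,
                            network17_id = geom$network17_id),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(stem) {
  tbl <- readr::read_tsv(paste0(stem, ".tsv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(
    list(
      coords = cbind(tbl$x, tbl$y, tbl$z),
      parcel_id = as.integer(tbl$parcel_id),
      network17_id = as.integer(meta$network17_id),
      hemisphere = tbl$hemisphere,
      gm_mask = tbl$gm_mask,
      subcortical_id = as.integer(tbl$subcortical_id),
      n_parcels = as.integer(meta$n_parcels)
    ),
    class = "toy_geometry"
  )
}

#' Write / read a canonical atlas (NIfTI maps + JSON metadata)
#'
#' Label atlases are stored as a 3D label volume; component atlases as a 4D
#' weight volume.
#'
#' @param atlas A `canonical_atlas`.
#' @param stem Path stem.
#' @return `stem` / a `canonical_atlas`.
#' @export
write_atlas <- function(atlas, stem) {
  if (atlas$kind == "label") {
    v <- length(atlas$labels)
    write_map_nifti(atlas$labels, paste0(stem, ".nii.gz"))
  } else {
    v <- ncol(atlas$weights)
    side <- grid_side(v)
    arr <- array(0, dim = c(side, side, side, atlas$M))
    for (m in seq_len(atlas$M)) arr[, , , m][seq_len(v)] <- atlas$weights[m, ]
    RNifti::writeNifti(RNifti::asNifti(arr), paste0(stem, ".nii.gz"))
  }
  jsonlite::write_json(list(name = atlas$name, kind = atlas$kind, M = atlas$M,
                            n_vertices = v),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  v <- meta$n_vertices
  if (meta$kind == "label") {
    labels <- as.integer(read_map_nifti(paste0(stem, ".nii.gz"), v))
    supports <- t(vapply(seq_len(meta$M), function(k) labels == k, logical(v)))
    out <- list(name = meta$name, kind = "label", M = meta$M,
                labels = labels, supports = supports)
  } else {
    arr <- RNifti::readNifti(paste0(stem, ".nii.gz"))
    weights <- t(vapply(seq_len(meta$M), function(m) {
      as.numeric(arr[, , , m])[seq_len(v)]
    }, numeric(v)))
    out <- list(name = meta$name, kind = "component", M = meta$M,
                weights = weights, supports = weights > 0)
  }
  structure(out, class = "canonical_atlas")
}

valid_group_labels <- function() {
  c("HP", "focal", "TLE-L", "TLE-R", "EXE", "GGE", "SeLECTS", "AE")
}

#' Validate and load pipeline inputs from disk
#'
#' Reads the geometry, cohort table, atlases and per-subject BOLD series
#' written by [write_inputs()], validating as it goes: duplicate subject ids,
#' group labels outside the closed set, missing covariate columns, and
#' BOLD/geometry shape mismatches each raise a distinct error. Subjects whose
#' frame count falls below `min_frames` are flagged, not dropped.
#'
#' @param dir Input directory.
#' @param min_frames Minimum acceptable frame count (default 0, no check).
#' @return A list: `geom`, `cohort` (with a `flagged_short` column), `atlases`,
#'   `bold` (named list of [bold_ts()]).
#' @export
load_inputs <- function(dir, min_frames = 0L) {
  geom <- read_geometry(file.path(dir, "geometry"))
  cohort <- readr::read_tsv(file.path(dir, "cohort.tsv"), show_col_types = FALSE)
  if (anyDuplicated(cohort$subject_id)) {
    abort("Duplicate subject ids in the cohort table.",
          class = "netdax_error_duplicate_id")
  }
  bad_groups <- setdiff(unique(cohort$group), valid_group_labels())
  if (length(bad_groups) > 0) {
    abort(sprintf("Unknown group label(s): %s", paste(bad_groups, collapse = ", ")),
          class = "netdax_error_group")
  }
  needed <- c("subject_id", "group", "age", "sex", "motion")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing covariate column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "netdax_error_missing_covariate")
  }
  atlas_meta <- list.files(dir, pattern = "^atlas[0-9]+\\.json$", full.names = TRUE)
  atlases <- lapply(sub("\\.json$", "", sort(atlas_meta)), read_atlas)
  bold <- list()
  flagged <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    path <- file.path(dir, "bold", paste0(cohort$subject_id[i], ".nii.gz"))
    ts <- read_bold_nifti(path)
    if (ncol(ts$data) != nrow(geom$coords)) {
      abort(sprintf("BOLD/geometry vertex mismatch for %s.", cohort$subject_id[i]),
            class = "netdax_error_shape")
    }
    flagged[i] <- nrow(ts$data) < min_frames
    bold[[cohort$subject_id[i]]] <- ts
  }
  cohort$flagged_short <- flagged
  list(geom = geom, cohort = cohort, atlases = atlases, bold = bold)
}

#' Write a simulated input bundle to disk
#'
#' Inverse of [load_inputs()]: geometry TSV/JSON, cohort TSV, atlases and
#' per-subject BOLD as NIfTI, and the ground-truth ledger as JSON.
#'
#' @param sim A list with `geom`, `cohort`, `atlases`, `bold`, and optionally
#'   `truth`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_inputs <- function(sim, dir) {
  dir.create(file.path(dir, "bold"), recursive = TRUE, showWarnings = FALSE)
  write_geometry(sim$geom, file.path(dir, "geometry"))
  readr::write_tsv(sim$cohort, file.path(dir, "cohort.tsv"))
  for (i in seq_along(sim$atlases)) {
    write_atlas(sim$atlases[[i]], file.path(dir, sprintf("atlas%02d", i)))
  }
  for (id in names(sim$bold)) {
    write_bold_nifti(sim$bold[[id]], file.path(dir, "bold", paste0(id, ".nii.gz")))
  }
  if (!is.null(sim$truth)) {
    jsonlite::write_json(serializable_truth(sim$truth),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

serializable_truth <- function(truth) {
  lapply(truth, function(x) {
    if (is.matrix(x)) apply(x, 1, identity, simplify = FALSE) else unclass(x)
  })
}
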