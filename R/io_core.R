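# Readers/writers for skeleton graphs, surface clouds, image stacks, depth
# profiles, and the analysis configuration. All coordinates are in microns,
# 0-based, right-handed, z increasing with slice index.

cond_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "coroalign_error")))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    cond_error(sprintf("%s is missing column(s): %s", what,
                       paste(missing, collapse = ", ")),
               "coroalign_format_error")
  }
}

#' Construct and validate a vessel skeleton graph
#'
#' A skeleton graph is the centerline representation of a segmented vessel
#' volume: nodes (branch/end points), segments (edges between two nodes) and
#' ordered points tracing each segment's polyline, all in microns.
#'
#' @param nodes data.frame with columns `node_id`, `x_um`, `y_um`, `z_um`.
#' @param segments data.frame with columns `segment_id`, `start_node_id`,
#'   `end_node_id`.
#' @param points data.frame with columns `segment_id`, `point_order`,
#'   `x_um`, `y_um`, `z_um` and optionally `radius_um`.
#' @return object of class `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes, segments, points) {
  require_columns(nodes, c("node_id", "x_um", "y_um", "z_um"), "node table")
  require_columns(segments, c("segment_id", "start_node_id", "end_node_id"),
                  "segment table")
  require_columns(points, c("segment_id", "point_order", "x_um", "y_um", "z_um"),
                  "point table")
  if (anyDuplicated(nodes$node_id)) {
    cond_error("duplicate node ids", "coroalign_integrity_error")
  }
  if (anyDuplicated(segments$segment_id)) {
    cond_error("duplicate segment ids", "coroalign_integrity_error")
  }
  bad <- setdiff(c(segments$start_node_id, segments$end_node_id), nodes$node_id)
  if (length(bad) > 0) {
    cond_error(sprintf("segment references unknown node id(s): %s",
                       paste(sort(bad), collapse = ", ")),
               "coroalign_integrity_error")
  }
  pts <- split(points, factor(points$segment_id, levels = segments$segment_id))
  node_xyz <- as.matrix(nodes[c("x_um", "y_um", "z_um")])
  rownames(node_xyz) <- as.character(nodes$node_id)
  for (i in seq_len(nrow(segments))) {
    p <- pts[[i]]
    if (is.null(p) || nrow(p) < 2) {
      cond_error(sprintf("segment %s has fewer than 2 points",
                         segments$segment_id[i]), "coroalign_integrity_error")
    }
    p <- p[order(p$point_order), , drop = FALSE]
    ends <- rbind(node_xyz[as.character(segments$start_node_id[i]), ],
                  node_xyz[as.character(segments$end_node_id[i]), ])
    got <- as.matrix(p[c(1, nrow(p)), c("x_um", "y_um", "z_um")])
    if (max(abs(got - ends)) > 1e-6) {
      cond_error(sprintf(
        "segment %s endpoints do not coincide with its nodes (tol 1e-6 um)",
        segments$segment_id[i]), "coroalign_integrity_error")
    }
  }
  points <- points[order(match(points$segment_id, segments$segment_id),
                         points$point_order), , drop = FALSE]
  rownames(points) <- NULL
  structure(list(nodes = nodes, segments = segments, points = points),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d segments, %d points\n",
              nrow(x$nodes), nrow(x$segments), nrow(x$points)))
  invisible(x)
}

#' Read a skeleton graph from a three-table delimited layout
#'
#' The on-disk dialect is a directory containing `nodes.csv`, `segments.csv`
#' and `points.csv` with the column layout of [skeleton_graph()]. A plain
#' table dialect is tool-agnostic and diffable, unlike the proprietary scene
#' formats skeletonization tools export.
#'
#' @param path directory containing the three CSV files.
#' @return a validated `skeleton_graph`.
#' @export
read_skeleton <- function(path) {
  files <- file.path(path, c("nodes.csv", "segments.csv", "points.csv"))
  ok <- file.exists(files)
  if (!all(ok)) {
    cond_error(sprintf("missing skeleton table(s): %s",
                       paste(basename(files[!ok]), collapse = ", ")),
               "coroalign_format_error")
  }
  skeleton_graph(utils::read.csv(files[1]), utils::read.csv(files[2]),
                 utils::read.csv(files[3]))
}

#' Write a skeleton graph as three CSV tables
#'
#' @param graph a `skeleton_graph`.
#' @param path directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(graph, path) {
  stopifnot(inherits(graph, "skeleton_graph"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(graph$nodes, file.path(path, "nodes.csv"), row.names = FALSE)
  utils::write.csv(graph$segments, file.path(path, "segments.csv"),
                   row.names = FALSE)
  utils::write.csv(graph$points, file.path(path, "points.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read / write an epicardial surface point cloud
#'
#' CSV with columns `x_um`, `y_um`, `z_um`.
#'
#' @param path CSV file path.
#' @return numeric matrix with columns x, y, z (microns).
#' @export
read_surface <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("x_um", "y_um", "z_um"), "surface table")
  m <- as.matrix(df[c("x_um", "y_um", "z_um")])
  if (nrow(m) == 0 || !all(is.finite(m))) {
    cond_error("surface cloud must be non-empty with finite coordinates",
               "coroalign_integrity_error")
  }
  m
}

#' @rdname read_surface
#' @param surface numeric matrix/data.frame of surface points (microns).
#' @export
write_surface <- function(surface, path) {
  m <- as.matrix(surface)
  colnames(m) <- c("x_um", "y_um", "z_um")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Construct an image stack
#'
#' @param data 3D numeric array indexed `[row(y), col(x), slice(z)]` (a 2D
#'   matrix is promoted to a single-slice stack).
#' @param voxel voxel size `c(dx, dy, dz)` in microns.
#' @param origin coordinate of the stack corner (micron offset of the first
#'   voxel's lower corner).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(data, voxel, origin = c(0, 0, 0)) {
  if (length(dim(data)) == 2) data <- array(data, c(dim(data), 1))
  stopifnot(length(dim(data)) == 3, length(voxel) == 3, all(voxel > 0),
            all(dim(data) >= 1), length(origin) == 3)
  structure(list(data = data, voxel = as.numeric(voxel),
                 origin = as.numeric(origin)), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels, voxel %.3g x %.3g x %.3g um\n",
              d[2], d[1], d[3], x$voxel[1], x$voxel[2], x$voxel[3]))
  invisible(x)
}

stack_sidecar <- function(path) paste0(path, ".json")

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Voxel sizes come from the JSON sidecar written by [write_stack()] when
#' present; a `voxel` override always wins over file metadata (acquisition
#' z-spacing varies between samples, so the configured value is
#' authoritative).
#'
#' @param path TIFF file path.
#' @param voxel optional `c(dx, dy, dz)` micron override.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, voxel = NULL) {
  if (!file.exists(path)) {
    cond_error(sprintf("no such file: %s", path), "coroalign_format_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse accidental channels
    arr[, , i] <- p
  }
  origin <- c(0, 0, 0)
  meta_voxel <- NULL
  sc <- stack_sidecar(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta_voxel <- as.numeric(meta$voxel_um)
    if (!is.null(meta$origin_um)) origin <- as.numeric(meta$origin_um)
  }
  vox <- if (!is.null(voxel)) voxel else meta_voxel
  if (is.null(vox)) {
    cond_error("no voxel size metadata and no override supplied",
               "coroalign_config_error")
  }
  image_stack(arr, vox, origin)
}

#' Write an image stack as a multi-page TIFF plus JSON voxel-size sidecar
#'
#' @param stack an `image_stack`; values are clamped to \[0, 1\] for storage.
#' @param path output TIFF path.
#' @param bits bits per sample (8 for masks, 16 for images).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$data)[3]
  pages <- lapply(seq_len(nz), function(i) {
    m <- stack$data[, , i]
    m[] <- pmin(1, pmax(0, m))  # keep matrix dims
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(list(voxel_um = stack$voxel, origin_um = stack$origin),
                       stack_sidecar(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write / read a transmural depth profile
#'
#' Delimited table with columns `depth`, `mean_angle_deg`, `kappa`, `u_deg`,
#' `n` (depth in microns, or in wall fraction 0-1 after
#' [normalize_depth()]).
#'
#' @param profile a `depth_profile` (see [depth_profile()]).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  if (nrow(profile) == 0) {
    cond_error("refusing to write an empty profile", "coroalign_format_error")
  }
  df <- as.data.frame(profile)[c("depth", "mean_angle_deg", "kappa",
                                 "u_deg", "n")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("depth", "mean_angle_deg", "kappa", "u_deg", "n"),
                  "profile table")
  as_depth_profile(df, normalized = FALSE)
}

as_depth_profile <- function(df, normalized = FALSE) {
  structure(df, class = c("depth_profile", "data.frame"),
            normalized = normalized)
}

#' Analysis configuration
#'
#' Bundles the apex-to-base reference axis, region of interest, and the
#' windowing parameters of the depth and local-neighborhood analyses.
#'
#' @param apex,base 3-vectors (microns); the unit apex-to-base axis is
#'   derived from them and anchors the `g2` direction.
#' @param roi optional axis-aligned box `c(x0, y0, z0, x1, y1, z1)` microns.
#' @param half_width depth moving-window half-width (microns; default 15).
#' @param local_window local mean-angle window extents in microns
#'   (default `c(136, 136, 175)`).
#' @param increment angular grid increment in degrees (default 5).
#' @param resample_n number of depth points for profile correlation
#'   (default 200).
#' @param seed RNG seed recorded with the run.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(apex, base, roi = NULL, half_width = 15,
                            local_window = c(136, 136, 175), increment = 5,
                            resample_n = 200, seed = NULL) {
  apex <- as.numeric(apex); base <- as.numeric(base)
  stopifnot(length(apex) == 3, length(base) == 3, half_width > 0,
            length(local_window) == 3, all(local_window > 0),
            increment > 0, resample_n >= 2)
  if (sqrt(sum((base - apex)^2)) < 1e-9) {
    cond_error("apex and base coincide", "coroalign_config_error")
  }
  structure(list(apex = apex, base = base, roi = roi, half_width = half_width,
                 local_window = local_window, increment = increment,
                 resample_n = resample_n, seed = seed),
            class = "analysis_config")
}

#' Read / write the analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  analysis_config(apex = y$apex_um, base = y$base_um, roi = y$roi_um,
                  half_width = y$half_width_um %||% 15,
                  local_window = y$local_window_um %||% c(136, 136, 175),
                  increment = y$increment_deg %||% 5,
                  resample_n = y$resample_n %||% 200, seed = y$seed)
}

#' @rdname read_config
#' @param config an `analysis_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(list(apex_um = config$apex, base_um = config$base,
                        roi_um = config$roi, half_width_um = config$half_width,
                        local_window_um = config$local_window,
                        increment_deg = config$increment,
                        resample_n = config$resample_n, seed = config$seed),
                   path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
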