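# Surface-anchored local reference frames. For every vessel point the triad
# g1 (toward the nearest epicardial surface point), g2 (apex-base axis
# projected on the surface tangent plane) and g3 = g2 x g1 (circumferential)
# defines the coordinate system in which helical and projection angles are
# measured; the nearest-surface distance is the point's depth.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

unitize <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) cond_error("cannot normalize a zero vector",
                            "coroalign_degenerate_error")
  a / n
}

#' Build a uniform-grid spatial index over a point cloud
#'
#' Buckets points into cubic cells so nearest-neighbor queries inspect only
#' a growing shell of cells instead of the whole cloud; results are exact
#' (equal to brute force, ties broken by lowest point index).
#'
#' @param points numeric matrix (n x 3) of coordinates in microns.
#' @param cell cell edge length in microns; by default scaled so cells hold
#'   a handful of points each.
#' @return object of class `surface_index`.
#' @export
surface_index <- function(points, cell = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 1, all(is.finite(points)))
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  if (is.null(cell)) {
    ext <- sort(hi - lo, decreasing = TRUE)
    # surfaces are ~2D: size cells from the two largest extents
    cell <- max(sqrt(max(ext[1] * ext[2], 1e-12) / nrow(points)) * 8, 1e-6)
  }
  ix <- floor(sweep(points, 2, lo) / cell)
  dims <- pmax(apply(ix, 2, max) + 1L, 1L)
  id <- ix[, 1] + dims[1] * (ix[, 2] + dims[2] * ix[, 3])
  buckets <- split(seq_len(nrow(points)), id)
  # coarse subsample used to bound the nearest distance before cell gathering
  sub <- seq(1, nrow(points), by = max(1L, nrow(points) %/% 4096L))
  structure(list(points = points, cell = cell, lo = lo, dims = dims,
                 buckets = buckets, sub = sub), class = "surface_index")
}

# indices of all points in cells intersecting the ball of radius r around p
ball_candidates <- function(index, p, r) {
  d <- index$dims
  clo <- pmax(floor((p - r - index$lo) / index$cell), 0)
  chi <- pmin(floor((p + r - index$lo) / index$cell), d - 1L)
  if (any(chi < clo)) return(integer(0))
  cells <- expand.grid(x = clo[1]:chi[1], y = clo[2]:chi[2], z = clo[3]:chi[3])
  # distance from p to each cell box; drop cells that cannot hold a point in r
  bl <- index$lo
  cs <- index$cell
  dx <- pmax(bl[1] + cells$x * cs - p[1], p[1] - (bl[1] + (cells$x + 1) * cs), 0)
  dy <- pmax(bl[2] + cells$y * cs - p[2], p[2] - (bl[2] + (cells$y + 1) * cs), 0)
  dz <- pmax(bl[3] + cells$z * cs - p[3], p[3] - (bl[3] + (cells$z + 1) * cs), 0)
  keep <- dx * dx + dy * dy + dz * dz <= r * r
  if (!any(keep)) return(integer(0))
  ids <- cells$x[keep] + d[1] * (cells$y[keep] + d[2] * cells$z[keep])
  unlist(index$buckets[as.character(ids)], use.names = FALSE)
}

#' Depth and g1 direction from the nearest surface point
#'
#' For each query point, finds the closest surface point (smallest Euclidean
#' distance = the point's depth) and the unit vector g1 pointing from the
#' query toward it. The grid index makes the search sub-quadratic; a brute
#' force method is provided as an oracle and for small clouds. Ties are
#' broken by the lowest surface-point index. A query coinciding with a
#' surface point (depth 0) has no defined g1 and is flagged degenerate.
#'
#' @param points numeric matrix (m x 3) of query points (microns), or a
#'   single 3-vector.
#' @param surface numeric matrix (n x 3) of surface points, or a
#'   `surface_index` built from one.
#' @param method `"grid"` (spatial index) or `"brute"` (exhaustive).
#' @return data.frame with columns `depth`, `g1x`, `g1y`, `g1z`,
#'   `surface_point` (1-based index of the nearest surface point) and
#'   `degenerate`.
#' @export
nearest_surface <- function(points, surface, method = c("grid", "brute")) {
  method <- match.arg(method)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (method == "brute") {
    sp <- if (inherits(surface, "surface_index")) surface$points
          else as.matrix(surface)
    stopifnot(nrow(sp) >= 1)
    res <- t(apply(points, 1, function(p) {
      d2 <- (sp[, 1] - p[1])^2 + (sp[, 2] - p[2])^2 + (sp[, 3] - p[3])^2
      j <- which.min(d2)  # first minimum = lowest index
      c(sqrt(d2[j]), j)
    }))
  } else {
    idx <- if (inherits(surface, "surface_index")) surface
           else surface_index(surface)
    res <- matrix(0, nrow(points), 2)
    subp <- idx$points[idx$sub, , drop = FALSE]
    for (i in seq_len(nrow(points))) {
      p <- points[i, ]
      # upper bound on the nearest distance from the coarse subsample
      d2s <- (subp[, 1] - p[1])^2 + (subp[, 2] - p[2])^2 +
             (subp[, 3] - p[3])^2
      r <- sqrt(min(d2s)) + 1e-9
      cand <- sort(ball_candidates(idx, p, r))
      sp <- idx$points[cand, , drop = FALSE]
      d2 <- (sp[, 1] - p[1])^2 + (sp[, 2] - p[2])^2 + (sp[, 3] - p[3])^2
      j <- which.min(d2)  # candidates sorted: ties resolve to lowest index
      res[i, ] <- c(sqrt(d2[j]), cand[j])
    }
  }
  sp <- if (inherits(surface, "surface_index")) surface$points
        else as.matrix(surface)
  depth <- res[, 1]
  nearest <- sp[res[, 2], , drop = FALSE]
  degenerate <- depth < 1e-12
  g1 <- (nearest - points) / ifelse(degenerate, NA_real_, depth)
  data.frame(depth = depth, g1x = g1[, 1], g1y = g1[, 2], g1z = g1[, 3],
             surface_point = as.integer(res[, 2]), degenerate = degenerate)
}

#' Complete the local frame from g1 and the apex-base axis
#'
#' Given the surface-ward unit vector `g1` and the unit apex-to-base axis,
#' computes `g2 = g1 x (v_ab x g1)` normalized (the axis projected onto the
#' surface tangent plane) and `g3 = g2 x g1` (circumferential). The operand
#' order of the final cross product fixes the handedness and hence the sign
#' convention of helical angles throughout the pipeline.
#'
#' @param g1 unit 3-vector toward the nearest surface point.
#' @param v_ab apex-to-base axis (normalized internally, so only its
#'   direction matters).
#' @return list with unit vectors `g1`, `g2`, `g3`.
#' @export
build_frame <- function(g1, v_ab) {
  g1 <- unitize(as.numeric(g1))
  v <- unitize(as.numeric(v_ab))
  g2u <- vcross(g1, vcross(v, g1))
  if (vnorm(g2u) < 1e-9) {
    cond_error("degenerate frame: apex-base axis parallel to g1",
               "coroalign_degenerate_error")
  }
  g2 <- g2u / vnorm(g2u)
  g3 <- unitize(vcross(g2, g1))
  list(g1 = g1, g2 = g2, g3 = g3)
}

#' Extract a surface point cloud from a labeled image stack
#'
#' Thresholds the stack and returns the centers of foreground voxels having
#' at least one 6-connected background (or out-of-stack) neighbor -- the
#' outer boundary of the labeled tissue.
#'
#' @param stack an `image_stack`.
#' @param threshold intensity above which a voxel is foreground.
#' @return numeric matrix of surface point coordinates (microns).
#' @export
surface_from_labels <- function(stack, threshold) {
  stopifnot(inherits(stack, "image_stack"))
  fg <- stack$data > threshold
  if (!any(fg)) cond_error("empty foreground: no surface to extract",
                           "coroalign_empty_surface_error")
  d <- dim(fg)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  boundary <- which(core & !nb, arr.ind = TRUE)
  # arr.ind: (row=y, col=x, slice=z); voxel centers in microns
  cbind(x_um = stack$origin[1] + (boundary[, 2] - 0.5) * stack$voxel[1],
        y_um = stack$origin[2] + (boundary[, 1] - 0.5) * stack$voxel[2],
        z_um = stack$origin[3] + (boundary[, 3] - 0.5) * stack$voxel[3])
}

# Polyline helpers --------------------------------------------------------

polyline_length <- function(xyz) {
  if (nrow(xyz) < 2) return(0)
  sum(sqrt(rowSums((xyz[-1, , drop = FALSE] -
                    xyz[-nrow(xyz), , drop = FALSE])^2)))
}

# point at half arc length along the polyline
polyline_midpoint <- function(xyz) {
  if (nrow(xyz) == 1) return(xyz[1, ])
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                       xyz[-nrow(xyz), , drop = FALSE])^2))
  total <- sum(seg)
  if (total < 1e-12) return(xyz[1, ])
  half <- total / 2
  cum <- cumsum(seg)
  i <- which(cum >= half)[1]
  prev <- if (i == 1) 0 else cum[i - 1]
  t <- (half - prev) / seg[i]
  xyz[i, ] + t * (xyz[i + 1, ] - xyz[i, ])
}

segment_point_list <- function(graph) {
  split(as.matrix(graph$points[c("x_um", "y_um", "z_um")]),
        factor(graph$points$segment_id, levels = graph$segments$segment_id))
}

#' Per-segment midpoints, vectors and lengths
#'
#' The segment vector links its start node to its end node; the midpoint is
#' taken at half arc length along the polyline (the least-biased single
#' anchor for the one-frame-per-segment convention); the length is the sum
#' of inter-point distances.
#'
#' @param graph a `skeleton_graph`.
#' @return data.frame with `segment_id`, midpoint `mx/my/mz`, vector
#'   `vx/vy/vz` and `length_um`.
#' @export
segment_geometry <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  node_xyz <- as.matrix(graph$nodes[c("x_um", "y_um", "z_um")])
  rownames(node_xyz) <- as.character(graph$nodes$node_id)
  plists <- segment_point_list(graph)
  n <- nrow(graph$segments)
  mid <- matrix(0, n, 3)
  len <- numeric(n)
  for (i in seq_len(n)) {
    xyz <- matrix(plists[[i]], ncol = 3)
    mid[i, ] <- polyline_midpoint(xyz)
    len[i] <- polyline_length(xyz)
  }
  v <- node_xyz[as.character(graph$segments$end_node_id), , drop = FALSE] -
       node_xyz[as.character(graph$segments$start_node_id), , drop = FALSE]
  data.frame(segment_id = graph$segments$segment_id,
             mx = mid[, 1], my = mid[, 2], mz = mid[, 3],
             vx = v[, 1], vy = v[, 2], vz = v[, 3], length_um = len)
}

#' Local frames at every segment midpoint
#'
#' Combines [nearest_surface()] and [build_frame()] for all segments of a
#' skeleton graph. Segments whose midpoint coincides with a surface point or
#' whose g1 is parallel to the apex-base axis are flagged degenerate (and
#' excluded from downstream angle statistics, with counts reported via
#' `message`), rather than propagating NaNs into circular means.
#'
#' @param graph a `skeleton_graph`.
#' @param surface surface cloud matrix or `surface_index`.
#' @param config an `analysis_config` (provides apex/base).
#' @return data.frame: segment geometry columns plus `depth`, the frame
#'   components `g1x..g3z`, and `degenerate`.
#' @export
segment_frames <- function(graph, surface, config) {
  stopifnot(inherits(config, "analysis_config"))
  geo <- segment_geometry(graph)
  v_ab <- unitize(config$base - config$apex)
  ns <- nearest_surface(as.matrix(geo[c("mx", "my", "mz")]), surface)
  n <- nrow(geo)
  out <- cbind(geo, depth = ns$depth,
               g1x = ns$g1x, g1y = ns$g1y, g1z = ns$g1z,
               g2x = NA_real_, g2y = NA_real_, g2z = NA_real_,
               g3x = NA_real_, g3y = NA_real_, g3z = NA_real_,
               degenerate = ns$degenerate)
  for (i in seq_len(n)) {
    if (out$degenerate[i]) next
    fr <- tryCatch(build_frame(c(ns$g1x[i], ns$g1y[i], ns$g1z[i]), v_ab),
                   coroalign_degenerate_error = function(e) NULL)
    if (is.null(fr)) {
      out$degenerate[i] <- TRUE
      next
    }
    out[i, c("g2x", "g2y", "g2z")] <- fr$g2
    out[i, c("g3x", "g3y", "g3z")] <- fr$g3
  }
  if (any(out$degenerate)) {
    message(sprintf("segment_frames: %d of %d segments degenerate (excluded)",
                    sum(out$degenerate), n))
  }
  out
}
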