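# Phantom generators: ventricular-wall vessel networks (slab and
# hemispherical shell) with known transmural orientation statistics, their
# voxelized masks, and image stacks of elongated nuclei. Every phantom
# carries a ground-truth table so each pipeline stage can be validated
# against what was actually drawn.

#' Preset transmural mean-angle profiles
#'
#' Returns a function mapping normalized wall depth (0 = epicardium,
#' 1 = endocardium) to a mean orientation in degrees. `"linear"`
#' interpolates between the endpoints; `"piecewise"` mimics the layered
#' pattern of the embryonic wall: shallow negative angles over the outer
#' half, then a steep counterclockwise rotation toward vertical near the
#' endocardium.
#'
#' @param name `"linear"` or `"piecewise"`, or a function(depth01) -> deg
#'   passed through unchanged.
#' @param range endpoint angles `c(epicardial, endocardial)` in degrees for
#'   the linear preset (default -30 to +80).
#' @return function mapping depth in \[0, 1\] to degrees.
#' @export
profile_preset <- function(name = "linear", range = c(-30, 80)) {
  if (is.function(name)) return(name)
  name <- match.arg(name, c("linear", "piecewise"))
  if (name == "linear") {
    function(d) range[1] + (range[2] - range[1]) * d
  } else {
    knots_d <- c(0, 0.15, 0.40, 0.65, 0.85, 1)
    knots_a <- c(-30, -25, -12, 10, 55, 80)
    function(d) stats::approx(knots_d, knots_a, pmin(pmax(d, 0), 1),
                              rule = 2)$y
  }
}

#' Specification of a synthetic ventricular-wall vessel phantom
#'
#' Geometry presets mirror the study conditions: `"ed9"` is a hemispherical
#' shell of 550 um wall thickness (outer radius 800 um), `"ed13"` a
#' 900 um-thick shell (outer radius 1200 um), and `"slab"` a flat 550 um
#' wall over a 700 x 700 um patch (the exact-geometry sanity case).
#'
#' @param geometry `"slab"`, `"ed9"` or `"ed13"`.
#' @param thickness wall thickness in microns (preset default if `NULL`).
#' @param outer_radius shell outer (epicardial) radius in microns.
#' @param lateral_extent slab patch side length in microns.
#' @param profile mean-angle profile: name or function (see
#'   [profile_preset()]).
#' @param profile_range endpoints for the linear profile (degrees).
#' @param kappa concentration of the drawn angles: a constant or a
#'   function(depth01); default 8.
#' @param n_segments number of vessel segments.
#' @param seg_length_mean,seg_length_sd segment length distribution (um).
#' @param radius_um vessel radius used when rasterizing the mask.
#' @param surface_spacing target spacing of surface cloud points (um).
#' @param pad margin kept between segment midpoints and the wall faces (um).
#' @param snap_to_grid slab only: place midpoints laterally on the surface
#'   lattice so the nearest surface point lies exactly above each midpoint
#'   and frames are exact (default TRUE).
#' @param seed RNG seed.
#' @return object of class `wall_phantom_spec`.
#' @export
wall_phantom_spec <- function(geometry = c("slab", "ed9", "ed13"),
                              thickness = NULL, outer_radius = NULL,
                              lateral_extent = 700,
                              profile = "linear", profile_range = c(-30, 80),
                              kappa = 8, n_segments = 2000,
                              seg_length_mean = 40, seg_length_sd = 10,
                              radius_um = 4, surface_spacing = 5, pad = 15,
                              snap_to_grid = TRUE, seed = 1L) {
  geometry <- match.arg(geometry)
  if (is.null(thickness)) {
    thickness <- switch(geometry, slab = 550, ed9 = 550, ed13 = 900)
  }
  if (is.null(outer_radius)) {
    outer_radius <- switch(geometry, slab = NA_real_, ed9 = 800, ed13 = 1200)
  }
  stopifnot(thickness > 0, n_segments >= 1, seg_length_mean > 0,
            radius_um > 0, surface_spacing > 0, pad >= 0)
  kfun <- if (is.function(kappa)) kappa else function(d) rep(kappa, length(d))
  stopifnot(all(kfun(c(0, 0.5, 1)) >= 0))
  structure(list(geometry = geometry, thickness = thickness,
                 outer_radius = outer_radius, lateral_extent = lateral_extent,
                 profile = profile_preset(profile, profile_range),
                 kappa = kfun, n_segments = n_segments,
                 seg_length_mean = seg_length_mean,
                 seg_length_sd = seg_length_sd, radius_um = radius_um,
                 surface_spacing = surface_spacing, pad = pad,
                 snap_to_grid = snap_to_grid, seed = seed),
            class = "wall_phantom_spec")
}

# Fibonacci lattice on the sphere band cos(phi) in [cmin, cmax] (phi from -z)
fibonacci_band <- function(radius, spacing, cmin, cmax) {
  n_full <- max(64L, ceiling(4 * pi * radius^2 / spacing^2))
  i <- seq_len(n_full) - 0.5
  cosphi <- 1 - 2 * i / n_full           # uniform in cos
  keep <- cosphi >= cmin & cosphi <= cmax
  cosphi <- cosphi[keep]
  lam <- (pi * (1 + sqrt(5)) * i[keep]) %% (2 * pi)
  sinphi <- sqrt(pmax(0, 1 - cosphi^2))
  cbind(x_um = radius * sinphi * cos(lam),
        y_um = radius * sinphi * sin(lam),
        z_um = -radius * cosphi)         # apex at z = -radius
}

#' Generate a wall phantom: skeleton, surface cloud, mask and ground truth
#'
#' Segment midpoints are placed uniformly in the wall (kept `pad` microns
#' off the faces); each segment's in-tangent-plane direction is drawn from
#' the bimodal von Mises distribution with mean `profile(depth / thickness)`
#' and concentration `kappa(depth / thickness)`, so the drawn angle is the
#' segment's true helical angle in the analytic local frame. Straight
#' two-point segments with randomized node order exercise the axial-folding
#' convention. The epicardial surface is sampled as a point cloud (lattice
#' for the slab, Fibonacci sphere band for the shells).
#'
#' @param spec a `wall_phantom_spec`.
#' @param rasterize also voxelize the vessel mask (default FALSE; see
#'   [rasterize_skeleton()]).
#' @param voxel_um voxel edge length for the mask.
#' @return list with `graph` (`skeleton_graph`), `surface` (matrix),
#'   `config` (`analysis_config` with the phantom's apex/base axis), `truth`
#'   (data.frame: `segment_id`, `depth_um`, `depth01`, `alpha_true_deg`,
#'   `mu_true_deg`, `length_um`), and `mask` (an `image_stack`, or `NULL`).
#' @export
make_wall_phantom <- function(spec, rasterize = FALSE, voxel_um = 2) {
  stopifnot(inherits(spec, "wall_phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_segments
  th <- spec$thickness
  if (spec$geometry == "slab") {
    ext <- spec$lateral_extent
    gx <- seq(0, ext, by = spec$surface_spacing)
    surface <- cbind(x_um = rep(gx, times = length(gx)),
                     y_um = rep(gx, each = length(gx)),
                     z_um = 0)
    lat_lo <- spec$pad
    lat_hi <- ext - spec$pad
    if (spec$snap_to_grid) {
      ok <- gx >= lat_lo & gx <= lat_hi
      mx <- sample(gx[ok], n, replace = TRUE)
      my <- sample(gx[ok], n, replace = TRUE)
    } else {
      mx <- stats::runif(n, lat_lo, lat_hi)
      my <- stats::runif(n, lat_lo, lat_hi)
    }
    mz <- stats::runif(n, spec$pad, th - spec$pad)
    depth <- mz
    g1 <- cbind(0, 0, -1)[rep(1, n), , drop = FALSE]
    v_ab <- c(0, 1, 0)
    apex <- c(ext / 2, -500, th / 2)
    base <- c(ext / 2, 500, th / 2)
    mid <- cbind(mx, my, mz)
  } else {
    r_out <- spec$outer_radius
    r_in <- r_out - th
    stopifnot(r_in > 0)
    surface <- fibonacci_band(r_out, spec$surface_spacing,
                              cos(deg2rad(95)), cos(deg2rad(40)))
    cosphi <- stats::runif(n, cos(deg2rad(85)), cos(deg2rad(50)))
    lam <- stats::runif(n, 0, 2 * pi)
    rr <- stats::runif(n, r_in + spec$pad, r_out - spec$pad)
    sinphi <- sqrt(1 - cosphi^2)
    nhat <- cbind(sinphi * cos(lam), sinphi * sin(lam), -cosphi)
    mid <- nhat * rr
    depth <- r_out - rr
    g1 <- nhat                        # outward, toward the epicardium
    v_ab <- c(0, 0, 1)                # apex (0,0,-r_out) -> base (0,0,0)
    apex <- c(0, 0, -r_out)
    base <- c(0, 0, 0)
  }
  d01 <- depth / th
  mu <- spec$profile(d01)
  kap <- spec$kappa(d01)
  alpha <- vapply(seq_len(n),
                  function(i) rvonmises_axial(1, mu[i], kap[i]), numeric(1))
  len <- pmax(5, stats::rnorm(n, spec$seg_length_mean, spec$seg_length_sd))
  ends <- matrix(0, 2 * n, 3)
  for (i in seq_len(n)) {
    fr <- build_frame(g1[i, ], v_ab)
    a <- deg2rad(alpha[i])
    t_dir <- cos(a) * fr$g3 + sin(a) * fr$g2
    ends[2 * i - 1, ] <- mid[i, ] - len[i] / 2 * t_dir
    ends[2 * i, ] <- mid[i, ] + len[i] / 2 * t_dir
  }
  flip <- stats::runif(n) < 0.5       # node order is arbitrary in real data
  start_idx <- ifelse(flip, 2 * seq_len(n), 2 * seq_len(n) - 1)
  end_idx <- ifelse(flip, 2 * seq_len(n) - 1, 2 * seq_len(n))
  nodes <- data.frame(node_id = seq_len(2 * n), x_um = ends[, 1],
                      y_um = ends[, 2], z_um = ends[, 3])
  segments <- data.frame(segment_id = seq_len(n),
                         start_node_id = start_idx, end_node_id = end_idx)
  ord <- as.vector(rbind(start_idx, end_idx))  # start1, end1, start2, ...
  points <- data.frame(segment_id = rep(seq_len(n), each = 2),
                       point_order = rep(1:2, n),
                       x_um = ends[ord, 1], y_um = ends[ord, 2],
                       z_um = ends[ord, 3])
  graph <- skeleton_graph(nodes, segments, points)
  config <- analysis_config(apex = apex, base = base, seed = spec$seed)
  truth <- data.frame(segment_id = seq_len(n), depth_um = depth,
                      depth01 = d01, alpha_true_deg = alpha,
                      mu_true_deg = mu, length_um = len)
  mask <- if (rasterize) {
    rasterize_skeleton(graph, radius_um = spec$radius_um, voxel_um = voxel_um)
  } else NULL
  list(graph = graph, surface = surface, config = config, truth = truth,
       mask = mask)
}

#' Voxelize a skeleton graph into a binary vessel mask
#'
#' Each polyline edge becomes a flat-capped cylinder of the given radius: a
#' voxel is foreground when its center projects onto the edge (projection
#' parameter in \[0, 1\]) within `radius_um` of the centerline, so the
#' analytic foreground volume of non-overlapping straight segments is
#' exactly `pi * r^2 * L`.
#'
#' @param graph a `skeleton_graph`.
#' @param radius_um vessel radius in microns.
#' @param voxel_um cubic voxel edge length in microns.
#' @param bounds optional box `c(x0, y0, z0, x1, y1, z1)`; default is the
#'   skeleton bounding box padded by `radius_um + voxel_um`.
#' @return a binary `image_stack`.
#' @export
rasterize_skeleton <- function(graph, radius_um, voxel_um = 2,
                               bounds = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"), radius_um > 0, voxel_um > 0)
  pts <- as.matrix(graph$points[c("x_um", "y_um", "z_um")])
  if (is.null(bounds)) {
    pad <- radius_um + voxel_um
    bounds <- c(apply(pts, 2, min) - pad, apply(pts, 2, max) + pad)
  }
  b <- roi_box(bounds)
  nv <- pmax(1, ceiling((b$hi - b$lo) / voxel_um))  # (nx, ny, nz)
  arr <- array(FALSE, c(nv[2], nv[1], nv[3]))       # [y, x, z]
  cx <- b$lo[1] + (seq_len(nv[1]) - 0.5) * voxel_um
  cy <- b$lo[2] + (seq_len(nv[2]) - 0.5) * voxel_um
  cz <- b$lo[3] + (seq_len(nv[3]) - 0.5) * voxel_um
  plists <- segment_point_list(graph)
  for (pl in plists) {
    xyz <- matrix(pl, ncol = 3)
    for (e in seq_len(nrow(xyz) - 1)) {
      p <- xyz[e, ]; q <- xyz[e + 1, ]
      d <- q - p
      L2 <- sum(d^2)
      if (L2 < 1e-18) next
      lo <- pmin(p, q) - radius_um
      hi <- pmax(p, q) + radius_um
      jx <- which(cx >= lo[1] & cx <= hi[1])
      iy <- which(cy >= lo[2] & cy <= hi[2])
      kz <- which(cz >= lo[3] & cz <= hi[3])
      if (!length(jx) || !length(iy) || !length(kz)) next
      gx <- cx[jx]; gy <- cy[iy]; gz <- cz[kz]
      G <- cbind(rep(gy, times = length(jx) * length(kz)),
                 rep(rep(gx, each = length(iy)), times = length(kz)),
                 rep(gz, each = length(iy) * length(jx)))
      # G columns: y, x, z matching array index order [iy, jx, kz]
      rel <- cbind(G[, 2] - p[1], G[, 1] - p[2], G[, 3] - p[3])
      tpar <- (rel[, 1] * d[1] + rel[, 2] * d[2] + rel[, 3] * d[3]) / L2
      perp2 <- rowSums(rel^2) - tpar^2 * L2
      inside <- tpar >= 0 & tpar <= 1 & perp2 <= radius_um^2
      if (any(inside)) {
        sub <- array(arr[iy, jx, kz], c(length(iy), length(jx), length(kz)))
        sub[inside] <- TRUE
        arr[iy, jx, kz] <- sub
      }
    }
  }
  image_stack(arr * 1, voxel = rep(voxel_um, 3), origin = b$lo)
}

#' Specification of a synthetic nuclei image stack
#'
#' Defaults emulate DAPI imaging of embryonic myocardium: a 360 x 360 um
#' field at 1 um/pixel, ~150 visibly elongated nuclei per slice (12 x 3 um
#' ellipses, 4:1 aspect), orientations drawn around a transmural profile
#' with the counterclockwise rotation reported for the ventricular wall
#' (-40 deg near the epicardium to +79 deg near the endocardium).
#'
#' @param img_px image side length in pixels.
#' @param pixel_um pixel size in microns.
#' @param n_slices number of z slices spanning the wall.
#' @param thickness wall thickness spanned by the stack (um).
#' @param n_nuclei nuclei per slice.
#' @param axes_um ellipse full axes `c(long, short)` in microns.
#' @param profile orientation profile name or function of depth01.
#' @param profile_range endpoints for the linear profile (degrees).
#' @param kappa concentration of nuclei orientations about the profile.
#' @param noise_sd additive Gaussian intensity noise (image scale 0-1).
#' @param seed RNG seed.
#' @return object of class `nuclei_phantom_spec`.
#' @export
nuclei_phantom_spec <- function(img_px = 360, pixel_um = 1, n_slices = 16,
                                thickness = 550, n_nuclei = 150,
                                axes_um = c(12, 3), profile = "linear",
                                profile_range = c(-40, 79), kappa = 6,
                                noise_sd = 0.05, seed = 1L) {
  stopifnot(img_px >= 64, pixel_um > 0, n_slices >= 1, n_nuclei >= 1,
            axes_um[1] > axes_um[2], axes_um[2] > 0, kappa >= 0,
            noise_sd >= 0)
  structure(list(img_px = img_px, pixel_um = pixel_um, n_slices = n_slices,
                 thickness = thickness, n_nuclei = n_nuclei,
                 axes_um = axes_um,
                 profile = profile_preset(profile, profile_range),
                 kappa = kappa, noise_sd = noise_sd, seed = seed),
            class = "nuclei_phantom_spec")
}

# render one anti-aliased ellipse into canvas (max blend), angle in degrees
# measured from +x (columns) toward +y (rows)
render_ellipse <- function(canvas, cx, cy, a_px, b_px, angle_deg) {
  npx <- ncol(canvas); npy <- nrow(canvas)
  r <- a_px + 1
  jx <- max(1, floor(cx - r)):min(npx, ceiling(cx + r))
  iy <- max(1, floor(cy - r)):min(npy, ceiling(cy + r))
  if (!length(jx) || !length(iy)) return(canvas)
  X <- matrix(jx, length(iy), length(jx), byrow = TRUE) - cx
  Y <- matrix(iy, length(iy), length(jx)) - cy
  ca <- cos(deg2rad(angle_deg)); sa <- sin(deg2rad(angle_deg))
  u <- X * ca + Y * sa
  v <- -X * sa + Y * ca
  s <- sqrt((u / a_px)^2 + (v / b_px)^2)
  val <- pmin(1, pmax(0, (1 - s) * b_px + 0.5))  # ~1 px soft edge
  canvas[iy, jx] <- pmax(canvas[iy, jx], val)
  canvas
}

#' Generate a synthetic nuclei image stack with known orientations
#'
#' Per slice, elongated ellipses at orientations drawn from the bimodal von
#' Mises distribution around `profile(z / thickness)` are rendered with a
#' soft (anti-aliased) edge and additive Gaussian noise. The truth table
#' records, per slice, the profile value and the realized axial mean of the
#' drawn orientations.
#'
#' @param spec a `nuclei_phantom_spec`.
#' @return list with `stack` (an `image_stack`, slice depth = slice center)
#'   and `truth` (data.frame `slice`, `depth_um`, `mu_true_deg`,
#'   `mean_drawn_deg`, `n_nuclei`).
#' @export
make_nuclei_stack <- function(spec) {
  stopifnot(inherits(spec, "nuclei_phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  npx <- spec$img_px
  dz <- spec$thickness / spec$n_slices
  a_px <- spec$axes_um[1] / 2 / spec$pixel_um
  b_px <- spec$axes_um[2] / 2 / spec$pixel_um
  arr <- array(0, c(npx, npx, spec$n_slices))
  truth <- data.frame(slice = seq_len(spec$n_slices), depth_um = NA_real_,
                      mu_true_deg = NA_real_, mean_drawn_deg = NA_real_,
                      n_nuclei = spec$n_nuclei)
  for (s in seq_len(spec$n_slices)) {
    z <- (s - 0.5) * dz
    mu <- spec$profile(z / spec$thickness)
    ang <- rvonmises_axial(spec$n_nuclei, mu, spec$kappa)
    cxs <- stats::runif(spec$n_nuclei, 1, npx)
    cys <- stats::runif(spec$n_nuclei, 1, npx)
    canvas <- matrix(0, npx, npx)
    for (k in seq_len(spec$n_nuclei)) {
      canvas <- render_ellipse(canvas, cxs[k], cys[k], a_px, b_px, ang[k])
    }
    if (spec$noise_sd > 0) {
      canvas <- canvas + matrix(stats::rnorm(npx * npx, 0, spec$noise_sd),
                                npx, npx)
    }
    arr[, , s] <- pmin(1, pmax(0, canvas))
    truth$depth_um[s] <- z
    truth$mu_true_deg[s] <- mu
    truth$mean_drawn_deg[s] <- axial_mean(ang)$mean_deg
  }
  stack <- image_stack(arr, voxel = c(spec$pixel_um, spec$pixel_um, dz))
  list(stack = stack, truth = truth)
}
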