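# Vessel density morphometry, depth-profile correlation, and group
# comparison tests. Internal lengths stay in microns; density outputs are
# converted to mm-based units exactly once, here at reporting.

roi_box <- function(roi) {
  roi <- as.numeric(roi)
  stopifnot(length(roi) == 6)
  lo <- roi[1:3]; hi <- roi[4:6]
  if (any(hi <= lo)) cond_error("ROI box has non-positive extent",
                                "coroalign_config_error")
  list(lo = lo, hi = hi)
}

#' Vessel volume fraction within a region of interest
#'
#' Number of foreground (vessel) voxels divided by the total number of
#' voxels in the ROI; voxel membership by voxel center.
#'
#' @param mask a binary `image_stack` (values > 0.5 are vessel).
#' @param roi axis-aligned box `c(x0, y0, z0, x1, y1, z1)` in microns, or
#'   `NULL` for the whole stack.
#' @return dimensionless fraction in \[0, 1\].
#' @export
volume_fraction <- function(mask, roi = NULL) {
  stopifnot(inherits(mask, "image_stack"))
  d <- dim(mask$data)
  if (is.null(roi)) {
    sub <- mask$data
  } else {
    b <- roi_box(roi)
    cx <- mask$origin[1] + (seq_len(d[2]) - 0.5) * mask$voxel[1]
    cy <- mask$origin[2] + (seq_len(d[1]) - 0.5) * mask$voxel[2]
    cz <- mask$origin[3] + (seq_len(d[3]) - 0.5) * mask$voxel[3]
    jx <- which(cx >= b$lo[1] & cx <= b$hi[1])
    iy <- which(cy >= b$lo[2] & cy <= b$hi[2])
    kz <- which(cz >= b$lo[3] & cz <= b$hi[3])
    if (length(jx) == 0 || length(iy) == 0 || length(kz) == 0) {
      cond_error("ROI contains no voxels", "coroalign_config_error")
    }
    sub <- mask$data[iy, jx, kz, drop = FALSE]
  }
  mean(sub > 0.5)
}

# Liang-Barsky: fraction [t0, t1] of the segment p -> q inside the box
clip_param <- function(p, q, lo, hi) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (a in 1:3) {
    if (abs(d[a]) < 1e-15) {
      if (p[a] < lo[a] || p[a] > hi[a]) return(NULL)
    } else {
      ta <- (lo[a] - p[a]) / d[a]
      tb <- (hi[a] - p[a]) / d[a]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(NULL)
    }
  }
  c(t0, t1)
}

#' Vessel length density within a region of interest
#'
#' Sum of the centerline (polyline) lengths of all vessel segments clipped
#' to the ROI box (partial segments contribute the linearly interpolated
#' portion inside), in mm, divided by the ROI volume in mm^3; units mm^-2.
#'
#' @param graph a `skeleton_graph`.
#' @param roi axis-aligned box `c(x0, y0, z0, x1, y1, z1)` in microns.
#' @return length density in mm^-2 (mm of vessel per mm^3 of tissue).
#' @export
length_density <- function(graph, roi) {
  stopifnot(inherits(graph, "skeleton_graph"))
  b <- roi_box(roi)
  total_um <- 0
  plists <- segment_point_list(graph)
  for (pl in plists) {
    xyz <- matrix(pl, ncol = 3)
    if (nrow(xyz) < 2) next
    for (i in seq_len(nrow(xyz) - 1)) {
      tt <- clip_param(xyz[i, ], xyz[i + 1, ], b$lo, b$hi)
      if (!is.null(tt)) {
        total_um <- total_um + (tt[2] - tt[1]) * vnorm(xyz[i + 1, ] - xyz[i, ])
      }
    }
  }
  vol_mm3 <- prod(b$hi - b$lo) / 1e9
  (total_um / 1e3) / vol_mm3
}

# unwrap an axial (period-180) angle series: jumps > 90 deg are continued
# by +-180 so the series is suitable for linear interpolation/correlation
unwrap_axial <- function(a) {
  out <- a
  for (i in seq_along(a)[-1]) {
    d <- out[i] - out[i - 1]
    out[i] <- out[i] - 180 * round(d / 180)
  }
  out
}

#' Pearson correlation of two depth profiles
#'
#' Restricts both profiles to their overlapping depth range, unwraps axial
#' jumps larger than 90 degrees by +-180-degree continuation (so series
#' passing through +-90 are not corrupted by the fold), linearly
#' interpolates both mean-angle series onto `n` evenly spaced depths, and
#' returns their Pearson correlation coefficient.
#'
#' @param a,b `depth_profile` objects with means defined on at least 2 bins
#'   each; their depth axes must be in the same units (microns, or both
#'   normalized).
#' @param n number of resampled depth points (default 200).
#' @return list with `rho`, `n_resampled`, `depth_range`, `flagged` (TRUE
#'   when either resampled series is constant and rho is undefined).
#' @export
correlate_profiles <- function(a, b, n = 200) {
  stopifnot(inherits(a, "depth_profile"), inherits(b, "depth_profile"),
            n >= 2)
  ga <- a[is.finite(a$mean_angle_deg), ]
  gb <- b[is.finite(b$mean_angle_deg), ]
  if (nrow(ga) < 2 || nrow(gb) < 2) {
    cond_error("profiles need means on at least 2 bins each",
               "coroalign_config_error")
  }
  lo <- max(min(ga$depth), min(gb$depth))
  hi <- min(max(ga$depth), max(gb$depth))
  if (hi <= lo) cond_error("profiles do not overlap in depth",
                           "coroalign_config_error")
  grid <- seq(lo, hi, length.out = n)
  ya <- stats::approx(ga$depth, unwrap_axial(ga$mean_angle_deg), grid)$y
  yb <- stats::approx(gb$depth, unwrap_axial(gb$mean_angle_deg), grid)$y
  if (stats::sd(ya) < 1e-12 || stats::sd(yb) < 1e-12) {
    return(list(rho = NA_real_, n_resampled = n, depth_range = c(lo, hi),
                flagged = TRUE))
  }
  list(rho = stats::cor(ya, yb), n_resampled = n, depth_range = c(lo, hi),
       flagged = FALSE)
}

#' Compare a metric between two groups (F-test then Welch T-test)
#'
#' One-tailed F-test on the variances (larger sample variance in the
#' numerator), then a two-tailed T-test assuming unequal variances (Welch)
#' on the means. Both p-values and statistics are returned; no
#' multiple-testing correction is applied.
#'
#' @param x,y numeric vectors, one value per animal/sample (`n >= 2` each).
#' @return list with `f_statistic`, `f_df`, `f_p`, `t_statistic`, `t_df`,
#'   `t_p`, `degenerate` (TRUE when both groups have zero variance, in
#'   which case the p-values are `NA`).
#' @export
compare_groups <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx < 1e-30 && vy < 1e-30) {
    return(list(f_statistic = NA_real_, f_df = c(NA, NA), f_p = NA_real_,
                t_statistic = NA_real_, t_df = NA_real_, t_p = NA_real_,
                degenerate = TRUE))
  }
  if (vx >= vy) {
    f <- vx / max(vy, 1e-300); df <- c(length(x) - 1, length(y) - 1)
  } else {
    f <- vy / max(vx, 1e-300); df <- c(length(y) - 1, length(x) - 1)
  }
  f_p <- stats::pf(f, df[1], df[2], lower.tail = FALSE)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(f_statistic = f, f_df = df, f_p = f_p,
       t_statistic = unname(tt$statistic), t_df = unname(tt$parameter),
       t_p = tt$p.value, degenerate = FALSE)
}
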