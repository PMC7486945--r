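# Per-segment helical and projection angles in the local surface frame, and
# their depth-resolved / spatially windowed summaries.

#' Helical angle of a vessel vector
#'
#' Elevation of the segment vector out of the circumferential-radial plane:
#' `alpha_H = 90 - acos(V.g2 / |V|)` degrees, so 0 deg is circumferential
#' (along g3) and +90 deg is the apex-base direction (along g2). Because a
#' segment's start/end node order is arbitrary, the vector is first
#' canonicalized to a non-negative circumferential component (flip so that
#' `V.g3 >= 0`, tie broken toward `V.g2 >= 0`), which makes the angle a
#' property of the undirected centerline.
#'
#' @param v segment 3-vector (start node to end node, microns).
#' @param frame local frame list with unit `g1`, `g2`, `g3` (see
#'   [build_frame()]).
#' @return angle in degrees in \[-90, 90\], or `NA` for a zero-length vector
#'   (excluded-segment signal).
#' @export
helical_angle <- function(v, frame) {
  v <- as.numeric(v)
  nv <- vnorm(v)
  if (nv < 1e-12) return(NA_real_)
  s3 <- sum(v * frame$g3)
  s2 <- sum(v * frame$g2)
  if (s3 < 0 || (s3 == 0 && s2 < 0)) v <- -v
  cosang <- sum(v * frame$g2) / nv
  90 - rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

#' Projection angle of a vessel vector
#'
#' Angle between the segment vector's projection onto the surface tangent
#' plane, `Vp = g1 x (V x g1)`, and the circumferential direction g3,
#' reported signed and folded to the axial range (-90, 90] so it is directly
#' comparable with the 2D nuclei orientation. Vectors nearly parallel to g1
#' (`|Vp|/|V| < 1e-6`) have no defined in-plane direction and return `NA`.
#'
#' @inheritParams helical_angle
#' @return angle in degrees in (-90, 90], or `NA` when excluded.
#' @export
projection_angle <- function(v, frame) {
  v <- as.numeric(v)
  nv <- vnorm(v)
  if (nv < 1e-12) return(NA_real_)
  vp <- v - sum(v * frame$g1) * frame$g1   # = g1 x (v x g1)
  if (vnorm(vp) / nv < 1e-6) return(NA_real_)
  fold_axial(rad2deg(atan2(sum(vp * frame$g2), sum(vp * frame$g3))))
}

#' Helical and projection angles for every segment of a skeleton
#'
#' Runs [segment_frames()] and evaluates both angles per segment.
#'
#' @param graph a `skeleton_graph`.
#' @param surface surface cloud matrix or `surface_index`.
#' @param config an `analysis_config`.
#' @return data.frame with `segment_id`, `depth`, `length_um`,
#'   `helical_deg`, `projection_deg`, `excluded` plus the frame columns.
#' @export
vessel_angles <- function(graph, surface, config) {
  fr <- segment_frames(graph, surface, config)
  n <- nrow(fr)
  hel <- rep(NA_real_, n)
  prj <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (fr$degenerate[i]) next
    frame <- list(g1 = c(fr$g1x[i], fr$g1y[i], fr$g1z[i]),
                  g2 = c(fr$g2x[i], fr$g2y[i], fr$g2z[i]),
                  g3 = c(fr$g3x[i], fr$g3y[i], fr$g3z[i]))
    v <- c(fr$vx[i], fr$vy[i], fr$vz[i])
    hel[i] <- helical_angle(v, frame)
    prj[i] <- projection_angle(v, frame)
  }
  fr$helical_deg <- hel
  fr$projection_deg <- prj
  fr$excluded <- fr$degenerate | !is.finite(hel)
  fr
}

#' Moving-window transmural depth profile of axial angles
#'
#' At evaluation depths spaced every `step` microns between the shallowest
#' and deepest sample, pools all samples within `half_width` microns of the
#' evaluation depth (segment membership by midpoint depth only) and reports
#' the axial circular mean, the least-squares von Mises concentration
#' `kappa`, and the standard uncertainty `u`. Windows holding fewer than
#' `n_min` samples are flagged (`NA` mean) rather than interpolated.
#'
#' @param angles_deg axial angles in degrees, one per sample (segment).
#' @param depths_um sample depths in microns.
#' @param half_width moving-window half-width in microns (default 15).
#' @param step evaluation-depth spacing in microns (default 5).
#' @param n_min minimum samples per window before a mean is reported.
#' @param increment angular grid increment for the kappa fit (degrees).
#' @param weights optional per-sample weights (e.g. segment lengths) for a
#'   length-weighted mean; default equal weights.
#' @return a `depth_profile` data.frame with columns `depth`,
#'   `mean_angle_deg`, `kappa`, `u_deg`, `n`, `flagged`.
#' @export
depth_profile <- function(angles_deg, depths_um, half_width = 15, step = 5,
                          n_min = 10, increment = 5, weights = NULL) {
  keep <- is.finite(angles_deg) & is.finite(depths_um)
  angles_deg <- angles_deg[keep]
  depths_um <- depths_um[keep]
  if (!is.null(weights)) weights <- weights[keep]
  stopifnot(length(angles_deg) >= 1)
  centers <- seq(min(depths_um), max(depths_um), by = step)
  rows <- lapply(centers, function(d) {
    sel <- abs(depths_um - d) <= half_width
    n <- sum(sel)
    if (n < n_min) {
      return(data.frame(depth = d, mean_angle_deg = NA_real_,
                        kappa = NA_real_, u_deg = NA_real_, n = n,
                        flagged = TRUE))
    }
    m <- axial_mean(angles_deg[sel],
                    weights = if (is.null(weights)) NULL else weights[sel])
    if (m$flagged) {
      return(data.frame(depth = d, mean_angle_deg = NA_real_,
                        kappa = NA_real_, u_deg = NA_real_, n = n,
                        flagged = TRUE))
    }
    kf <- fit_kappa(angles_deg[sel], m$mean_deg, increment = increment)
    data.frame(depth = d, mean_angle_deg = m$mean_deg, kappa = kf$kappa,
               u_deg = standard_uncertainty(kf$kappa), n = n, flagged = FALSE)
  })
  as_depth_profile(do.call(rbind, rows), normalized = FALSE)
}

#' Local mean helical angle in a 3D moving window
#'
#' For each segment, the axial circular mean of the helical angles of all
#' segments whose midpoints fall inside an axis-aligned box of the given
#' extents centered on its own midpoint (the window always contains the
#' segment itself).
#'
#' @param angles data.frame from [vessel_angles()].
#' @param window window extents `c(wx, wy, wz)` in microns
#'   (default `c(136, 136, 175)`).
#' @return data.frame `segment_id`, `mean_angle_deg`, `n` (class
#'   `local_angle_field`).
#' @export
local_angle_field <- function(angles, window = c(136, 136, 175)) {
  stopifnot(length(window) == 3, all(window > 0))
  ok <- !angles$excluded
  mx <- angles$mx; my <- angles$my; mz <- angles$mz
  out <- data.frame(segment_id = angles$segment_id,
                    mean_angle_deg = NA_real_, n = 0L)
  h <- window / 2
  for (i in seq_len(nrow(angles))) {
    sel <- ok & abs(mx - mx[i]) <= h[1] & abs(my - my[i]) <= h[2] &
           abs(mz - mz[i]) <= h[3]
    if (!any(sel)) next
    m <- axial_mean(angles$helical_deg[sel])
    out$mean_angle_deg[i] <- m$mean_deg
    out$n[i] <- m$n
  }
  structure(out, class = c("local_angle_field", "data.frame"),
            window = window)
}

#' Normalize profile depths to wall fraction 0-1
#'
#' Affine map of the depth axis so 0 is the epicardial end and 1 the
#' endocardial end of the sampled wall; angles are unchanged, which lets
#' hearts of different wall thickness be overlaid and correlated.
#'
#' @param profile a `depth_profile`.
#' @param wall_bounds `c(min, max)` depth in the profile's current units
#'   (typically min/max segment depth in the region of interest).
#' @return the profile with depths mapped to \[0, 1\] and the `normalized`
#'   attribute set.
#' @export
normalize_depth <- function(profile, wall_bounds) {
  stopifnot(inherits(profile, "depth_profile"), length(wall_bounds) == 2)
  thick <- wall_bounds[2] - wall_bounds[1]
  if (thick <= 0) cond_error("zero wall thickness", "coroalign_config_error")
  profile$depth <- (profile$depth - wall_bounds[1]) / thick
  attr(profile, "normalized") <- TRUE
  profile
}

#' End-to-end vessel depth profile from a skeleton and surface
#'
#' Convenience wrapper: [vessel_angles()] followed by [depth_profile()] on
#' the requested angle type, using the windowing parameters of the config.
#'
#' @param graph a `skeleton_graph`.
#' @param surface surface cloud matrix or `surface_index`.
#' @param config an `analysis_config`.
#' @param angle `"helical"` or `"projection"`.
#' @param ... passed on to [depth_profile()].
#' @return a `depth_profile`.
#' @export
vessel_depth_profile <- function(graph, surface, config,
                                 angle = c("helical", "projection"), ...) {
  angle <- match.arg(angle)
  va <- vessel_angles(graph, surface, config)
  a <- if (angle == "helical") va$helical_deg else va$projection_deg
  depth_profile(a[!va$excluded], va$depth[!va$excluded],
                half_width = config$half_width,
                increment = config$increment, ...)
}
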