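# Shared fixtures: tiny skeletons, analytic frames, and a rotated frame used
# to exercise angle identities away from the coordinate axes.

# canonical axis-aligned frame: g1 radial (z), g2 apex-base (y), g3 circ (x)
axis_frame <- function() {
  build_frame(c(0, 0, 1), c(0, 1, 0))
}

# a frame with no zero components, built from a skewed g1 / axis pair
skew_frame <- function() {
  build_frame(c(1, 2, 3) / sqrt(14), c(-1, 1, 0.5))
}

# straight two-point segment skeleton from a matrix of node pairs
straight_skeleton <- function(starts, ends) {
  n <- nrow(starts)
  nodes <- data.frame(node_id = seq_len(2 * n),
                      x_um = as.vector(rbind(starts[, 1], ends[, 1])),
                      y_um = as.vector(rbind(starts[, 2], ends[, 2])),
                      z_um = as.vector(rbind(starts[, 3], ends[, 3])))
  segments <- data.frame(segment_id = seq_len(n),
                         start_node_id = 2 * seq_len(n) - 1,
                         end_node_id = 2 * seq_len(n))
  points <- data.frame(segment_id = rep(seq_len(n), each = 2),
                       point_order = rep(1:2, n),
                       x_um = nodes$x_um, y_um = nodes$y_um,
                       z_um = nodes$z_um)
  skeleton_graph(nodes, segments, points)
}

# smallest absolute axial difference between two orientations (degrees)
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# sinusoidal stripe image elongated at spatial angle `ang` degrees
stripe_image <- function(ang, npx = 128, freq = 0.1) {
  X <- matrix(rep(seq_len(npx), each = npx), npx, npx)  # X[i,j] = j
  Y <- matrix(rep(seq_len(npx), npx), npx, npx)         # Y[i,j] = i
  beta <- deg2rad_test(ang + 90)  # variation runs perpendicular to stripes
  sin(2 * pi * freq * (X * cos(beta) + Y * sin(beta)))
}

deg2rad_test <- function(x) x * pi / 180

# exact discretized bimodal von Mises spectrum on the 5-degree grid
pdf_spectrum <- function(mu_deg, kappa, increment = 5) {
  g <- angular_grid(increment)
  structure(list(theta_deg = g,
                 amplitude = vonmises_pdf(deg2rad_test(g),
                                          deg2rad_test(mu_deg), kappa),
                 increment = increment, normalized = TRUE,
                 no_signal = FALSE),
            class = "angular_spectrum")
}

# depth profile object from bare vectors (for correlation tests)
bare_profile <- function(depth, mean_deg) {
  structure(data.frame(depth = depth, mean_angle_deg = mean_deg,
                       kappa = NA_real_, u_deg = NA_real_,
                       n = 1L, flagged = FALSE),
            class = c("depth_profile", "data.frame"), normalized = FALSE)
}
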