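test_that("nearest surface point gives depth and g1 by hand", {
  r <- nearest_surface(c(0, 0, 0), matrix(c(0, 0, 10), 1))
  expect_equal(r$depth, 10)
  expect_equal(c(r$g1x, r$g1y, r$g1z), c(0, 0, 1))
  # 3-4-5 triangle; the far point is ignored
  r2 <- nearest_surface(c(0, 0, 0), rbind(c(3, 4, 0), c(0, 0, 100)))
  expect_equal(r2$depth, 5)
  expect_equal(c(r2$g1x, r2$g1y, r2$g1z), c(0.6, 0.8, 0))
})

test_that("grid index equals brute force on random clouds", {
  set.seed(101)
  q <- matrix(runif(1000 * 3, -20, 120), ncol = 3)
  s <- matrix(runif(5000 * 3, 0, 100), ncol = 3)
  a <- nearest_surface(q, s, method = "grid")
  b <- nearest_surface(q, s, method = "brute")
  expect_identical(a$surface_point, b$surface_point)
  expect_equal(a$depth, b$depth, tolerance = 1e-12)
})

test_that("nearest-surface ties resolve to the lowest point index", {
  s <- rbind(c(0, 0, 5), c(0, 0, -5), c(0, 0, 5))  # 1 and 3 identical
  r <- nearest_surface(c(0, 0, 0), s, method = "grid")
  expect_equal(r$surface_point, 1L)
  expect_equal(nearest_surface(c(0, 0, 0), s, method = "brute")$surface_point,
               1L)
})

test_that("a query on the surface is flagged degenerate", {
  r <- nearest_surface(c(1, 2, 3), rbind(c(1, 2, 3), c(9, 9, 9)))
  expect_true(r$degenerate)
  expect_true(is.na(r$g1x))
})

test_that("frame construction matches the hand-computed cases", {
  fr <- build_frame(c(0, 0, 1), c(0, 1, 0))
  expect_equal(fr$g2, c(0, 1, 0))
  expect_equal(fr$g3, c(1, 0, 0))
  # projecting the axis removes its g1 component
  fr2 <- build_frame(c(1, 0, 0), c(1, 1, 0) / sqrt(2))
  expect_equal(fr2$g2, c(0, 1, 0))
  # parallel axis is degenerate
  expect_error(build_frame(c(0, 0, 1), c(0, 0, 1)),
               class = "coroalign_degenerate_error")
})

test_that("frames are orthonormal and magnitude-invariant", {
  set.seed(17)
  for (i in 1:30) {
    g1 <- rnorm(3); g1 <- g1 / sqrt(sum(g1^2))
    v <- rnorm(3)
    if (abs(sum(g1 * v) / sqrt(sum(v^2))) > 1 - 1e-6) next
    fr <- build_frame(g1, v)
    M <- rbind(fr$g1, fr$g2, fr$g3)
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-9)
    fr_scaled <- build_frame(g1, v * 37.5)
    expect_lt(max(abs(fr_scaled$g2 - fr$g2)), 1e-12)
    expect_lt(max(abs(fr_scaled$g3 - fr$g3)), 1e-12)
  }
})

test_that("boundary extraction returns cube faces and rejects empty stacks", {
  st <- image_stack(array(1, c(10, 10, 10)), voxel = c(1, 1, 1))
  surf <- surface_from_labels(st, 0.5)
  expect_equal(nrow(surf), 1000 - 8^3)    # all but the interior core
  on_face <- surf[, 1] %in% c(0.5, 9.5) | surf[, 2] %in% c(0.5, 9.5) |
             surf[, 3] %in% c(0.5, 9.5)
  expect_true(all(on_face))
  expect_error(surface_from_labels(image_stack(array(0, c(4, 4, 4)),
                                               voxel = c(1, 1, 1)), 0.5),
               class = "coroalign_empty_surface_error")
})

test_that("boundary voxels of a hollow hemisphere lie on the ideal surface", {
  vox <- 5
  dims <- c(40, 40, 22)
  arr <- array(0, dims)
  for (k in seq_len(dims[3])) {
    z <- (k - 0.5) * vox
    for (i in seq_len(dims[1])) {
      y <- (i - 0.5) * vox - 100
      for (j in seq_len(dims[2])) {
        x <- (j - 0.5) * vox - 100
        r <- sqrt(x^2 + y^2 + z^2)
        if (r >= 60 && r <= 90) arr[i, j, k] <- 1
      }
    }
  }
  surf <- surface_from_labels(image_stack(arr, voxel = rep(vox, 3)), 0.5)
  p <- sweep(surf, 2, c(100, 100, 0))
  r <- sqrt(rowSums(p^2))
  rxy <- sqrt(p[, 1]^2 + p[, 2]^2)
  # ideal boundary: outer cap r=90, inner cap r=60, base annulus z=0
  d <- pmin(abs(r - 90), abs(r - 60),
            ifelse(rxy >= 60 - vox & rxy <= 90 + vox, abs(p[, 3]), Inf))
  expect_lte(max(d), sqrt(3) * vox)
})

test_that("slab phantom frames are exact: g1 vertical, depth equals |z|", {
  ph <- make_wall_phantom(wall_phantom_spec("slab", n_segments = 50,
                                            seed = 31))
  fr <- segment_frames(ph$graph, ph$surface, ph$config)
  expect_false(any(fr$degenerate))
  expect_equal(fr$g1z, rep(-1, 50))
  expect_lt(max(abs(fr$g1x)), 1e-12)
  expect_equal(fr$depth, ph$truth$depth_um, tolerance = 1e-9)
})
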