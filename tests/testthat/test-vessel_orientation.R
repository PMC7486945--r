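test_that("helical angle identities hold in any frame", {
  for (fr in list(axis_frame(), skew_frame())) {
    expect_equal(helical_angle(fr$g2, fr), 90)
    expect_equal(helical_angle(fr$g3, fr), 0)
    expect_equal(helical_angle((fr$g2 + fr$g3) / sqrt(2), fr), 45)
    expect_equal(helical_angle((fr$g3 - fr$g2) / sqrt(2), fr), -45)
    # any vector in the g1-g3 plane is circumferential
    expect_equal(helical_angle(0.3 * fr$g1 + 0.8 * fr$g3, fr), 0,
                 tolerance = 1e-9)
  }
})

test_that("projection angle identities hold and drop the g1 component", {
  for (fr in list(axis_frame(), skew_frame())) {
    expect_equal(projection_angle(fr$g3, fr), 0)
    expect_equal(projection_angle(fr$g2, fr), 90)
    v <- 0.5 * fr$g2 + 0.5 * fr$g3 + 1.7 * fr$g1
    expect_equal(projection_angle(v, fr), 45, tolerance = 1e-9)
    # a radial vessel has no in-plane direction
    expect_true(is.na(projection_angle(fr$g1 * 2, fr)))
  }
})

test_that("angles are invariant under segment direction reversal", {
  set.seed(23)
  fr <- skew_frame()
  for (i in 1:50) {
    v <- rnorm(3)
    expect_equal(helical_angle(-v, fr), helical_angle(v, fr),
                 tolerance = 1e-9)
    pa <- projection_angle(v, fr)
    if (is.finite(pa)) {
      expect_lt(axial_diff(projection_angle(-v, fr), pa), 1e-9)
    }
  }
  expect_true(is.na(helical_angle(c(0, 0, 0), fr)))
})

test_that("in-plane slab vessels have equal projection and helical angles", {
  ph <- make_wall_phantom(wall_phantom_spec("slab", n_segments = 200,
                                            seed = 47))
  va <- vessel_angles(ph$graph, ph$surface, ph$config)
  expect_false(any(va$excluded))
  expect_equal(va$helical_deg, ph$truth$alpha_true_deg, tolerance = 1e-9)
  expect_equal(va$projection_deg, va$helical_deg, tolerance = 1e-9)
})

test_that("depth profile reports windowed means, kappa and uncertainty", {
  # zero dispersion: every window mean exact, kappa very large
  prof <- depth_profile(rep(30, 40), runif(40, 0, 50), half_width = 15,
                        n_min = 10)
  expect_true(all(abs(prof$mean_angle_deg[!prof$flagged] - 30) < 1e-9))
  expect_true(all(prof$kappa[!prof$flagged] > 500))
  # two separated strata with disjoint windows
  a <- c(rep(-20, 30), rep(70, 30))
  d <- c(runif(30, 0, 20), runif(30, 200, 220))
  p2 <- depth_profile(a, d, half_width = 15, n_min = 10)
  shallow <- p2$depth <= 20 & !p2$flagged
  deep <- p2$depth >= 200 & !p2$flagged
  expect_true(all(abs(p2$mean_angle_deg[shallow] + 20) < 1e-9))
  expect_true(all(abs(p2$mean_angle_deg[deep] - 70) < 1e-9))
  # bins between the strata are flagged empty, not interpolated
  expect_true(all(p2$flagged[p2$depth > 40 & p2$depth < 190]))
})

test_that("small windows are flagged rather than reported", {
  prof <- depth_profile(c(10, 20), c(0, 100), half_width = 15, n_min = 10)
  expect_true(all(prof$flagged))
  expect_true(all(is.na(prof$mean_angle_deg)))
})

test_that("local angle field averages within the moving box", {
  # single segment: field equals its own angle
  ph1 <- make_wall_phantom(wall_phantom_spec("slab", n_segments = 1,
                                             kappa = 2, seed = 3))
  va1 <- vessel_angles(ph1$graph, ph1$surface, ph1$config)
  f1 <- local_angle_field(va1)
  expect_equal(f1$mean_angle_deg, va1$helical_deg)
  expect_equal(f1$n, 1L)
  # uniform-angle phantom: constant field
  ph2 <- make_wall_phantom(wall_phantom_spec("slab", n_segments = 60,
                                             kappa = 1e6,
                                             profile_range = c(25, 25),
                                             seed = 9))
  va2 <- vessel_angles(ph2$graph, ph2$surface, ph2$config)
  f2 <- local_angle_field(va2)
  expect_lt(max(abs(f2$mean_angle_deg - 25)), 0.5)
})

test_that("two-layer phantom field transitions only near the interface", {
  # layers at -20 (shallow half) and +60 (deep half), tight concentration
  prof_fun <- function(d) ifelse(d < 0.5, -20, 60)
  ph <- make_wall_phantom(wall_phantom_spec("slab", n_segments = 400,
                                            profile = prof_fun, kappa = 1e6,
                                            seed = 27))
  va <- vessel_angles(ph$graph, ph$surface, ph$config)
  fld <- local_angle_field(va, window = c(136, 136, 175))
  d01 <- ph$truth$depth01
  away_shallow <- d01 < 0.5 - (175 / 2) / 550
  away_deep <- d01 > 0.5 + (175 / 2) / 550
  expect_lt(max(abs(fld$mean_angle_deg[away_shallow] + 20)), 1)
  expect_lt(max(abs(fld$mean_angle_deg[away_deep] - 60)), 1)
})

test_that("depth normalization is the affine endpoint map", {
  prof <- bare_profile(c(100, 350, 600), c(0, 10, 20))
  np <- normalize_depth(prof, c(100, 600))
  expect_equal(np$depth, c(0, 0.5, 1))
  expect_equal(np$mean_angle_deg, prof$mean_angle_deg)
  expect_true(attr(np, "normalized"))
  # already-normalized profile maps to itself with bounds (0, 1)
  expect_equal(normalize_depth(np, c(0, 1))$depth, np$depth)
  expect_error(normalize_depth(prof, c(5, 5)),
               class = "coroalign_config_error")
})

test_that("walls of different thickness overlay after normalization", {
  mk <- function(thick, seed) {
    ph <- make_wall_phantom(wall_phantom_spec(
      "slab", thickness = thick, n_segments = 1200, kappa = 8, seed = seed))
    va <- vessel_angles(ph$graph, ph$surface, ph$config)
    p <- depth_profile(va$helical_deg, va$depth, half_width = 15,
                       step = thick / 60)
    normalize_depth(p, range(va$depth))
  }
  thin <- mk(550, 61)
  thick <- mk(900, 62)
  cc <- correlate_profiles(thin, thick, n = 200)
  expect_gt(cc$rho, 0.95)
})
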