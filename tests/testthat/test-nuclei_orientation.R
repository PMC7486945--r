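test_that("stripe textures put the spectral peak at the stripe orientation", {
  for (ang in c(0, 30, 75, 120)) {
    sp <- angular_amplitude(stripe_image(ang))
    peak <- sp$theta_deg[which.max(sp$amplitude)]
    expect_lte(axial_diff(peak, ang), 5)
  }
})

test_that("the amplitude is normalized (min 0, unit area) and idempotent", {
  sp <- angular_amplitude(stripe_image(30))
  expect_equal(min(sp$amplitude), 0)
  expect_equal(sum(sp$amplitude) * 5 * pi / 180, 1, tolerance = 1e-6)
  sp2 <- normalize_spectrum(sp)
  expect_equal(sp2$amplitude, sp$amplitude, tolerance = 1e-12)
})

test_that("the amplitude ignores a constant intensity offset", {
  img <- stripe_image(60)
  a <- angular_amplitude(img)$amplitude
  b <- angular_amplitude(img + 0.37)$amplitude
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("rotating the texture shifts the recovered mean accordingly", {
  base <- spectrum_mean(angular_amplitude(stripe_image(20)))$mean_deg
  for (delta in c(15, 45, 90)) {
    rot <- spectrum_mean(angular_amplitude(stripe_image(20 + delta)))$mean_deg
    expect_lte(axial_diff(rot, base + delta), 5)
  }
})

test_that("constant images are flagged as having no orientation signal", {
  sp <- angular_amplitude(matrix(0.5, 64, 64))
  expect_true(sp$no_signal)
  sm <- spectrum_mean(sp)
  expect_true(sm$flagged)
  expect_true(is.na(sm$mean_deg))
  expect_error(angular_amplitude(matrix(0, 16, 16)),
               class = "coroalign_format_error")
})

test_that("isotropic noise shows no preferred orientation", {
  # min-zero normalization rescales a flat spectrum's sampling noise to unit
  # area, so the fitted kappa of pure noise has a floor well above zero; the
  # resultant length R is the normalization-free isotropy measure, and the
  # noise-floor kappa must sit far below that of genuinely oriented texture
  set.seed(55)
  R <- numeric(50)
  kap <- numeric(50)
  for (i in seq_along(R)) {
    sm <- spectrum_mean(angular_amplitude(matrix(rnorm(96 * 96), 96, 96)))
    R[i] <- sm$R
    kap[i] <- sm$kappa
  }
  expect_lte(median(R), 0.2)
  expect_lte(median(kap), 2)
  # oriented texture is far above the noise floor on both measures
  tex <- spectrum_mean(angular_amplitude(stripe_image(30, npx = 96)))
  expect_gt(tex$R, 0.5)
  expect_gt(tex$kappa, 2 * median(kap))
})

test_that("synthetic nuclei at a prescribed orientation are recovered", {
  ns <- make_nuclei_stack(nuclei_phantom_spec(
    n_slices = 1, profile_range = c(60, 60), kappa = 6, seed = 71))
  sm <- spectrum_mean(angular_amplitude(ns$stack$data[, , 1]))
  expect_lte(axial_diff(sm$mean_deg, 60), 5)
})

test_that("spectrum mean matches the generating parameters on exact input", {
  sm <- spectrum_mean(pdf_spectrum(45, 4))
  expect_lte(axial_diff(sm$mean_deg, 45), 1)
  expect_lt(abs(sm$kappa - 4) / 4, 0.15)
  # uniform spectrum: kappa ~ 0 and u at the uniform half-range value
  g <- angular_grid(5)
  unif <- structure(list(theta_deg = g, amplitude = rep(1 / pi, length(g)),
                         increment = 5, normalized = TRUE,
                         no_signal = FALSE), class = "angular_spectrum")
  smu <- spectrum_mean(unif)
  expect_lt(smu$kappa, 0.05)
  expect_equal(smu$u_deg, 61.2, tolerance = 0.01)
  # two equal antipodal peaks cancel
  amp <- rep(0, length(g)); amp[g == 0] <- 1; amp[g == 90] <- 1
  two <- structure(list(theta_deg = g, amplitude = amp, increment = 5,
                        normalized = FALSE, no_signal = FALSE),
                   class = "angular_spectrum")
  expect_true(spectrum_mean(two)$flagged)
})

test_that("a stack of identical stripe slices gives a flat depth profile", {
  img <- (stripe_image(30, npx = 96) + 1) / 2
  st <- image_stack(array(rep(img, 4), c(96, 96, 4)), voxel = c(1, 1, 10))
  prof <- nuclei_depth_profile(st)
  expect_s3_class(prof, "depth_profile")
  expect_equal(prof$depth, c(5, 15, 25, 35))
  expect_true(all(axial_diff(prof$mean_angle_deg, 30) <= 5))
  expect_lt(diff(range(prof$mean_angle_deg)), 1e-6)
})

test_that("a stack with no usable slices is an error", {
  st <- image_stack(array(0.5, c(64, 64, 2)), voxel = c(1, 1, 1))
  expect_error(nuclei_depth_profile(st),
               class = "coroalign_empty_profile_error")
})
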