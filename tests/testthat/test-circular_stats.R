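test_that("axial mean identifies orientations 180 degrees apart", {
  m <- axial_mean(c(10, 190))
  expect_equal(m$mean_deg, 10)
  expect_equal(m$R, 1)
  expect_false(m$flagged)
  expect_equal(axial_mean(c(20, 40))$mean_deg, 30)
})

test_that("antipodal orientations cancel after doubling and are flagged", {
  m <- axial_mean(c(0, 90))
  expect_true(m$flagged)
  expect_true(is.na(m$mean_deg))
  expect_lt(m$R, 1e-12)
})

test_that("axial mean is invariant to 180-degree shifts and equivariant to rotation", {
  set.seed(41)
  for (rep in 1:20) {
    a <- runif(25, -90, 90)
    shift <- sample(c(0, 180), 25, replace = TRUE)
    expect_equal(axial_mean(a + shift)$mean_deg, axial_mean(a)$mean_deg,
                 tolerance = 1e-9)
    delta <- runif(1, -180, 180)
    expect_lt(axial_diff(axial_mean(a + delta)$mean_deg,
                         axial_mean(a)$mean_deg + delta), 1e-6)
  }
})

test_that("weighted axial mean respects weights", {
  # all weight on one orientation
  expect_equal(axial_mean(c(10, 80), weights = c(1, 0))$mean_deg, 10)
  # symmetric weights around 45
  expect_equal(axial_mean(c(30, 60), weights = c(2, 2))$mean_deg, 45)
})

test_that("bimodal von Mises density has the uniform limit and unit axial mass", {
  th <- seq(-pi / 2, pi / 2, length.out = 7)
  expect_equal(vonmises_pdf(th, 0, 0), rep(1 / pi, 7))
  for (k in c(0.1, 1, 10)) {
    mass <- integrate(vonmises_pdf, -pi / 2, pi / 2, mu = 0, kappa = k,
                      rel.tol = 1e-12)$value
    expect_equal(mass, 1, tolerance = 1e-8)
  }
  # period pi: same mass on any half-period
  m2 <- integrate(vonmises_pdf, 0.3, 0.3 + pi, mu = 0.7, kappa = 3,
                  rel.tol = 1e-12)$value
  expect_equal(m2, 1, tolerance = 1e-8)
})

test_that("large-kappa density narrows like a Gaussian of sd 1/sqrt(kappa)", {
  k <- 100
  # at one Gaussian sd from the mode the density falls to exp(-1/2)
  ratio <- vonmises_pdf(1 / sqrt(k), 0, k) / vonmises_pdf(0, 0, k)
  expect_equal(ratio, exp(-0.5), tolerance = 0.01)
  expect_true(all(is.finite(vonmises_pdf(c(0, 1, 3), 0, 5e3))))
})

test_that("von Mises sampler reproduces the target mean", {
  set.seed(7)
  a <- rvonmises_axial(10000, 25, 5)
  expect_true(all(a > -90 & a <= 90))
  expect_lt(axial_diff(axial_mean(a)$mean_deg, 25), 1)
})

test_that("kappa fit recovers itself on an exact discretized density", {
  for (k in c(0.5, 4, 20)) {
    fit <- fit_kappa(pdf_spectrum(45, k), 45)
    expect_lt(abs(fit$kappa - k), 0.05)
    expect_false(fit$at_bound)
  }
  # uniform density has no concentration
  g <- angular_grid(5)
  unif <- structure(list(theta_deg = g,
                         amplitude = rep(1 / pi, length(g)),
                         increment = 5, normalized = TRUE,
                         no_signal = FALSE), class = "angular_spectrum")
  expect_lt(fit_kappa(unif, 0)$kappa, 0.05)
})

test_that("kappa fit recovers the generating concentration from samples", {
  set.seed(13)
  kap <- numeric(25)
  for (r in seq_along(kap)) {
    x <- rvonmises_axial(500, 30, 8)
    kap[r] <- fit_kappa(x, axial_mean(x)$mean_deg)$kappa
  }
  expect_lt(abs(median(kap) - 8) / 8, 0.25)
})

test_that("standard uncertainty has the uniform and Gaussian limits", {
  expect_equal(standard_uncertainty(0), 61.2, tolerance = 1e-6)
  # monotone decreasing in kappa, vanishing as kappa grows
  u <- sapply(c(0, 0.5, 2, 8, 32, 128), standard_uncertainty)
  expect_true(all(diff(u) < 0))
  expect_lt(standard_uncertainty(1e4), 1)
  # Gaussian limit: u approaches the standard deviation 1/sqrt(kappa)
  u100 <- standard_uncertainty(100) * pi / 180
  expect_lt(abs(u100 - 0.1) / 0.1, 0.05)
})

test_that("uncertainty interval contains 68 percent of the axial mass", {
  for (k in c(0, 1, 10, 100)) {
    u <- standard_uncertainty(k) * pi / 180
    mass <- integrate(vonmises_pdf, -u, u, mu = 0, kappa = k,
                      rel.tol = 1e-12)$value /
            integrate(vonmises_pdf, -pi / 2, pi / 2, mu = 0, kappa = k,
                      rel.tol = 1e-12)$value
    expect_equal(mass, 0.68, tolerance = 1e-6)
  }
})

test_that("empirical density integrates to one over the half-period", {
  set.seed(3)
  e <- empirical_density(runif(200, -90, 90), 5)
  expect_equal(sum(e$density) * 5 * pi / 180, 1, tolerance = 1e-12)
})
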