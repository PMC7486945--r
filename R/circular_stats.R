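# Axial circular statistics: doubled-angle means, the bimodal von Mises
# density, concentration fits, and the standard uncertainty used for error
# bars. All internal arithmetic is in radians; user-facing angles in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Fold angles to the axial reporting range (-90, 90] degrees
#'
#' Orientations are axial (a line at 10 degrees is the same line at 190
#' degrees); all reported angles live on one half-period.
#'
#' @param x numeric vector of angles in degrees.
#' @return angles folded modulo 180 into (-90, 90].
#' @export
fold_axial <- function(x) {
  y <- (x + 90) %% 180 - 90
  y[y == -90] <- 90
  y
}

#' Axial circular mean by angle doubling
#'
#' Doubles each orientation, averages unit phasors in the complex plane
#' (optionally weighted), and halves the argument of the resultant. The
#' resultant length `R` is 1 for perfectly aligned orientations and 0 for
#' antipodal/uniform sets (e.g. equal mass at 0 and 90 degrees), in which
#' case the mean is undefined and the result is flagged.
#'
#' @param angles_deg numeric vector of orientations in degrees (axial,
#'   period 180).
#' @param weights optional non-negative weights, same length as `angles_deg`.
#' @return list with `mean_deg` (in (-90, 90], `NA` when flagged), `R`
#'   (resultant length in \[0, 1\]), `flagged` (TRUE when `R` < 1e-12) and `n`.
#' @examples
#' axial_mean(c(10, 190))   # same line twice: mean 10, R = 1
#' axial_mean(c(0, 90))     # antipodal after doubling: flagged
#' @export
axial_mean <- function(angles_deg, weights = NULL) {
  stopifnot(length(angles_deg) >= 1, all(is.finite(angles_deg)))
  if (is.null(weights)) {
    weights <- rep(1, length(angles_deg))
  } else {
    stopifnot(length(weights) == length(angles_deg), all(weights >= 0))
    if (sum(weights) <= 0) stop("weights must have positive sum")
  }
  w <- weights / sum(weights)
  z <- sum(w * exp(2i * deg2rad(angles_deg)))
  R <- Mod(z)
  if (R < 1e-12) {
    return(list(mean_deg = NA_real_, R = R, flagged = TRUE,
                n = length(angles_deg)))
  }
  list(mean_deg = fold_axial(rad2deg(Arg(z) / 2)), R = R, flagged = FALSE,
       n = length(angles_deg))
}

#' Bimodal (axial) von Mises probability density
#'
#' Density with antipodal modes at `mu` and `mu + pi`,
#' \deqn{f(\theta) = \frac{e^{\kappa\cos(\theta-\mu)} +
#'   e^{\kappa\cos(\theta+\pi-\mu)}}{2\pi I_0(\kappa)},}
#' evaluated in an exponent-shifted form that is stable for large
#' concentrations. `f` has period pi and unit mass on any half-period
#' (length-pi interval), which is the natural normalization for axial data;
#' at `kappa = 0` it is the uniform axial density 1/pi.
#'
#' @param theta numeric vector, angles in radians.
#' @param mu mode location in radians.
#' @param kappa concentration parameter, `>= 0`. Large kappa approaches a
#'   Gaussian with variance 1/kappa; kappa = 0 is uniform.
#' @return density values at `theta`.
#' @export
vonmises_pdf <- function(theta, mu = 0, kappa) {
  stopifnot(kappa >= 0, is.finite(kappa))
  i0e <- besselI(kappa, 0, expon.scaled = TRUE)  # I0(k) * exp(-k)
  d <- theta - mu
  (exp(kappa * (cos(d) - 1)) + exp(kappa * (cos(d + pi) - 1))) / (2 * pi * i0e)
}

#' Angular grid of wedge/bin centers
#'
#' @param increment bin width in degrees; must divide 180.
#' @return centers 0, increment, ..., 180 - increment.
#' @export
angular_grid <- function(increment = 5) {
  stopifnot(increment > 0, abs(180 / increment - round(180 / increment)) < 1e-9)
  seq(0, 180 - increment, by = increment)
}

# Bin index (1-based) on the axial grid; bins are [c - inc/2, c + inc/2)
# around each center c, boundary ties assigned to the lower center.
axial_bin_index <- function(angles_deg, increment = 5) {
  nb <- round(180 / increment)
  a <- angles_deg %% 180
  (ceiling((a - increment / 2) / increment) %% nb) + 1L
}

#' Empirical axial angular density on the shared grid
#'
#' Histogram of axial angles on the wedge grid, scaled to a density per
#' radian so that it integrates to 1 over one half-period -- the same scale
#' as [vonmises_pdf()].
#'
#' @param angles_deg orientations in degrees.
#' @param increment bin width in degrees.
#' @return list with `theta_deg` (bin centers) and `density`.
#' @export
empirical_density <- function(angles_deg, increment = 5) {
  grid <- angular_grid(increment)
  idx <- axial_bin_index(angles_deg, increment)
  counts <- tabulate(idx, nbins = length(grid))
  list(theta_deg = grid,
       density = counts / (length(angles_deg) * deg2rad(increment)))
}

#' Fit the von Mises concentration by least squares against the density
#'
#' Minimizes the sum of squared differences between an angular density and
#' the bimodal von Mises pdf with the mean held at `mu_deg`, over
#' `kappa` in `[0, kappa_max]`. Accepts either raw angles (converted to an
#' empirical density on the 5-degree grid) or an [angular_spectrum] object
#' (its normalized amplitude is the density). A coarse log-spaced bracket
#' search precedes golden-section refinement, so the objective need only be
#' locally unimodal.
#'
#' @param x numeric vector of angles in degrees, or an `angular_spectrum`.
#' @param mu_deg mean orientation in degrees (from [axial_mean()] or
#'   [spectrum_mean()]).
#' @param increment grid width in degrees for sample-based densities.
#' @param kappa_max upper bound of the search interval.
#' @return list with `kappa`, `at_bound` (TRUE when the minimizer sits at
#'   either end of the interval) and `objective` (residual sum of squares).
#' @export
fit_kappa <- function(x, mu_deg, increment = 5, kappa_max = 1e4) {
  if (inherits(x, "angular_spectrum")) {
    if (!isTRUE(x$normalized)) x <- normalize_spectrum(x)
    grid <- x$theta_deg
    dens <- x$amplitude
  } else {
    stopifnot(is.numeric(x), length(x) >= 1)
    e <- empirical_density(x, increment)
    grid <- e$theta_deg
    dens <- e$density
  }
  th <- deg2rad(grid)
  mu <- deg2rad(mu_deg)
  obj <- function(k) sum((dens - vonmises_pdf(th, mu, k))^2)
  cand <- c(0, 10^seq(-3, log10(kappa_max), length.out = 80))
  vals <- vapply(cand, obj, numeric(1))
  i <- which.min(vals)
  lo <- cand[max(1L, i - 1L)]
  hi <- cand[min(length(cand), i + 1L)]
  if (lo == hi) {
    kap <- lo
  } else {
    kap <- stats::optimize(obj, c(lo, hi), tol = 1e-6)$minimum
  }
  # snap to the boundary when the coarse scan already favoured it
  if (i == 1L && obj(0) <= obj(kap)) kap <- 0
  if (i == length(cand) && obj(kappa_max) <= obj(kap)) kap <- kappa_max
  list(kappa = kap,
       at_bound = (kap <= 1e-8) || (kap >= kappa_max * (1 - 1e-6)),
       objective = obj(kap))
}

#' Standard uncertainty of an axial von Mises distribution
#'
#' The half-width `u` such that the bimodal von Mises density centered at 0,
#' restricted (and renormalized) to the axial half-period (-pi/2, pi/2],
#' carries 68% of its mass on (-u, u). This replaces the standard deviation,
#' which is ill-defined for bimodal circular distributions: at `kappa = 0`
#' the axial distribution is uniform and `u = 0.68 * 90 = 61.2` degrees,
#' while for large `kappa` `u` approaches the Gaussian standard deviation
#' `1/sqrt(kappa)`.
#'
#' @param kappa concentration, `>= 0`.
#' @param level probability mass required inside (-u, u); default 0.68.
#' @return `u` in degrees, in `[0, 90]`.
#' @export
standard_uncertainty <- function(kappa, level = 0.68) {
  stopifnot(kappa >= 0, level > 0, level < 1)
  total <- stats::integrate(vonmises_pdf, -pi / 2, pi / 2, mu = 0,
                            kappa = kappa, rel.tol = 1e-12,
                            abs.tol = 1e-14)$value
  mass <- function(u) {
    stats::integrate(vonmises_pdf, -u, u, mu = 0, kappa = kappa,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value / total - level
  }
  u <- stats::uniroot(mass, c(0, pi / 2), tol = 1e-10)$root
  rad2deg(u)
}

#' Draw directed von Mises variates
#'
#' Best-Fisher rejection sampler for the (unimodal) von Mises distribution
#' on the circle; the axial sampler folds these draws.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration, `>= 0` (0 gives the uniform distribution).
#' @return numeric vector of angles in radians in \[0, 2*pi).
#' @export
rvonmises <- function(n, mu = 0, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.6))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    out <- c(out, th)
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

#' Draw axial orientations from the bimodal von Mises distribution
#'
#' Folding a directed von Mises draw to one half-period yields exactly the
#' bimodal axial density of [vonmises_pdf()].
#'
#' @param n number of draws.
#' @param mu_deg mean orientation in degrees.
#' @param kappa concentration.
#' @return orientations in degrees in (-90, 90].
#' @export
rvonmises_axial <- function(n, mu_deg, kappa) {
  fold_axial(rad2deg(rvonmises(n, deg2rad(mu_deg), kappa)))
}
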