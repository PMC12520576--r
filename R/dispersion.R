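#' Viscous capillary growth rate (long-wave dispersion relation)
#'
#' Growth rate of an axisymmetric sinusoidal perturbation of wavenumber `k`
#' on a viscous liquid cylinder of radius `r_jet`, from the long-wave viscous
#' dispersion relation
#' \deqn{\omega^2 + 3\nu k^2 \omega = \frac{\gamma}{2\rho R^3}(kR)^2(1-(kR)^2)}
#' with kinematic viscosity nu = mu/rho. The positive root is returned;
#' perturbations with kR >= 1 are stable and yield 0.
#'
#' @param k wavenumber(s), 1/m, strictly positive
#' @param fluid a [fluid_properties()]
#' @param r_jet jet radius in m
#' @return growth rate(s) omega in 1/s, vectorised over `k`
#' @examples
#' weber_growth_rate(2 * pi / 1e-3, sorbitol_fluid(), 95e-6)
#' @export
weber_growth_rate <- function(k, fluid, r_jet) {
  stopifnot(inherits(fluid, "fluid_properties"), r_jet > 0)
  if (any(k <= 0)) abort("`k` must be > 0", class = "capsulejet_domain_error")
  kr <- k * r_jet
  nu <- fluid$viscosity / fluid$density
  a <- 3 * nu * k^2 / 2
  b <- fluid$surface_tension / (2 * fluid$density * r_jet^3) * kr^2 * (1 - kr^2)
  om <- -a + sqrt(pmax(a^2 + b, 0))
  ifelse(kr >= 1, 0, pmax(om, 0))
}

#' Dispersion curve over the unstable band
#'
#' Evaluates the viscous growth rate on a grid of dimensionless wavenumbers
#' kR in (0, 1) and normalises by omega_0 = 1/t_cap.
#'
#' @inheritParams weber_growth_rate
#' @param n grid size (default 512)
#' @return a tibble of class `dispersion_curve` with columns `k_per_m`, `kr`,
#'   `omega_per_s`, `omega_norm`; the fastest mode is attached as the
#'   `fastest` attribute (see [fastest_growing_mode()])
#' @export
dispersion_curve <- function(fluid, r_jet, n = 512) {
  kr <- seq(1 / (n + 1), 1, length.out = n)
  k <- kr / r_jet
  om <- weber_growth_rate(k, fluid, r_jet)
  om0 <- 1 / sqrt(fluid$density * r_jet^3 / fluid$surface_tension)
  out <- tibble(k_per_m = k, kr = kr, omega_per_s = om, omega_norm = om / om0)
  attr(out, "fastest") <- fastest_growing_mode(fluid, r_jet)
  attr(out, "fluid") <- fluid
  attr(out, "r_jet") <- r_jet
  class(out) <- c("dispersion_curve", class(out))
  out
}

#' Fastest-growing capillary mode
#'
#' Numerically maximises the viscous growth rate over kR in (0, 1) and checks
#' the result against the closed form kR* = 1 / sqrt(2 + 3 sqrt(2) Oh); the
#' two must agree to 1e-6 relative. Also reports the droplet radius that one
#' wavelength of jet volume would form at that wavenumber.
#'
#' @inheritParams weber_growth_rate
#' @return a one-row tibble: `kr_star`, `k_star_per_m`, `omega_star_per_s`,
#'   `radius_um`
#' @examples
#' fastest_growing_mode(sorbitol_fluid(), 95e-6) # kR* ~ 0.698, R0 ~ 180 um
#' @export
fastest_growing_mode <- function(fluid, r_jet) {
  stopifnot(inherits(fluid, "fluid_properties"), r_jet > 0)
  oh <- fluid$viscosity / sqrt(fluid$density * fluid$surface_tension * r_jet)
  kr_closed <- 1 / sqrt(2 + 3 * sqrt(2) * oh)
  opt <- optimize(function(kr) weber_growth_rate(kr / r_jet, fluid, r_jet),
                  interval = c(1e-6, 1 - 1e-9), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  if (abs(opt$maximum - kr_closed) / kr_closed > 1e-6)
    warn(sprintf(
      "numeric maximiser kR* = %.8f deviates from closed form %.8f",
      opt$maximum, kr_closed))
  k_star <- kr_closed / r_jet
  tibble(
    kr_star = kr_closed,
    k_star_per_m = k_star,
    omega_star_per_s = weber_growth_rate(k_star, fluid, r_jet),
    radius_um = m_to_um(drop_radius_from_wavenumber(k_star, r_jet))
  )
}

#' Droplet radius from a breakup wavenumber
#'
#' Volume conservation: one wavelength 2 pi / k of a cylinder of radius
#' `r_jet` collapses into a single sphere, so
#' R0 = R (3 pi / (2 k R))^(1/3).
#'
#' @param k wavenumber(s), 1/m, > 0
#' @param r_jet jet radius in m
#' @return droplet radius in m, vectorised over `k`
#' @export
drop_radius_from_wavenumber <- function(k, r_jet) {
  if (any(k <= 0)) abort("`k` must be > 0", class = "capsulejet_domain_error")
  stopifnot(r_jet > 0)
  r_jet * (3 * pi / (2 * k * r_jet))^(1 / 3)
}

#' Targeted droplet radius under periodic forcing
#'
#' When the jet is forced at frequency f, one droplet forms per period and
#' volume conservation gives the targeted radius
#' \deqn{R_{th} = \left(\frac{3 R_{jet}^2 v_{jet}}{4 f}\right)^{1/3}.}
#' `frequency_for_radius()` is the exact inverse.
#'
#' @param f_hz forcing frequency in Hz (> 0), vectorised
#' @param run a [jet_run()] supplying the jet radius and velocity
#' @return targeted radius in um
#' @examples
#' targeted_radius(c(650, 1150, 1500), jet_run()) # ~256, 212, 194 um
#' @export
targeted_radius <- function(f_hz, run) {
  stopifnot(inherits(run, "jet_run"))
  if (any(f_hz <= 0)) abort("`f_hz` must be > 0", class = "capsulejet_domain_error")
  v <- jet_velocity(run)
  m_to_um((3 * run$jet_radius^2 * v / (4 * f_hz))^(1 / 3))
}

#' @rdname targeted_radius
#' @param radius_um requested droplet radius in um (> 0), vectorised
#' @return `frequency_for_radius()`: forcing frequency in Hz
#' @export
frequency_for_radius <- function(radius_um, run) {
  stopifnot(inherits(run, "jet_run"))
  if (any(radius_um <= 0)) abort("`radius_um` must be > 0", class = "capsulejet_domain_error")
  v <- jet_velocity(run)
  3 * run$jet_radius^2 * v / (4 * um_to_m(radius_um)^3)
}

#' Piezo actuation band from dispersion bounds
#'
#' Converts the dimensionless-wavenumber band over which the compound jet can
#' be forced into a frequency band via k = 2 pi f / v_jet, i.e.
#' f = kR v_jet / (2 pi R). The band edges default to the fastest modes of
#' two bracketing fluids (the pure-alginate lower edge and pure-sorbitol
#' upper edge), or may be given explicitly as `kr_bounds`.
#'
#' @param run a [jet_run()]
#' @param fluid_lo,fluid_hi fluids whose fastest modes set the lower and
#'   upper kR bounds (ignored when `kr_bounds` is given)
#' @param kr_bounds optional explicit numeric length-2 vector of kR bounds
#' @return a one-row tibble: `kr_lo`, `kr_hi`, `f_min_hz`, `f_max_hz`
#' @examples
#' actuation_band(jet_run(), kr_bounds = c(0.185, 0.7)) # ~ 500-1900 Hz
#' @export
actuation_band <- function(run, fluid_lo = alginate_fluid(),
                           fluid_hi = sorbitol_fluid(), kr_bounds = NULL) {
  stopifnot(inherits(run, "jet_run"))
  if (is.null(kr_bounds)) {
    kr_bounds <- sort(c(
      fastest_growing_mode(fluid_lo, run$jet_radius)$kr_star,
      fastest_growing_mode(fluid_hi, run$jet_radius)$kr_star
    ))
  }
  stopifnot(length(kr_bounds) == 2, all(kr_bounds > 0))
  kr_bounds <- sort(kr_bounds)
  if (kr_bounds[1] == kr_bounds[2])
    warn("degenerate actuation band: identical kR bounds")
  v <- jet_velocity(run)
  f <- kr_bounds * v / (2 * pi * run$jet_radius)
  tibble(kr_lo = kr_bounds[1], kr_hi = kr_bounds[2],
         f_min_hz = f[1], f_max_hz = f[2])
}

#' Spatial growth rate from the fragmentation length
#'
#' Within the linear approximation, a perturbation seeded at the nozzle with
#' relative amplitude delta_0 grows as exp(sigma x) and pinches the jet when
#' the amplification reaches the jet radius, so sigma = ln(a/delta_0) / L_frag.
#' The log-amplification `gain` defaults to 7, i.e. a seed perturbation about
#' a thousandth of the jet radius; only relative comparisons across (f, U)
#' conditions are meaningful.
#'
#' @param l_frag_m fragmentation length(s) in m (> 0)
#' @param gain log-amplification constant (default 7)
#' @return spatial growth rate(s) in 1/m
#' @export
spatial_growth_rate <- function(l_frag_m, gain = 7) {
  if (any(l_frag_m <= 0)) abort("`l_frag_m` must be > 0", class = "capsulejet_domain_error")
  gain / l_frag_m
}
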