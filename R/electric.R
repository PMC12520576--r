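#' Bead velocity at fragmentation (mass and momentum conservation)
#'
#' In the beads-on-a-string regime the capillary tension of the connecting
#' filament decelerates the beads from the jet velocity toward
#' \deqn{v_d = v_{jet} - \frac{2\gamma}{\rho R_{jet} v_{jet}}.}
#' The value may be negative for slow jets; callers decide validity.
#'
#' @param run a [jet_run()]
#' @param fluid a [fluid_properties()]
#' @return bead velocity in m/s
#' @examples
#' schneider_bead_velocity(jet_run(), alginate_fluid()) # ~0.84 m/s
#' @export
schneider_bead_velocity <- function(run, fluid) {
  stopifnot(inherits(run, "jet_run"), inherits(fluid, "fluid_properties"))
  v <- jet_velocity(run)
  if (v <= 0) abort("jet velocity must be > 0", class = "capsulejet_domain_error")
  v - 2 * fluid$surface_tension / (fluid$density * run$jet_radius * v)
}

#' Capillary force exerted by a connecting filament
#'
#' F = 2 pi R r_f gamma, the retarding force a thin filament of radius `r_f`
#' exerts on a bead formed from a jet of radius `R`.
#'
#' @param r_jet_m jet (bead-scale) radius, m, >= 0
#' @param r_filament_m filament radius, m, >= 0
#' @param surface_tension N/m
#' @return force in N
#' @export
capillary_force <- function(r_jet_m, r_filament_m, surface_tension) {
  if (any(c(r_jet_m, r_filament_m, surface_tension) < 0))
    abort("inputs must be >= 0", class = "capsulejet_domain_error")
  2 * pi * r_jet_m * r_filament_m * surface_tension
}

#' Electric Bond number and whipping thresholds
#'
#' The electric Bond number compares electric to capillary stress on a
#' charged cylinder: Gamma = eps0 U^2 / (R gamma). Whipping (lateral bending)
#' sets in when Gamma reaches a critical value Gamma_c, so the threshold
#' potential for a cylinder of radius r is U_c(r) = sqrt(Gamma_c r gamma /
#' eps0) and scales as sqrt(r). The thin filament connecting consecutive
#' beads, about `filament_ratio` times thinner than the jet, therefore whips
#' at a proportionally lower potential. Gamma_c is a calibration constant
#' absorbing the electrode geometry; its default places the jet threshold at
#' 7000 V for a 95 um jet of 2% alginate.
#'
#' @param u_volts applied potential, V, >= 0 (vectorised)
#' @param r_jet_m jet radius, m
#' @param surface_tension N/m
#' @param gamma_c critical Bond number (calibration constant); default
#'   [calibrate_gamma_c()] with its defaults
#' @param filament_ratio jet-to-filament radius ratio (>= 1, default 10)
#' @return a tibble with one row per `u_volts`: `u_volts`, `bond_number`,
#'   `jet_whipping_v`, `filament_whipping_v`, `gamma_c`, `filament_ratio`,
#'   `whipping` (one of "none", "filament", "jet")
#' @examples
#' electric_report(c(0, 2500, 7500), 95e-6, 59.8e-3)
#' @export
electric_report <- function(u_volts, r_jet_m, surface_tension,
                            gamma_c = calibrate_gamma_c(),
                            filament_ratio = 10) {
  if (any(u_volts < 0)) abort("`u_volts` must be >= 0", class = "capsulejet_domain_error")
  stopifnot(r_jet_m > 0, surface_tension > 0, gamma_c > 0, filament_ratio >= 1)
  gam <- .eps0 * u_volts^2 / (r_jet_m * surface_tension)
  u_jet <- sqrt(gamma_c * r_jet_m * surface_tension / .eps0)
  u_fil <- sqrt(gamma_c * (r_jet_m / filament_ratio) * surface_tension / .eps0)
  tibble(
    u_volts = u_volts,
    bond_number = gam,
    jet_whipping_v = u_jet,
    filament_whipping_v = u_fil,
    gamma_c = gamma_c,
    filament_ratio = filament_ratio,
    whipping = dplyr::case_when(
      u_volts >= u_jet ~ "jet",
      u_volts >= u_fil ~ "filament",
      TRUE ~ "none"
    )
  )
}

#' Calibrate the critical electric Bond number
#'
#' Returns the Gamma_c for which the jet whipping threshold equals
#' `u_jet_volts` at the given jet radius and surface tension (defaults:
#' 7000 V, 95 um, 59.8 mN/m).
#'
#' @param u_jet_volts observed jet whipping potential (V)
#' @param r_jet_m jet radius (m)
#' @param surface_tension N/m
#' @return dimensionless Gamma_c
#' @export
calibrate_gamma_c <- function(u_jet_volts = 7000, r_jet_m = 95e-6,
                              surface_tension = 59.8e-3) {
  .eps0 * u_jet_volts^2 / (r_jet_m * surface_tension)
}

#' Cutoff and threshold set for phase classification
#'
#' Bundles the boundaries of the (kR, Gamma) phase plane: the unstable-band
#' cutoff wavenumbers at zero charge (where the spatial growth rate falls to
#' `iso_level`, 850 1/m by default), a linear charge-induced shift of the
#' band toward higher wavenumbers, and the two whipping thresholds expressed
#' as Bond numbers.
#'
#' @param kr_lo,kr_hi cutoff dimensionless wavenumbers at Gamma = 0
#' @param kr_shift fractional band shift per unit Gamma (default 0.15)
#' @param gamma_filament,gamma_jet whipping Bond-number thresholds. Defaults
#'   derive from the calibrated Gamma_c: the filament (ten times thinner than
#'   the jet) whips at Gamma_c/10 measured on the jet scale, the jet at
#'   Gamma_c.
#' @param iso_level growth-rate iso-level defining the cutoffs (1/m)
#' @return a list of class `phase_cutoffs`
#' @export
phase_cutoffs <- function(kr_lo = 0.185, kr_hi = 0.7, kr_shift = 0.15,
                          gamma_filament = calibrate_gamma_c() / 10,
                          gamma_jet = calibrate_gamma_c(),
                          iso_level = 850) {
  stopifnot(kr_lo > 0, kr_hi > kr_lo, gamma_jet > gamma_filament)
  structure(list(kr_lo = kr_lo, kr_hi = kr_hi, kr_shift = kr_shift,
                 gamma_filament = gamma_filament, gamma_jet = gamma_jet,
                 iso_level = iso_level),
            class = "phase_cutoffs")
}

#' Classify a point of the (kR, Gamma) phase plane
#'
#' Returns the jet response regime at dimensionless wavenumber `kr` and
#' electric Bond number `gamma`:
#' \itemize{
#'   \item "jet-whipping" for Gamma >= the jet threshold;
#'   \item "filament-whipping" for Gamma >= the filament threshold;
#'   \item "II" (bimodal: the second harmonic 2k is also inside the excitable
#'     band) when kr < upper cutoff / 2;
#'   \item "I" (monomodal Plateau-Rayleigh) otherwise.
#' }
#' Cutoffs shift toward higher wavenumbers with charge:
#' kR_cut(Gamma) = kR_cut(0) (1 + kr_shift Gamma). All boundaries are
#' half-open; a point exactly on a boundary takes the lower region's label
#' (region order I < II < filament-whipping < jet-whipping).
#'
#' @param kr dimensionless wavenumber(s), > 0
#' @param gamma electric Bond number(s), >= 0
#' @param cutoffs a [phase_cutoffs()]
#' @return character vector of labels
#' @examples
#' classify_phase_point(0.5, 0)   # "I"
#' classify_phase_point(0.2, 0)   # "II"
#' @export
classify_phase_point <- function(kr, gamma, cutoffs = phase_cutoffs()) {
  stopifnot(inherits(cutoffs, "phase_cutoffs"))
  if (any(kr <= 0)) abort("`kr` must be > 0", class = "capsulejet_domain_error")
  if (any(gamma < 0)) abort("`gamma` must be >= 0", class = "capsulejet_domain_error")
  n <- max(length(kr), length(gamma))
  kr <- rep_len(kr, n); gamma <- rep_len(gamma, n)
  kr_hi <- cutoffs$kr_hi * (1 + cutoffs$kr_shift * gamma)
  # Half-open rule: ties go to the lower region, so whipping requires strict
  # exceedance and the II/I split keeps the boundary point in II.
  dplyr::case_when(
    gamma > cutoffs$gamma_jet ~ "jet-whipping",
    gamma > cutoffs$gamma_filament ~ "filament-whipping",
    kr <= kr_hi / 2 ~ "II",
    TRUE ~ "I"
  )
}

#' Phase diagram over a (kR, Gamma) grid
#'
#' @param kr_range,gamma_range numeric length-2 ranges
#' @param n_kr,n_gamma grid sizes
#' @inheritParams classify_phase_point
#' @return a tibble of class `phase_diagram` with columns `kR`, `Gamma`,
#'   `region`, suitable for CSV export and [autoplot()]
#' @export
phase_diagram <- function(kr_range = c(0.05, 1.2), gamma_range = c(0, 100),
                          n_kr = 100, n_gamma = 100,
                          cutoffs = phase_cutoffs()) {
  grid <- tidyr::expand_grid(
    kR = seq(kr_range[1], kr_range[2], length.out = n_kr),
    Gamma = seq(gamma_range[1], gamma_range[2], length.out = n_gamma)
  )
  out <- mutate(grid, region = classify_phase_point(.data$kR, .data$Gamma, cutoffs))
  class(out) <- c("phase_diagram", class(out))
  out
}
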