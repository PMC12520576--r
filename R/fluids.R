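#' Fluid properties of one jet phase
#'
#' Container for the density, surface tension and zero-shear viscosity of a
#' single liquid phase (e.g. the sorbitol core or the alginate shell
#' solution). All fields are SI.
#'
#' @param density kg/m^3, must be positive
#' @param surface_tension N/m, must be positive
#' @param viscosity Pa.s (zero-shear), must be non-negative
#' @param label free-text label
#' @return an object of class `fluid_properties`
#' @examples
#' sorbitol_fluid()
#' fluid_properties(1000, 59.8e-3, 1.04, "alginate 2%")
#' @export
fluid_properties <- function(density, surface_tension, viscosity, label = "fluid") {
  stopifnot(is.numeric(density), is.numeric(surface_tension), is.numeric(viscosity))
  if (density <= 0) abort("`density` must be > 0", class = "capsulejet_invalid_configuration")
  if (surface_tension <= 0) abort("`surface_tension` must be > 0", class = "capsulejet_invalid_configuration")
  if (viscosity < 0) abort("`viscosity` must be >= 0", class = "capsulejet_invalid_configuration")
  structure(
    list(density = density, surface_tension = surface_tension,
         viscosity = viscosity, label = label),
    class = "fluid_properties"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties: %s>\n", x$label))
  cat(sprintf("  density         %g kg/m^3\n", x$density))
  cat(sprintf("  surface tension %g mN/m\n", x$surface_tension * 1e3))
  cat(sprintf("  viscosity       %g mPa.s\n", x$viscosity * 1e3))
  invisible(x)
}

#' Reference fluids
#'
#' Presets for the two pure phases bracketing the compound jet, and an
#' effective single-phase stand-in for the compound jet itself. The pure
#' sorbitol solution has density 1000 kg/m^3, surface tension 72 mN/m and
#' viscosity 1 mPa.s; the pure 2% alginate solution has surface tension
#' 59.8 mN/m and zero-shear viscosity 1.04 Pa.s. The compound preset keeps
#' the alginate interface tension with an effective viscosity of 30 mPa.s,
#' which places the fragmentation length of the forced jet a few millimetres
#' from the nozzle, between the two pure-fluid limits (see the methods
#' vignette).
#'
#' @return a `fluid_properties` object
#' @export
sorbitol_fluid <- function() fluid_properties(1000, 72e-3, 1e-3, "sorbitol")

#' @rdname sorbitol_fluid
#' @export
alginate_fluid <- function() fluid_properties(1000, 59.8e-3, 1.04, "alginate 2%")

#' @rdname sorbitol_fluid
#' @export
compound_fluid <- function() fluid_properties(1000, 59.8e-3, 0.03, "compound (effective)")

#' Jet run configuration
#'
#' Geometry, flow splits and actuation of one production run. Arguments are
#' in bench units (um, mL/h, Hz, V); the stored object is SI with derived
#' totals.
#'
#' @param nozzle_radius_um nozzle radius R in um (default 95)
#' @param q_cs_mlh,q_is_mlh,q_as_mlh cell-suspension, intermediate and
#'   alginate flow rates in mL/h (defaults 45/45/75, totalling 165)
#' @param frequency_hz piezo actuation frequency f (Hz, >= 0; 0 = free breakup)
#' @param potential_v DC electric potential U (V, >= 0)
#' @param jet_radius_um jet radius, defaults to the nozzle radius
#' @param piezo_amplitude_um piezo displacement amplitude (default 4 um)
#' @return an object of class `jet_run`
#' @examples
#' jet_run(frequency_hz = 1000)
#' @export
jet_run <- function(nozzle_radius_um = 95,
                    q_cs_mlh = 45, q_is_mlh = 45, q_as_mlh = 75,
                    frequency_hz = 0, potential_v = 0,
                    jet_radius_um = nozzle_radius_um,
                    piezo_amplitude_um = 4) {
  if (nozzle_radius_um <= 0 || jet_radius_um <= 0)
    abort("nozzle and jet radii must be > 0", class = "capsulejet_invalid_configuration")
  if (frequency_hz < 0) abort("`frequency_hz` must be >= 0", class = "capsulejet_invalid_configuration")
  if (potential_v < 0) abort("`potential_v` must be >= 0", class = "capsulejet_invalid_configuration")
  if (min(q_cs_mlh, q_is_mlh, q_as_mlh) < 0)
    abort("flow rates must be >= 0", class = "capsulejet_invalid_configuration")
  flows <- mlh_to_m3s(c(cs = q_cs_mlh, is = q_is_mlh, as = q_as_mlh))
  structure(
    list(
      nozzle_radius = um_to_m(nozzle_radius_um),
      jet_radius = um_to_m(jet_radius_um),
      flows = flows,
      total_flow = sum(flows),
      frequency = frequency_hz,
      potential = potential_v,
      piezo_amplitude = um_to_m(piezo_amplitude_um)
    ),
    class = "jet_run"
  )
}

#' @export
print.jet_run <- function(x, ...) {
  cat("<jet_run>\n")
  cat(sprintf("  nozzle radius  %g um (jet %g um)\n",
              m_to_um(x$nozzle_radius), m_to_um(x$jet_radius)))
  cat(sprintf("  flows CS/IS/AS %g/%g/%g mL/h (total %g)\n",
              m3s_to_mlh(x$flows[["cs"]]), m3s_to_mlh(x$flows[["is"]]),
              m3s_to_mlh(x$flows[["as"]]), m3s_to_mlh(x$total_flow)))
  cat(sprintf("  actuation      f = %g Hz, U = %g V\n", x$frequency, x$potential))
  invisible(x)
}

#' Jet kinematics and dimensionless groups
#'
#' Computes the jet velocity v_jet = Q / (pi R^2), the Weber number
#' We = rho v^2 D / gamma, the Ohnesorge number Oh = mu / sqrt(rho gamma R),
#' the capillary time t_cap = sqrt(rho R^3 / gamma) and its inverse, the
#' reference growth rate omega_0. We > ~1 is the jetting condition; Oh sets
#' the fastest-growing wavenumber of the capillary instability.
#'
#' @param run a [jet_run()]
#' @param fluid a [fluid_properties()]
#' @return a one-row tibble with columns `v_jet_m_per_s`, `jet_diameter_um`,
#'   `weber`, `ohnesorge`, `t_cap_s`, `omega0_per_s`
#' @examples
#' derive_kinematics(jet_run(), sorbitol_fluid())
#' @export
derive_kinematics <- function(run, fluid) {
  stopifnot(inherits(run, "jet_run"), inherits(fluid, "fluid_properties"))
  R <- run$nozzle_radius
  Rj <- run$jet_radius
  v <- run$total_flow / (pi * R^2)
  t_cap <- sqrt(fluid$density * Rj^3 / fluid$surface_tension)
  tibble(
    v_jet_m_per_s = v,
    jet_diameter_um = m_to_um(2 * Rj),
    weber = fluid$density * v^2 * (2 * Rj) / fluid$surface_tension,
    ohnesorge = fluid$viscosity / sqrt(fluid$density * fluid$surface_tension * Rj),
    t_cap_s = t_cap,
    omega0_per_s = 1 / t_cap
  )
}

# Internal shortcut: jet velocity in m/s.
jet_velocity <- function(run) run$total_flow / (pi * run$nozzle_radius^2)
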