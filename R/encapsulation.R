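#' Poisson cell-loading forecast
#'
#' When cells at concentration c are carried only by the core flow, the
#' expected number per capsule of radius r is
#' lambda = c (4/3) pi r^3 fraction, where `core_flow_fraction` is the share
#' of the total flow occupied by the cell suspension, and counts follow a
#' Poisson distribution.
#'
#' @param concentration_per_ml cell concentration, cells/mL, >= 0
#' @param capsule_radius_um capsule radius, um, >= 0
#' @param core_flow_fraction fraction of total flow carrying cells, in [0, 1]
#' @param n_max largest count tabulated in the pmf (default 20)
#' @return a list of class `encapsulation_forecast`: `lambda`, a `pmf` tibble
#'   (`n`, `p`) over 0..n_max, and `tail_mass` = P(N > n_max)
#' @examples
#' expected_cells_per_capsule(5e5, 200, 45 / 165) # lambda ~ 4.57
#' @export
expected_cells_per_capsule <- function(concentration_per_ml, capsule_radius_um,
                                       core_flow_fraction, n_max = 20) {
  stopifnot(concentration_per_ml >= 0, capsule_radius_um >= 0,
            core_flow_fraction >= 0, core_flow_fraction <= 1)
  r <- um_to_m(capsule_radius_um)
  lambda <- per_ml_to_per_m3(concentration_per_ml) *
    (4 / 3) * pi * r^3 * core_flow_fraction
  pmf <- tibble(n = 0:n_max, p = dpois(0:n_max, lambda))
  structure(
    list(lambda = lambda, pmf = pmf, tail_mass = 1 - sum(pmf$p)),
    class = "encapsulation_forecast"
  )
}

#' @export
print.encapsulation_forecast <- function(x, ...) {
  cat(sprintf("<encapsulation_forecast: lambda = %.3f cells/capsule>\n", x$lambda))
  cat(sprintf("  P(N = 0) = %.4f, tail P(N > %d) = %.2e\n",
              x$pmf$p[1], max(x$pmf$n), x$tail_mass))
  invisible(x)
}

#' Radius of n coalesced droplets
#'
#' Volume conservation: merging n droplets of radius R0 yields radius
#' n^(1/3) R0 (a doublet is 2^(1/3) R0, a triplet 3^(1/3) R0).
#'
#' @param r0_um primary droplet radius (um), vectorised
#' @param n number of merged droplets, integer >= 1
#' @return merged radius in um
#' @export
coalescence_radius <- function(r0_um, n = 2) {
  if (any(n < 1)) abort("`n` must be >= 1", class = "capsulejet_domain_error")
  n^(1 / 3) * r0_um
}

#' Core/shell partition of a compound droplet
#'
#' The inner flows (cell suspension + intermediate) form the liquid core and
#' the alginate flow the shell; by volume conservation the core radius is the
#' drop radius times the cube root of the inner flow fraction.
#'
#' @param drop_radius_um compound droplet radius, um
#' @param run a [jet_run()] supplying the flow split
#' @return a one-row tibble: `core_radius_um`, `shell_thickness_um`,
#'   `core_volume_fraction`
#' @examples
#' core_shell_geometry(200, jet_run()) # core ~163 um, shell ~37 um
#' @export
core_shell_geometry <- function(drop_radius_um, run) {
  stopifnot(inherits(run, "jet_run"))
  if (run$total_flow <= 0) abort("total flow must be > 0", class = "capsulejet_domain_error")
  frac <- (run$flows[["cs"]] + run$flows[["is"]]) / run$total_flow
  core <- drop_radius_um * frac^(1 / 3)
  tibble(
    core_radius_um = core,
    shell_thickness_um = drop_radius_um - core,
    core_volume_fraction = frac
  )
}
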