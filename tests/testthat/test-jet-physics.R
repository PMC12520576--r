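# Closed-form jet physics: kinematics, dispersion relation, droplet-size
# predictions, electric thresholds, loading statistics.

run0 <- jet_run()  # R = 95 um, Q = 45/45/75 mL/h, 165 total

test_that("jet kinematics reproduce the bench values", {
  kin <- derive_kinematics(run0, sorbitol_fluid())
  expect_equal(kin$v_jet_m_per_s, 165e-6 / 3600 / (pi * (95e-6)^2), tolerance = 1e-12)
  expect_equal(kin$v_jet_m_per_s, 1.6, tolerance = 0.02)
  expect_equal(kin$jet_diameter_um, 190)
  expect_equal(kin$omega0_per_s * kin$t_cap_s, 1, tolerance = 1e-12)
  # Ohnesorge numbers of the two pure phases (direct arithmetic oracle)
  oh <- function(fl) fl$viscosity / sqrt(fl$density * fl$surface_tension * 95e-6)
  expect_equal(kin$ohnesorge, oh(sorbitol_fluid()), tolerance = 1e-12)
  expect_equal(kin$ohnesorge, 0.0121, tolerance = 1e-2)
  expect_equal(derive_kinematics(run0, alginate_fluid())$ohnesorge, 13.8,
               tolerance = 1e-2)
  # zero flow: jet at rest
  kin0 <- derive_kinematics(jet_run(q_cs_mlh = 0, q_is_mlh = 0, q_as_mlh = 0),
                            sorbitol_fluid())
  expect_equal(kin0$v_jet_m_per_s, 0)
  expect_equal(kin0$weber, 0)
  expect_error(jet_run(nozzle_radius_um = -1), class = "capsulejet_invalid_configuration")
})

test_that("viscous growth rate matches the quadratic-root oracle and its limits", {
  fl <- sorbitol_fluid(); R <- 95e-6
  # marginal stability at kR = 1
  expect_equal(weber_growth_rate(1 / R, fl, R), 0)
  expect_equal(weber_growth_rate(1.3 / R, fl, R), 0)  # clamped beyond the band
  # independent quadratic-formula oracle on a 1000-point grid
  kr <- seq(0.001, 0.999, length.out = 1000)
  nu <- fl$viscosity / fl$density
  k <- kr / R
  b <- fl$surface_tension / (2 * fl$density * R^3) * kr^2 * (1 - kr^2)
  oracle <- -3 * nu * k^2 / 2 + sqrt((3 * nu * k^2 / 2)^2 + b)
  expect_equal(weber_growth_rate(k, fl, R), oracle, tolerance = 1e-12)
  # inviscid optimum: omega(1/sqrt(2)) = omega0 / (2 sqrt(2))
  inv <- fluid_properties(1000, 72e-3, 0, "inviscid")
  om0 <- 1 / sqrt(1000 * R^3 / 72e-3)
  expect_equal(weber_growth_rate(1 / sqrt(2) / R, inv, R), om0 / (2 * sqrt(2)),
               tolerance = 1e-12)
  expect_error(weber_growth_rate(-1, fl, R), class = "capsulejet_domain_error")
})

test_that("fastest mode matches numeric maximisation and the printed sorbitol anchor", {
  R <- 95e-6
  for (oh in c(0, 0.01, 0.1, 1, 10)) {
    mu <- oh * sqrt(1000 * 60e-3 * R)
    fl <- fluid_properties(1000, 60e-3, mu, sprintf("oh=%g", oh))
    fm <- fastest_growing_mode(fl, R)
    # independent numeric maximiser
    opt <- optimize(function(kr) weber_growth_rate(kr / R, fl, R),
                    c(1e-6, 1 - 1e-9), maximum = TRUE, tol = 1e-12)
    expect_equal(fm$kr_star, opt$maximum, tolerance = 1e-6)
    expect_equal(fm$kr_star, 1 / sqrt(2 + 3 * sqrt(2) * oh), tolerance = 1e-9)
  }
  # inviscid limit
  inv <- fluid_properties(1000, 72e-3, 0)
  fmi <- fastest_growing_mode(inv, R)
  expect_equal(fmi$kr_star, 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(fmi$omega_star_per_s, (1 / sqrt(1000 * R^3 / 72e-3)) / (2 * sqrt(2)),
               tolerance = 1e-9)
  # printed anchors: sorbitol kR* ~ 0.70, R0 ~ 180 um
  fms <- fastest_growing_mode(sorbitol_fluid(), R)
  expect_equal(fms$kr_star, 0.698, tolerance = 1e-3)
  expect_equal(fms$radius_um, 180, tolerance = 0.01)
  # alginate under this relation (the printed 272 um uses an unstated variant)
  fma <- fastest_growing_mode(alginate_fluid(), R)
  expect_equal(fma$kr_star, 0.128, tolerance = 0.01)
  expect_equal(fma$radius_um, 315, tolerance = 0.01)
})

test_that("droplet radius from wavenumber conserves volume", {
  R <- 95e-6
  expect_equal(drop_radius_from_wavenumber(3 * pi / 2 / R, R), R, tolerance = 1e-12)
  expect_equal(m_um <- drop_radius_from_wavenumber(0.698 / R, R) * 1e6, 180, tolerance = 0.005)
  expect_equal(drop_radius_from_wavenumber(0.185 / R, R) * 1e6, 279.6, tolerance = 0.001)
  expect_error(drop_radius_from_wavenumber(0, R), class = "capsulejet_domain_error")
})

test_that("targeted radius matches the printed values and scales as f^(-1/3)", {
  expect_equal(targeted_radius(650, run0), 256, tolerance = 0.005)
  expect_equal(targeted_radius(1150, run0), 212, tolerance = 0.005)
  expect_equal(targeted_radius(1500, run0), 193, tolerance = 0.005)
  # algebraic identity: f = 3 v / (4 R) gives R_th = R_jet
  v <- 165e-6 / 3600 / (pi * (95e-6)^2)
  expect_equal(targeted_radius(3 * v / (4 * 95e-6), run0), 95, tolerance = 1e-9)
  # exact 1/2 at 8x the frequency
  expect_equal(targeted_radius(8 * 650, run0), targeted_radius(650, run0) / 2,
               tolerance = 1e-12)
  # inverse round-trips
  for (f in c(400, 650, 1000, 1500, 2400))
    expect_equal(frequency_for_radius(targeted_radius(f, run0), run0), f,
                 tolerance = 1e-12)
  expect_error(targeted_radius(0, run0), class = "capsulejet_domain_error")
})

test_that("actuation band converts kR bounds to the printed frequency range", {
  band <- actuation_band(run0, kr_bounds = c(0.185, 0.7))
  expect_equal(band$f_min_hz, 500, tolerance = 0.01)
  expect_equal(band$f_max_hz, 1900, tolerance = 0.01)
  expect_warning(actuation_band(run0, kr_bounds = c(0.4, 0.4)), "degenerate")
  # k = 2 pi f / v round-trip at 1500 Hz
  v <- 165e-6 / 3600 / (pi * (95e-6)^2)
  kr <- 2 * pi * 1500 / v * 95e-6
  b2 <- actuation_band(run0, kr_bounds = c(0.1, kr))
  expect_equal(b2$f_max_hz, 1500, tolerance = 1e-12)
  # default bounds come from the two pure-fluid fastest modes
  b3 <- actuation_band(run0)
  expect_equal(b3$kr_lo, fastest_growing_mode(alginate_fluid(), 95e-6)$kr_star)
  expect_equal(b3$kr_hi, fastest_growing_mode(sorbitol_fluid(), 95e-6)$kr_star)
})

test_that("capillary-retarded bead velocity behaves as derived", {
  expect_equal(schneider_bead_velocity(run0, alginate_fluid()), 0.83,
               tolerance = 0.03)
  nosurf <- fluid_properties(1000, 1e-12, 1e-3)
  v <- 165e-6 / 3600 / (pi * (95e-6)^2)
  expect_equal(schneider_bead_velocity(run0, nosurf), v, tolerance = 1e-6)
  # monotone in v_jet above the stationary point sqrt(2 gamma / rho R)
  fl <- alginate_fluid()
  vmin <- sqrt(2 * fl$surface_tension / (fl$density * 95e-6))
  q_grid <- seq(1.05, 3, length.out = 20) * vmin * pi * (95e-6)^2
  vd <- vapply(q_grid, function(q) {
    schneider_bead_velocity(jet_run(q_cs_mlh = q * 3600 / 1e-6, q_is_mlh = 0,
                                    q_as_mlh = 0), fl)
  }, numeric(1))
  expect_true(all(diff(vd) > 0))
})

test_that("capillary force is linear and correctly scaled", {
  expect_equal(capillary_force(95e-6, 0, 59.8e-3), 0)
  expect_equal(capillary_force(95e-6, 9.5e-6, 59.8e-3),
               2 * pi * 95e-6 * 9.5e-6 * 59.8e-3, tolerance = 1e-12)
  expect_equal(capillary_force(95e-6, 9.5e-6, 59.8e-3), 3.39e-10, tolerance = 0.001)
  expect_equal(capillary_force(95e-6, 2 * 9.5e-6, 59.8e-3),
               2 * capillary_force(95e-6, 9.5e-6, 59.8e-3), tolerance = 1e-12)
  expect_error(capillary_force(-1, 1, 1), class = "capsulejet_domain_error")
})

test_that("electric Bond number and whipping thresholds", {
  er0 <- electric_report(0, 95e-6, 59.8e-3)
  expect_equal(er0$bond_number, 0)
  # quadratic scaling in U
  e1 <- electric_report(1000, 95e-6, 59.8e-3)
  e2 <- electric_report(2000, 95e-6, 59.8e-3)
  expect_equal(e2$bond_number, 4 * e1$bond_number, tolerance = 1e-12)
  # calibrated thresholds: 7000 V at the jet, sqrt(10) lower at the filament
  expect_equal(e1$jet_whipping_v, 7000, tolerance = 1e-9)
  expect_equal(e1$filament_whipping_v, 7000 / sqrt(10), tolerance = 1e-9)
  expect_equal(e1$filament_whipping_v, 2214, tolerance = 0.001)
  # the printed 2500 V corresponds to a radius ratio near 7.8
  e78 <- electric_report(0, 95e-6, 59.8e-3, filament_ratio = 7.84)
  expect_equal(e78$filament_whipping_v, 2500, tolerance = 0.001)
  # sqrt(radius) scaling of thresholds at fixed Gamma_c
  ea <- electric_report(0, 4 * 95e-6, 59.8e-3)
  expect_equal(ea$jet_whipping_v, 2 * e1$jet_whipping_v, tolerance = 1e-12)
  expect_match(electric_report(7500, 95e-6, 59.8e-3)$whipping, "jet")
  expect_match(electric_report(3000, 95e-6, 59.8e-3)$whipping, "filament")
})

test_that("spatial growth rate is reciprocal in the fragmentation length", {
  expect_equal(spatial_growth_rate(1e6), 7e-6)      # -> 0 as L -> infinity
  expect_equal(spatial_growth_rate(2e-3), 2 * spatial_growth_rate(4e-3))
  expect_equal(spatial_growth_rate(8e-3, gain = 7), 875)
  expect_error(spatial_growth_rate(0), class = "capsulejet_domain_error")
})

test_that("phase classification partitions the plane with half-open boundaries", {
  co <- phase_cutoffs()
  expect_equal(classify_phase_point(0.5, 0, co), "I")
  expect_equal(classify_phase_point(0.2, 0, co), "II")
  # above the jet threshold the label is jet-whipping at any kR
  expect_true(all(classify_phase_point(c(0.1, 0.5, 1.1),
                                       co$gamma_jet * 1.01, co) == "jet-whipping"))
  # exact boundary points take the lower region (half-open rule)
  expect_equal(classify_phase_point(0.35, co$gamma_jet, co), "filament-whipping")
  expect_equal(classify_phase_point(0.35, co$gamma_filament, co), "II")
  expect_equal(classify_phase_point(co$kr_hi / 2, 0, co), "II")
  # every grid point gets exactly one label on a 200 x 200 grid
  pd <- phase_diagram(n_kr = 200, n_gamma = 200, cutoffs = co)
  expect_equal(nrow(pd), 200 * 200)
  expect_true(all(pd$region %in% c("I", "II", "filament-whipping", "jet-whipping")))
  expect_false(any(is.na(pd$region)))
  expect_setequal(unique(pd$region),
                  c("I", "II", "filament-whipping", "jet-whipping"))
})

test_that("Poisson loading forecast", {
  fc0 <- expected_cells_per_capsule(0, 200, 0.5)
  expect_equal(fc0$lambda, 0)
  expect_equal(fc0$pmf$p[1], 1)
  fc <- expected_cells_per_capsule(5e5, 200, 45 / 165)
  expect_equal(fc$lambda, 4.57, tolerance = 0.001)
  expect_gt(fc$lambda, 3); expect_lt(fc$lambda, 6)
  expect_equal(fc$pmf$p[1], dpois(0, fc$lambda))
  expect_equal(fc$pmf$p[1], 0.0104, tolerance = 0.01)
  expect_equal(sum(fc$pmf$p) + fc$tail_mass, 1, tolerance = 1e-9)
})

test_that("coalescence radii and core-shell geometry conserve volume", {
  expect_equal(coalescence_radius(200, 1), 200)
  expect_equal(coalescence_radius(196, 2), 2^(1 / 3) * 196, tolerance = 1e-12)
  expect_equal(coalescence_radius(196, 2), 246.9, tolerance = 0.001)
  expect_equal(coalescence_radius(100, 8), 200, tolerance = 1e-12)
  expect_error(coalescence_radius(100, 0), class = "capsulejet_domain_error")

  cs <- core_shell_geometry(200, run0)
  expect_equal(cs$core_radius_um, 200 * (90 / 165)^(1 / 3), tolerance = 1e-12)
  expect_equal(cs$core_radius_um, 163, tolerance = 0.005)
  expect_equal(cs$shell_thickness_um, 200 - cs$core_radius_um)
  # no alginate flow -> no shell
  cs0 <- core_shell_geometry(200, jet_run(q_as_mlh = 0))
  expect_equal(cs0$shell_thickness_um, 0, tolerance = 1e-12)
  # shell grows monotonically with the alginate flow fraction
  th <- vapply(c(10, 30, 60, 90), function(q)
    core_shell_geometry(200, jet_run(q_as_mlh = q))$shell_thickness_um, numeric(1))
  expect_true(all(diff(th) > 0))
})
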