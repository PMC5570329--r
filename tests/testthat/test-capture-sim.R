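# Reaction-diffusion capture simulator: validation, conservation, trivial
# limits and agreement with the well-mixed oracle.

test_that("site-density unit conversion follows Avogadro arithmetic", {
  expect_equal(convert_site_density(1e-9), 602.214076, tolerance = 1e-6)
  expect_equal(convert_site_density(0), 0)
  expect_equal(convert_site_density(1e-7), 6.02214076e4, tolerance = 1e-6)
  expect_error(convert_site_density(-1), "non-negative")
})

test_that("geometry and placement invariants are enforced", {
  expect_error(well_geometry(well_width = -5), "> 0")
  expect_error(well_geometry(50, 60, buffer_height = 30), "buffer_height")
  expect_error(well_geometry(50, 60, 60, voxel_size = 7), "divide")
  # overlapping spheres
  expect_error(placement(c(10, 10, 4), c(12, 10, 2.5)), "overlap")
  # sphere pokes out of the well -> rejected by the solver
  geo <- geo40(4)
  bad <- placement(c(14, 20, 4), c(26, 18, 39))
  expect_error(simulate_capture(geo, bad, binding_kinetics(),
                                sim_settings(t_end = 0.2)),
               "inside the well")
})

test_that("initial state is empty and k_on = 0 never binds", {
  geo <- geo40(4)
  st <- sim_settings(t_end = 0.25, open_top = TRUE)
  ts <- simulate_capture(geo, plc_aligned(),
                         binding_kinetics(k_on = 0, theta0 = 1e-8), st)
  expect_equal(ts$frac_occupancy[1], 0)
  expect_equal(ts$bound[1], 0)
  expect_equal(ts$escaped[1], 0)
  expect_true(all(ts$frac_occupancy == 0))
  expect_true(all(ts$bound == 0))
  # everything secreted is free or escaped
  n <- nrow(ts)
  expect_lt(abs(ts$secreted[n] - ts$free[n] - ts$escaped[n]) /
              ts$secreted[n], 0.01)
})

test_that("sealed runs conserve mass exactly and occupancy is monotone", {
  geo <- geo40(4)
  ts <- simulate_capture(geo, plc_aligned(),
                         binding_kinetics(theta0 = 1e-9, k_off = 0),
                         sim_settings(t_end = 1))
  expect_true(all(ts$escaped == 0))
  expect_true(all(diff(ts$frac_occupancy) >= 0))
  expect_true(all(ts$frac_occupancy <= 1))
  expect_lt(mass_balance_residual(ts), 1e-9)
  # bound count ties to captured density through the bead area
  area <- attr(ts, "capture_meta")$bead_area_um2
  expect_equal(ts$bound, ts$captured_density_per_um2 * area,
               tolerance = 1e-12)
})

test_that("open-top mass-balance residual is small and shrinks on refinement", {
  st <- sim_settings(t_end = 1, open_top = TRUE)
  kin <- binding_kinetics(theta0 = 1e-8)
  r4 <- mass_balance_residual(simulate_capture(geo40(4), plc_aligned(), kin, st))
  r2 <- mass_balance_residual(simulate_capture(geo40(2), plc_aligned(), kin, st))
  expect_lt(r4, 0.01)
  expect_lt(r2, r4)
})

test_that("zero secretion leaves the domain empty with zero residual", {
  ts <- simulate_capture(geo40(4), plc_aligned(),
                         binding_kinetics(secretion_rate = 0, theta0 = 1e-8),
                         sim_settings(t_end = 0.25, open_top = TRUE))
  expect_true(all(ts$free == 0))
  expect_equal(mass_balance_residual(ts), 0)
})

test_that("sealed high-diffusivity run matches the well-mixed oracle", {
  st <- sim_settings(t_end = 1)
  kin <- binding_kinetics(D = 1e-8, theta0 = 1e-8)
  pde <- simulate_capture(geo40(2), placement_default(geo40(2)), kin, st)
  ode <- wellmixed_oracle(geo40(2), kin, sealed = TRUE, settings = st)
  rel <- abs(pde$frac_occupancy[-1] / ode$frac_occupancy[-1] - 1)
  expect_lt(max(rel), 0.05)
})

test_that("well-mixed oracle honours its closed-form limits", {
  geo <- well_geometry()
  # no binding
  o0 <- wellmixed_oracle(geo, binding_kinetics(k_on = 0, theta0 = 1e-8))
  expect_true(all(o0$frac_occupancy == 0))
  # Langmuir isotherm at held concentration C* = Kd -> occupancy 1/2
  kin <- binding_kinetics(theta0 = 1e-8)
  kd_molar <- kin$k_off / kin$k_on
  iso <- wellmixed_oracle(geo, kin, settings = sim_settings(t_end = 200,
                                                            dt_max = 30),
                          fixed_C_molar = kd_molar)
  expect_equal(iso$frac_occupancy[nrow(iso)], 0.5, tolerance = 1e-3)
  # sealed, k_off = 0: bound approaches min(total secreted, total sites)
  kin_site <- binding_kinetics(theta0 = 1e-10, k_off = 0)
  site_cap <- convert_site_density(1e-10) * 4 * pi * 2.5^2
  o1 <- wellmixed_oracle(geo, kin_site, settings = sim_settings(t_end = 6))
  expect_equal(o1$bound[nrow(o1)], site_cap, tolerance = 0.02)
  kin_sec <- binding_kinetics(theta0 = 1e-7, k_off = 0, secretion_rate = 1)
  o2 <- wellmixed_oracle(geo, kin_sec, settings = sim_settings(t_end = 6))
  expect_equal(o2$bound[nrow(o2)], o2$secreted[nrow(o2)], tolerance = 0.01)
  expect_lt(mass_balance_residual(o1), 1e-6)
})

test_that("degenerate sweep equals a direct run and SEM behaves", {
  geo <- geo40(4)
  st <- sim_settings(t_end = 0.5)
  kin <- binding_kinetics(theta0 = 1e-8)
  direct <- simulate_capture(geo, plc_aligned(), kin, st)
  sw <- sweep_binding_density(geo, plc_aligned(), kin, 1e-8, st)
  expect_equal(sw$summary$mean_occupancy, direct$frac_occupancy)
  expect_true(all(sw$summary$sem_occupancy == 0))
  # identical placements -> zero SEM across "positions"
  sp <- sweep_positions(geo, kin, list(plc_aligned(), plc_aligned()), st)
  expect_true(all(sp$summary$sem_occupancy == 0))
  expect_error(sweep_binding_density(geo, plc_aligned(), kin, numeric(0)),
               "non-empty")
  expect_error(sweep_positions(geo, kin, list(plc_aligned()), st),
               "at least two")
})

test_that("a bead adjacent to the cell captures earlier than a distant bead", {
  geo <- geo40(2)
  st <- sim_settings(t_end = 0.5)
  ps <- placement_axial_set(geo, n = 3)
  sw <- sweep_positions(geo, binding_kinetics(theta0 = 1e-8),
                        list(ps[[1]], ps[[3]]), st)
  runs <- sw$runs
  near <- runs[runs$placement_id == 1, ]
  far <- runs[runs$placement_id == 2, ]
  expect_true(all(near$frac_occupancy[-1] >= far$frac_occupancy[-1]))
  # sweep mean lies between the extremes at every time
  s <- sw$summary[sw$summary$time_min > 0, ]
  expect_true(all(s$mean_occupancy <= pmax(near$frac_occupancy[-1],
                                           far$frac_occupancy[-1])))
  expect_true(all(s$mean_occupancy >= pmin(near$frac_occupancy[-1],
                                           far$frac_occupancy[-1])))
  expect_true(all(s$sem_occupancy >= 0))
})

test_that("fractional occupancy decreases with site density (ambient analyte)", {
  geo <- geo40(4)
  st <- sim_settings(t_end = 1.5)
  sw <- sweep_binding_density(geo, plc_aligned(), binding_kinetics(),
                              c(1e-9, 1e-8, 1e-7), st)
  s <- sw$summary
  occ <- sapply(c(1e-9, 1e-8, 1e-7), function(th)
    s$mean_occupancy[s$theta0 == th & s$time_min > 0])
  expect_true(all(occ[, 1] > occ[, 2]))
  expect_true(all(occ[, 2] > occ[, 3]))
})
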