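# Particle mechanics: forces, seeding, integration contracts.

test_that("particle mass and Stokes time follow from diameter and density", {
  spec <- particle_spec(4e-6, 5230, 9)
  expect_equal(spec$m_p, pi / 6 * (4e-6)^3 * 5230, tolerance = 1e-15)
  expect_equal(stokes_time(spec, 1.78e-5), 5230 * (4e-6)^2 / (18 * 1.78e-5))
  # 1 um particle: tau ~ 1.63e-5 s
  expect_equal(stokes_time(particle_spec(1e-6, 5230, 9), 1.78e-5),
               1.633e-5, tolerance = 1e-3)
  expect_error(particle_spec(4e-6, 5230, 0.5), "mu_r_p")
})

test_that("drag reduces exactly to Stokes law in the low-Re limit", {
  spec <- particle_spec(4e-6, 5230, 9)
  u <- c(1e-6, 0, 0); v <- c(0, 0, 0)   # Re_p ~ 3e-7
  Fd <- drag_force(u, v, spec, rho = 1.22, eta = 1.78e-5)
  stokes <- 3 * pi * 1.78e-5 * 4e-6 * (u - v)
  expect_lt(max(abs(Fd - stokes)) / max(abs(stokes)), 1e-5)
  # the correction factor, not the full force, is exact at Re = 0
  expect_equal(drag_force(c(0, 0, 0), c(0, 0, 0), spec), c(0, 0, 0))
})

test_that("Schiller-Naumann drag coefficient has the standard finite-Re form", {
  expect_equal(drag_coefficient(1), 24 * 1.15)
  Re <- c(0.01, 0.1, 1, 10, 100)
  expect_equal(drag_coefficient(Re), 24 / Re * (1 + 0.15 * Re^0.687))
  # monotone decreasing, always above the Newton plateau range used here
  expect_true(all(diff(drag_coefficient(Re)) < 0))
})

test_that("magnetophoretic force scales with the permeability contrast factor", {
  g2 <- c(0, 0, 3e12)
  f9 <- magnetophoretic_force(particle_spec(4e-6, 5230, 9), g2)
  K9 <- 8 / 11
  expect_equal(f9, pi / 4 * (4e-6)^3 * mu0 * K9 * g2, tolerance = 1e-12)
  # K increases with mu_r_p but saturates below 1
  mus <- c(2, 3, 6, 9, 15, 50, 500)
  Ks <- (mus - 1) / (mus + 2)
  fz <- vapply(mus, function(m)
    magnetophoretic_force(particle_spec(4e-6, 5230, m), g2)[3], numeric(1))
  expect_true(all(diff(fz) > 0))
  expect_true(all(Ks < 1))
  expect_equal(fz / (pi / 4 * (4e-6)^3 * mu0 * 3e12), Ks, tolerance = 1e-12)
  # matched permeabilities: no force
  f_match <- magnetophoretic_force(particle_spec(4e-6, 5230, 1 + 1e-12), g2)
  expect_lt(abs(f_match[3]), 1e-12 * abs(f9[3]))
})

test_that("seeding is deterministic, on the inlet disc, at the air velocity", {
  tree <- default_tree(); flow <- default_flow()
  s1 <- seed_particles(500, tree, flow, seed = 99)
  s2 <- seed_particles(500, tree, flow, seed = 99)
  expect_identical(s1$pos, s2$pos)
  expect_identical(s1$vel, s2$vel)
  expect_true(all(s1$status == "in_flight"))
  # on the inlet disc: x ~ 0, radius within R_G0
  expect_true(all(abs(s1$pos[, 1]) < 1e-5))
  expect_true(all(s1$pos[, 2]^2 + s1$pos[, 3]^2 <= 0.009^2))
  expect_equal(s1$vel, flow_velocity(flow, s1$pos), tolerance = 1e-12)
  # flux weighting samples fast stations more often than area weighting
  su <- seed_particles(4000, tree, flow, seed = 99, weighting = "uniform")
  sf <- seed_particles(4000, tree, flow, seed = 99, weighting = "flux")
  expect_gt(mean(vnorm(sf$vel)), mean(vnorm(su$vel)))
})

test_that("velocity relaxes exponentially to a uniform stream (closed form)", {
  # straight duct, uniform-ish core flow, no magnet: v(t) = u0 (1 - e^(-t/tau));
  # checked for a 1 um particle against the exact Stokes-limit solution
  dims <- data.frame(generation = 0L, length_mm = 200, radius_mm = 20)
  tree <- build_weibel_tree(dims)
  flow <- solve_flow(tree, Q_lpm = 0.7)   # slow stream keeps Re_p ~ 1e-3
  spec <- particle_spec(1e-6, 5230, 9)
  tau <- stokes_time(spec, flow$eta)
  # release on the axis with v = 0 and inspect velocity shortly after
  st <- seed_particles(1, tree, flow, seed = 1)
  st$pos <- matrix(c(1e-4, 0, 0), 1)
  u0 <- drop(flow_velocity(flow, st$pos))
  st$vel <- matrix(0, 1, 3)
  t_end <- 5e-5    # ~ 3 tau
  out <- integrate_particles(st, flow, NULL, spec, dt_max = 1e-6,
                             t_max = t_end)
  # u is uniform along the core at this scale, so the ODE is exact
  expect_equal(out$status, "suspended")   # still airborne, time budget hit
  tt <- out$t[1]
  v_exact <- u0 * (1 - exp(-tt / tau))
  expect_lt(max(abs(out$vel[1, ] - v_exact)) / max(abs(v_exact)), 1e-3)
})

test_that("zero force in a straight duct gives a straight trajectory", {
  dims <- data.frame(generation = 0L, length_mm = 100, radius_mm = 5)
  tree <- build_weibel_tree(dims)
  flow <- solve_flow(tree, Q_lpm = 5)
  spec <- particle_spec(4e-6, 5230, 9)
  st <- seed_particles(10, tree, flow, seed = 4)
  # generous time budget so even near-wall releases reach the outlet
  out <- integrate_particles(st, flow, NULL, spec, dt_max = 2e-4, t_max = 2)
  done <- out$status == "exited_outlet"
  expect_true(all(done))
  # transverse coordinates unchanged along the straight duct
  expect_equal(out$pos[, 2:3], st$pos[, 2:3], tolerance = 1e-6)
  expect_true(all(abs(out$pos[done, 1] - 0.1) < 1e-4))
})

test_that("particles seeded on the wall deposit immediately", {
  tree <- default_tree(); flow <- default_flow()
  st <- seed_particles(3, tree, flow, seed = 6)
  st$pos[1, ] <- c(0.06, 0, 0.009001)   # just outside the G0 wall
  out <- integrate_particles(st, flow, NULL, particle_spec(), dt_max = 2e-4,
                             t_max = 1e-3)
  expect_equal(out$status[1], "deposited_wall")
})

test_that("statuses are absorbing and counts are conserved", {
  cfg <- make_toy_case()
  res <- run_case(cfg, return_states = TRUE)
  st <- res$states
  tab <- table(factor(st$status, levels = c("in_flight", "deposited_wall",
                                            "deposited_tumor", "exited_outlet",
                                            "suspended", "error")))
  expect_equal(sum(tab), st$n)
  expect_equal(unname(tab["in_flight"]), 0L)
  expect_equal(unname(tab["error"]), 0L)
  # deposited particles sit on the boundary they report
  dep <- which(st$status == "deposited_tumor")
  if (length(dep) > 0) {
    tum <- res$tree$tumor
    dd <- vnorm(st$dep_pos[dep, , drop = FALSE] -
                  matrix(tum$center, length(dep), 3, byrow = TRUE))
    expect_true(all(abs(dd - tum$r) < 1e-4))
  }
})

test_that("halving the time step leaves the toy PDE essentially unchanged", {
  cfg <- make_toy_case()
  cfg$particles$n <- 400
  r1 <- run_case(cfg)
  cfg2 <- cfg; cfg2$run$dt_max <- cfg$run$dt_max / 2
  r2 <- run_case(cfg2)
  expect_lt(abs(r1$pde - r2$pde), 1.0)   # percentage points, incl. MC jitter
})

test_that("magnet-off field reduces to pure aerosol transport", {
  cfg <- make_toy_case()
  cfg$magnet$enabled <- FALSE
  r1 <- run_case(cfg)
  r2 <- run_case(cfg)
  expect_identical(r1$pde, r2$pde)   # deterministic under the fixed seed
  expect_true(r1$n_tumor + r1$n_wall + r1$n_exited + r1$n_suspended ==
                cfg$particles$n)
})
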