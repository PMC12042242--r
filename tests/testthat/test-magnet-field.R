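# Magnetostatics: Bean closed form, Biot-Savart quadrature, calibration,
# field maps.

test_that("Bean k factor matches its closed form and limits", {
  # a = t: k = log(1 + sqrt(2)) / 2 for any size
  expect_equal(bean_k_factor(1, 1), log(1 + sqrt(2)) / 2, tolerance = 1e-12)
  expect_equal(bean_k_factor(0.007, 0.007), log(1 + sqrt(2)) / 2,
               tolerance = 1e-12)
  # direct evaluation for the reference magnet
  a <- 0.0325; t <- 0.019
  expect_equal(bean_k_factor(a, t),
               t / (2 * a) * log(a / t + sqrt(1 + (a / t)^2)),
               tolerance = 1e-12)
  expect_equal(bean_k_factor(a, t), 0.381798, tolerance = 1e-5)
  # thin-sample limit: k -> 0 as t -> 0 (like t log(1/t))
  expect_lt(bean_k_factor(a, 1e-9), 1e-6)
  expect_lt(bean_k_factor(a, 1e-12), bean_k_factor(a, 1e-9))
  expect_error(bean_k_factor(-1, 1), "positive")
})

test_that("trapped field peak is linear in Jc0 and scales with a k(a,t)", {
  a <- 0.0325; t <- 0.019
  expect_equal(trapped_field_peak(0, a, t), 0)
  B1 <- trapped_field_peak(2e8, a, t)
  expect_equal(B1, bean_k_factor(a, t) * mu0 * 2e8 * a, tolerance = 1e-12)
  expect_equal(B1, 3.1186, tolerance = 1e-4)
  expect_equal(trapped_field_peak(4e8, a, t), 2 * B1, tolerance = 1e-12)
})

test_that("on-axis Biot-Savart at the surface centre equals the Bean closed form", {
  # the k-factor expression is the exact on-axis integral, so the loop
  # quadrature must reproduce it closely for every studied dimension pair
  for (i in seq_len(nrow(table3_dims()))) {
    a <- table3_dims()$a_mm[i] / 1000
    t <- table3_dims()$t_mm[i] / 1000
    m <- bulk_magnet(a, t, jc_curve("constant", 2e8))
    cur <- magnetize(m)
    B <- field_at_point(m, cur, c(0, 0, 0))
    expect_equal(B[1], 0, tolerance = 1e-12)
    expect_equal(B[2], 0, tolerance = 1e-12)
    expect_lt(abs(B[3] - trapped_field_peak(2e8, a, t)) /
                trapped_field_peak(2e8, a, t), 0.005)
  }
})

test_that("far field approaches the point dipole of the current distribution", {
  mm <- m1_magnet()
  a <- 0.0325; t <- 0.019; jc0 <- mm$magnet$jc$Jc0
  moment <- pi * jc0 * t * a^3 / 3
  # measured from the cylinder mid-thickness
  for (zt in c(10 * a, 15 * a)) {
    B <- field_at_point(mm$magnet, mm$current, c(0, 0, zt))
    Bdip <- mu0 * 2 * moment / (4 * pi * (zt + t / 2)^3)
    expect_lt(abs(B[3] - Bdip) / Bdip, 0.02)
  }
})

test_that("field is axisymmetric and transverse-free on the axis", {
  mm <- m1_magnet()
  B_axis <- field_at_point(mm$magnet, mm$current, c(0, 0, 0.05))
  expect_equal(B_axis[1:2], c(0, 0), tolerance = 1e-12)
  # same |B| at two azimuths of equal (rho, z)
  B1 <- field_at_point(mm$magnet, mm$current, c(0.02, 0, 0.05))
  B2 <- field_at_point(mm$magnet, mm$current, c(0, 0.02, 0.05))
  expect_equal(sqrt(sum(B1^2)), sqrt(sum(B2^2)), tolerance = 1e-10)
})

test_that("magnetize: constant mode is one pass; Kim mode suppresses the peak", {
  m_const <- bulk_magnet(0.02, 0.012, jc_curve("constant", 2e8))
  cur <- magnetize(m_const)
  expect_equal(cur$iterations, 1L)
  expect_true(all(cur$J == 2e8))

  # Kim with huge B0 reduces to the constant mode
  m_kim0 <- bulk_magnet(0.02, 0.012, jc_curve("kim", 2e8, B0 = 1e9))
  cur0 <- magnetize(m_kim0, nr = 6, nz = 6, pr = 2, pz = 2)
  expect_equal(max(abs(cur0$J - 2e8)) / 2e8, 0, tolerance = 1e-6)

  # finite B0: current suppressed under self-field, peak field strictly lower
  m_kim <- bulk_magnet(0.02, 0.012, jc_curve("kim", 2e8, B0 = 1))
  cur_k <- magnetize(m_kim, nr = 6, nz = 6, pr = 2, pz = 2)
  expect_true(all(cur_k$J < 2e8))
  Bk <- field_at_point(m_kim, cur_k, c(0, 0, 0))
  Bc <- field_at_point(m_const, cur, c(0, 0, 0))
  expect_lt(Bk[3], Bc[3])
})

test_that("Jc curves are positive, non-increasing, with correct limits", {
  jk <- jc_curve("kim", 3e8, B0 = 1.5)
  B <- seq(0, 12, by = 0.5)
  J <- eval_jc(jk, B)
  expect_true(all(J > 0))
  expect_true(all(diff(J) <= 0))
  expect_equal(eval_jc(jk, 1.5), 1.5e8)
  jc <- jc_curve("constant", 3e8)
  expect_true(all(eval_jc(jc, B) == 3e8))
  expect_error(jc_curve("kim", 3e8), "B0")
  expect_error(jc_curve("constant", -1), "positive")
})

test_that("constant-mode calibration is an exact closed-form round trip", {
  for (i in seq_len(nrow(table3_dims()))) {
    a <- table3_dims()$a_mm[i] / 1000
    t <- table3_dims()$t_mm[i] / 1000
    BT <- table3_dims()$B_T[i]
    jc <- calibrate_jc(BT, a, t, model = "constant")
    expect_equal(jc$Jc0, BT / (bean_k_factor(a, t) * mu0 * a), tolerance = 1e-12)
    expect_equal(trapped_field_peak(jc$Jc0, a, t), BT, tolerance = 1e-12)
  }
  expect_error(calibrate_jc(-2, 0.03, 0.02), "positive")
})

test_that("Kim-mode calibration reproduces the target peak field", {
  jc <- calibrate_jc(3.42, 0.0325, 0.019, model = "kim", B0 = 1.5)
  m <- bulk_magnet(0.0325, 0.019, jc)
  cur <- magnetize(m, nr = 8, nz = 8, pr = 2, pz = 2)
  B <- field_at_point(m, cur, c(0, 0, 0))
  expect_equal(B[3], 3.42, tolerance = 0.01)
  # suppression: the Kim Jc0 must exceed the constant-mode value
  expect_gt(jc$Jc0, calibrate_jc(3.42, 0.0325, 0.019, "constant")$Jc0)
})

test_that("field map interpolation matches the direct integral away from the magnet", {
  mm <- m1_magnet()
  map <- build_field_map(mm$magnet, mm$current, spacing = 1e-3,
                         rho_max = 0.06, zeta_range = c(0.02, 0.08))
  pf <- place_magnet(map, c(0, 0, 0.04), axis = c(0, 0, -1))
  # magnet above at d = 40 mm: probe the origin (on axis) and off-axis
  for (p in list(c(0, 0, 0), c(0.02, 0.01, 0.002))) {
    q <- query_field(pf, p)
    direct <- field_at_point(bulk_magnet(0.0325, 0.019, mm$magnet$jc,
                                         center = c(0, 0, 0.04),
                                         axis = c(0, 0, -1)),
                             mm$current, p)
    expect_lt(sqrt(sum((q$B - direct)^2)) / sqrt(sum(direct^2)), 0.01)
  }
})

test_that("field map: B = mu0 H, divergence-free, monotone on-axis decay, gradient checks", {
  mm <- m1_magnet()
  map <- build_field_map(mm$magnet, mm$current, spacing = 1e-3,
                         rho_max = 0.05, zeta_range = c(0.02, 0.09))
  # stored H^2 is |B|^2 / mu0^2 (mu_r = 1 outside the magnet)
  expect_equal(map$H2, (map$Brho^2 + map$Bz^2) / mu0^2, tolerance = 1e-12)
  # numerical divergence at interior nodes is a small discretisation residual
  expect_lt(max(abs(field_map_divergence(map))), 0.01)
  # |B| and |gradH2| decay monotonically with distance along the axis
  Bax <- abs(map$Bz[1, ])
  g2ax <- abs(map$g2zeta[1, ])
  expect_true(all(diff(Bax) < 0))
  expect_true(all(diff(g2ax) < 0))
  # on the axis gradH2 points along the axis, toward the magnet
  pf <- place_magnet(map, c(0, 0, 0.04), axis = c(0, 0, -1))
  q <- query_field(pf, c(0, 0, 0))
  expect_equal(q$gradH2[1:2], c(0, 0), tolerance = 1e-9 * abs(q$gradH2[3]))
  expect_gt(q$gradH2[3], 0)   # toward the magnet at z = +d
  # interpolated gradH2 agrees with finite differences of the direct H^2
  mshift <- bulk_magnet(0.0325, 0.019, mm$magnet$jc, center = c(0, 0, 0.04),
                        axis = c(0, 0, -1))
  p <- c(0.013, 0.007, 0.001); hfd <- 5e-4
  for (k in 1:3) {
    dp <- c(0, 0, 0); dp[k] <- hfd
    H2p <- sum(field_at_point(mshift, mm$current, p + dp)^2) / mu0^2
    H2m <- sum(field_at_point(mshift, mm$current, p - dp)^2) / mu0^2
    fd <- (H2p - H2m) / (2 * hfd)
    q <- query_field(pf, p)
    expect_equal(q$gradH2[k], fd, tolerance = 0.05 * sqrt(sum(q$gradH2^2)))
  }
})

test_that("halving the map spacing changes interpolated gradients by < 2%", {
  mm <- m1_magnet()
  m2 <- build_field_map(mm$magnet, mm$current, spacing = 2e-3,
                        rho_max = 0.04, zeta_range = c(0.025, 0.06))
  m1 <- build_field_map(mm$magnet, mm$current, spacing = 1e-3,
                        rho_max = 0.04, zeta_range = c(0.025, 0.06))
  probes <- cbind(c(0, 0.011, 0.0215), c(0, 0.0065, 0.013), c(0, 0.0035, -0.0065))
  pf2 <- place_magnet(m2, c(0, 0, 0.04), c(0, 0, -1))
  pf1 <- place_magnet(m1, c(0, 0, 0.04), c(0, 0, -1))
  g2 <- vnorm(query_field(pf2, probes)$gradH2)
  g1 <- vnorm(query_field(pf1, probes)$gradH2)
  expect_true(all(abs(g2 - g1) / g1 < 0.02))
})

test_that("query_field errors outside the map and supports clipping", {
  mm <- m1_magnet()
  map <- build_field_map(mm$magnet, mm$current, spacing = 2e-3,
                         rho_max = 0.03, zeta_range = c(0.02, 0.06))
  pf <- place_magnet(map, c(0, 0, 0.04), c(0, 0, -1))
  expect_error(query_field(pf, c(0, 0, 0.03)), "axial")
  expect_error(query_field(pf, c(0.2, 0, 0)), "radial")
  q <- query_field(pf, c(0.2, 0, 0), clip = TRUE)
  expect_equal(q$B, matrix(0, 1, 3))
})
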