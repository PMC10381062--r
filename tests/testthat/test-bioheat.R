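test_that("water content follows the piecewise vaporization model", {
  expect_equal(water_content(37), 0.778 * (1 - exp(-69 / 3.42)),
               tolerance = 1e-12)
  expect_equal(water_content(37), 0.778, tolerance = 1e-4)
  expect_equal(water_content(100), 0.778 * (1 - exp(-6 / 3.42)),
               tolerance = 1e-12)
  expect_equal(round(water_content(100), 4), 0.6434)
  expect_equal(water_content(110), 0.778 * exp(-30 / 34.37), tolerance = 1e-12)
  # branch continuity: gaps measured and bounded
  expect_lt(abs(water_content(103 - 1e-8) - water_content(103 + 1e-8)), 1e-6)
  expect_lt(abs(water_content(104 - 1e-8) - water_content(104 + 1e-8)), 1e-6)
  # monotone decreasing across the whole range
  Tg <- seq(20, 130, by = 0.1)
  expect_true(all(diff(water_content(Tg)) <= 1e-12))
  # slope matches finite differences of the value
  fd <- (water_content(Tg + 1e-5) - water_content(Tg - 1e-5)) / 2e-5
  expect_equal(water_content_slope(Tg), fd, tolerance = 1e-5)
})

test_that("effective specific heat includes the latent-heat term", {
  mat <- thermal_materials()
  expect_equal(effective_specific_heat(37, mat, "liver"), 3540,
               tolerance = 1e-6)   # dW/dT ~ 0 at body temperature
  mat0 <- thermal_materials(alpha = 0)
  Tg <- c(37, 60, 90, 103.5, 110)
  expect_equal(effective_specific_heat(Tg, mat0, "liver"), rep(3540, 5))
  # vaporization band: C well above C_t
  expect_gt(effective_specific_heat(103.5, mat, "liver"), 3540)
  # everywhere dW/dT <= 0, so C >= C_t
  expect_true(all(effective_specific_heat(seq(20, 130, 0.5), mat,
                                          "liver") >= 3540))
})

test_that("thermal conductivity is affine in temperature", {
  mat <- thermal_materials()
  expect_equal(thermal_conductivity(37, mat, "liver"), 0.497)
  expect_equal(thermal_conductivity(85, mat, "liver"), 0.497)  # dk = 0 default
  mat2 <- thermal_materials(dk = c(liver = 0.001))
  expect_equal(thermal_conductivity(47, mat2, "liver"), 0.507,
               tolerance = 1e-12)
})

test_that("the perfusion latch is irreversible", {
  mat <- thermal_materials()
  p1 <- perfusion_rate(59.9, FALSE, mat, TRUE)
  expect_equal(p1$omega, 0.0036)
  expect_false(p1$latched)
  p2 <- perfusion_rate(60.0, FALSE, mat, TRUE)
  expect_equal(p2$omega, 0)
  expect_true(p2$latched)
  p3 <- perfusion_rate(45, p2$latched, mat, TRUE)   # cooled down again
  expect_equal(p3$omega, 0)
  expect_true(p3$latched)
  expect_equal(perfusion_rate(37, FALSE, mat, TRUE)$omega, 0.0036)
  expect_equal(perfusion_rate(37, FALSE, mat, FALSE)$omega, 0)  # non-tissue
})

test_that("uniform body temperature with no sources is an equilibrium", {
  mesh <- fixture_cube(3, tag = "exterior", side = 0.02)
  mat <- thermal_materials(Q_m = 0)
  sv <- bioheat_solver(mesh, mat)
  st <- thermal_state(sv, 37)
  for (i in 1:5) st <- advance_temperature(sv, st, 0, 10)
  expect_equal(st$T, rep(37, sv$n_nodes), tolerance = 1e-10)
})

test_that("metabolic heating balances perfusion at the closed-form value", {
  mesh <- fixture_cube(3, tag = "exterior", side = 0.02)
  mat <- thermal_materials()
  sv <- bioheat_solver(mesh, mat)
  st <- thermal_state(sv, 37)
  for (i in 1:300) st <- advance_temperature(sv, st, 0, 10)
  target <- 37 + 33800 / (1058 * 0.0036 * 3600)
  expect_equal(max(abs(st$T - target)), 0, tolerance = 0.05)
})

test_that("backward Euler converges at first order in time", {
  # uniform heating of an insulated block with constant properties has the
  # exact solution dT/dt = (Qe + perfusion)/rho C; with perfusion the ODE
  # T' = a - b T is stiffness-free, so the full FEM error is the BE error
  mesh <- fixture_cube(2, tag = "exterior", side = 0.02)
  mat <- thermal_materials(alpha = 0, Q_m = 0)
  sv <- bioheat_solver(mesh, mat)
  a <- 5e5 / (1030 * 3540)
  b <- 1058 * 0.0036 * 3600 / (1030 * 3540)
  Tex <- function(t) 37 + a / b * (1 - exp(-b * t))
  errs <- vapply(c(10, 5, 2.5), function(dt) {
    st <- thermal_state(sv, 37)
    for (i in seq_len(60 / dt)) st <- advance_temperature(sv, st, 5e5, dt)
    max(abs(st$T - Tex(60)))
  }, 1)
  rates <- log2(errs[-3] / errs[-1])
  expect_true(all(rates > 0.8 & rates < 1.3))   # O(dt)
})

test_that("spatial error of a steady manufactured solution is O(h^2)", {
  # T(x) = cos(pi x / L): insulated at x = 0, L; steady state of
  # k T'' + q = 0 with q = k (pi/L)^2 cos(pi x / L) + perfusion term
  L <- 0.02
  mat <- thermal_materials(alpha = 0, Q_m = 0, omega0 = 0)
  k <- 0.497
  errs <- vapply(c(3, 6), function(n) {
    mesh <- fixture_cube(n, tag = "exterior", side = L)
    sv <- bioheat_solver(mesh, mat)
    cen <- (mesh$vertices[mesh$tets[, 1], 1] + mesh$vertices[mesh$tets[, 2], 1] +
            mesh$vertices[mesh$tets[, 3], 1] + mesh$vertices[mesh$tets[, 4], 1]) / 4
    q <- k * (pi / L)^2 * cos(pi * cen / L)
    Tex <- 37 + cos(pi * mesh$vertices[, 1] / L)
    st <- thermal_state(sv, Tex)  # start at the exact solution
    # large time steps converge to the discrete steady state
    for (i in 1:60) st <- advance_temperature(sv, st, q, 100)
    sqrt(mean((st$T - Tex)^2))
  }, 1)
  expect_gt(log2(errs[1] / errs[2]), 1.5)   # O(h^2) in the L2 norm
})

test_that("the discrete energy balance closes on an insulated domain", {
  mesh <- fixture_cube(3, tag = "exterior", side = 0.02)
  mat <- thermal_materials(alpha = 0)
  sv <- bioheat_solver(mesh, mat)
  set.seed(11)
  Qe <- runif(sv$n_elem, 0, 1e5)
  st0 <- thermal_state(sv, 37 + runif(sv$n_nodes))
  dt <- 2
  st1 <- advance_temperature(sv, st0, Qe, dt)
  rhoC <- 1030 * effective_specific_heat(ablatesim:::element_mean_T(sv, st0$T),
                                         mat, sv$region)
  dE <- sum(rhoC * sv$V4 * 4 *
            ablatesim:::element_mean_T(sv, st1$T - st0$T)) / dt
  pf <- perfusion_rate(ablatesim:::element_mean_T(sv, st0$T), st0$latched,
                       mat, sv$tissue)
  Pin <- sum((Qe + 33800) * sv$geom$volume) +
    sum(1058 * 3600 * pf$omega * sv$V4 *
        (4 * 37 - as.numeric(rowSums(matrix(st1$T[mesh$tets], ncol = 4)))))
  expect_equal(dE, Pin, tolerance = 1e-8)
})

test_that("with no sources new temperature extrema stay within old bounds", {
  mesh <- fixture_cube(3, tag = "exterior", side = 0.02)
  mat <- thermal_materials(alpha = 0, Q_m = 0, omega0 = 0)
  sv <- bioheat_solver(mesh, mat)
  set.seed(12)
  st <- thermal_state(sv, 37 + 10 * runif(sv$n_nodes))
  lo <- min(st$T); hi <- max(st$T)
  for (i in 1:20) {
    st <- advance_temperature(sv, st, 0, 2)
    expect_gte(min(st$T), lo - 0.01)
    expect_lte(max(st$T), hi + 0.01)
  }
})

test_that("the perfusion-off element set never shrinks", {
  mesh <- fixture_cube(2, tag = "exterior", side = 0.02)
  mat <- thermal_materials()
  sv <- bioheat_solver(mesh, mat)
  st <- thermal_state(sv, 37)
  # heat one corner strongly, then switch the source off
  Qe <- numeric(sv$n_elem); Qe[1:6] <- 5e7
  prev <- st$latched
  for (i in 1:30) {
    st <- advance_temperature(sv, st, if (i <= 15) Qe else 0, 2)
    expect_true(all(st$latched >= prev))
    prev <- st$latched
  }
  expect_true(any(prev))
})

test_that("mismatched source vectors and bad steps are errors", {
  mesh <- fixture_cube(2, tag = "exterior")
  sv <- bioheat_solver(mesh, thermal_materials())
  st <- thermal_state(sv)
  expect_error(advance_temperature(sv, st, numeric(3), 1), "mismatch")
  expect_error(advance_temperature(sv, st, 0, 0), "positive")
})
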