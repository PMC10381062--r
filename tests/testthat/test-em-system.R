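test_that("an all-PEC problem with zero load has the zero solution", {
  mesh <- fixture_cube(2, tag = "pec")
  edges <- build_edge_structure(mesh)
  sys <- assemble_system(mesh, edges, em_materials())
  sol <- solve_em(sys)
  expect_true(all(Mod(sol$coeff) == 0))
})

test_that("without losses, port and absorbing terms the system is purely real", {
  mesh <- fixture_cube(2, tag = "pec")   # pec boundary: no ABC surface terms
  edges <- build_edge_structure(mesh)
  mat <- em_materials(sigma = c(liver = 0, tumor = 0))
  sys <- assemble_system(mesh, edges, mat)
  expect_equal(Matrix::norm(sys$Aim, "F"), 0)
})

test_that("the assembled complex form is dissipative", {
  dc <- driven_cube_system(2)
  free <- dc$system$free
  Are <- as.matrix(dc$system$Are[free, free])
  Aim <- as.matrix(dc$system$Aim[free, free])
  set.seed(4)
  for (rep in 1:5) {
    x <- complex(real = rnorm(length(free)), imaginary = rnorm(length(free)))
    # A_c = Are + i Aim; Im(x^H A_c x) = x^H Aim x >= 0: every absorption
    # mechanism dissipates under the exp(+j omega t) convention
    q <- Im(Conj(x) %*% (Are %*% x + 1i * (Aim %*% x)))
    expect_gte(Re(q[1, 1]), -1e-9 * sum(Mod(x)^2) * max(abs(Are)))
  }
})

test_that("block solve matches the native complex solve to 1e-10", {
  dc <- driven_cube_system(3)
  sol <- solve_em(dc$system)
  ref <- solve_em_complex_dense(dc$system)
  relerr <- sqrt(sum(Mod(sol$coeff - ref)^2) / sum(Mod(ref)^2))
  expect_lt(relerr, 1e-10)
})

test_that("PEC edge coefficients are exactly zero", {
  dc <- driven_cube_system(3)
  sol <- solve_em(dc$system)
  pec <- dc$edges$surface_edges$pec
  expect_true(length(pec) > 0)
  expect_true(all(Mod(sol$coeff[pec]) == 0))
  expect_true(any(Mod(sol$coeff) > 0))
})

test_that("zero incident power gives a zero load and zero field", {
  mesh <- driven_cube_system(2)$mesh
  edges <- build_edge_structure(mesh)
  port <- tem_incident_field(1e-300, 1e-3, 5e-3, 2.03,
                             axis = c(0.01, 0.01))
  sys <- assemble_system(mesh, edges, em_materials(), port = port)
  expect_lt(max(Mod(sys$b)), 1e-130)
})

test_that("doubling the incident amplitude doubles the load", {
  mesh <- driven_cube_system(2)$mesh
  edges <- build_edge_structure(mesh)
  p1 <- tem_incident_field(10, 1e-3, 5e-3, 2.03, axis = c(0.01, 0.01))
  p4 <- tem_incident_field(40, 1e-3, 5e-3, 2.03, axis = c(0.01, 0.01))
  b1 <- assemble_system(mesh, edges, em_materials(), port = p1)$b
  b4 <- assemble_system(mesh, edges, em_materials(), port = p4)$b
  expect_equal(b4, 2 * b1, tolerance = 1e-12)  # amplitude ~ sqrt(power)
})

test_that("a port excitation without a port surface is a configuration error", {
  mesh <- fixture_cube(2, tag = "exterior")
  edges <- build_edge_structure(mesh)
  port <- tem_incident_field(10, 1e-3, 5e-3)
  expect_error(assemble_system(mesh, edges, em_materials(), port = port),
               "configuration error")
})

test_that("tangential surface mass matches a facet-quadrature oracle", {
  mesh <- fixture_two_tets(tag = "port")
  edges <- build_edge_structure(mesh)
  st <- surface_terms(mesh, edges, "port")
  geom <- ablatesim:::tet_geometry(mesh)
  # oracle: dense mid-edge-subdivision quadrature on one facet
  fi <- 1
  f <- mesh$facets[fi, ]
  own <- mesh$facet_cell[fi]
  fg <- facet_geometry(mesh, fi)
  # centroid rule on an n^2 triangular sub-grid (independent code path)
  S_oracle <- matrix(0, 6, 6)
  nsub <- 40
  cents <- NULL
  for (i in 0:(nsub - 1)) for (j in 0:(nsub - 1 - i)) {
    cents <- rbind(cents, c((i + 1 / 3) / nsub, (j + 1 / 3) / nsub))
    if (i + j <= nsub - 2)
      cents <- rbind(cents, c((i + 2 / 3) / nsub, (j + 2 / 3) / nsub))
  }
  wq <- fg$area / nsub^2
  for (r in seq_len(nrow(cents))) {
    l1 <- cents[r, 1]; l2 <- cents[r, 2]; l3 <- 1 - l1 - l2
    x <- l1 * mesh$vertices[f[1], ] + l2 * mesh$vertices[f[2], ] +
         l3 * mesh$vertices[f[3], ]
    W <- ablatesim:::whitney_at(geom, edges$tet_signs, own, rbind(x))
    Wt <- lapply(W, function(wk)
      wk[1, ] - sum(wk[1, ] * fg$normal[1, ]) * fg$normal[1, ])
    for (k in 1:6) for (l in 1:6)
      S_oracle[k, l] <- S_oracle[k, l] + wq * sum(Wt[[k]] * Wt[[l]])
  }
  expect_equal(matrix(st$S[1, ], 6, 6), S_oracle, tolerance = 2e-3)
})
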