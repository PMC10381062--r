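test_that("reference edge basis matches the closed-form polynomials", {
  # expanded Whitney forms on the reference tetrahedron, edges
  # (4,1),(1,2),(2,4),(2,3),(3,4),(3,1)
  forms <- list(
    function(p) c(1 - p[2] - p[3], p[1], p[1]),
    function(p) c(-p[2], p[1], 0),
    function(p) c(-p[2], -1 + p[1] + p[3], -p[2]),
    function(p) c(0, -p[3], p[2]),
    function(p) c(-p[3], -p[3], -1 + p[1] + p[2]),
    function(p) c(p[3], 0, -p[1]))
  set.seed(1)
  for (i in 1:6) {
    for (rep in 1:5) {
      p <- runif(3); p <- p / (sum(p) + runif(1, 0.1, 1))  # inside ref tet
      expect_equal(reference_basis(i, p)$value, forms[[i]](p),
                   tolerance = 1e-14)
    }
  }
  expect_equal(reference_basis(2, c(0, 0, 0))$value, c(0, 0, 0))
  expect_equal(reference_basis(2, c(0, 0, 0))$curl, c(0, 0, 2))
  expect_error(reference_basis(7, c(0, 0, 0)), "1..6")
  expect_error(reference_basis(1, c(0.9, 0.9, 0.9)), "reference")
})

test_that("each basis function is dual to its own edge (Whitney duality)", {
  refv <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  ed <- rbind(c(4, 1), c(1, 2), c(2, 4), c(2, 3), c(3, 4), c(3, 1))
  ts <- seq(0, 1, length.out = 401)
  D <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    a <- refv[[ed[j, 1]]]; b <- refv[[ed[j, 2]]]
    vals <- vapply(ts, function(t)
      sum(reference_basis(i, a + t * (b - a))$value * (b - a)), 1)
    D[i, j] <- sum((vals[-1] + vals[-length(vals)]) / 2) / (length(ts) - 1)
  }
  expect_equal(D, diag(6), tolerance = 1e-12)
})

test_that("basis curls are constant over the element", {
  set.seed(2)
  for (i in 1:6) {
    c0 <- reference_basis(i, c(0.1, 0.1, 0.1))$curl
    for (rep in 1:4) {
      p <- runif(3); p <- p / (sum(p) + 0.5)
      expect_equal(reference_basis(i, p)$curl, c0, tolerance = 1e-14)
    }
  }
})

test_that("element matrices are symmetric and match the quadrature oracle", {
  set.seed(7)
  for (rep in 1:4) {
    v <- matrix(rnorm(12), 4, 3)
    if (det(cbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])) < 0)
      v[c(3, 4), ] <- v[c(4, 3), ]
    signs <- sample(c(-1, 1), 6, replace = TRUE)
    em <- element_matrices(v, mu_r = 1.5, signs = signs)
    orc <- oracle_element_matrices(v, mu_r = 1.5, signs = signs)
    expect_equal(em$curl, t(em$curl), tolerance = 1e-13)
    expect_equal(em$mass, t(em$mass), tolerance = 1e-13)
    expect_equal(em$curl, orc$curl, tolerance = 1e-12)
    expect_equal(em$mass, orc$mass, tolerance = 1e-12)
  }
})

test_that("mass scales linearly and curl-curl inversely with element size", {
  v0 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 0.01
  base <- element_matrices(v0)
  for (s in c(0.5, 2)) {
    em <- element_matrices(v0 * s)
    orc <- oracle_element_matrices(v0 * s)   # exponents confirmed by oracle
    expect_equal(em$mass, base$mass * s, tolerance = 1e-12)
    expect_equal(em$curl, base$curl / s, tolerance = 1e-12)
    expect_equal(orc$mass, base$mass * s, tolerance = 1e-11)
    expect_equal(orc$curl, base$curl / s, tolerance = 1e-11)
  }
})

test_that("curl-curl matrix is positive semidefinite with a nullspace", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  em <- element_matrices(v)
  ev <- eigen(em$curl, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_gte(sum(abs(ev) < 1e-10), 3)  # gradients of the vertex functions
})

test_that("the degenerate element is a geometry error", {
  vdeg <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(element_matrices(vdeg), "degenerate")
})

test_that("tangential trace is continuous across a shared face", {
  mesh <- fixture_two_tets()
  edges <- build_edge_structure(mesh)
  geom <- ablatesim:::tet_geometry(mesh)
  set.seed(3)
  coeff <- rnorm(edges$n_edges)
  shared <- c(2L, 3L, 4L)   # face shared by the two elements
  nrm <- c(1, 1, 1) / sqrt(3)
  for (rep in 1:6) {
    lam <- runif(3); lam <- lam / sum(lam)
    x <- as.numeric(lam %*% mesh$vertices[shared, ])
    vals <- lapply(1:2, function(el) {
      W <- ablatesim:::whitney_at(geom, edges$tet_signs, rep(el, 1),
                                  matrix(x, 1))
      f <- c(0, 0, 0)
      for (k in 1:6) f <- f + coeff[edges$tet_edges[el, k]] * W[[k]][1, ]
      f - sum(f * nrm) * nrm
    })
    expect_equal(vals[[1]], vals[[2]], tolerance = 1e-11)
  }
})
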