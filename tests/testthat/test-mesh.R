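test_that("two glued tetrahedra have the expected combinatorics", {
  m <- fixture_two_tets()
  expect_s3_class(m, "abl_mesh")
  expect_equal(nrow(m$tets), 2)
  expect_equal(nrow(m$facets), 6)
  expect_true(all(m$volumes > 0))
  e <- build_edge_structure(m)
  expect_equal(e$n_edges, 9)  # 6 + 6 - 3 shared
  expect_silent(validate_mesh(m))
})

test_that("a single tetrahedron yields six ascending-oriented edges", {
  m <- abl_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                matrix(1:4, 1), "tumor")
  e <- build_edge_structure(m)
  expect_equal(e$n_edges, 6)
  expect_true(all(e$edges[, 1] < e$edges[, 2]))
  expect_true(all(e$tet_signs == 1))  # vertex order already ascending
})

test_that("an untagged boundary facet is a tagging error", {
  m <- fixture_two_tets()
  bad <- abl_mesh(m$vertices, m$tets, as.character(m$region),
                  facets = m$facets[-1, , drop = FALSE],
                  facet_tag = as.character(m$facet_tag)[-1])
  expect_error(validate_mesh(bad), "tagging error")
})

test_that("inverted input cells are repaired, degenerate ones rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- abl_mesh(v, matrix(c(1L, 2L, 4L, 3L), 1), "liver")  # negative volume
  expect_gt(m$volumes[1], 0)
  expect_error(abl_mesh(v, matrix(c(1L, 2L, 4L, 3L), 1), "liver",
                        reorder = FALSE), "non-positive")
  vdeg <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0))
  expect_error(abl_mesh(vdeg, matrix(1:4, 1), "liver"), "degenerate")
})

test_that("interior edges are referenced with a globally consistent direction", {
  mesh <- random_small_mesh(2)
  e <- build_edge_structure(mesh)
  LE <- local_edge_pairs()
  # brute force: for every element and local edge, the signed local edge
  # vector must equal the global edge vector
  for (el in seq_len(nrow(mesh$tets))) {
    for (k in 1:6) {
      va <- mesh$tets[el, LE[k, 1]]; vb <- mesh$tets[el, LE[k, 2]]
      ge <- e$edges[e$tet_edges[el, k], ]
      local_vec <- mesh$vertices[vb, ] - mesh$vertices[va, ]
      global_vec <- mesh$vertices[ge[2], ] - mesh$vertices[ge[1], ]
      expect_equal(e$tet_signs[el, k] * local_vec, global_vec,
                   tolerance = 1e-14)
    }
  }
})

test_that("phantom volume converges to the analytic cylinder volume", {
  spec <- geometry_spec()
  target <- pi * spec$liver_radius^2 * spec$liver_height
  errs <- vapply(c(6, 3), function(sc) {
    ph <- build_phantom(spec, c(-7e-3, 7e-3, 10e-3), scale = sc)
    abs(mesh_volume(ph) - target) / target
  }, 1)
  expect_lt(errs[2], errs[1])       # refinement reduces the error
  expect_lt(errs[2], 0.02)          # within mesh-discretization tolerance
})

test_that("the phantom carries all five regions and all surface tags", {
  ph <- build_phantom(geometry_spec(), c(-7e-3, 7e-3, 10e-3), scale = 4)
  expect_setequal(as.character(unique(ph$region)),
                  c("liver", "tumor", "dielectric", "catheter", "slot"))
  expect_true(all(c("pec", "port", "exterior") %in% ph$facet_tag))
  expect_silent(validate_mesh(ph))
  expect_gt(length(ph$pec_wire), 2)
})

test_that("phantom generation is deterministic", {
  a <- build_phantom(geometry_spec(), c(0, 0, 10e-3), scale = 5)
  b <- build_phantom(geometry_spec(), c(0, 0, 10e-3), scale = 5)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$tets, b$tets)
})

test_that("geometry invariants are enforced", {
  expect_error(geometry_spec(tumor_radius = 0.05), "geometry error")
  expect_error(build_phantom(geometry_spec(), c(0.03, 0.03, 0.01)),
               "outside the tumor")
})

test_that("tumor volume of the 4 cm sphere is 33.5 cm^3", {
  av <- analytic_volumes(geometry_spec())
  expect_equal(signif(av$tumor_cm3, 3), 33.5)
})
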