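# shared helpers: independent quadrature oracles and small fixtures

# independent tetrahedron quadrature for the oracle: the symmetric 4-point
# rule (exact for polynomials of degree 2 -- the degree of every Whitney
# product integrand) applied on the 8 sub-tetrahedra of one uniform
# refinement, so the oracle shares no constants with the closed-form path
tet_quad_oracle <- local({
  a <- (5 + 3 * sqrt(5)) / 20
  b <- (5 - sqrt(5)) / 20
  lam <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  list(lam = lam, w = rep(0.25, 4))
})

# split a tetrahedron (rows = vertices) into 8 sub-tetrahedra via edge
# midpoints (standard red refinement)
subdivide_tet <- function(v) {
  m <- function(i, j) (v[i, ] + v[j, ]) / 2
  v12 <- m(1, 2); v13 <- m(1, 3); v14 <- m(1, 4)
  v23 <- m(2, 3); v24 <- m(2, 4); v34 <- m(3, 4)
  list(rbind(v[1, ], v12, v13, v14), rbind(v12, v[2, ], v23, v24),
       rbind(v13, v23, v[3, ], v34), rbind(v14, v24, v34, v[4, ]),
       rbind(v12, v13, v14, v24), rbind(v12, v13, v23, v24),
       rbind(v13, v14, v24, v34), rbind(v13, v23, v24, v34))
}

# independent oracle: element curl-curl and mass matrices by degree-5
# quadrature of the Whitney basis (separate code path from the closed form)
oracle_element_matrices <- function(verts, mu_r = 1, signs = rep(1, 6)) {
  verts <- as.matrix(verts)
  p1 <- verts[1, ]
  J <- cbind(verts[2, ] - p1, verts[3, ] - p1, verts[4, ] - p1)
  V <- abs(det(J)) / 6
  Jinv <- solve(J)
  G <- rbind(-colSums(Jinv), Jinv)  # grad lam_1..4 as rows
  LE <- local_edge_pairs()
  curl <- matrix(0, 6, 6); mass <- matrix(0, 6, 6)
  cvec <- lapply(1:6, function(k) {
    a <- LE[k, 1]; b <- LE[k, 2]
    2 * signs[k] * c(G[a, 2] * G[b, 3] - G[a, 3] * G[b, 2],
                     G[a, 3] * G[b, 1] - G[a, 1] * G[b, 3],
                     G[a, 1] * G[b, 2] - G[a, 2] * G[b, 1])
  })
  for (sub in subdivide_tet(verts)) {
    Vs <- abs(det(cbind(sub[2, ] - sub[1, ], sub[3, ] - sub[1, ],
                        sub[4, ] - sub[1, ]))) / 6
    for (q in seq_along(tet_quad_oracle$w)) {
      x <- as.numeric(tet_quad_oracle$lam[q, ] %*% sub)
      lam <- c(0, Jinv %*% (x - p1))
      lam[1] <- 1 - sum(lam)
      wq <- tet_quad_oracle$w[q] * Vs
      N <- lapply(1:6, function(k) {
        a <- LE[k, 1]; b <- LE[k, 2]
        signs[k] * (lam[a] * G[b, ] - lam[b] * G[a, ])
      })
      for (k in 1:6) for (l in 1:6) {
        mass[k, l] <- mass[k, l] + wq * sum(N[[k]] * N[[l]])
        curl[k, l] <- curl[k, l] + wq * sum(cvec[[k]] * cvec[[l]]) / mu_r
      }
    }
  }
  list(curl = curl, mass = mass)
}

# a small driven fixture: cube of lossy tissue with a port on top, pec on
# bottom, absorbing sides; exercises every term of the assembly
driven_cube_system <- function(n = 3, side = 0.02, frequency = 2.45e9) {
  mesh <- fixture_cube(n, tag = "exterior", side = side)
  cen <- (mesh$vertices[mesh$facets[, 1], ] +
          mesh$vertices[mesh$facets[, 2], ] +
          mesh$vertices[mesh$facets[, 3], ]) / 3
  tag <- as.character(mesh$facet_tag)
  tag[abs(cen[, 3] - side) < 1e-12] <- "port"
  tag[abs(cen[, 3]) < 1e-12] <- "pec"
  mesh <- abl_mesh(mesh$vertices, mesh$tets,
                   as.character(mesh$region), mesh$facets, tag,
                   reorder = FALSE)
  edges <- build_edge_structure(mesh)
  mat <- em_materials(frequency)
  port <- tem_incident_field(10, 1e-3, side / 2, 2.03, frequency,
                             axis = c(side / 2, side / 2))
  sys <- assemble_system(mesh, edges, mat, port = port)
  list(mesh = mesh, edges = edges, materials = mat, system = sys)
}

# random small tetrahedral mesh (perturbed structured cube), for
# orientation-consistency brute-force checks
random_small_mesh <- function(n = 2, seed = 42, jitter = 0.15) {
  set.seed(seed)
  mesh <- fixture_cube(n, tag = "exterior")
  v <- mesh$vertices
  inner <- v[, 1] > 0 & v[, 1] < 1 & v[, 2] > 0 & v[, 2] < 1 &
           v[, 3] > 0 & v[, 3] < 1
  v[inner, ] <- v[inner, ] + matrix(runif(3 * sum(inner), -jitter, jitter) / n,
                                    ncol = 3)
  abl_mesh(v, mesh$tets, as.character(mesh$region), mesh$facets,
           as.character(mesh$facet_tag))
}
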