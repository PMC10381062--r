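# manufactured outgoing plane wave E = p exp(j k0 d.x) in a lossless
# homogeneous cube with exact first-order absorbing data on the boundary
plane_wave_problem <- function(n, side = 0.02, frequency = 2.45e9) {
  mesh <- fixture_cube(n, tag = "exterior", side = side)
  edges <- build_edge_structure(mesh)
  mat <- em_materials(frequency)   # lossy liver medium
  k0 <- mat$k0
  kap <- k0 * sqrt(mat$eps_R[["liver"]])   # complex wavevector magnitude
  d <- c(1, 2, 2) / 3
  p <- c(2, -1, -1) / sqrt(6)   # p . d = 0
  Eex <- function(x) {
    # decaying outgoing wave under the exp(+j omega t) convention;
    # curl curl E = kap^2 E exactly, so E solves the lossy wave equation
    ph <- exp(-1i * kap * (x %*% d))
    cbind(p[1] * ph, p[2] * ph, p[3] * ph)
  }
  curlE <- function(x) {
    ph <- -1i * kap * exp(-1i * kap * (x %*% d))
    dxp <- c(d[2] * p[3] - d[3] * p[2],
             d[3] * p[1] - d[1] * p[3],
             d[1] * p[2] - d[2] * p[1])
    cbind(dxp[1] * ph, dxp[2] * ph, dxp[3] * ph)
  }
  gfun <- function(x) {
    # outward normal of the cube at boundary quadrature points
    nrm <- matrix(0, nrow(x), 3)
    for (c3 in 1:3) {
      nrm[abs(x[, c3]) < 1e-12, c3] <- -1
      nrm[abs(x[, c3] - side) < 1e-12, c3] <- 1
    }
    cE <- curlE(x); E <- Eex(x)
    ncE <- cbind(nrm[, 2] * cE[, 3] - nrm[, 3] * cE[, 2],
                 nrm[, 3] * cE[, 1] - nrm[, 1] * cE[, 3],
                 nrm[, 1] * cE[, 2] - nrm[, 2] * cE[, 1])
    Et <- E - rowSums(Re(E) * nrm) * nrm - 1i * (rowSums(Im(E) * nrm) * nrm)
    ncE - 1i * k0 * Et          # n x (n x E) = -E_t
  }
  sys <- assemble_system(mesh, edges, mat, abc_load = gfun)
  list(mesh = mesh, edges = edges, mat = mat, sys = sys, Eex = Eex,
       curlE = curlE, k0 = k0)
}

hcurl_error <- function(pb, coeff) {
  mesh <- pb$mesh; edges <- pb$edges
  geom <- ablatesim:::tet_geometry(mesh)
  m <- nrow(mesh$tets)
  LE <- local_edge_pairs()
  err2 <- 0
  # 4-point rule per element for the field error; curls are constant
  a <- (5 + 3 * sqrt(5)) / 20; b <- (5 - sqrt(5)) / 20
  lam4 <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  verts <- lapply(1:4, function(i) mesh$vertices[mesh$tets[, i], , drop = FALSE])
  ce <- matrix(coeff[edges$tet_edges], ncol = 6)
  # constant exact & discrete curls
  curl_h <- matrix(0 + 0i, m, 3)
  for (k in 1:6) {
    aa <- LE[k, 1]; bb <- LE[k, 2]
    ga <- geom$grads[[aa]]; gb <- geom$grads[[bb]]
    cr <- 2 * edges$tet_signs[, k] *
      cbind(ga[, 2] * gb[, 3] - ga[, 3] * gb[, 2],
            ga[, 3] * gb[, 1] - ga[, 1] * gb[, 3],
            ga[, 1] * gb[, 2] - ga[, 2] * gb[, 1])
    curl_h <- curl_h + ce[, k] * cr
  }
  for (q in 1:4) {
    xq <- lam4[q, 1] * verts[[1]] + lam4[q, 2] * verts[[2]] +
          lam4[q, 3] * verts[[3]] + lam4[q, 4] * verts[[4]]
    W <- ablatesim:::whitney_at(geom, edges$tet_signs, seq_len(m), xq)
    Eh <- matrix(0 + 0i, m, 3)
    for (k in 1:6) Eh <- Eh + ce[, k] * W[[k]]
    dE <- Eh - pb$Eex(xq)
    dC <- curl_h - pb$curlE(xq)
    err2 <- err2 + 0.25 * geom$volume *
      (rowSums(Mod(dE)^2) + rowSums(Mod(dC)^2))
  }
  sqrt(sum(err2))
}

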