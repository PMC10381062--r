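#' Element curl-curl and mass matrices for edge elements
#'
#' Closed-form barycentric integration (exact for the degree-2 integrands of
#' lowest-order edge elements):
#' curl N_i is constant, so the curl-curl matrix is V (c_i . c_j) / mu_r;
#' the mass matrix uses int lam_a lam_c dV = V (1 + delta_ac) / 20.
#'
#' @param vertices 4 x 3 matrix of tetrahedron vertices
#' @param mu_r relative permeability
#' @param signs orientation signs of the six local edges (default all +1)
#' @return list with `curl` and `mass`, both 6 x 6 symmetric
#' @export
element_matrices <- function(vertices, mu_r = 1, signs = rep(1, 6)) {
  mesh <- abl_mesh(vertices, matrix(1:4, 1), "liver", reorder = FALSE)
  geom <- tet_geometry(mesh)
  em <- element_matrix_arrays(geom, matrix(signs, 1))
  list(curl = matrix(em$curl[1, ], 6, 6) / mu_r,
       mass = matrix(em$mass[1, ], 6, 6))
}

# vectorized element matrices over all elements: returns m x 36 matrices
# (column-major 6x6 layout) for unit-material curl-curl and mass
element_matrix_arrays <- function(geom, signs) {
  LE <- local_edge_pairs()
  m <- length(geom$volume)
  V <- geom$volume
  G <- geom$grads
  # constant curls c_i = 2 s_i (G_a x G_b)
  curls <- vector("list", 6)
  for (k in 1:6) {
    a <- LE[k, 1]; b <- LE[k, 2]
    ga <- G[[a]]; gb <- G[[b]]
    curls[[k]] <- 2 * signs[, k] *
      cbind(ga[, 2] * gb[, 3] - ga[, 3] * gb[, 2],
            ga[, 3] * gb[, 1] - ga[, 1] * gb[, 3],
            ga[, 1] * gb[, 2] - ga[, 2] * gb[, 1])
  }
  # g_ab = grad lam_a . grad lam_b
  g <- array(0, c(m, 4, 4))
  for (a in 1:4) for (b in a:4) {
    g[, a, b] <- rowSums(G[[a]] * G[[b]])
    g[, b, a] <- g[, a, b]
  }
  Kmat <- matrix(0, m, 36)
  Mmat <- matrix(0, m, 36)
  ii <- function(a, c) V * (1 + (a == c)) / 20
  for (k in 1:6) for (l in k:6) {
    a <- LE[k, 1]; b <- LE[k, 2]
    cc <- LE[l, 1]; d <- LE[l, 2]
    kv <- V * rowSums(curls[[k]] * curls[[l]])
    mv <- signs[, k] * signs[, l] *
      (g[, b, d] * ii(a, cc) - g[, b, cc] * ii(a, d) -
       g[, a, d] * ii(b, cc) + g[, a, cc] * ii(b, d))
    Kmat[, (l - 1) * 6 + k] <- kv
    Mmat[, (l - 1) * 6 + k] <- mv
    if (l != k) {
      Kmat[, (k - 1) * 6 + l] <- kv
      Mmat[, (k - 1) * 6 + l] <- mv
    }
  }
  list(curl = Kmat, mass = Mmat)
}

# degree-4 triangle quadrature (6 points), barycentric
TRI_QUAD <- list(
  lam = rbind(c(0.108103018168070, 0.445948490915965, 0.445948490915965),
              c(0.445948490915965, 0.108103018168070, 0.445948490915965),
              c(0.445948490915965, 0.445948490915965, 0.108103018168070),
              c(0.816847572980459, 0.091576213509771, 0.091576213509771),
              c(0.091576213509771, 0.816847572980459, 0.091576213509771),
              c(0.091576213509771, 0.091576213509771, 0.816847572980459)),
  w = c(rep(0.223381589678011, 3), rep(0.109951743655322, 3)))

#' Tangential surface mass matrices on tagged facets
#'
#' For each facet on `tag`, the 6 x 6 matrix
#' S_ij = int_F (N_i)_t . (N_j)_t dS over the owning element's edge basis,
#' where ()_t removes the facet-normal component. These are the building
#' blocks of the port (beta-weighted) and absorbing-boundary (k0-weighted)
#' terms.
#'
#' @param mesh an `abl_mesh`
#' @param edges an `abl_edges`
#' @param tag surface tag (`port` or `exterior`)
#' @return list with `facet_idx`, `owner`, `S` (nf x 36)
#' @export
surface_terms <- function(mesh, edges, tag) {
  fi <- which(mesh$facet_tag == tag)
  if (!length(fi))
    return(list(facet_idx = integer(0), owner = integer(0),
                S = matrix(0, 0, 36)))
  geom <- tet_geometry(mesh)
  fg <- facet_geometry(mesh, fi)
  own <- mesh$facet_cell[fi]
  f <- mesh$facets[fi, , drop = FALSE]
  nf <- length(fi)
  S <- matrix(0, nf, 36)
  for (q in seq_along(TRI_QUAD$w)) {
    lamq <- TRI_QUAD$lam[q, ]
    xq <- lamq[1] * mesh$vertices[f[, 1], , drop = FALSE] +
          lamq[2] * mesh$vertices[f[, 2], , drop = FALSE] +
          lamq[3] * mesh$vertices[f[, 3], , drop = FALSE]
    W <- whitney_at(geom, edges$tet_signs, own, xq)
    Wt <- lapply(W, function(wk) wk - rowSums(wk * fg$normal) * fg$normal)
    wq <- TRI_QUAD$w[q]
    for (k in 1:6) for (l in k:6) {
      v <- wq * rowSums(Wt[[k]] * Wt[[l]])
      S[, (l - 1) * 6 + k] <- S[, (l - 1) * 6 + k] + v
      if (l != k) S[, (k - 1) * 6 + l] <- S[, (k - 1) * 6 + l] + v
    }
  }
  list(facet_idx = fi, owner = own, S = S * fg$area)
}

#' Surface load vector int_S N_i . g dS on a tagged surface
#'
#' @param mesh an `abl_mesh`
#' @param edges an `abl_edges`
#' @param tag surface tag
#' @param gfun function(points n x 3) -> complex n x 3 matrix
#' @return complex vector over all global edges
#' @export
surface_load <- function(mesh, edges, tag, gfun) {
  b <- complex(edges$n_edges)
  fi <- which(mesh$facet_tag == tag)
  if (!length(fi)) return(b)
  geom <- tet_geometry(mesh)
  fg <- facet_geometry(mesh, fi)
  own <- mesh$facet_cell[fi]
  f <- mesh$facets[fi, , drop = FALSE]
  acc <- matrix(0 + 0i, length(fi), 6)
  for (q in seq_along(TRI_QUAD$w)) {
    lamq <- TRI_QUAD$lam[q, ]
    xq <- lamq[1] * mesh$vertices[f[, 1], , drop = FALSE] +
          lamq[2] * mesh$vertices[f[, 2], , drop = FALSE] +
          lamq[3] * mesh$vertices[f[, 3], , drop = FALSE]
    gq <- gfun(xq)
    W <- whitney_at(geom, edges$tet_signs, own, xq)
    for (k in 1:6)
      acc[, k] <- acc[, k] + TRI_QUAD$w[q] * rowSums(W[[k]] * gq)
  }
  acc <- acc * fg$area
  for (k in 1:6) {
    ge <- edges$tet_edges[own, k]
    agg_re <- rowsum(Re(acc[, k]), ge)
    agg_im <- rowsum(Im(acc[, k]), ge)
    ids <- as.integer(rownames(agg_re))
    b[ids] <- b[ids] + complex(real = agg_re[, 1], imaginary = agg_im[, 1])
  }
  b
}

#' Assemble the time-harmonic curl-curl system
#'
#' Builds the complex system A_c = A_re + j A_im with
#' A_re = (1/mu_r) K - k0^2 eps_r M,
#' A_im = k0^2 (sigma/(omega eps0)) M + (beta/mu_r) M_port + (k0/mu_r) M_abc,
#' b_c = +2 j (beta/mu_r) int_Sp N . E_inc dS (+ any extra absorbing-boundary
#' load), stored as two real sparse matrices plus a complex load. The real
#' and imaginary rows of this system are the printed real-valued weak form
#' pair of the wave model. Edges on `pec` facets are constrained to zero and
#' eliminated from the solve.
#'
#' @param mesh an `abl_mesh`
#' @param edges an `abl_edges`
#' @param materials an `abl_em_materials`
#' @param port optional TEM port excitation from [tem_incident_field()];
#'   required for a driven problem (an empty port surface with a port
#'   excitation is a configuration error)
#' @param abc_load optional function(points) -> complex n x 3, an extra
#'   inhomogeneous absorbing-boundary datum g = n x (curl E) + j k0 n x (n x E)
#'   on the exterior surface (used by manufactured-solution studies);
#'   contributes -int g . N dS to the load
#' @return list of class `abl_em_system` with `Are`, `Aim` (sparse, full
#'   edge set), `b` (complex), `free` (unconstrained edge indices), `edges`,
#'   `mesh`, `materials`
#' @export
assemble_system <- function(mesh, edges, materials, port = NULL,
                            abc_load = NULL) {
  geom <- tet_geometry(mesh)
  em <- element_matrix_arrays(geom, edges$tet_signs)
  k0 <- materials$k0
  mu <- region_lookup(materials, mesh, "mu_r")
  er <- region_lookup(materials, mesh, "eps_r")
  si <- region_lookup(materials, mesh, "sigma")
  sig_scaled <- si / (materials$omega * materials$eps0)

  m <- nrow(mesh$tets)
  iidx <- matrix(0L, m, 36); jidx <- matrix(0L, m, 36)
  for (k in 1:6) for (l in 1:6) {
    col <- (l - 1) * 6 + k
    iidx[, col] <- edges$tet_edges[, k]
    jidx[, col] <- edges$tet_edges[, l]
  }
  vre <- em$curl / mu - (k0^2 * er) * em$mass
  vim <- (k0^2 * sig_scaled) * em$mass
  n <- edges$n_edges
  Are <- Matrix::sparseMatrix(i = as.vector(iidx), j = as.vector(jidx),
                              x = as.vector(vre), dims = c(n, n))
  Aim <- Matrix::sparseMatrix(i = as.vector(iidx), j = as.vector(jidx),
                              x = as.vector(vim), dims = c(n, n))

  b <- complex(n)
  if (!is.null(port)) {
    if (!any(mesh$facet_tag == "port"))
      stop("configuration error: port excitation given but port surface is empty")
    st <- surface_terms(mesh, edges, "port")
    mu_f <- mu[st$owner]
    Aim <- Aim + facet_sparse(st, edges, port$beta / mu_f, n)
    b <- b + 2i * port$beta *
      surface_load_scaled(mesh, edges, "port", port$field, 1 / mu)
  }
  st_abc <- surface_terms(mesh, edges, "exterior")
  if (nrow(st_abc$S)) {
    mu_f <- mu[st_abc$owner]
    Aim <- Aim + facet_sparse(st_abc, edges, k0 / mu_f, n)
  }
  if (!is.null(abc_load))
    b <- b - surface_load(mesh, edges, "exterior", abc_load)

  pec <- edges$surface_edges$pec
  free <- setdiff(seq_len(n), pec)
  structure(list(Are = Are, Aim = Aim, b = b, free = free,
                 n_edges = n, edges = edges, mesh = mesh,
                 materials = materials, port = port),
            class = "abl_em_system")
}

# assemble nf x 36 facet matrices (scaled per facet) into a sparse matrix
facet_sparse <- function(st, edges, scale, n) {
  nf <- nrow(st$S)
  ii <- matrix(0L, nf, 36); jj <- matrix(0L, nf, 36)
  for (k in 1:6) for (l in 1:6) {
    col <- (l - 1) * 6 + k
    ii[, col] <- edges$tet_edges[st$owner, k]
    jj[, col] <- edges$tet_edges[st$owner, l]
  }
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                       x = as.vector(st$S * scale), dims = c(n, n))
}

# surface load with a per-element scalar multiplier (e.g. 1/mu_r)
surface_load_scaled <- function(mesh, edges, tag, gfun, elem_scale) {
  fi <- which(mesh$facet_tag == tag)
  if (!length(fi)) return(complex(edges$n_edges))
  own <- mesh$facet_cell[fi]
  sc <- elem_scale[own]
  if (all(sc == sc[1])) return(sc[1] * surface_load(mesh, edges, tag, gfun))
  # rare: spatially varying mu on the port; fall back to facet loop
  b <- complex(edges$n_edges)
  for (i in seq_along(fi)) {
    sub <- mesh
    keep <- fi[i]
    sub$facet_tag[] <- NA
    sub$facet_tag[keep] <- tag
    b <- b + sc[i] * surface_load(sub, edges, tag, gfun)
  }
  b
}
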