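#' Lowest-order edge (Whitney/Nedelec) basis on the reference tetrahedron
#'
#' The reference tetrahedron has vertices v4 = (0,0,0), v1 = (1,0,0),
#' v2 = (0,1,0), v3 = (0,0,1) in coordinates (xi, nu, eta), with barycentric
#' coordinates (lam1, lam2, lam3, lam4) = (xi, nu, eta, 1-xi-nu-eta). The six
#' edge functions are the Whitney forms
#' N_ab = lam_a grad(lam_b) - lam_b grad(lam_a) for the directed edges
#' (4,1), (1,2), (2,4), (2,3), (3,4), (3,1). Expanded, they are the
#' polynomial vectors
#' (1-nu-eta, xi, xi), (-nu, xi, 0), (-nu, -1+xi+eta, -nu), (0, -eta, nu),
#' (-eta, -eta, -1+xi+nu), (eta, 0, -xi).
#' Each has unit tangential line integral along its own edge and zero along
#' the other five; each curl is constant.
#'
#' @param local_edge edge index 1..6 in the order above
#' @param point length-3 reference coordinates (xi, nu, eta)
#' @return list with `value` (3-vector) and `curl` (constant 3-vector)
#' @export
reference_basis <- function(local_edge, point) {
  if (!(local_edge %in% 1:6)) stop("local edge index must be in 1..6")
  p <- as.numeric(point)
  if (length(p) != 3 || any(p < -1e-12) || sum(p) > 1 + 1e-12)
    stop("point must lie in the reference tetrahedron")
  lam <- c(p[1], p[2], p[3], 1 - sum(p))
  G <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, -1, -1))
  ed <- REFERENCE_EDGES[local_edge, ]
  a <- ed[1]; b <- ed[2]
  list(value = lam[a] * G[b, ] - lam[b] * G[a, ],
       curl = 2 * cross3(G[a, ], G[b, ]))
}

# directed reference edges, in the order the basis formulas are listed
REFERENCE_EDGES <- rbind(c(4L, 1L), c(1L, 2L), c(2L, 4L),
                         c(2L, 3L), c(3L, 4L), c(3L, 1L))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Per-element affine geometry of a tetrahedral mesh
#'
#' Barycentric gradients and volumes for every element, vectorized. The
#' gradients define the physical Whitney basis
#' N_i = s_i (lam_a grad lam_b - lam_b grad lam_a) for local edge
#' i = (a, b) and orientation sign s_i, which is the covariant (H(curl))
#' mapping of the reference basis.
#'
#' @param mesh an `abl_mesh`
#' @return list with `volume` (m), `grads` (list of four m x 3 matrices),
#'   `p1` (m x 3 first-vertex coordinates)
#' @keywords internal
tet_geometry <- function(mesh) {
  v <- mesh$vertices; t4 <- mesh$tets
  p1 <- v[t4[, 1], , drop = FALSE]
  a <- v[t4[, 2], , drop = FALSE] - p1
  b <- v[t4[, 3], , drop = FALSE] - p1
  d <- v[t4[, 4], , drop = FALSE] - p1
  det <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
         a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
         a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
  # rows of inv(J), J = [a b d] columns: grad lam2, lam3, lam4
  g2 <- cbind(b[, 2] * d[, 3] - b[, 3] * d[, 2],
              b[, 3] * d[, 1] - b[, 1] * d[, 3],
              b[, 1] * d[, 2] - b[, 2] * d[, 1]) / det
  g3 <- cbind(d[, 2] * a[, 3] - d[, 3] * a[, 2],
              d[, 3] * a[, 1] - d[, 1] * a[, 3],
              d[, 1] * a[, 2] - d[, 2] * a[, 1]) / det
  g4 <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1]) / det
  g1 <- -(g2 + g3 + g4)
  list(volume = det / 6, grads = list(g1, g2, g3, g4), p1 = p1)
}

# evaluate all six Whitney functions of given elements at physical points
# (one point per element row). geom from tet_geometry, signs m x 6.
# Returns list of six m x 3 matrices.
whitney_at <- function(geom, signs, elems, points) {
  LE <- local_edge_pairs()
  lam <- vector("list", 4)
  dx <- points - geom$p1[elems, , drop = FALSE]
  for (i in 1:4) {
    gi <- geom$grads[[i]][elems, , drop = FALSE]
    lam[[i]] <- (if (i == 1) 1 else 0) + rowSums(gi * dx)
  }
  out <- vector("list", 6)
  for (k in 1:6) {
    a <- LE[k, 1]; b <- LE[k, 2]
    ga <- geom$grads[[a]][elems, , drop = FALSE]
    gb <- geom$grads[[b]][elems, , drop = FALSE]
    out[[k]] <- signs[elems, k] * (lam[[a]] * gb - lam[[b]] * ga)
  }
  out
}
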