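#' Locate points in a tetrahedral mesh
#'
#' Bucket-accelerated point location: returns for each query point a
#' containing element (barycentric coordinates all >= -tol) or, for points
#' outside the mesh hull, the element with the least-negative barycentric
#' coordinate among the nearby candidates (nearest-cell fallback).
#'
#' @param mesh an `abl_mesh`
#' @param points n x 3 coordinates (m)
#' @param tol barycentric tolerance for containment
#' @return list with `elem` (n), `lambda` (n x 4), `inside` (logical)
#' @export
locate_points <- function(mesh, points, tol = 1e-9) {
  points <- rbind(points)
  geom <- tet_geometry(mesh)
  np <- nrow(points)
  m <- nrow(mesh$tets)
  # bucket grid over the mesh bounding box
  nb <- max(2L, min(40L, floor(m^(1 / 3))))
  lo <- apply(mesh$vertices, 2, min) - 1e-12
  hi <- apply(mesh$vertices, 2, max) + 1e-12
  span <- pmax(hi - lo, 1e-12)
  bucket_of <- function(p) {
    b <- floor((sweep(p, 2, lo) / rep(span, each = nrow(p))) * nb)
    b <- pmin(pmax(b, 0), nb - 1)
    b[, 1] + nb * (b[, 2] + nb * b[, 3]) + 1
  }
  # for a handful of query points brute force beats building the index
  brute <- np * m <= 5e6
  if (!brute) {
    # tets can straddle buckets: register each tet in every bucket its
    # vertices' bounding box touches
    vx <- matrix(mesh$vertices[mesh$tets, 1], m, 4)
    vy <- matrix(mesh$vertices[mesh$tets, 2], m, 4)
    vz <- matrix(mesh$vertices[mesh$tets, 3], m, 4)
    bmin <- bucket_ijk(cbind(apply(vx, 1, min), apply(vy, 1, min),
                             apply(vz, 1, min)), lo, span, nb)
    bmax <- bucket_ijk(cbind(apply(vx, 1, max), apply(vy, 1, max),
                             apply(vz, 1, max)), lo, span, nb)
    nrep <- (bmax[, 1] - bmin[, 1] + 1) * (bmax[, 2] - bmin[, 2] + 1) *
            (bmax[, 3] - bmin[, 3] + 1)
    reg_tet <- rep(seq_len(m), nrep)
    reg_bkt <- integer(sum(nrep)); pos <- 1L
    for (e in seq_len(m)) {
      ii <- bmin[e, 1]:bmax[e, 1]; jj <- bmin[e, 2]:bmax[e, 2]
      kk <- bmin[e, 3]:bmax[e, 3]
      bk <- as.vector(outer(outer(ii, nb * jj, "+"), nb * nb * kk, "+")) + 1L
      reg_bkt[pos:(pos + length(bk) - 1L)] <- bk
      pos <- pos + length(bk)
    }
    reg <- split(reg_tet, reg_bkt)
    pb <- bucket_of(points)
  }
  elem <- integer(np); lambda <- matrix(0, np, 4); inside <- logical(np)
  for (q in seq_len(np)) {
    cand <- if (brute) seq_len(m) else reg[[as.character(pb[q])]]
    if (is.null(cand)) cand <- seq_len(m)  # far outside: brute force
    lam <- bary_at(geom, cand, points[q, ])
    worst <- apply(lam, 1, min)
    best <- which.max(worst)
    elem[q] <- cand[best]
    lambda[q, ] <- pmax(lam[best, ], 0)
    lambda[q, ] <- lambda[q, ] / sum(lambda[q, ])
    inside[q] <- worst[best] >= -tol
  }
  list(elem = elem, lambda = lambda, inside = inside)
}

bucket_ijk <- function(p, lo, span, nb) {
  b <- floor((sweep(p, 2, lo) / rep(span, each = nrow(p))) * nb)
  pmin(pmax(b, 0), nb - 1)
}

# barycentric coordinates of one point w.r.t. candidate elements
bary_at <- function(geom, elems, point) {
  dx <- matrix(point, length(elems), 3, byrow = TRUE) -
    geom$p1[elems, , drop = FALSE]
  lam <- matrix(0, length(elems), 4)
  for (i in 1:4)
    lam[, i] <- (if (i == 1) 1 else 0) +
      rowSums(geom$grads[[i]][elems, , drop = FALSE] * dx)
  lam
}

#' Transfer nodal fields between meshes covering the same domain
#'
#' Barycentric (P1) interpolation of nodal fields from a source mesh onto
#' the nodes of a target mesh. Points outside the source hull take the
#' values of the nearest cell (clamped barycentric weights). Linear fields
#' are reproduced exactly; the conservation drift of the volume integral of
#' each field is reported.
#'
#' @param source_mesh,target_mesh `abl_mesh` objects over the same domain
#' @param fields named list of nodal vectors on the source mesh (or a single
#'   vector)
#' @return list with `fields` (same shape, on target nodes) and `drift`
#'   (relative change of the volume integral per field)
#' @export
transfer_fields <- function(source_mesh, target_mesh, fields) {
  single <- !is.list(fields)
  if (single) fields <- list(field = fields)
  nvs <- nrow(source_mesh$vertices)
  for (f in fields)
    if (length(f) != nvs) stop("field length does not match source mesh")
  loc <- locate_points(source_mesh, target_mesh$vertices)
  if (!any(loc$inside))
    stop("disjoint domains: no target vertex lies inside the source mesh")
  t4 <- source_mesh$tets
  out <- lapply(fields, function(f) {
    fv <- matrix(f[t4[loc$elem, ]], ncol = 4)
    rowSums(fv * loc$lambda)
  })
  drift <- vapply(seq_along(fields), function(i) {
    is_ <- integral_p1(source_mesh, fields[[i]])
    it_ <- integral_p1(target_mesh, out[[i]])
    if (abs(is_) > 0) (it_ - is_) / is_ else it_ - is_
  }, 1)
  names(drift) <- names(fields)
  list(fields = if (single) out[[1]] else out, drift = drift)
}

# volume integral of a nodal P1 field
integral_p1 <- function(mesh, f) {
  t4 <- mesh$tets
  sum(mesh$volumes * (f[t4[, 1]] + f[t4[, 2]] + f[t4[, 3]] + f[t4[, 4]]) / 4)
}
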