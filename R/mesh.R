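#' Tagged tetrahedral mesh
#'
#' The shared substrate of all solvers: vertex coordinates in metres,
#' tetrahedra as 4 vertex indices each (reordered to positive signed volume),
#' a region tag per tetrahedron (`liver`, `tumor`, `dielectric`, `catheter`,
#' `slot`) and tagged surface facets (`pec`, `port`, `exterior`).
#'
#' Port and exterior facets must be true boundary facets (owned by exactly one
#' tetrahedron). Perfect-electric-conductor (`pec`) facets may be interior:
#' at tissue-scale resolution the antenna metal is a thin sheet between the
#' coax dielectric and the catheter, and the constraint lives on the facet's
#' edges regardless of how many cells share it.
#'
#' @param vertices numeric n x 3 matrix of coordinates (m)
#' @param tets integer m x 4 matrix of vertex indices
#' @param region character/factor of length m with values in
#'   `liver, tumor, dielectric, catheter, slot`
#' @param facets integer f x 3 matrix of facet vertex indices
#' @param facet_tag character/factor of length f with values in
#'   `pec, port, exterior`
#' @param reorder reorder tet vertices so all signed volumes are positive
#'   (default TRUE); with `reorder = FALSE` a non-positive volume is an error
#' @return object of class `abl_mesh`
#' @export
abl_mesh <- function(vertices, tets, region, facets = NULL, facet_tag = NULL,
                     reorder = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  stopifnot(ncol(vertices) == 3)
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(tets) == 4)
  if (any(tets < 1L) || any(tets > nrow(vertices)))
    stop("tetrahedron refers to a vertex outside the mesh")

  region <- as.character(region)
  if (length(region) != nrow(tets))
    stop("region tag vector must have one entry per tetrahedron")
  bad <- setdiff(unique(region), REGION_TAGS)
  if (length(bad))
    stop("unknown region tag(s): ", paste(bad, collapse = ", "))

  vol <- tet_signed_volumes(vertices, tets)
  neg <- which(vol < 0)
  if (length(neg)) {
    if (!reorder)
      stop("tetrahedron with non-positive volume at cell index ",
           neg[1], " (reorder disabled)")
    tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
    vol <- abs(vol)
  }
  dg <- which(vol <= .Machine$double.eps * max(vol, 1e-300))
  if (length(dg))
    stop("degenerate (zero-volume) tetrahedron at cell index ", dg[1])

  if (is.null(facets)) {
    facets <- matrix(integer(0), 0, 3)
    facet_tag <- character(0)
  }
  facets <- as.matrix(facets)
  storage.mode(facets) <- "integer"
  facet_tag <- as.character(facet_tag)
  if (nrow(facets) != length(facet_tag))
    stop("facet_tag must have one entry per facet")
  bad <- setdiff(unique(facet_tag), SURFACE_TAGS)
  if (length(bad))
    stop("unknown surface tag(s): ", paste(bad, collapse = ", "))

  m <- structure(list(
    vertices = vertices, tets = tets,
    region = factor(region, levels = REGION_TAGS),
    facets = facets,
    facet_tag = factor(facet_tag, levels = SURFACE_TAGS),
    volumes = vol
  ), class = "abl_mesh")
  m$facet_cell <- facet_owner_cells(m)
  m
}

#' @export
print.abl_mesh <- function(x, ...) {
  cat("<abl_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$tets),
      " tetrahedra, ", nrow(x$facets), " tagged facets\n", sep = "")
  cat("  regions: ",
      paste(sprintf("%s=%d", levels(x$region), tabulate(x$region, 5)),
            collapse = " "), "\n", sep = "")
  if (nrow(x$facets))
    cat("  surfaces:",
        paste(sprintf("%s=%d", levels(x$facet_tag), tabulate(x$facet_tag, 3)),
              collapse = " "), "\n")
  invisible(x)
}

#' Signed volumes of tetrahedra
#' @param vertices n x 3 coordinates
#' @param tets m x 4 indices
#' @return numeric vector of signed volumes (m^3)
#' @export
tet_signed_volumes <- function(vertices, tets) {
  a <- vertices[tets[, 2], , drop = FALSE] - vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 3], , drop = FALSE] - vertices[tets[, 1], , drop = FALSE]
  d <- vertices[tets[, 4], , drop = FALSE] - vertices[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

# The four faces of a tet, opposite local vertices 1..4.
TET_FACES <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))

facet_key <- function(f) {
  if (!nrow(f)) return(character(0))
  a <- pmin(f[, 1], f[, 2], f[, 3])
  c3 <- pmax(f[, 1], f[, 2], f[, 3])
  b <- f[, 1] + f[, 2] + f[, 3] - a - c3
  paste(a, b, c3, sep = "_")
}

# For each tagged facet, an owning tetrahedron index (the lowest-index cell
# containing the facet). Errors if a facet is not a face of any cell.
facet_owner_cells <- function(mesh) {
  if (!nrow(mesh$facets)) return(integer(0))
  m <- nrow(mesh$tets)
  allf <- matrix(0L, 4 * m, 3)
  for (k in 1:4)
    allf[seq.int(k, by = 4, length.out = m), ] <-
      mesh$tets[, TET_FACES[k, ], drop = FALSE]
  owner <- rep(seq_len(m), each = 4)
  idx <- match(facet_key(mesh$facets), facet_key(allf))
  if (anyNA(idx))
    stop("tagged facet is not a face of any tetrahedron (facet ",
         which(is.na(idx))[1], ")")
  owner[idx]
}

#' All boundary facets of a mesh
#'
#' A boundary facet is a triangular face belonging to exactly one tetrahedron.
#'
#' @param mesh an `abl_mesh` (or a bare list with `$tets`)
#' @return integer b x 3 matrix of vertex indices
#' @export
boundary_facets <- function(mesh) {
  m <- nrow(mesh$tets)
  allf <- matrix(0L, 4 * m, 3)
  for (k in 1:4)
    allf[seq.int(k, by = 4, length.out = m), ] <-
      mesh$tets[, TET_FACES[k, ], drop = FALSE]
  keys <- facet_key(allf)
  dup <- unique(keys[duplicated(keys)])
  allf[!(keys %in% dup), , drop = FALSE]
}

#' Validate mesh tagging and boundary coverage
#'
#' Checks that every boundary facet of the mesh carries a surface tag, that
#' port/exterior facets are true boundary facets, and that region tags cover
#' all cells (guaranteed by construction, re-checked here for loaded meshes).
#'
#' @param mesh an `abl_mesh`
#' @return invisibly TRUE; stops with a tagging error otherwise
#' @export
validate_mesh <- function(mesh) {
  bf <- boundary_facets(mesh)
  bkey <- facet_key(bf)
  fkey <- facet_key(mesh$facets)
  missing <- setdiff(bkey, fkey)
  if (length(missing))
    stop("tagging error: ", length(missing),
         " boundary facet(s) carry no surface tag (first: ", missing[1], ")")
  ext <- mesh$facet_tag %in% c("port", "exterior")
  notb <- which(ext & !(fkey %in% bkey))
  if (length(notb))
    stop("tagging error: port/exterior facet ", notb[1],
         " is not a boundary facet")
  if (anyNA(mesh$region))
    stop("tagging error: untagged cell present")
  invisible(TRUE)
}

#' Outward unit normals and areas of tagged facets
#'
#' Normals are oriented away from the owning tetrahedron's opposite vertex,
#' i.e. outward for boundary facets.
#'
#' @param mesh an `abl_mesh`
#' @param which integer facet indices (default all)
#' @return list with `normal` (k x 3), `area` (k)
#' @export
facet_geometry <- function(mesh, which = seq_len(nrow(mesh$facets))) {
  f <- mesh$facets[which, , drop = FALSE]
  own <- mesh$facet_cell[which]
  p1 <- mesh$vertices[f[, 1], , drop = FALSE]
  e1 <- mesh$vertices[f[, 2], , drop = FALSE] - p1
  e2 <- mesh$vertices[f[, 3], , drop = FALSE] - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(n^2)) / 2
  n <- n / (2 * area)
  # flip toward outward: away from the tet vertex not on the facet
  tv <- mesh$tets[own, , drop = FALSE]
  opp <- integer(length(own))
  for (k in 1:4) {
    cand <- tv[, k]
    isopp <- cand != f[, 1] & cand != f[, 2] & cand != f[, 3] & opp == 0L
    opp[isopp] <- cand[isopp]
  }
  d <- mesh$vertices[opp, , drop = FALSE] - p1
  s <- sign(rowSums(d * n))
  n <- n * (-s)
  list(normal = n, area = area)
}

#' Total mesh volume by region
#' @param mesh an `abl_mesh`
#' @param region optional region name(s); default all cells
#' @return volume in m^3
#' @export
mesh_volume <- function(mesh, region = NULL) {
  if (is.null(region)) return(sum(mesh$volumes))
  sum(mesh$volumes[mesh$region %in% region])
}
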