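#' Geometry specification for the liver/tumor/antenna phantom
#'
#' The liver is a cylinder (default radius 4 cm, height 8 cm, centred at the
#' origin), the tumor a concentric sphere (default radius 2 cm). The
#' single-slot coaxial antenna is inserted vertically through the bottom
#' face of the cylinder, so its shaft crosses the tumor and its tip sits at
#' the scheduled position (placing the tip a little past the tumor centre
#' lets the heated oval along slot and shaft cover the tumor chord, which
#' is what makes near-complete kills of a 4 cm tumor geometrically
#' possible at all). Only the 1 mm slot
#' height is fixed by the treatment design; the cross-section radii default
#' to the usual single-slot coax build (inner conductor 0.135 mm, dielectric
#' 0.47 mm, catheter 0.895 mm) and are configurable.
#'
#' Mesh sizing: `h_fine` is the lateral target size at the antenna axis,
#' `h_coarse` the far-field cap, `h_fine_z` the vertical size over the active
#' band around tip and slot, `growth` the geometric expansion ratio. `scale`
#' multiplies all of them, so one knob shrinks the whole problem for tests.
#'
#' @param liver_radius,liver_height,tumor_radius,tumor_center geometry (m)
#' @param r_inner,r_diel,r_cath antenna cross-section radii (m)
#' @param slot_offset distance from the antenna tip to the near slot edge
#'   (m), on the feed side; single-slot designs place the radiating slot
#'   within a few millimetres of the shorted tip
#' @param slot_height slot height (m), 1 mm in the treatment design
#' @param h_fine,h_coarse,h_fine_z,h_coarse_z,growth,scale mesh sizing
#'   controls; `h_coarse_z` caps the vertical cell size along the antenna
#'   shaft so the deposited power is not smeared over tall far-field cells
#' @return object of class `abl_geometry_spec`
#' @export
geometry_spec <- function(liver_radius = 0.04, liver_height = 0.08,
                          tumor_radius = 0.02, tumor_center = c(0, 0, 0),
                          r_inner = 0.135e-3, r_diel = 0.47e-3,
                          r_cath = 0.895e-3,
                          slot_offset = 2.5e-3, slot_height = 1e-3,
                          h_fine = 0.6e-3, h_coarse = 9e-3,
                          h_fine_z = 2.0e-3, h_coarse_z = 5.5e-3,
                          growth = 1.9, scale = 1) {
  if (tumor_radius >= liver_radius)
    stop("geometry error: tumor sphere does not fit strictly inside the liver cylinder")
  rxy <- sqrt(sum(tumor_center[1:2]^2))
  if (rxy + tumor_radius >= liver_radius ||
      abs(tumor_center[3]) + tumor_radius >= liver_height / 2)
    stop("geometry error: tumor sphere does not fit strictly inside the liver cylinder")
  if (!(r_inner < r_diel && r_diel < r_cath))
    stop("geometry error: antenna radii must satisfy r_inner < r_diel < r_cath")
  structure(list(liver_radius = liver_radius, liver_height = liver_height,
                 tumor_radius = tumor_radius, tumor_center = tumor_center,
                 r_inner = r_inner, r_diel = r_diel, r_cath = r_cath,
                 slot_offset = slot_offset, slot_height = slot_height,
                 h_fine = h_fine, h_coarse = h_coarse, h_fine_z = h_fine_z,
                 h_coarse_z = h_coarse_z, growth = growth, scale = scale),
            class = "abl_geometry_spec")
}

#' Analytic phantom volumes
#'
#' @param spec an `abl_geometry_spec`
#' @return list with `liver_cm3` (cylinder) and `tumor_cm3` (sphere)
#' @export
analytic_volumes <- function(spec) {
  list(liver_cm3 = pi * spec$liver_radius^2 * spec$liver_height * 1e6,
       tumor_cm3 = 4 / 3 * pi * spec$tumor_radius^3 * 1e6)
}

# geometric spacing run: starts at h0, grows by g, capped at hmax, rescaled to
# sum exactly to L
geom_spacing <- function(L, h0, hmax, g) {
  if (L <= h0) return(L)
  s <- numeric(0); h <- h0; total <- 0
  while (total < L) {
    s <- c(s, h); total <- total + h; h <- min(h * g, hmax)
  }
  s * (L / total)
}

# 1-D graded axis on [lo, hi] with fine spacing h0 at each cluster point
graded_axis <- function(lo, hi, clusters, h0, hmax, g) {
  clusters <- sort(unique(pmin(pmax(clusters, lo), hi)))
  if (length(clusters) > 1)
    clusters <- clusters[c(TRUE, diff(clusters) > h0 / 2)]
  if (!length(clusters)) {
    n <- max(1L, ceiling((hi - lo) / hmax))
    return(seq(lo, hi, length.out = n + 1))
  }
  brks <- unique(c(lo, clusters, hi))
  iscl <- brks %in% clusters
  pts <- lo
  for (i in seq_len(length(brks) - 1)) {
    L <- brks[i + 1] - brks[i]
    if (L <= 0) next
    lcl <- iscl[i]; rcl <- iscl[i + 1]
    if (lcl && rcl) {
      sp <- c(geom_spacing(L / 2, h0, hmax, g),
              rev(geom_spacing(L / 2, h0, hmax, g)))
    } else if (lcl) {
      sp <- geom_spacing(L, h0, hmax, g)
    } else if (rcl) {
      sp <- rev(geom_spacing(L, h0, hmax, g))
    } else {
      n <- max(1L, ceiling(L / hmax))
      sp <- rep(L / n, n)
    }
    pts <- c(pts, brks[i] + cumsum(sp))
  }
  pts[length(pts)] <- hi
  pts
}

# elliptical square->disk map on [-1,1]^2 (times radius R); boundary |u|=1 or
# |v|=1 lands exactly on the circle of radius R
disk_map <- function(u, v, R) {
  cbind(R * u * sqrt(pmax(0, 1 - v^2 / 2)),
        R * v * sqrt(pmax(0, 1 - u^2 / 2)))
}

# inverse of disk_map by fixed-point iteration
disk_map_inverse <- function(x, y, R) {
  u <- x / R; v <- y / R
  for (i in 1:100) {
    u <- (x / R) / sqrt(1 - v^2 / 2)
    v <- (y / R) / sqrt(1 - u^2 / 2)
  }
  c(u, v)
}

# Kuhn/Freudenthal subdivision: 6 tetrahedra per hexahedron, conforming on
# structured grids. perms of axis insertion order; corners indexed by
# (dx, dy, dz) offsets.
KUHN_PERMS <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

structured_tets <- function(nx, ny, nz) {
  vid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * (nx * ny)
  i <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  j <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  k <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  corner <- function(dx, dy, dz) vid(i + dx, j + dy, k + dz)
  tets <- vector("list", 6)
  for (p in 1:6) {
    perm <- KUHN_PERMS[p, ]
    off <- matrix(0L, 4, 3)
    for (s in 1:3) off[s + 1, ] <- off[s, ] + as.integer(perm[s] == 1:3)
    tets[[p]] <- cbind(corner(off[1, 1], off[1, 2], off[1, 3]),
                       corner(off[2, 1], off[2, 2], off[2, 3]),
                       corner(off[3, 1], off[3, 2], off[3, 3]),
                       corner(off[4, 1], off[4, 2], off[4, 3]))
  }
  do.call(rbind, tets)
}

#' Build the graded liver/tumor/antenna phantom mesh
#'
#' Builds a structured graded tetrahedral mesh of the liver cylinder whose
#' lateral boundary vertices lie exactly on the cylinder surface (elliptical
#' square-to-disk mapping of a graded tensor grid), with the grid clustered
#' laterally around every antenna axis in `clusters` and vertically around
#' the tip/slot band, then tags regions and surfaces for the antenna at
#' `position`.
#'
#' @param spec an `abl_geometry_spec`
#' @param position antenna tip position, length-3 numeric (m)
#' @param clusters optional matrix of positions (rows) the mesh should also
#'   resolve (e.g. all scheduled positions of a protocol); defaults to
#'   `position`
#' @param scale optional override of `spec$scale`
#' @return an `abl_mesh`
#' @export
build_phantom <- function(spec, position, clusters = NULL, scale = NULL) {
  if (is.null(scale)) scale <- spec$scale
  position <- as.numeric(position)
  if (is.null(clusters)) clusters <- matrix(position, 1)
  clusters <- as.matrix(clusters)
  if (ncol(clusters) != 3) stop("clusters must be an n x 3 matrix")
  check_antenna_position(spec, position)
  for (i in seq_len(nrow(clusters))) check_antenna_position(spec, clusters[i, ])

  R <- spec$liver_radius; H <- spec$liver_height
  h0 <- spec$h_fine * scale; hmax <- spec$h_coarse * scale
  h0z <- spec$h_fine_z * scale; hmaxz <- spec$h_coarse_z * scale
  g <- spec$growth

  uv <- t(apply(clusters, 1, function(p) disk_map_inverse(p[1], p[2], R)))
  u_ax <- graded_axis(-1, 1, uv[, 1], h0 / R, hmax / R, g)
  v_ax <- graded_axis(-1, 1, uv[, 2], h0 / R, hmax / R, g)

  zlo <- -H / 2; zhi <- H / 2
  # the antenna enters through the bottom face with its tip at the
  # scheduled position, so the shaft (and its heated tail) spans the tumor
  # chord; the band grid is anchored at the tip so the tip plane and the
  # conducting wire lie exactly on the grid
  ztip <- min(clusters[, 3])
  band_lo <- max(zlo + 1e-9,
                 ztip - (spec$slot_offset + spec$slot_height + 6e-3))
  band_hi <- min(zhi, max(clusters[, 3]) + 4e-3)
  hstep <- min(h0z, (ztip - band_lo) / max(1, round((ztip - band_lo) / h0z)))
  z_dn <- rev(seq(ztip, band_lo + 1e-12, by = -hstep))
  if (z_dn[1] - band_lo > 1e-9) z_dn <- c(band_lo, z_dn)
  n_up <- max(1L, ceiling((band_hi - ztip) / hstep))
  z_up <- ztip + hstep * seq_len(n_up)
  z_ax <- c(z_dn, z_up)
  lo0 <- z_ax[1]; hi0 <- z_ax[length(z_ax)]
  if (lo0 - zlo > 1e-12)   # shaft side: cap the vertical growth
    z_ax <- c(lo0 - rev(cumsum(geom_spacing(lo0 - zlo, h0z, hmaxz, g))),
              z_ax)
  if (zhi - hi0 > 1e-12)
    z_ax <- c(z_ax, hi0 + cumsum(geom_spacing(zhi - hi0, h0z, hmax, g)))
  z_ax[1] <- zlo; z_ax[length(z_ax)] <- zhi

  nx <- length(u_ax); ny <- length(v_ax); nz <- length(z_ax)
  uu <- rep(u_ax, times = ny); vv <- rep(v_ax, each = nx)
  xy <- disk_map(uu, vv, R)
  verts <- cbind(rep(xy[, 1], times = nz), rep(xy[, 2], times = nz),
                 rep(z_ax, each = nx * ny))
  tets <- structured_tets(nx, ny, nz)
  tag_phantom(verts, tets, spec, position, scale)
}

# Antenna features narrower than the local mesh are inflated to about one
# cell so the core/conductor/slot/catheter topology survives coarsening.
effective_antenna <- function(spec, scale) {
  h0 <- spec$h_fine * scale
  h0z <- spec$h_fine_z * scale
  r_d <- max(spec$r_diel, 1.3 * h0)
  list(r_diel = r_d,
       r_cath = max(spec$r_cath, r_d + h0),
       slot_height = max(spec$slot_height, 1.2 * h0z))
}

check_antenna_position <- function(spec, position) {
  d <- sqrt(sum((as.numeric(position) - spec$tumor_center)^2))
  if (d >= spec$tumor_radius)
    stop("geometry error: antenna tip at (",
         paste(signif(position * 1e3, 4), collapse = ", "),
         ") mm lies outside the tumor")
  invisible(TRUE)
}

# region + surface tagging for a given antenna position; returns abl_mesh
tag_phantom <- function(verts, tets, spec, position, scale) {
  cen <- (verts[tets[, 1], , drop = FALSE] + verts[tets[, 2], , drop = FALSE] +
          verts[tets[, 3], , drop = FALSE] + verts[tets[, 4], , drop = FALSE]) / 4
  region <- phantom_region_of(cen, spec, position, scale)
  mesh <- abl_mesh(verts, tets, region)
  mesh <- retag_surfaces(mesh, spec, position, scale)
  mesh$phantom <- list(spec = spec, position = position, scale = scale)
  mesh
}

phantom_region_of <- function(p, spec, position, scale) {
  eff <- effective_antenna(spec, scale)
  xa <- position[1]; ya <- position[2]; ztip <- position[3]
  bottom <- -spec$liver_height / 2
  slot_hi <- ztip - spec$slot_offset
  slot_lo <- slot_hi - eff$slot_height
  rxy <- sqrt((p[, 1] - xa)^2 + (p[, 2] - ya)^2)
  dtum <- sqrt((p[, 1] - spec$tumor_center[1])^2 +
               (p[, 2] - spec$tumor_center[2])^2 +
               (p[, 3] - spec$tumor_center[3])^2)
  region <- ifelse(dtum < spec$tumor_radius, "tumor", "liver")
  in_ant <- rxy < eff$r_cath & p[, 3] < ztip & p[, 3] >= bottom
  core <- in_ant & rxy < eff$r_diel
  annul <- in_ant & !core
  region[core] <- "dielectric"
  region[annul & p[, 3] > slot_lo & p[, 3] <= slot_hi] <- "slot"
  region[annul & !(p[, 3] > slot_lo & p[, 3] <= slot_hi)] <- "catheter"
  region
}

#' Re-tag the phantom for a new antenna position
#'
#' Region tags and pec/port surface tags follow the antenna; the mesh
#' geometry is unchanged, so nodal fields carry over without interpolation.
#' The previous antenna track reverts to tissue.
#'
#' @param mesh an `abl_mesh` produced by [build_phantom()]
#' @param spec the `abl_geometry_spec` the mesh was built from
#' @param position new antenna tip position (m)
#' @return an `abl_mesh`
#' @export
retag_antenna <- function(mesh, spec, position) {
  check_antenna_position(spec, position)
  scale <- if (!is.null(mesh$phantom)) mesh$phantom$scale else 1
  cen <- (mesh$vertices[mesh$tets[, 1], , drop = FALSE] +
          mesh$vertices[mesh$tets[, 2], , drop = FALSE] +
          mesh$vertices[mesh$tets[, 3], , drop = FALSE] +
          mesh$vertices[mesh$tets[, 4], , drop = FALSE]) / 4
  mesh$region <- factor(phantom_region_of(cen, spec, position, scale),
                        levels = REGION_TAGS)
  out <- retag_surfaces(mesh, spec, position, scale)
  out$phantom <- list(spec = spec, position = position, scale = scale)
  out
}

# boundary facets: port above the coax core, exterior elsewhere; interior
# pec facets: dielectric core against catheter or tissue (the outer conductor
# sheet and the shorted tip), but not against the slot ring
retag_surfaces <- function(mesh, spec, position, scale = 1) {
  bf <- boundary_facets(mesh)
  cen <- (mesh$vertices[bf[, 1], , drop = FALSE] +
          mesh$vertices[bf[, 2], , drop = FALSE] +
          mesh$vertices[bf[, 3], , drop = FALSE]) / 3
  bottom <- -spec$liver_height / 2
  # the port is the feed-side cap of the coax core: boundary facets on the
  # bottom plane owned by a dielectric-tagged cell (consistent with the
  # conductor sheet, which follows the same region interfaces)
  own <- facet_owner_cells(list(tets = mesh$tets, facets = bf))
  isport <- abs(cen[, 3] - bottom) < 1e-9 &
            as.character(mesh$region)[own] == "dielectric"
  btag <- ifelse(isport, "port", "exterior")

  pec <- conductor_facets(mesh)
  mesh2 <- abl_mesh(mesh$vertices, mesh$tets, as.character(mesh$region),
                    facets = rbind(bf, pec),
                    facet_tag = c(btag, rep("pec", nrow(pec))),
                    reorder = FALSE)
  # inner conductor: a perfectly conducting wire of mesh edges along the
  # antenna axis (the axis is a grid line of the phantom), from the input
  # port down to the shorted tip; without it the coax would be a hollow
  # guide far below cutoff and could not transport power to the slot
  onaxis <- abs(mesh2$vertices[, 1] - position[1]) < 1e-7 &
            abs(mesh2$vertices[, 2] - position[2]) < 1e-7 &
            mesh2$vertices[, 3] <= position[3] + 1e-9
  mesh2$pec_wire <- which(onaxis)
  mesh2
}

# interior facets separating the dielectric core from catheter/tissue
conductor_facets <- function(mesh) {
  m <- nrow(mesh$tets)
  allf <- matrix(0L, 4 * m, 3)
  for (k in 1:4)
    allf[seq.int(k, by = 4, length.out = m), ] <-
      mesh$tets[, TET_FACES[k, ], drop = FALSE]
  keys <- facet_key(allf)
  owner_region <- as.character(mesh$region)[rep(seq_len(m), each = 4)]
  ord <- order(keys)
  keys <- keys[ord]; owner_region <- owner_region[ord]
  allf <- allf[ord, , drop = FALSE]
  n <- length(keys)
  shared <- keys[-n] == keys[-1]
  r1 <- owner_region[-n][shared]; r2 <- owner_region[-1][shared]
  ispec <- (r1 == "dielectric" & r2 %in% c("catheter", "liver", "tumor")) |
           (r2 == "dielectric" & r1 %in% c("catheter", "liver", "tumor"))
  allf[-n, , drop = FALSE][shared, , drop = FALSE][ispec, , drop = FALSE]
}

#' Two glued tetrahedra fixture
#'
#' Five vertices, two tetrahedra sharing a face, all liver, six boundary
#' facets tagged as requested.
#'
#' @param tag surface tag for all boundary facets
#' @return an `abl_mesh`
#' @export
fixture_two_tets <- function(tag = "exterior") {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  tets <- rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L))
  mesh <- abl_mesh(v, tets, c("liver", "liver"))
  bf <- boundary_facets(mesh)
  abl_mesh(v, tets, c("liver", "liver"), facets = bf,
           facet_tag = rep(tag, nrow(bf)))
}

#' Structured unit-cube fixture
#'
#' `n` hexahedra per side, 6 tetrahedra each, all liver; all boundary facets
#' carry `tag` (use `pec` for the cavity eigenproblem, `exterior` for
#' manufactured-solution runs with absorbing data).
#'
#' @param n subdivisions per side
#' @param tag surface tag for the whole boundary
#' @param side cube side length (m)
#' @return an `abl_mesh`
#' @export
fixture_cube <- function(n = 3, tag = "pec", side = 1) {
  ax <- seq(0, side, length.out = n + 1)
  nx <- n + 1L
  verts <- cbind(rep(ax, times = nx * nx),
                 rep(rep(ax, each = nx), times = nx),
                 rep(ax, each = nx * nx))
  tets <- structured_tets(nx, nx, nx)
  mesh <- abl_mesh(verts, tets, rep("liver", nrow(tets)))
  bf <- boundary_facets(mesh)
  abl_mesh(verts, tets, rep("liver", nrow(tets)), facets = bf,
           facet_tag = rep(tag, nrow(bf)))
}
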