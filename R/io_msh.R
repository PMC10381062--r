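#' Load a tagged tetrahedral mesh from a Gmsh MSH file
#'
#' Accepts ASCII MSH v2.2 and v4.1. Region and surface tags are resolved by
#' physical-group *name* (liver, tumor, dielectric, catheter, slot for
#' volumes; pec, port, exterior for surfaces), never by numeric id.
#' Tetrahedra are reordered to positive volume; the mesh is validated
#' (boundary coverage, degenerate cells).
#'
#' @param path MSH file path
#' @return an `abl_mesh`
#' @export
load_mesh <- function(path) {
  lines <- readLines(path)
  ver <- msh_section(lines, "MeshFormat")[1]
  vnum <- as.numeric(strsplit(trimws(ver), "\\s+")[[1]][1])
  parsed <- if (vnum >= 4) parse_msh41(lines) else parse_msh22(lines)

  phys <- parsed$phys # data.frame: dim, id, name
  vol_ids <- phys$id[phys$name %in% REGION_TAGS & phys$dim == 3]
  sur_ids <- phys$id[phys$name %in% SURFACE_TAGS & phys$dim == 2]

  tets <- parsed$tets; tet_phys <- parsed$tet_phys
  tris <- parsed$tris; tri_phys <- parsed$tri_phys
  if (!nrow(tets)) stop("tagging error: no tetrahedra in mesh")
  reg_of <- function(ids) {
    idx <- match(ids, phys$id)
    if (anyNA(idx))
      stop("tagging error: element references physical group id ",
           ids[which(is.na(idx))[1]], " with no physical name")
    nm <- phys$name[idx]
    bad <- setdiff(unique(nm[!(nm %in% c(REGION_TAGS, SURFACE_TAGS))]), NULL)
    if (length(bad))
      stop("tagging error: unknown physical group name '", bad[1], "'")
    nm
  }
  region <- reg_of(tet_phys)
  ftag <- if (nrow(tris)) reg_of(tri_phys) else character(0)
  mesh <- abl_mesh(parsed$vertices, tets, region, facets = tris,
                   facet_tag = ftag)
  validate_mesh(mesh)
  mesh
}

msh_section <- function(lines, name) {
  i0 <- which(lines == paste0("$", name))
  i1 <- which(lines == paste0("$End", name))
  if (!length(i0) || !length(i1))
    stop("MSH file lacks a $", name, " section")
  lines[(i0[1] + 1):(i1[1] - 1)]
}

msh_phys <- function(lines) {
  if (!any(lines == "$PhysicalNames"))
    stop("tagging error: MSH file has no $PhysicalNames section")
  pn <- msh_section(lines, "PhysicalNames")
  n <- as.integer(pn[1])
  rows <- strsplit(trimws(pn[1 + seq_len(n)]), "\\s+")
  data.frame(dim = vapply(rows, function(r) as.integer(r[1]), 1L),
             id = vapply(rows, function(r) as.integer(r[2]), 1L),
             name = vapply(rows, function(r)
               gsub('"', "", paste(r[-(1:2)], collapse = " ")), ""))
}

parse_msh22 <- function(lines) {
  phys <- msh_phys(lines)
  nd <- msh_section(lines, "Nodes")
  nn <- as.integer(nd[1])
  nod <- matrix(scan(text = nd[1 + seq_len(nn)], quiet = TRUE), nn, 4,
                byrow = TRUE)
  ids <- as.integer(nod[, 1])
  vertices <- matrix(0, max(ids), 3)
  vertices[ids, ] <- nod[, 2:4]
  el <- msh_section(lines, "Elements")
  ne <- as.integer(el[1])
  rows <- strsplit(trimws(el[1 + seq_len(ne)]), "\\s+")
  tets <- list(); tp <- integer(0); tris <- list(); rp <- integer(0)
  for (r in rows) {
    v <- as.integer(r)
    type <- v[2]; ntags <- v[3]
    physid <- if (ntags >= 1) v[4] else NA_integer_
    nodes <- v[(4 + ntags):length(v)]
    if (type == 4L) { tets[[length(tets) + 1]] <- nodes; tp <- c(tp, physid) }
    if (type == 2L) { tris[[length(tris) + 1]] <- nodes; rp <- c(rp, physid) }
  }
  if (anyNA(tp) || anyNA(rp))
    stop("tagging error: element without a physical tag")
  list(phys = phys, vertices = vertices,
       tets = do.call(rbind, tets) %||% matrix(integer(0), 0, 4),
       tet_phys = tp,
       tris = do.call(rbind, tris) %||% matrix(integer(0), 0, 3),
       tri_phys = rp)
}

parse_msh41 <- function(lines) {
  phys <- msh_phys(lines)
  # $Entities: map (dim, entityTag) -> physical id (first listed)
  ent <- msh_section(lines, "Entities")
  counts <- as.integer(strsplit(trimws(ent[1]), "\\s+")[[1]])
  ent_map <- list()
  row <- 2
  for (dim in 0:3) {
    for (k in seq_len(counts[dim + 1])) {
      v <- as.numeric(strsplit(trimws(ent[row]), "\\s+")[[1]])
      tag <- as.integer(v[1])
      nbox <- if (dim == 0) 3 else 6
      nphys <- as.integer(v[1 + nbox + 1])
      pid <- if (nphys >= 1) as.integer(v[1 + nbox + 2]) else NA_integer_
      ent_map[[paste(dim, tag)]] <- pid
      row <- row + 1
    }
  }
  nd <- msh_section(lines, "Nodes")
  hdr <- as.numeric(strsplit(trimws(nd[1]), "\\s+")[[1]])
  nblocks <- hdr[1]
  row <- 2
  ids <- integer(0); coords <- list()
  for (b in seq_len(nblocks)) {
    bh <- as.numeric(strsplit(trimws(nd[row]), "\\s+")[[1]])
    nn <- bh[4]
    if (nn > 0) {
      bid <- as.integer(nd[row + seq_len(nn)])
      cc <- matrix(scan(text = nd[row + nn + seq_len(nn)], quiet = TRUE),
                   nn, 3, byrow = TRUE)
      ids <- c(ids, bid); coords[[b]] <- cc
    }
    row <- row + 1 + 2 * nn
  }
  cc <- do.call(rbind, coords)
  vertices <- matrix(0, max(ids), 3)
  vertices[ids, ] <- cc
  el <- msh_section(lines, "Elements")
  hdr <- as.numeric(strsplit(trimws(el[1]), "\\s+")[[1]])
  nblocks <- hdr[1]
  row <- 2
  tets <- list(); tp <- integer(0); tris <- list(); rp <- integer(0)
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(trimws(el[row]), "\\s+")[[1]])
    dim <- bh[1]; etag <- bh[2]; etype <- bh[3]; ne <- bh[4]
    pid <- ent_map[[paste(dim, etag)]]
    if (ne > 0) {
      dat <- matrix(scan(text = el[row + seq_len(ne)], quiet = TRUE),
                    ne, byrow = TRUE,
                    ncol = length(strsplit(trimws(el[row + 1]),
                                           "\\s+")[[1]]))
      if (etype == 4L) {
        if (is.na(pid) || is.null(pid))
          stop("tagging error: volume entity ", etag, " has no physical group")
        tets[[length(tets) + 1]] <- dat[, -1, drop = FALSE]
        tp <- c(tp, rep(pid, ne))
      }
      if (etype == 2L) {
        if (is.na(pid) || is.null(pid))
          stop("tagging error: surface entity ", etag, " has no physical group")
        tris[[length(tris) + 1]] <- dat[, -1, drop = FALSE]
        rp <- c(rp, rep(pid, ne))
      }
    }
    row <- row + 1 + ne
  }
  list(phys = phys, vertices = vertices,
       tets = do.call(rbind, tets) %||% matrix(integer(0), 0, 4),
       tet_phys = tp,
       tris = do.call(rbind, tris) %||% matrix(integer(0), 0, 3),
       tri_phys = rp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mesh to Gmsh MSH v2.2 (ASCII)
#'
#' Physical groups are written per region/surface name with stable numeric
#' ids (volumes 1..5, surfaces 11..13).
#'
#' @param mesh an `abl_mesh`
#' @param path output file
#' @export
write_msh <- function(mesh, path) {
  vol_id <- stats::setNames(1:5, REGION_TAGS)
  sur_id <- stats::setNames(11:13, SURFACE_TAGS)
  used_r <- REGION_TAGS[REGION_TAGS %in% mesh$region]
  used_s <- SURFACE_TAGS[SURFACE_TAGS %in% mesh$facet_tag]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", length(used_r) + length(used_s)), con)
  for (s in used_s) writeLines(sprintf('2 %d "%s"', sur_id[s], s), con)
  for (r in used_r) writeLines(sprintf('3 %d "%s"', vol_id[r], r), con)
  writeLines("$EndPhysicalNames", con)
  nv <- nrow(mesh$vertices)
  writeLines(c("$Nodes", nv), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nv),
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines("$EndNodes", con)
  nf <- nrow(mesh$facets); nt <- nrow(mesh$tets)
  writeLines(c("$Elements", nf + nt), con)
  if (nf)
    writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(nf),
                       sur_id[as.character(mesh$facet_tag)],
                       sur_id[as.character(mesh$facet_tag)],
                       mesh$facets[, 1], mesh$facets[, 2], mesh$facets[, 3]),
               con)
  if (nt)
    writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", nf + seq_len(nt),
                       vol_id[as.character(mesh$region)],
                       vol_id[as.character(mesh$region)],
                       mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                       mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}
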