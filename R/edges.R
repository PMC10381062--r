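#' Globally oriented edge structure for edge elements
#'
#' Tangential degrees of freedom live on mesh edges. Each unique edge is
#' stored once with a deterministic global direction (from lower to higher
#' vertex index); every element maps its six local edges to global edge
#' indices with an orientation sign that is +1 exactly when the local edge
#' direction agrees with the global one. This makes the assembled basis
#' tangentially continuous regardless of element ordering.
#'
#' Local edges are numbered in the fixed order
#' (1,2), (1,3), (1,4), (2,3), (2,4), (3,4) of local vertex pairs.
#'
#' @param mesh an `abl_mesh`
#' @return list of class `abl_edges` with `edges` (E x 2, ascending vertex
#'   indices), `tet_edges` (m x 6 global indices), `tet_signs` (m x 6, +-1),
#'   `surface_edges` (named list of global edge index vectors per surface
#'   tag), `n_edges`
#' @export
build_edge_structure <- function(mesh) {
  LOCAL_EDGES <- local_edge_pairs()
  m <- nrow(mesh$tets)
  nv <- nrow(mesh$vertices)
  a <- matrix(0L, m, 6); b <- matrix(0L, m, 6)
  for (k in 1:6) {
    a[, k] <- mesh$tets[, LOCAL_EDGES[k, 1]]
    b[, k] <- mesh$tets[, LOCAL_EDGES[k, 2]]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- as.numeric(lo) * (nv + 1) + as.numeric(hi)
  ukey <- sort(unique(key))
  idx <- matrix(match(key, ukey), m, 6)
  edges <- cbind(as.integer(ukey %/% (nv + 1)), as.integer(ukey %% (nv + 1)))
  signs <- matrix(ifelse(a < b, 1L, -1L), m, 6)

  surface_edges <- lapply(SURFACE_TAGS, function(tag) {
    f <- mesh$facets[mesh$facet_tag == tag, , drop = FALSE]
    if (!nrow(f)) return(integer(0))
    fa <- c(f[, 1], f[, 1], f[, 2]); fb <- c(f[, 2], f[, 3], f[, 3])
    k <- pmin(fa, fb) * as.numeric(nv + 1) + pmax(fa, fb)
    sort(unique(match(k, ukey)))
  })
  names(surface_edges) <- SURFACE_TAGS
  if (!is.null(mesh$pec_wire) && length(mesh$pec_wire) > 1) {
    # conducting wire: every mesh edge with both endpoints on the wire
    onwire <- edges[, 1] %in% mesh$pec_wire & edges[, 2] %in% mesh$pec_wire
    surface_edges$pec <- sort(union(surface_edges$pec, which(onwire)))
  }

  structure(list(edges = edges, tet_edges = idx, tet_signs = signs,
                 surface_edges = surface_edges, n_edges = nrow(edges)),
            class = "abl_edges")
}

#' @export
print.abl_edges <- function(x, ...) {
  cat("<abl_edges> ", x$n_edges, " global edges over ",
      nrow(x$tet_edges), " tetrahedra\n", sep = "")
  invisible(x)
}

#' Local edge numbering of a tetrahedron
#' @return 6 x 2 matrix of local vertex pairs
#' @export
local_edge_pairs <- function() {
  rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
        c(2L, 3L), c(2L, 4L), c(3L, 4L))
}
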