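#' Write a mesh with fields to an ASCII VTU file
#'
#' Minimal XML UnstructuredGrid writer (tetrahedra, cell type 10) for
#' visualization in ParaView and friends.
#'
#' @param mesh an `abl_mesh`
#' @param path output file
#' @param point_data named list of nodal numeric vectors
#' @param cell_data named list of per-element numeric vectors
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  nv <- nrow(mesh$vertices); nc <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) paste(formatC(x, format = "g", digits = 9),
                           collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nc))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$vertices, 1, num), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$tets - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(num(seq_len(nc) * 4L), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(num(rep(10L, nc)), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <PointData>')
  for (nm in names(point_data)) {
    w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">',
              nm))
    writeLines(num(point_data[[nm]]), con)
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('      <CellData>')
  cell_data <- c(cell_data, list(region = as.integer(mesh$region)))
  for (nm in names(cell_data)) {
    w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">',
              nm))
    writeLines(num(as.numeric(cell_data[[nm]])), con)
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
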