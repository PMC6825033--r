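## Minimal ASCII VTK XML (.vtu) unstructured-grid writer for results
## inspection in ParaView, plus a .pvd collection for time series.

#' Write a mesh with attached fields as an ASCII .vtu file
#'
#' @param mesh A [pf_mesh()].
#' @param path Output file path (conventionally `.vtu`).
#' @param point_data Named list of per-node fields: numeric vectors (scalars)
#'   or N x dim matrices (vectors, padded to 3 components).
#' @param cell_data Named list of per-element fields: vectors or E x k
#'   matrices.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  N <- nrow(mesh$nodes); E <- nrow(mesh$elems)
  xyz <- cbind(mesh$nodes, matrix(0, N, 3 - mesh$dim))
  vtk_type <- if (mesh$etype == "quad4") 9L else 10L
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) paste(format(x, digits = 9, trim = TRUE), collapse = " ")
  da <- function(name, x, ncomp) {
    w(sprintf('      <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              name, ncomp))
    w("        ", num(t(x)))
    w("      </DataArray>")
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w("  <UnstructuredGrid>")
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', N, E))
  w("      <Points>")
  da("Points", xyz, 3L)
  w("      </Points>")
  w("      <Cells>")
  w('      <DataArray type="Int32" Name="connectivity" format="ascii">')
  w("        ", paste(t(mesh$elems) - 1L, collapse = " "))
  w("      </DataArray>")
  w('      <DataArray type="Int32" Name="offsets" format="ascii">')
  w("        ", paste(seq_len(E) * 4L, collapse = " "))
  w("      </DataArray>")
  w('      <DataArray type="UInt8" Name="types" format="ascii">')
  w("        ", paste(rep(vtk_type, E), collapse = " "))
  w("      </DataArray>")
  w("      </Cells>")
  if (length(point_data)) {
    w("      <PointData>")
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      if (is.matrix(x)) {
        x <- cbind(x, matrix(0, nrow(x), 3 - ncol(x)))
        da(nm, x, 3L)
      } else da(nm, x, 1L)
    }
    w("      </PointData>")
  }
  if (length(cell_data)) {
    w("      <CellData>")
    for (nm in names(cell_data)) {
      x <- cell_data[[nm]]
      if (is.matrix(x)) da(nm, x, ncol(x)) else da(nm, x, 1L)
    }
    w("      </CellData>")
  }
  w("    </Piece>")
  w("  </UnstructuredGrid>")
  w("</VTKFile>")
  invisible(path)
}

#' Write a ParaView collection (.pvd) for a VTK time series
#'
#' @param path Output `.pvd` path.
#' @param times Numeric time stamps.
#' @param files Corresponding `.vtu` file names (relative to the `.pvd`).
#' @return `path`, invisibly.
#' @export
write_pvd <- function(path, times, files) {
  stopifnot(length(times) == length(files))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0"?>', con)
  writeLines('<VTKFile type="Collection" version="0.1">', con)
  writeLines("  <Collection>", con)
  for (i in seq_along(times))
    writeLines(sprintf('    <DataSet timestep="%g" file="%s"/>',
                       times[i], files[i]), con)
  writeLines("  </Collection>", con)
  writeLines("</VTKFile>", con)
  invisible(path)
}

#' Per-element Cauchy stress components in cylindrical coordinates
#'
#' Rotates the per-element Cartesian Cauchy stresses returned by
#' [assemble_mechanics()] into the cylindrical basis at each element centroid,
#' returning the components relevant to dissection mechanics
#' (`sigma_tt` hoop, `sigma_rt` and `sigma_rz` in-plane shear, `sigma_rr`,
#' `sigma_zz`).
#'
#' @param mesh A tube [pf_mesh()].
#' @param cauchy E x 6 matrix of components (xx, yy, zz, xy, yz, xz), kPa.
#' @return A tibble with one row per element.
#' @export
cylindrical_stress <- function(mesh, cauchy) {
  cent <- element_centroids(mesh)
  th <- atan2(cent[, 2], cent[, 1])
  ct <- cos(th); st <- sin(th)
  sxx <- cauchy[, 1]; syy <- cauchy[, 2]; szz <- cauchy[, 3]
  sxy <- cauchy[, 4]; syz <- cauchy[, 5]; sxz <- cauchy[, 6]
  ## e_r = (ct, st, 0), e_t = (-st, ct, 0), e_z = (0, 0, 1)
  srr <- ct^2 * sxx + 2 * ct * st * sxy + st^2 * syy
  stt <- st^2 * sxx - 2 * ct * st * sxy + ct^2 * syy
  srt <- -ct * st * sxx + (ct^2 - st^2) * sxy + ct * st * syy
  srz <- ct * sxz + st * syz
  stz <- -st * sxz + ct * syz
  tibble::tibble(sigma_rr = srr, sigma_tt = stt, sigma_zz = szz,
                 sigma_rt = srt, sigma_rz = srz, sigma_tz = stz)
}
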