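# File I/O: VTU (ascii XML unstructured grid) mesh export/import, CSV
# field tables, and YAML run configurations.

vtk_cell_type <- function(k) c(`2` = 3L, `3` = 5L, `4` = 10L)[[as.character(k)]]

#' Write a mesh with attached fields to an ASCII VTU file
#'
#' Point-data arrays are written for every supplied per-node field (and,
#' when present on the mesh, \code{fact}, \code{fpas}, region/layer codes,
#' transmural coordinate); the fiber field is written as cell data.
#'
#' @param mesh an \code{sw_mesh}.
#' @param file output path.
#' @param point_data named list of per-node numeric fields.
#' @param cell_data named list of per-element numeric fields.
#' @return the file path, invisibly.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems); k <- ncol(mesh$elems)
  num <- function(x, digits = 9) {
    paste(formatC(x, digits = digits, format = "g"), collapse = " ")
  }
  pd <- point_data
  if (!is.null(mesh$fact)) pd$fact <- mesh$fact
  if (!is.null(mesh$fpas)) pd$fpas <- mesh$fpas
  if (!is.null(mesh$transmural)) pd$transmural <- mesh$transmural
  if (!is.null(mesh$region))
    pd$region_code <- match(mesh$region, c("remote", "structural_bz", "core")) - 1
  if (!is.null(mesh$layer))
    pd$layer_code <- match(mesh$layer, c("endo", "sub_endo", "mid", "epi")) - 1
  cd <- cell_data
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste0("          ", apply(mesh$nodes, 1, num)),
    '        </DataArray>',
    '      </Points>',
    '      <Cells>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste0("          ", apply(mesh$elems - 1L, 1, paste, collapse = " ")),
    '        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste0("          ", paste(seq_len(m) * k, collapse = " ")),
    '        </DataArray>',
    '        <DataArray type="UInt8" Name="types" format="ascii">',
    paste0("          ", paste(rep(vtk_cell_type(k), m), collapse = " ")),
    '        </DataArray>',
    '      </Cells>')
  if (length(pd)) {
    lines <- c(lines, '      <PointData>')
    for (nm in names(pd))
      lines <- c(lines,
        sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm),
        paste0("          ", num(as.numeric(pd[[nm]]))),
        '        </DataArray>')
    lines <- c(lines, '      </PointData>')
  }
  if (!is.null(mesh$fibers)) cd$fiber <- mesh$fibers
  if (length(cd)) {
    lines <- c(lines, '      <CellData>')
    for (nm in names(cd)) {
      v <- cd[[nm]]
      ncomp <- if (is.matrix(v)) ncol(v) else 1L
      body <- if (is.matrix(v)) apply(v, 1, num) else num(as.numeric(v))
      lines <- c(lines,
        sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, ncomp),
        paste0("          ", body),
        '        </DataArray>')
    }
    lines <- c(lines, '      </CellData>')
  }
  lines <- c(lines, '    </Piece>', '  </UnstructuredGrid>', '</VTKFile>')
  writeLines(lines, file)
  invisible(file)
}

#' Read an ASCII VTU file written by \code{\link{write_vtu}}
#'
#' @param file path to the VTU file.
#' @return an \code{sw_mesh} with point-data fields re-attached
#'   (\code{fact}, \code{fpas}, labels) and other arrays under
#'   \code{$point_data}.
#' @export
read_vtu <- function(file) {
  doc <- xml2::read_xml(file)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  getv <- function(xpath) {
    nd <- xml2::xml_find_first(piece, xpath)
    as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
  }
  pts <- matrix(getv(".//Points/DataArray"), ncol = 3, byrow = TRUE)
  conn <- getv(".//Cells/DataArray[@Name='connectivity']")
  offs <- getv(".//Cells/DataArray[@Name='offsets']")
  k <- offs[1]
  elems <- matrix(as.integer(conn) + 1L, ncol = k, byrow = TRUE)
  mesh <- sw_mesh(pts, elems)
  arrs <- xml2::xml_find_all(piece, ".//PointData/DataArray")
  pd <- list()
  for (a in arrs) {
    nm <- xml2::xml_attr(a, "Name")
    pd[[nm]] <- as.numeric(strsplit(trimws(xml2::xml_text(a)), "\\s+")[[1]])
  }
  if (!is.null(pd$fact)) mesh$fact <- pd$fact
  if (!is.null(pd$fpas)) mesh$fpas <- pd$fpas
  if (!is.null(pd$transmural)) mesh$transmural <- pd$transmural
  if (!is.null(pd$region_code))
    mesh$region <- c("remote", "structural_bz", "core")[pd$region_code + 1]
  if (!is.null(pd$layer_code))
    mesh$layer <- c("endo", "sub_endo", "mid", "epi")[pd$layer_code + 1]
  fib <- xml2::xml_find_first(piece, ".//CellData/DataArray[@Name='fiber']")
  if (!inherits(fib, "xml_missing")) {
    v <- as.numeric(strsplit(trimws(xml2::xml_text(fib)), "\\s+")[[1]])
    mesh$fibers <- matrix(v, ncol = 3, byrow = TRUE)
  }
  mesh$point_data <- pd
  mesh
}

#' Write / read a per-node field as CSV (node_id, value)
#' @param field numeric per-node vector.
#' @param file path.
#' @export
write_field_csv <- function(field, file) {
  utils::write.csv(data.frame(node_id = seq_along(field), value = field),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(file) {
  df <- utils::read.csv(file)
  out <- df$value[order(df$node_id)]
  out
}
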