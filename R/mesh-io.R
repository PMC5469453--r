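# Mesh I/O: STL (ASCII and binary), VTK XML (VTP for surfaces, VTU for
# tetrahedral meshes) and CSV export of per-face fields.
#
# Region labels travel as an integer cell-data array named "region" with the
# code table 0 = other, 1 = sac, 2 = neck, 3 = parent, 4 = near_vessel.

region_to_code <- function(region) unname(REGION_CODES[region])

code_to_region <- function(code) {
  code <- as.integer(round(code))
  if (any(code < 0L | code >= length(REGION_LEVELS))) {
    stop("region codes must be in 0..", length(REGION_LEVELS) - 1L)
  }
  REGION_LEVELS[code + 1L]
}

#' Read a mesh from a standard format
#'
#' Reads STL (ASCII or binary, auto-detected), VTP (surface) or VTU
#' (tetrahedral volume) files. STL carries no labels, so the region is taken
#' from the `region` argument or a sidecar file (one label per face); VTP/VTU
#' files written by [write_mesh()] carry the integer `region` cell-data array.
#'
#' @param path file path.
#' @param format `"stl"`, `"vtp"` or `"vtu"`; inferred from the extension by
#'   default.
#' @param region for STL: a single label, a per-face label vector, or the path
#'   of a sidecar text file with one label per face. Ignored when the file
#'   itself carries labels.
#' @return A [labeled_surface_mesh()] (STL/VTP) or [labeled_volume_mesh()]
#'   (VTU).
#' @export
read_mesh <- function(path, format = c("auto", "stl", "vtp", "vtu"),
                      region = "other") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "vtp", "vtu")) {
      stop("cannot infer mesh format from extension '.", format, "'")
    }
  }
  switch(format,
    stl = read_stl(path, region = region),
    vtp = read_vtp(path),
    vtu = read_vtu(path)
  )
}

#' Write a mesh to STL, VTP or VTU
#'
#' @param mesh a [labeled_surface_mesh()] or (for VTU) a
#'   [labeled_volume_mesh()].
#' @param path output path.
#' @param format `"stl"` (surface only; labels are dropped), `"vtp"` (surface
#'   with region labels) or `"vtu"` (volume with region labels); inferred from
#'   the extension by default.
#' @param binary for STL only: write the 50-byte-per-facet binary dialect
#'   instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "vtp", "vtu"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  switch(format,
    stl = write_stl(mesh, path, binary = binary),
    vtp = write_vtp(mesh, path),
    vtu = write_vtu(mesh, path),
    stop("unknown mesh format '", format, "'")
  )
  invisible(path)
}

## ---- STL ----

is_binary_stl <- function(path) {
  sz <- file.size(path)
  if (sz < 84) {
    return(FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  # a binary STL's size is fully determined by its facet count
  identical(sz, 84 + 50 * as.numeric(n)) &&
    !grepl("^solid", rawToChar(header[1:5]))
}

read_stl <- function(path, region = "other", merge_tol = 1e-8) {
  tri_soup <- if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
  # weld duplicate corner coordinates into shared vertices
  key <- apply(round(tri_soup / max(merge_tol, 1e-300)) * merge_tol, 1L,
    paste,
    collapse = ","
  )
  idx <- match(key, unique(key))
  vertices <- tri_soup[!duplicated(key), , drop = FALSE]
  triangles <- matrix(idx, ncol = 3L, byrow = TRUE)
  if (length(region) == 1L && is.character(region) && file.exists(region)) {
    region <- scan(region, what = character(), quiet = TRUE)
  }
  labeled_surface_mesh(vertices, triangles, region)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop("malformed ASCII STL: vertex count not a multiple of 3")
  }
  nums <- t(vapply(
    strsplit(trimws(vl), "\\s+"),
    function(x) as.numeric(x[2:4]), numeric(3L)
  ))
  nums
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  # the 2-byte attribute word after each facet forces record-wise reads
  out <- matrix(0, nrow = 3L * n, ncol = 3L)
  for (i in seq_len(n)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
    out[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], ncol = 3L, byrow = TRUE)
  }
  out
}

write_stl <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "labeled_surface_mesh"))
  tr <- mesh$triangles
  v <- mesh$vertices
  n <- nrow(tr)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("hemorobust binary STL", width = -80)), con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    for (i in seq_len(n)) {
      writeBin(as.numeric(c(
        mesh$normals[i, ],
        t(v[tr[i, ], , drop = FALSE])
      )), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    out <- character(2L + 7L * n)
    out[1L] <- "solid mesh"
    out[length(out)] <- "endsolid mesh"
    k <- 2L
    for (i in seq_len(n)) {
      p <- v[tr[i, ], , drop = FALSE]
      out[k:(k + 6L)] <- c(
        sprintf(
          "  facet normal %.9g %.9g %.9g",
          mesh$normals[i, 1L], mesh$normals[i, 2L], mesh$normals[i, 3L]
        ),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L]),
        "    endloop",
        "  endfacet"
      )
      k <- k + 7L
    }
    writeLines(out, path)
  }
  invisible(path)
}

## ---- VTK XML (ASCII appended-free dialect) ----

vtk_data_array <- function(name, values, ncomp = 1L, type = "Float64") {
  sprintf(
    '<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
    type, name, ncomp, paste(format(values, scientific = FALSE, trim = TRUE),
      collapse = " "
    )
  )
}

write_vtp <- function(mesh, path) {
  stopifnot(inherits(mesh, "labeled_surface_mesh"))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  conn <- as.vector(t(mesh$triangles)) - 1L
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    "<PolyData>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfPolys="%d">', nv, nf),
    "<Points>",
    vtk_data_array("Points", sprintf("%.12g", t(mesh$vertices)), 3L),
    "</Points>",
    "<Polys>",
    vtk_data_array("connectivity", conn, 1L, "Int64"),
    vtk_data_array("offsets", seq_len(nf) * 3L, 1L, "Int64"),
    "</Polys>",
    "<CellData>",
    vtk_data_array("region", region_to_code(mesh$face_region), 1L, "Int32"),
    "</CellData>",
    "</Piece>",
    "</PolyData>",
    "</VTKFile>"
  )
  writeLines(xml, path)
  invisible(path)
}

write_vtu <- function(mesh, path) {
  stopifnot(inherits(mesh, "labeled_volume_mesh"))
  nv <- nrow(mesh$vertices)
  nc <- nrow(mesh$tetrahedra)
  code <- match(mesh$cell_region, c("other", "aneurysm", "near_vessel")) - 1L
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "<UnstructuredGrid>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nc),
    "<Points>",
    vtk_data_array("Points", sprintf("%.12g", t(mesh$vertices)), 3L),
    "</Points>",
    "<Cells>",
    vtk_data_array("connectivity", as.vector(t(mesh$tetrahedra)) - 1L, 1L, "Int64"),
    vtk_data_array("offsets", seq_len(nc) * 4L, 1L, "Int64"),
    vtk_data_array("types", rep(10L, nc), 1L, "UInt8"),
    "</Cells>",
    "<CellData>",
    vtk_data_array("region", code, 1L, "Int32"),
    "</CellData>",
    "</Piece>",
    "</UnstructuredGrid>",
    "</VTKFile>"
  )
  writeLines(xml, path)
  invisible(path)
}

vtk_read_array <- function(piece, name) {
  node <- xml2::xml_find_first(
    piece, sprintf(".//*[local-name()='DataArray'][@Name='%s']", name)
  )
  if (inherits(node, "xml_missing")) stop("VTK file lacks array '", name, "'")
  as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1L]])
}

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//*[local-name()='Piece']")
  pts <- matrix(vtk_read_array(piece, "Points"), ncol = 3L, byrow = TRUE)
  conn <- vtk_read_array(piece, "connectivity")
  offs <- vtk_read_array(piece, "offsets")
  if (any(diff(c(0, offs)) != 3)) stop("VTP file contains non-triangle polys")
  tri <- matrix(as.integer(conn) + 1L, ncol = 3L, byrow = TRUE)
  region <- tryCatch(code_to_region(vtk_read_array(piece, "region")),
    error = function(e) "other"
  )
  labeled_surface_mesh(pts, tri, region)
}

read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//*[local-name()='Piece']")
  pts <- matrix(vtk_read_array(piece, "Points"), ncol = 3L, byrow = TRUE)
  types <- vtk_read_array(piece, "types")
  if (any(types != 10)) stop("VTU reader supports tetrahedral cells only")
  conn <- vtk_read_array(piece, "connectivity")
  tet <- matrix(as.integer(conn) + 1L, ncol = 4L, byrow = TRUE)
  code <- tryCatch(vtk_read_array(piece, "region"), error = function(e) 0)
  region <- c("other", "aneurysm", "near_vessel")[as.integer(round(code)) + 1L]
  labeled_volume_mesh(pts, tet, region)
}

#' Export a per-face scalar field as CSV
#'
#' Writes one row per face with the face index, region label, area and field
#' value, for inspection in external tools.
#'
#' @param field numeric vector, one value per face.
#' @param mesh a [labeled_surface_mesh()].
#' @param path output CSV path.
#' @param name column name for the field values.
#' @return `path`, invisibly.
#' @export
write_face_field_csv <- function(field, mesh, path, name = "value") {
  stopifnot(length(field) == nrow(mesh$triangles))
  df <- data.frame(
    face = seq_along(field),
    region = mesh$face_region,
    area_mm2 = mesh$face_area
  )
  df[[name]] <- field
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
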