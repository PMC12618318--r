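# Readers/writers for the FE exchange formats the toolkit touches:
# legacy + XML VTK unstructured grids, ASCII + binary STL, Abaqus-style
# .inp decks and LS-DYNA keyword files. Only node / element / part cards
# are interpreted; solver cards are never parsed and are emitted as
# comments where relevant.

VTK_CELL_TYPES <- c(triangle = 5L, quad = 9L, tet = 10L, hex = 12L)

#' Read a mesh file
#'
#' Supported formats: legacy VTK unstructured (`"vtk"`), XML VTK (`"vtu"`),
#' STL (`"stl"`, ASCII or binary auto-detected), Abaqus-style `.inp`
#' (`"inp"`) and LS-DYNA keyword (`"keyword"`). With `format = "auto"` the
#' dialect is inferred from the file extension. Node ids are re-indexed to
#' contiguous 1-based ids; the original ids are kept in the mesh's
#' `orig_id` field.
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"vtk"`, `"vtu"`, `"stl"`, `"inp"`,
#'   `"keyword"`.
#' @return a `tet_mesh`, `hex_mesh` or `surface_mesh` depending on the
#'   element type found in the file.
#' @export
read_mesh <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- resolve_format(path, format)
  switch(format,
         vtk = read_vtk_legacy(path),
         vtu = read_vtu(path),
         stl = read_stl(path),
         inp = read_inp(path),
         keyword = read_keyword(path),
         stop("unsupported format: ", format))
}

#' Write a mesh file
#'
#' The inverse of [read_mesh()]: the emitted file re-reads to an equivalent
#' mesh (coordinates to at least 1e-6 mm; binary STL stores 32-bit floats).
#' STL accepts triangle surface meshes only. The keyword writer emits
#' `*NODE`, `*ELEMENT_SOLID` / `*ELEMENT_SHELL` (plus `*ELEMENT_BEAM` when
#' `beams` is given) and `*PART` cards, with element-formulation notes as
#' `$` comments that no reader interprets.
#'
#' @param mesh a `tet_mesh`, `hex_mesh` or `surface_mesh`.
#' @param path output file.
#' @param format as in [read_mesh()]; `"auto"` infers from the extension.
#' @param binary for STL: write the binary dialect instead of ASCII.
#' @param beams optional `beam_set` written alongside a keyword mesh.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = "auto", binary = FALSE,
                       beams = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"))
  format <- resolve_format(path, format)
  switch(format,
         vtk = write_vtk_legacy(mesh, path),
         vtu = write_vtu(mesh, path),
         stl = write_stl(mesh, path, binary = binary),
         inp = write_inp(mesh, path),
         keyword = write_keyword(mesh, path, beams = beams),
         stop("unsupported format: ", format))
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format != "auto") {
    format <- match.arg(format, c("vtk", "vtu", "stl", "inp", "keyword"))
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  fmt <- c(vtk = "vtk", vtu = "vtu", stl = "stl", inp = "inp",
           k = "keyword", key = "keyword", dyn = "keyword")[ext]
  if (is.na(fmt)) stop("cannot infer mesh format from extension '.",
                       ext, "'; pass format= explicitly")
  unname(fmt)
}

mesh_kind <- function(mesh) {
  if (inherits(mesh, "tet_mesh")) "tet"
  else if (inherits(mesh, "hex_mesh")) "hex"
  else if (mesh$face_kind == "triangle") "triangle"
  else "quad"
}

build_mesh <- function(kind, nodes, elements, part_label, orig_id = NULL) {
  switch(kind,
         tet = tet_mesh(nodes, elements, part_label, orig_id),
         hex = hex_mesh(nodes, elements, part_label, orig_id),
         triangle = ,
         quad = surface_mesh(nodes, elements, part_label, orig_id))
}

num_fmt <- function(x) sprintf("%.10g", x)

# ---- legacy VTK --------------------------------------------------------

write_vtk_legacy <- function(mesh, path) {
  kind <- mesh_kind(mesh)
  el <- mesh_elements(mesh)
  k <- ncol(el)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               mesh$part_label,
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(paste(num_fmt(mesh$nodes[, 1L]), num_fmt(mesh$nodes[, 2L]),
                   num_fmt(mesh$nodes[, 3L])), con)
  writeLines(sprintf("CELLS %d %d", nrow(el), nrow(el) * (k + 1L)), con)
  conn <- cbind(k, el - 1L)
  writeLines(apply(conn, 1L, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(as.character(rep(VTK_CELL_TYPES[[kind]], nrow(el))), con)
}

read_vtk_legacy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  find_line <- function(pat) {
    i <- grep(pat, lines, ignore.case = TRUE)
    if (length(i) == 0L) stop("malformed VTK file ", path,
                              ": missing '", pat, "' section")
    i[1L]
  }
  if (!any(grepl("UNSTRUCTURED_GRID", lines, ignore.case = TRUE))) {
    stop("VTK file ", path, " is not an unstructured grid")
  }
  ip <- find_line("^POINTS")
  npts <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1L]][2L])
  pts <- scan(text = lines[(ip + 1L):length(lines)], n = npts * 3L,
              quiet = TRUE)
  nodes <- matrix(pts, ncol = 3L, byrow = TRUE)
  ic <- find_line("^CELLS")
  hdr <- as.integer(strsplit(trimws(lines[ic]), "\\s+")[[1L]][2:3])
  vals <- scan(text = lines[(ic + 1L):length(lines)], n = hdr[2L],
               quiet = TRUE)
  it <- find_line("^CELL_TYPES")
  types <- scan(text = lines[(it + 1L):length(lines)], n = hdr[1L],
                quiet = TRUE)
  utype <- unique(types)
  if (length(utype) != 1L) {
    stop("VTK file ", path, " mixes cell types (", toString(utype),
         "); only homogeneous meshes are supported")
  }
  kind <- names(VTK_CELL_TYPES)[match(utype, VTK_CELL_TYPES)]
  if (is.na(kind)) stop("unsupported VTK cell type ", utype, " in ", path)
  k <- c(triangle = 3L, quad = 4L, tet = 4L, hex = 8L)[[kind]]
  conn <- matrix(vals, ncol = k + 1L, byrow = TRUE)
  if (any(conn[, 1L] != k)) {
    stop("malformed VTK file ", path, ": cell size does not match type")
  }
  build_mesh(kind, nodes, conn[, -1L, drop = FALSE] + 1L, lines[2L])
}

# ---- XML VTK (.vtu, ascii-encoded) ------------------------------------

write_vtu <- function(mesh, path) {
  kind <- mesh_kind(mesh)
  el <- mesh_elements(mesh)
  k <- ncol(el)
  pts <- paste(apply(mesh$nodes, 1L, function(r)
    paste(num_fmt(r), collapse = " ")), collapse = "\n")
  conn <- paste(apply(el - 1L, 1L, paste, collapse = " "), collapse = "\n")
  offs <- paste(seq_len(nrow(el)) * k, collapse = " ")
  typ <- paste(rep(VTK_CELL_TYPES[[kind]], nrow(el)), collapse = " ")
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    sprintf('  <UnstructuredGrid name="%s">', mesh$part_label),
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">',
            nrow(mesh$nodes), nrow(el)),
    "      <Points>",
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    pts, "        </DataArray>", "      </Points>", "      <Cells>",
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    conn, "        </DataArray>",
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    offs, "        </DataArray>",
    '        <DataArray type="UInt8" Name="types" format="ascii">',
    typ, "        </DataArray>", "      </Cells>", "    </Piece>",
    "  </UnstructuredGrid>", "</VTKFile>")
  writeLines(xml, path)
}

read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) {
    stop("malformed .vtu file ", path, ": no <Piece> node")
  }
  get_array <- function(xpath) {
    node <- xml2::xml_find_first(doc, xpath)
    if (inherits(node, "xml_missing")) {
      stop("malformed .vtu file ", path, ": missing ", xpath)
    }
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pts <- get_array(".//Points/DataArray")
  nodes <- matrix(pts, ncol = 3L, byrow = TRUE)
  conn <- get_array(".//Cells/DataArray[@Name='connectivity']")
  types <- get_array(".//Cells/DataArray[@Name='types']")
  utype <- unique(types)
  if (length(utype) != 1L) {
    stop(".vtu file ", path, " mixes cell types; unsupported")
  }
  kind <- names(VTK_CELL_TYPES)[match(utype, VTK_CELL_TYPES)]
  if (is.na(kind)) stop("unsupported .vtu cell type ", utype)
  k <- c(triangle = 3L, quad = 4L, tet = 4L, hex = 8L)[[kind]]
  grid <- xml2::xml_find_first(doc, ".//UnstructuredGrid")
  label <- xml2::xml_attr(grid, "name")
  if (is.na(label)) label <- "part"
  build_mesh(kind, nodes, matrix(conn, ncol = k, byrow = TRUE) + 1L, label)
}

# ---- STL ---------------------------------------------------------------

write_stl <- function(mesh, path, binary = FALSE) {
  if (!inherits(mesh, "surface_mesh") || mesh$face_kind != "triangle") {
    stop("STL export supports triangle surface meshes only; got ",
         class(mesh)[1L],
         if (inherits(mesh, "surface_mesh")) paste0(" of ", mesh$face_kind,
                                                    "s"))
  }
  tri <- mesh$faces
  p1 <- mesh$nodes[tri[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3L], , drop = FALSE]
  nrm <- vcross(p2 - p1, p3 - p1)
  len <- vnorm(nrm)
  nrm <- nrm / ifelse(len > 0, len, 1)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("hexamesh binary STL", width = -80)), con)
    writeBin(as.integer(nrow(tri)), con, size = 4L, endian = "little")
    dat <- t(cbind(nrm, p1, p2, p3))
    for (i in seq_len(nrow(tri))) {
      writeBin(as.numeric(dat[, i]), con, size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("solid", mesh$part_label), con)
    body <- sprintf(
      "facet normal %s %s %s\n outer loop\n  vertex %s %s %s\n  vertex %s %s %s\n  vertex %s %s %s\n endloop\nendfacet",
      num_fmt(nrm[, 1L]), num_fmt(nrm[, 2L]), num_fmt(nrm[, 3L]),
      num_fmt(p1[, 1L]), num_fmt(p1[, 2L]), num_fmt(p1[, 3L]),
      num_fmt(p2[, 1L]), num_fmt(p2[, 2L]), num_fmt(p2[, 3L]),
      num_fmt(p3[, 1L]), num_fmt(p3[, 2L]), num_fmt(p3[, 3L]))
    writeLines(body, con)
    writeLines(paste("endsolid", mesh$part_label), con)
  }
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", 84L)
  is_binary <- FALSE
  if (length(head) == 84L) {
    ntri <- readBin(head[81:84], "integer", 1L, size = 4L,
                    endian = "little")
    if (sz == 84 + 50 * ntri) is_binary <- TRUE
  }
  close(con)
  if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  verts <- matrix(NA_real_, ntri * 3L, 3L)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    invisible(readBin(con, "raw", 2L))
    verts[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L,
                                              byrow = TRUE)
  }
  stl_assemble(verts, "part")
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop("malformed ASCII STL ", path, ": ", length(vl), " vertex lines")
  }
  toks <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 4L)
  if (length(bad) > 0L) {
    stop("malformed ASCII STL ", path, " at line ", vl[bad[1L]])
  }
  verts <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3L)))
  label <- sub("^\\s*solid\\s*", "", lines[grep("^\\s*solid", lines)[1L]])
  if (is.na(label) || !nzchar(label)) label <- "part"
  stl_assemble(verts, label)
}

# Merge coincident STL vertices back into a shared node table.
stl_assemble <- function(verts, label) {
  key <- paste(sprintf("%.9g", verts[, 1L]), sprintf("%.9g", verts[, 2L]),
               sprintf("%.9g", verts[, 3L]))
  first <- !duplicated(key)
  nodes <- verts[first, , drop = FALSE]
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  surface_mesh(nodes, faces, part_label = label)
}

# ---- Abaqus-style .inp -------------------------------------------------

INP_TYPES <- c(C3D4 = "tet", C3D8 = "hex", C3D8R = "hex",
               S3 = "triangle", S3R = "triangle", STRI3 = "triangle",
               S4 = "quad", S4R = "quad")

write_inp <- function(mesh, path) {
  kind <- mesh_kind(mesh)
  type <- switch(kind, tet = "C3D4", hex = "C3D8", triangle = "S3",
                 quad = "S4")
  el <- mesh_elements(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("*Heading", paste0("** part: ", mesh$part_label), "*Node"),
             con)
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   num_fmt(mesh$nodes[, 1L]), num_fmt(mesh$nodes[, 2L]),
                   num_fmt(mesh$nodes[, 3L]), sep = ", "), con)
  writeLines(sprintf("*Element, type=%s, elset=%s", type, mesh$part_label),
             con)
  writeLines(paste(seq_len(nrow(el)),
                   apply(el, 1L, paste, collapse = ", "), sep = ", "), con)
}

read_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\*\\*", lines)]
  hdr <- grep("^\\*", lines)
  nodes <- NULL; node_ids <- NULL; elements <- NULL; kind <- NULL
  label <- "part"
  for (h in seq_along(hdr)) {
    start <- hdr[h]
    end <- if (h < length(hdr)) hdr[h + 1L] - 1L else length(lines)
    head_line <- lines[start]
    body <- lines[(start + 1L):end]
    body <- body[nzchar(trimws(body))]
    if (start == end || length(body) == 0L) body <- character()
    if (grepl("^\\*node\\b", head_line, ignore.case = TRUE)) {
      vals <- parse_csv_block(body, path, start)
      if (ncol(vals) < 4L) stop("malformed *Node block in ", path,
                                " near line ", start)
      node_ids <- c(node_ids, vals[, 1L])
      nodes <- rbind(nodes, vals[, 2:4, drop = FALSE])
    } else if (grepl("^\\*element\\b", head_line, ignore.case = TRUE)) {
      type <- sub(".*type\\s*=\\s*([A-Za-z0-9]+).*", "\\1", head_line,
                  ignore.case = TRUE)
      k <- INP_TYPES[toupper(type)]
      if (is.na(k)) stop("unsupported element type '", type, "' in ", path,
                         " at line ", start)
      if (!is.null(kind) && kind != k) {
        stop("mixed element kinds in ", path, "; unsupported")
      }
      kind <- unname(k)
      if (grepl("elset\\s*=", head_line, ignore.case = TRUE)) {
        label <- sub(".*elset\\s*=\\s*([^,\\s]+).*", "\\1", head_line,
                     ignore.case = TRUE)
      }
      vals <- parse_csv_block(body, path, start)
      elements <- rbind(elements, vals[, -1L, drop = FALSE])
    }
  }
  if (is.null(nodes) || is.null(elements)) {
    stop("no *Node / *Element sections found in ", path)
  }
  finish_file_mesh(kind, nodes, node_ids, elements, label)
}

parse_csv_block <- function(body, path, start_line) {
  if (length(body) == 0L) {
    stop("empty data block in ", path, " near line ", start_line)
  }
  toks <- strsplit(trimws(body), "\\s*,\\s*|\\s+")
  n <- vapply(toks, length, 1L)
  if (length(unique(n)) != 1L) {
    stop("ragged data block in ", path, " near line ", start_line)
  }
  vals <- suppressWarnings(vapply(toks, as.numeric, numeric(n[1L])))
  if (anyNA(vals)) stop("non-numeric entry in ", path, " near line ",
                        start_line)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  t(vals)
}

# Re-index file node ids (arbitrary, 1-based, possibly sparse) to rows.
finish_file_mesh <- function(kind, nodes, node_ids, elements, label) {
  conn <- matrix(match(elements, node_ids), nrow = nrow(elements))
  if (anyNA(conn)) {
    stop("element connectivity references undefined node id(s): ",
         toString(utils::head(unique(elements[is.na(conn)]), 5L)))
  }
  build_mesh(kind, nodes, conn, label, orig_id = node_ids)
}

# ---- LS-DYNA keyword ---------------------------------------------------

write_keyword <- function(mesh, path, beams = NULL) {
  kind <- mesh_kind(mesh)
  el <- mesh_elements(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("*KEYWORD", "*PART", mesh$part_label,
               "$#     pid", "         1"), con)
  if (kind %in% c("tet", "hex")) {
    writeLines(c("$ solid element formulation metadata (comment, not parsed):",
                 "$   brain gray/white matter ELFORM=-2 (fully integrated)",
                 "$   CSF ELFORM=1 with hourglass control IHQ=6"), con)
  }
  writeLines("*NODE", con)
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   num_fmt(mesh$nodes[, 1L]), num_fmt(mesh$nodes[, 2L]),
                   num_fmt(mesh$nodes[, 3L]), sep = ","), con)
  card <- switch(kind, tet = , hex = "*ELEMENT_SOLID",
                 triangle = , quad = "*ELEMENT_SHELL")
  writeLines(card, con)
  conn <- switch(kind,
                 tet = cbind(el, el[, 4L], el[, 4L], el[, 4L], el[, 4L]),
                 hex = el,
                 triangle = cbind(el, el[, 3L]),
                 quad = el)
  writeLines(paste(seq_len(nrow(el)), 1L,
                   apply(conn, 1L, paste, collapse = ","), sep = ","), con)
  if (!is.null(beams)) {
    stopifnot(inherits(beams, "beam_set"))
    writeLines(paste0("$ beam kind: ", beams$kind), con)
    writeLines("*ELEMENT_BEAM", con)
    writeLines(paste(seq_len(nrow(beams$elements)), 2L,
                     beams$elements[, 1L], beams$elements[, 2L], sep = ","),
               con)
  }
  writeLines("*END", con)
}

read_keyword <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\$", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  lines2 <- lines[keep]
  hdr <- grep("^\\*", lines2)
  nodes <- NULL; node_ids <- NULL; elements <- NULL; kind_card <- NULL
  label <- "part"
  for (h in seq_along(hdr)) {
    start <- hdr[h]
    end <- if (h < length(hdr)) hdr[h + 1L] - 1L else length(lines2)
    card <- toupper(trimws(lines2[start]))
    body <- if (end > start) lines2[(start + 1L):end] else character()
    if (card == "*NODE") {
      vals <- parse_csv_block(body, path, idx[start])
      node_ids <- c(node_ids, vals[, 1L])
      nodes <- rbind(nodes, vals[, 2:4, drop = FALSE])
    } else if (card %in% c("*ELEMENT_SOLID", "*ELEMENT_SHELL")) {
      if (!is.null(kind_card) && kind_card != card) {
        stop("mixed solid and shell cards in ", path, "; unsupported")
      }
      kind_card <- card
      vals <- parse_csv_block(body, path, idx[start])
      elements <- rbind(elements, vals[, -(1:2), drop = FALSE])
    } else if (card == "*PART") {
      if (length(body) >= 1L) label <- trimws(body[1L])
    } else if (card == "*ELEMENT_BEAM") {
      stop("beam element cards in ", path,
           " are not readable as a volume/surface mesh")
    }
  }
  if (is.null(nodes) || is.null(elements)) {
    stop("no *NODE / *ELEMENT cards found in ", path)
  }
  if (kind_card == "*ELEMENT_SOLID") {
    if (ncol(elements) == 4L) {
      kind <- "tet"
    } else if (ncol(elements) == 8L) {
      degen <- elements[, 5L] == elements[, 4L] &
        elements[, 6L] == elements[, 4L] &
        elements[, 7L] == elements[, 4L] & elements[, 8L] == elements[, 4L]
      if (all(degen)) {
        kind <- "tet"
        elements <- elements[, 1:4, drop = FALSE]
      } else if (any(degen)) {
        stop("mixed tet/hex solids in ", path, "; unsupported")
      } else {
        kind <- "hex"
      }
    } else {
      stop("unsupported solid card width in ", path, ": ", ncol(elements))
    }
  } else {
    if (ncol(elements) != 4L) {
      stop("unsupported shell card width in ", path, ": ", ncol(elements))
    }
    degen <- elements[, 4L] == elements[, 3L]
    if (all(degen)) {
      kind <- "triangle"
      elements <- elements[, 1:3, drop = FALSE]
    } else if (any(degen)) {
      stop("mixed triangle/quad shells in ", path, "; unsupported")
    } else {
      kind <- "quad"
    }
  }
  finish_file_mesh(kind, nodes, node_ids, elements, label)
}

# ---- landmark / point tables ------------------------------------------

#' Read or write a labelled point table (CSV: label,x,y,z)
#'
#' @param path CSV file with columns `label,x,y,z` (mm).
#' @return data frame with those four columns.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("point CSV must have columns label,x,y,z; got ",
         toString(names(df)))
  }
  df[, need]
}

#' @rdname read_points_csv
#' @param points data frame with columns `label,x,y,z`.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points[, c("label", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}
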