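## Plain-text mesh exchange: Gmsh .msh v2.2 (read/write) and VTK
## UnstructuredGrid .vtu (ASCII; write, plus a reader for files this package
## writes).  Patch labels travel as physical groups / cell data.

#' Write a labeled mesh in Gmsh 2.2 ASCII format
#'
#' Surface patches are exported as triangle elements in named 2D physical
#' groups; the volume is a single 3D physical group.
#'
#' @param mesh a [labeled_mesh()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pn <- names(mesh$surface_patches)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$PhysicalNames",
               as.character(length(pn) + 1L)), con)
  for (k in seq_along(pn))
    writeLines(sprintf("2 %d \"%s\"", k, pn[k]), con)
  writeLines(sprintf("3 %d \"volume\"", length(pn) + 1L), con)
  writeLines("$EndPhysicalNames", con)
  N <- nrow(mesh$vertices)
  writeLines(c("$Nodes", as.character(N)), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(N),
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines("$EndNodes", con)
  ntri <- sum(vapply(mesh$surface_patches, nrow, 1L))
  M <- nrow(mesh$tets)
  writeLines(c("$Elements", as.character(ntri + M)), con)
  eid <- 0L
  for (k in seq_along(pn)) {
    tri <- mesh$surface_patches[[k]]
    writeLines(sprintf("%d 2 2 %d %d %d %d %d", eid + seq_len(nrow(tri)),
                       k, k, tri[, 1], tri[, 2], tri[, 3]), con)
    eid <- eid + nrow(tri)
  }
  vt <- length(pn) + 1L
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", eid + seq_len(M), vt, vt,
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh 2.2 ASCII mesh
#'
#' Reconstructs a [labeled_mesh()]; 2D physical groups become surface
#' patches.  Cap planes and chamber registrations are not part of the format
#' and must be re-attached by the caller if needed.
#'
#' @param path .msh file
#' @param validate run [validate_labeled_mesh()]
#' @return a [labeled_mesh()]
#' @export
read_msh <- function(path, validate = TRUE) {
  lines <- readLines(path)
  sect <- function(name) {
    a <- which(lines == paste0("$", name)) + 1L
    b <- which(lines == paste0("$End", name)) - 1L
    if (!length(a) || !length(b)) stop("missing section $", name)
    lines[a:b]
  }
  phys <- sect("PhysicalNames")
  np <- as.integer(phys[1])
  pmap <- character(0)
  for (r in seq_len(np)) {
    f <- strsplit(phys[r + 1L], " ")[[1]]
    if (f[1] == "2") pmap[f[2]] <- gsub('"', "", paste(f[-(1:2)], collapse = " "))
  }
  nd <- sect("Nodes")
  nn <- as.integer(nd[1])
  nodes <- utils::read.table(text = nd[1 + seq_len(nn)])
  verts <- as.matrix(nodes[order(nodes[[1]]), 2:4])
  dimnames(verts) <- NULL
  el <- sect("Elements")
  ne <- as.integer(el[1])
  tets <- list(); patches <- list()
  for (r in seq_len(ne)) {
    f <- as.integer(strsplit(el[r + 1L], " ")[[1]])
    ntags <- f[3]
    conn <- f[(4 + ntags):length(f)]
    if (f[2] == 4L) {
      tets[[length(tets) + 1L]] <- conn
    } else if (f[2] == 2L) {
      nm <- pmap[as.character(f[4])]
      patches[[nm]] <- rbind(patches[[nm]], conn)
    }
  }
  labeled_mesh(verts, do.call(rbind, tets), patches, validate = validate)
}

#' Write a mesh with fields as ASCII VTU
#'
#' @param mesh a [labeled_mesh()]
#' @param path output file
#' @param point_data named list of per-vertex scalars (length N) or vectors
#'   (N x 3 matrices)
#' @param cell_data named list of per-element scalars (length M) or vectors
#'   (M x 3 matrices, e.g. fiber directions)
#' @return the path, invisibly
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  N <- nrow(mesh$vertices); M <- nrow(mesh$tets)
  fmt_arr <- function(name, x) {
    if (is.matrix(x)) {
      comp <- ncol(x)
      vals <- paste(apply(x, 1, function(r) paste(format(r, digits = 10), collapse = " ")),
                    collapse = "\n")
    } else {
      comp <- 1L
      vals <- paste(format(x, digits = 10), collapse = "\n")
    }
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            name, comp, vals)
  }
  pts <- paste(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 10), collapse = " ")), collapse = "\n")
  conn <- paste(apply(mesh$tets - 1L, 1, paste, collapse = " "), collapse = "\n")
  off <- paste(seq_len(M) * 4L, collapse = " ")
  types <- paste(rep(10L, M), collapse = " ")
  pd <- paste(vapply(names(point_data),
                     function(nm) fmt_arr(nm, point_data[[nm]]), ""), collapse = "\n")
  cd <- paste(vapply(names(cell_data),
                     function(nm) fmt_arr(nm, cell_data[[nm]]), ""), collapse = "\n")
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', N, M),
    '<Points>', fmt_arr("Points", mesh$vertices), '</Points>',
    '<Cells>',
    sprintf('<DataArray type="Int32" Name="connectivity" format="ascii">\n%s\n</DataArray>', conn),
    sprintf('<DataArray type="Int32" Name="offsets" format="ascii">\n%s\n</DataArray>', off),
    sprintf('<DataArray type="UInt8" Name="types" format="ascii">\n%s\n</DataArray>', types),
    '</Cells>',
    if (length(point_data)) c('<PointData>', pd, '</PointData>'),
    if (length(cell_data)) c('<CellData>', cd, '</CellData>'),
    '</Piece>', '</UnstructuredGrid>', '</VTKFile>')
  writeLines(unlist(xml), path)
  invisible(path)
}

#' Read an ASCII VTU file written by [write_vtu()]
#'
#' Requires the `xml2` package.
#'
#' @param path .vtu file
#' @return list with `vertices`, `tets`, `point_data`, `cell_data`
#' @export
read_vtu <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("read_vtu requires the xml2 package")
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  num <- function(node) scan(text = xml2::xml_text(node), quiet = TRUE)
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  verts <- matrix(num(pts_node), ncol = 3, byrow = TRUE)
  cells <- xml2::xml_find_all(piece, "./Cells/DataArray")
  nm <- vapply(cells, function(x) xml2::xml_attr(x, "Name"), "")
  conn <- num(cells[[which(nm == "connectivity")]])
  tets <- matrix(as.integer(conn), ncol = 4, byrow = TRUE) + 1L
  get_data <- function(xpath) {
    arrs <- xml2::xml_find_all(piece, xpath)
    out <- list()
    for (a in arrs) {
      comp <- as.integer(xml2::xml_attr(a, "NumberOfComponents"))
      v <- num(a)
      out[[xml2::xml_attr(a, "Name")]] <-
        if (!is.na(comp) && comp > 1) matrix(v, ncol = comp, byrow = TRUE) else v
    }
    out
  }
  list(vertices = verts, tets = tets,
       point_data = get_data("./PointData/DataArray"),
       cell_data = get_data("./CellData/DataArray"))
}
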