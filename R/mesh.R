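#' Labeled tetrahedral mesh
#'
#' Reference-configuration tetrahedral mesh with named oriented surface
#' patches, per-chamber cap planes (valve-plane closures used for cavity
#' volume computation) and a per-element size field.
#'
#' @param vertices N x 3 numeric matrix (mm)
#' @param tets M x 4 integer matrix of 1-based vertex indices, positively
#'   oriented (signed volume > 0)
#' @param surface_patches named list of T x 3 integer matrices; each triangle
#'   is oriented so its normal points out of the solid
#' @param cap_planes named list (per chamber) of `list(point, normal)`
#' @param endo_patches named character vector mapping chamber name to the
#'   patch name of its endocardial surface
#' @param validate check mesh invariants (positive volumes, watertight
#'   boundary fully covered by patches)
#' @return object of class `labeled_mesh`
#' @export
labeled_mesh <- function(vertices, tets, surface_patches = list(),
                         cap_planes = list(), endo_patches = character(),
                         validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(tets) <- "integer"
  mesh <- structure(list(
    vertices = vertices, tets = tets,
    surface_patches = surface_patches,
    cap_planes = cap_planes, endo_patches = endo_patches,
    h_e = element_sizes(vertices, tets)),
    class = "labeled_mesh")
  if (validate) validate_labeled_mesh(mesh)
  mesh
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat("labeled_mesh:", nrow(x$vertices), "vertices,", nrow(x$tets), "tets\n")
  cat("  patches:", paste(sprintf("%s(%d)", names(x$surface_patches),
                                  vapply(x$surface_patches, nrow, 1L)),
                          collapse = ", "), "\n")
  if (length(x$cap_planes))
    cat("  chambers:", paste(names(x$cap_planes), collapse = ", "), "\n")
  invisible(x)
}

tet_signed_volumes <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 2], , drop = FALSE] - a
  c3 <- vertices[tets[, 3], , drop = FALSE] - a
  d <- vertices[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c3[, 2] * d[, 3] - c3[, 3] * d[, 2]) -
   b[, 2] * (c3[, 1] * d[, 3] - c3[, 3] * d[, 1]) +
   b[, 3] * (c3[, 1] * d[, 2] - c3[, 2] * d[, 1])) / 6
}

element_sizes <- function(vertices, tets) {
  # h_e = longest edge of the element
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  h <- rep(0, nrow(tets))
  for (r in seq_len(6)) {
    d <- vertices[tets[, pairs[r, 1]], , drop = FALSE] -
         vertices[tets[, pairs[r, 2]], , drop = FALSE]
    h <- pmax(h, sqrt(rowSums(d^2)))
  }
  h
}

face_key <- function(tri) {
  s <- apply(tri, 1L, function(v) paste(sort(v), collapse = "_"))
  as.character(s)
}

#' Validate mesh invariants
#'
#' Checks positive element volumes, that the boundary (faces belonging to
#' exactly one tet) is exactly the union of the surface patches, that each
#' boundary face lies in exactly one patch, and that patch triangles are
#' oriented outward (the divergence-theorem volume of the full boundary
#' equals the summed element volume).
#'
#' @param mesh a [labeled_mesh()]
#' @return invisibly TRUE; stops on violation
#' @export
validate_labeled_mesh <- function(mesh) {
  v <- tet_signed_volumes(mesh$vertices, mesh$tets)
  if (any(v <= 0)) stop("mesh has ", sum(v <= 0), " non-positively oriented tets")
  if (any(mesh$h_e <= 0)) stop("degenerate element size")
  faces <- rbind(mesh$tets[, c(1, 2, 3)], mesh$tets[, c(1, 2, 4)],
                 mesh$tets[, c(1, 3, 4)], mesh$tets[, c(2, 3, 4)])
  keys <- face_key(faces)
  tab <- table(keys)
  boundary <- names(tab)[tab == 1L]
  patch_keys <- unlist(lapply(mesh$surface_patches, face_key))
  if (anyDuplicated(patch_keys))
    stop("a boundary triangle belongs to more than one patch")
  if (length(mesh$surface_patches)) {
    if (!setequal(boundary, patch_keys))
      stop("surface patches do not cover the mesh boundary exactly (",
           length(boundary), " boundary faces vs ", length(patch_keys),
           " patch faces)")
    vol_surf <- 0
    for (tri in mesh$surface_patches)
      vol_surf <- vol_surf + surface_signed_volume(mesh$vertices, tri)
    if (abs(vol_surf - sum(v)) > 1e-6 * sum(v))
      stop("patch orientation inconsistent: surface volume ",
           format(vol_surf), " vs element volume ", format(sum(v)))
  }
  invisible(TRUE)
}

# divergence-theorem signed volume of an oriented triangle set
surface_signed_volume <- function(vertices, tris) {
  a <- vertices[tris[, 1], , drop = FALSE]
  b <- vertices[tris[, 2], , drop = FALSE]
  c3 <- vertices[tris[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

## ---------------------------------------------------------------------------
## structured cell -> tetrahedra machinery
##
## Cells (hexahedra or wedges) are subdivided by inserting their centroid and
## coning over the triangulated faces.  Quadrilateral faces are split along
## the diagonal through their smallest global vertex index, which makes the
## triangulation of shared faces identical in both adjacent cells, so the
## resulting tetrahedral mesh is conforming -- including at the degenerate
## apex wedges of the ellipsoid grid.

split_quad <- function(q) {
  # returns 2 triangles; diagonal through the min-index corner
  m <- which.min(q)
  if (m == 1L || m == 3L)
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  else
    rbind(q[c(2, 3, 4)], q[c(2, 4, 1)])
}

cell_faces <- function(cell) {
  if (length(cell) == 8L) {
    # VTK hexahedron corner convention
    list(cell[c(1, 4, 3, 2)], cell[c(5, 6, 7, 8)],
         cell[c(1, 2, 6, 5)], cell[c(2, 3, 7, 6)],
         cell[c(3, 4, 8, 7)], cell[c(4, 1, 5, 8)])
  } else {
    # wedge: corners 1:3 bottom triangle, 4:6 top triangle
    list(cell[c(1, 3, 2)], cell[c(4, 5, 6)],
         cell[c(1, 2, 5, 4)], cell[c(2, 3, 6, 5)], cell[c(3, 1, 4, 6)])
  }
}

triangulate_face <- function(f) {
  if (length(f) == 3L) matrix(f, 1, 3) else split_quad(f)
}

# cells: list of integer vectors (length 8 or 6)
# boundary_faces: list of list(cell = idx, face = face idx within cell,
#                              patch = name)
cells_to_tets <- function(vertices, cells, boundary_faces) {
  ncell <- length(cells)
  cent <- t(vapply(cells, function(cl) colMeans(vertices[cl, , drop = FALSE]),
                   numeric(3)))
  nv0 <- nrow(vertices)
  verts <- rbind(vertices, cent)
  tets_list <- vector("list", ncell)
  for (ci in seq_len(ncell)) {
    faces <- cell_faces(cells[[ci]])
    tris <- do.call(rbind, lapply(faces, triangulate_face))
    tt <- cbind(tris, nv0 + ci)
    sv <- tet_signed_volumes(verts, tt)
    flip <- sv < 0
    if (any(flip)) tt[flip, c(1, 2)] <- tt[flip, c(2, 1)]
    tets_list[[ci]] <- tt
  }
  tets <- do.call(rbind, tets_list)
  patches <- list()
  for (bf in boundary_faces) {
    tri <- triangulate_face(cell_faces(cells[[bf$cell]])[[bf$face]])
    # orient outward: away from the cell centroid
    for (r in seq_len(nrow(tri))) {
      p <- verts[tri[r, ], , drop = FALSE]
      n <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
      if (sum(n * (colMeans(p) - cent[bf$cell, ])) < 0)
        tri[r, c(1, 2)] <- tri[r, c(2, 1)]
    }
    patches[[bf$patch]] <- rbind(patches[[bf$patch]], tri)
  }
  list(vertices = verts, tets = tets, patches = patches)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## ---------------------------------------------------------------------------

#' Specification of an idealized truncated-ellipsoid chamber wall
#'
#' Thick-walled prolate spheroid, truncated by the plane `z = trunc_height`
#' (the valve plane); the apex is at `z = -c`.  Endo/epi surfaces are
#' concentric spheroids with short-axis (equatorial) radii `a_*` and
#' long-axis (apex--base) radii `c_*`.
#'
#' @param chamber chamber name (default "lv")
#' @param a_endo,c_endo endocardial short/long-axis radii (mm)
#' @param a_epi,c_epi epicardial short/long-axis radii (mm)
#' @param trunc_height z-coordinate of the truncation (valve) plane (mm),
#'   must satisfy `|trunc_height| < c_endo`
#' @param target_edge target element edge length (mm); must be smaller than
#'   the wall thickness
#' @param n_trans,n_long,n_circ optional explicit subdivision counts
#'   (transmural layers, longitudinal rings, circumferential divisions)
#' @return object of class `ellipsoid_spec`
#' @export
ellipsoid_spec <- function(chamber = "lv", a_endo = 25, c_endo = 55,
                           a_epi = 35, c_epi = 65, trunc_height = 5,
                           target_edge = 8,
                           n_trans = NULL, n_long = NULL, n_circ = NULL) {
  if (!(a_epi > a_endo && c_epi > c_endo))
    stop("invalid ellipsoid spec: epicardial radii must exceed endocardial radii")
  if (abs(trunc_height) >= c_endo)
    stop("truncation plane must intersect the endocardial spheroid")
  if (target_edge <= 0) stop("target_edge must be positive")
  structure(list(chamber = chamber, a_endo = a_endo, c_endo = c_endo,
                 a_epi = a_epi, c_epi = c_epi, trunc_height = trunc_height,
                 target_edge = target_edge, n_trans = n_trans,
                 n_long = n_long, n_circ = n_circ),
            class = "ellipsoid_spec")
}

#' Generate a truncated thick-walled ellipsoid mesh
#'
#' Structured parametric tetrahedral mesh of a truncated prolate-spheroid
#' chamber wall with patches `"endo"`, `"epi"` and `"base"` (the flat
#' truncation annulus), and the truncation plane registered as the chamber's
#' cap plane for cavity-volume computation.
#'
#' @param spec an [ellipsoid_spec()]
#' @return a [labeled_mesh()]
#' @export
make_truncated_ellipsoid_mesh <- function(spec) {
  stopifnot(inherits(spec, "ellipsoid_spec"))
  wall <- min(spec$a_epi - spec$a_endo, spec$c_epi - spec$c_endo)
  if (spec$target_edge >= 2.5 * wall && is.null(spec$n_trans))
    stop("target edge length too coarse for the wall thickness")
  amid <- (spec$a_endo + spec$a_epi) / 2
  cmid <- (spec$c_endo + spec$c_epi) / 2
  # meridian arc length of the mid-surface, apex to truncation plane
  ut_mid <- acos(min(spec$trunc_height / cmid, 1 - 1e-12))
  uu <- seq(ut_mid, pi, length.out = 200)
  dx <- diff(amid * sin(uu)); dz <- diff(cmid * cos(uu))
  arc <- sum(sqrt(dx^2 + dz^2))
  n_s <- if (!is.null(spec$n_trans)) spec$n_trans else
    max(1L, round(wall / spec$target_edge))
  n_v <- if (!is.null(spec$n_long)) spec$n_long else
    max(3L, round(arc / spec$target_edge))
  n_p <- if (!is.null(spec$n_circ)) spec$n_circ else
    max(8L, round(2 * pi * amid / spec$target_edge))

  # structured vertices: layer i in 0..n_s, rings j in 0..n_v-1, apex j=n_v
  per_layer <- n_v * n_p + 1L
  nv <- (n_s + 1L) * per_layer
  verts <- matrix(0, nv, 3)
  vid <- function(i, j, k) {
    # k wraps circumferentially; j = n_v means apex
    if (j == n_v) return(i * per_layer + n_v * n_p + 1L)
    i * per_layer + j * n_p + ((k - 1L) %% n_p) + 1L
  }
  phis <- 2 * pi * (0:(n_p - 1)) / n_p
  for (i in 0:n_s) {
    s <- i / n_s
    a <- spec$a_endo + s * (spec$a_epi - spec$a_endo)
    cc <- spec$c_endo + s * (spec$c_epi - spec$c_endo)
    ut <- acos(spec$trunc_height / cc)
    for (j in 0:(n_v - 1)) {
      u <- ut + (j / n_v) * (pi - ut)
      idx <- i * per_layer + j * n_p + seq_len(n_p)
      verts[idx, ] <- cbind(a * sin(u) * cos(phis), a * sin(u) * sin(phis),
                            cc * cos(u))
    }
    verts[i * per_layer + n_v * n_p + 1L, ] <- c(0, 0, -cc)
  }

  cells <- list(); bfaces <- list(); ci <- 0L
  for (i in 1:n_s) {            # layer between surfaces i-1 and i
    for (j in 1:(n_v - 1)) {    # hex ring between rings j-1 and j
      for (k in 1:n_p) {
        ci <- ci + 1L
        cells[[ci]] <- c(vid(i - 1, j - 1, k), vid(i - 1, j - 1, k + 1),
                         vid(i - 1, j, k + 1), vid(i - 1, j, k),
                         vid(i, j - 1, k), vid(i, j - 1, k + 1),
                         vid(i, j, k + 1), vid(i, j, k))
        if (i == 1L)
          bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 1L, patch = "endo")
        if (i == n_s)
          bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 2L, patch = "epi")
        if (j == 1L)
          bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 3L, patch = "base")
      }
    }
    for (k in 1:n_p) {          # apex wedges
      ci <- ci + 1L
      cells[[ci]] <- c(vid(i - 1, n_v - 1, k), vid(i - 1, n_v - 1, k + 1),
                       vid(i - 1, n_v, 1),
                       vid(i, n_v - 1, k), vid(i, n_v - 1, k + 1),
                       vid(i, n_v, 1))
      if (i == 1L)
        bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 1L, patch = "endo")
      if (i == n_s)
        bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 2L, patch = "epi")
    }
  }
  built <- cells_to_tets(verts, cells, bfaces)
  cap <- list(list(point = c(0, 0, spec$trunc_height), normal = c(0, 0, 1)))
  names(cap) <- spec$chamber
  endo <- stats::setNames("endo", spec$chamber)
  labeled_mesh(built$vertices, built$tets, built$patches,
               cap_planes = cap, endo_patches = endo)
}

#' Generate a structured box mesh
#'
#' Axis-aligned box `[0,lx] x [0,ly] x [0,lz]` with boundary patches
#' `xmin/xmax/ymin/ymax/zmin/zmax`, used for patch tests and verification
#' problems.
#'
#' @param nx,ny,nz cell counts per direction
#' @param lx,ly,lz box side lengths (mm)
#' @return a [labeled_mesh()]
#' @export
make_box_mesh <- function(nx = 1, ny = 1, nz = 1, lx = 1, ly = 1, lz = 1) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  vid <- function(i, j, k) ((k - 1) * (ny + 1) + (j - 1)) * (nx + 1) + i
  verts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(verts) <- NULL
  cells <- list(); bfaces <- list(); ci <- 0L
  for (k in 1:nz) for (j in 1:ny) for (i in 1:nx) {
    ci <- ci + 1L
    cells[[ci]] <- c(vid(i, j, k), vid(i + 1, j, k), vid(i + 1, j + 1, k),
                     vid(i, j + 1, k), vid(i, j, k + 1), vid(i + 1, j, k + 1),
                     vid(i + 1, j + 1, k + 1), vid(i, j + 1, k + 1))
    if (k == 1) bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 1L, patch = "zmin")
    if (k == nz) bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 2L, patch = "zmax")
    if (j == 1) bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 3L, patch = "ymin")
    if (i == nx) bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 4L, patch = "xmax")
    if (j == ny) bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 5L, patch = "ymax")
    if (i == 1) bfaces[[length(bfaces) + 1L]] <- list(cell = ci, face = 6L, patch = "xmin")
  }
  built <- cells_to_tets(verts, cells, bfaces)
  labeled_mesh(built$vertices, built$tets, built$patches)
}

#' Nodes lying on a surface patch
#'
#' @param mesh a [labeled_mesh()]
#' @param patch patch name
#' @return sorted integer vector of vertex indices
#' @export
patch_nodes <- function(mesh, patch) {
  if (!patch %in% names(mesh$surface_patches))
    stop("mesh has no patch named '", patch, "'")
  sort(unique(as.vector(mesh$surface_patches[[patch]])))
}

#' Chamber cavity volume by the divergence theorem
#'
#' Closes the (possibly deformed) endocardial surface with a flat cap fanned
#' from the centroid of its boundary rim and returns
#' \eqn{V = \tfrac13 |\oint x \cdot n \, dS|} in mL.
#'
#' @param mesh a [labeled_mesh()]
#' @param chamber chamber name (must appear in `mesh$endo_patches`)
#' @param u optional nodal displacement vector (length 3N, interleaved) or
#'   N x 3 matrix; default reference configuration
#' @return cavity volume (mL)
#' @export
cavity_volume <- function(mesh, chamber = names(mesh$endo_patches)[1], u = NULL) {
  if (is.null(chamber) || is.na(chamber) ||
      !chamber %in% names(mesh$endo_patches))
    stop("unknown chamber '", chamber, "'")
  patch <- mesh$endo_patches[[chamber]]
  tris <- mesh$surface_patches[[patch]]
  verts <- mesh$vertices
  if (!is.null(u)) {
    if (is.matrix(u)) verts <- verts + u
    else verts <- verts + matrix(u, ncol = 3, byrow = TRUE)
  }
  closed_surface_volume_mm3(verts, tris) / 1000
}

# volume enclosed by an oriented triangle surface; open rims are closed by
# coning boundary directed edges to the rim centroid
closed_surface_volume_mm3 <- function(verts, tris) {
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  tab <- table(key)
  open_key <- names(tab)[tab == 1L]
  if (length(open_key)) {
    bnd <- edges[key %in% open_key, , drop = FALSE]
    if (nrow(bnd) < 3) stop("open surface without a closable rim")
    ctr <- colMeans(verts[unique(as.vector(bnd)), , drop = FALSE])
    verts <- rbind(verts, ctr)
    cap <- cbind(bnd[, 2], bnd[, 1], nrow(verts))
    tris <- rbind(tris, cap)
  } else if (any(tab > 2L)) {
    stop("non-manifold surface")
  }
  abs(surface_signed_volume(verts, tris))
}

# per-element P1 shape-function gradients and volumes
tet_grads <- function(mesh) {
  M <- nrow(mesh$tets)
  vol <- tet_signed_volumes(mesh$vertices, mesh$tets)
  G <- array(0, c(M, 4, 3))
  v <- mesh$vertices
  t1 <- mesh$tets
  for (e in seq_len(M)) {
    X <- v[t1[e, ], ]
    Dm <- t(X[2:4, ]) - X[1, ]          # columns X_a - X_1
    DmInv <- solve(Dm)
    G[e, 2:4, ] <- DmInv                 # rows of Dm^-1
    G[e, 1, ] <- -colSums(DmInv)
  }
  list(vol = vol, G = G)
}
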