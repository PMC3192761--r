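#' Triangle surface mesh
#'
#' Vertices are in physical units (voxel index times spacing; micrometres
#' when the source volume carries physical spacing). Faces are triangles of
#' 1-based vertex indices with consistent outward orientation.
#'
#' @param vertices `n x 3` numeric matrix `(x, y, z)`.
#' @param faces `m x 3` integer matrix of vertex indices.
#' @param label list with `id`, `name`, `color` of the source label
#'   (optional).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, label = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("face indices out of range")
    }
    a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    if (any(rowSums(cr^2) == 0)) stop("degenerate (zero-area) triangle")
  }
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$label)) paste0(" [", x$label$name, "]") else ""))
  invisible(x)
}

# --- tetrahedral isosurface extraction -------------------------------------
#
# The binary mask is polygonised at iso-level 0.5 by splitting every grid
# cell into the six Kuhn tetrahedra (translation-compatible: neighbouring
# cells share face diagonals) and emitting the linear isosurface inside each
# tetrahedron. On binary data every isosurface vertex is an edge midpoint,
# there are no ambiguous configurations, the surface is watertight by
# construction, and no smoothing of any kind is applied.

mt_cache <- new.env(parent = emptyenv())

# corners of the unit cell, id n = bx + 2*by + 4*bz + 1, coords (bx, by, bz)
unit_corners <- function() {
  cbind(bx = c(0, 1, 0, 1, 0, 1, 0, 1),
        by = c(0, 0, 1, 1, 0, 0, 1, 1),
        bz = c(0, 0, 0, 0, 1, 1, 1, 1))
}

# the six Kuhn tetrahedra as rows of 4 corner ids
kuhn_tets <- function() {
  e <- diag(3)
  corners <- unit_corners()
  corner_id <- function(p) which(corners[, 1] == p[1] & corners[, 2] == p[2] &
                                 corners[, 3] == p[3])
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  t(vapply(perms, function(p) {
    pts <- rbind(c(0, 0, 0), e[p[1], ], e[p[1], ] + e[p[2], ], c(1, 1, 1))
    apply(pts, 1L, corner_id)
  }, integer(4)))
}

# templates[[tet]][[case]]: (3*ntri) x 3 matrix of doubled midpoint coords
build_mt_templates <- function() {
  if (!is.null(mt_cache$templates)) return(mt_cache$templates)
  corners <- unit_corners()
  tets <- kuhn_tets()
  orient <- function(tri, inside_pts) {
    # tri: 3 x 3 coords; flip so the normal points away from the inside
    n <- c((tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
           (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
           (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
           (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
           (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
           (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
    ref <- colMeans(tri) - colMeans(inside_pts)
    if (sum(n * ref) < 0) tri[c(1, 3, 2), , drop = FALSE] else tri
  }
  templates <- vector("list", nrow(tets))
  for (t in seq_len(nrow(tets))) {
    ids <- tets[t, ]
    pts <- corners[ids, , drop = FALSE] * 2  # doubled, so midpoints stay integer
    per_case <- vector("list", 14L)
    for (cs in 1:14) {
      inside <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0L)
      outside <- setdiff(1:4, inside)
      inside_pts <- pts[inside, , drop = FALSE]
      mid <- function(i, j) (pts[i, ] + pts[j, ]) / 2
      tris <- list()
      if (length(inside) == 1L || length(inside) == 3L) {
        lone <- if (length(inside) == 1L) inside else outside
        rest <- setdiff(1:4, lone)
        tris[[1]] <- rbind(mid(lone, rest[1]), mid(lone, rest[2]),
                           mid(lone, rest[3]))
      } else {  # 2 inside, 2 outside: quad split into two triangles
        i1 <- inside[1]; i2 <- inside[2]
        o1 <- outside[1]; o2 <- outside[2]
        q <- rbind(mid(i1, o1), mid(i1, o2), mid(i2, o2), mid(i2, o1))
        tris[[1]] <- q[c(1, 2, 3), , drop = FALSE]
        tris[[2]] <- q[c(1, 3, 4), , drop = FALSE]
      }
      per_case[[cs]] <- do.call(rbind, lapply(tris, orient, inside_pts))
    }
    templates[[t]] <- per_case
  }
  mt_cache$templates <- templates
  templates
}

#' Isosurface mesh of one label ("surface generation without smoothing")
#'
#' Extracts the 0.5-isosurface of the binary mask of `id` as a triangle mesh
#' using a tetrahedral marching-cubes decomposition (six Kuhn tetrahedra per
#' cell). No vertex smoothing or decimation is performed anywhere in the
#' pipeline, so planar mask faces stay exactly planar. Vertex coordinates are
#' voxel indices scaled by the volume spacing (physical micrometres when
#' available), so meshes of different labels overlay in one space; under the
#' protocol spacing `(1, 1, 10)` the z-extent is stretched tenfold.
#'
#' @param volume a [label_volume] (or a logical/0-1 3D array).
#' @param id label id (ignored for plain mask input).
#' @return a [surface_mesh] (empty, with a warning, if the label has no
#'   voxels).
#' @export
marching_surface <- function(volume, id = 1L) {
  if (inherits(volume, "label_volume")) {
    mask <- volume$labels == as.integer(id)
    sp <- if (!is.null(volume$physical_spacing_um)) {
      volume$physical_spacing_um
    } else volume$spacing
    lab <- volume$table[[as.character(id)]]
    label <- if (is.null(lab)) NULL else {
      list(id = as.integer(id), name = lab$name, color = lab$color)
    }
  } else {
    mask <- volume > 0
    sp <- c(1, 1, 1)
    label <- NULL
  }
  if (!any(mask)) {
    warning("label has no voxels; returning empty mesh")
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), label))
  }
  d <- dim(mask)
  P <- array(0L, d + 2L)
  P[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  nc <- d + 1L  # cells per axis (between padded voxel centers)
  corners <- unit_corners()
  # corner value vectors over all cells
  cv <- vector("list", 8L)
  for (n in 1:8) {
    b <- corners[n, ]
    cv[[n]] <- as.vector(P[(1:nc[1]) + b[2], (1:nc[2]) + b[1],
                           (1:nc[3]) + b[3]])
  }
  code <- cv[[1]]
  for (n in 2:8) code <- code + cv[[n]] * 2L^(n - 1L)
  mixed <- which(code > 0L & code < 255L)
  if (!length(mixed)) {
    warning("mask has no surface cells; returning empty mesh")
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), label))
  }
  ci <- ((mixed - 1L) %% nc[1]) + 1L
  cj <- (((mixed - 1L) %/% nc[1]) %% nc[2]) + 1L
  ck <- ((mixed - 1L) %/% (nc[1] * nc[2])) + 1L
  # doubled cell-origin coordinates in unpadded 0-based voxel units
  ox2 <- 2L * (cj - 2L); oy2 <- 2L * (ci - 2L); oz2 <- 2L * (ck - 2L)
  cvm <- lapply(cv, function(v) v[mixed])
  tets <- kuhn_tets()
  templates <- build_mt_templates()
  VX <- list(); VY <- list(); VZ <- list()
  for (t in seq_len(nrow(tets))) {
    ids <- tets[t, ]
    case <- cvm[[ids[1]]] + 2L * cvm[[ids[2]]] + 4L * cvm[[ids[3]]] +
            8L * cvm[[ids[4]]]
    for (cs in 1:14) {
      idx <- which(case == cs)
      if (!length(idx)) next
      tmpl <- templates[[t]][[cs]]
      nvr <- nrow(tmpl)
      VX[[length(VX) + 1L]] <- rep(tmpl[, 1], times = length(idx)) +
        rep(ox2[idx], each = nvr)
      VY[[length(VY) + 1L]] <- rep(tmpl[, 2], times = length(idx)) +
        rep(oy2[idx], each = nvr)
      VZ[[length(VZ) + 1L]] <- rep(tmpl[, 3], times = length(idx)) +
        rep(oz2[idx], each = nvr)
    }
  }
  vx <- unlist(VX); vy <- unlist(VY); vz <- unlist(VZ)
  # deduplicate vertices (doubled coordinates are small exact integers)
  K <- 2 * max(d) + 5
  key <- (vx + 2) + (vy + 2) * K + (vz + 2) * K * K
  first <- !duplicated(key)
  vid <- match(key, key[first])
  verts <- cbind(vx[first] / 2 * sp[1], vy[first] / 2 * sp[2],
                 vz[first] / 2 * sp[3])
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces, label)
}

face_edge_keys <- function(faces, n_vertices) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  lo + (hi - 1) * as.numeric(n_vertices)
}

#' Quantitative mesh summary
#'
#' Reports triangle count, total surface area, enclosed volume (signed
#' tetrahedron sum — only meaningful, and only reported, when the mesh is
#' closed), connected component count (by shared-edge face adjacency),
#' closedness (every edge borders exactly two faces) and the Euler
#' characteristic `V - E + F`.
#'
#' @param mesh a [surface_mesh].
#' @return list with `n_triangles`, `area`, `volume` (`NA` when open),
#'   `n_components`, `closed`, `euler`.
#' @export
mesh_measures <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  f <- mesh$faces
  v <- mesh$vertices
  if (nrow(f) == 0L) {
    return(list(n_triangles = 0L, area = 0, volume = 0, n_components = 0L,
                closed = TRUE, euler = NA_integer_))
  }
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  a <- p2 - p1
  b <- p3 - p1
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  ek <- face_edge_keys(f, nrow(v))
  inc <- table(ek)
  closed <- all(inc == 2L)
  volume <- if (closed) {
    sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
        p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
        p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  } else NA_real_
  # face adjacency graph: faces sharing an edge are connected
  face_id <- rep(seq_len(nrow(f)), 3L)
  ord <- order(ek)
  ek_s <- ek[ord]
  fi_s <- face_id[ord]
  same <- which(ek_s[-1] == ek_s[-length(ek_s)])
  g <- igraph::make_graph(as.vector(rbind(fi_s[same], fi_s[same + 1L])),
                          n = nrow(f), directed = FALSE)
  n_comp <- igraph::components(g)$no
  euler <- nrow(v) - length(inc) + nrow(f)
  list(n_triangles = nrow(f), area = area, volume = volume,
       n_components = n_comp, closed = closed, euler = as.integer(euler))
}

#' Export a mesh to PLY, OBJ or STL
#'
#' PLY carries the label color as per-vertex color; OBJ uses 1-based face
#' indices per the standard; STL is written as ASCII facets. `binary = TRUE`
#' selects binary little-endian PLY.
#'
#' @param mesh a [surface_mesh].
#' @param path output file.
#' @param format `"ply"`, `"obj"` or `"stl"` (default from the extension).
#' @param binary write binary little-endian PLY instead of ASCII.
#' @return invisibly, `path`.
#' @export
export_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("ply", "obj", "stl")) stop("unknown format: ", format)
  v <- mesh$vertices
  f <- mesh$faces
  col <- if (!is.null(mesh$label)) as.integer(mesh$label$color)
         else c(200L, 200L, 200L)
  if (format == "ply") {
    hdr <- c("ply",
             if (binary) "format binary_little_endian 1.0"
             else "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             "property uchar red", "property uchar green",
             "property uchar blue",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices",
             "end_header")
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(hdr, con, sep = "\n")
      for (i in seq_len(nrow(v))) {
        writeBin(as.numeric(v[i, ]), con, size = 4L, endian = "little")
        writeBin(as.raw(col), con)
      }
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
      }
    } else {
      vl <- if (nrow(v)) sprintf("%.9g %.9g %.9g %d %d %d",
                                 v[, 1], v[, 2], v[, 3],
                                 col[1], col[2], col[3]) else character(0)
      fl <- if (nrow(f)) sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L,
                                 f[, 3] - 1L) else character(0)
      writeLines(c(hdr, vl, fl), path)
    }
  } else if (format == "obj") {
    nm <- if (!is.null(mesh$label)) mesh$label$name else "mesh"
    vl <- if (nrow(v)) sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
          else character(0)
    fl <- if (nrow(f)) sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
          else character(0)
    writeLines(c(sprintf("o %s", nm), vl, fl), path)
  } else {  # stl (ASCII)
    lines <- c("solid mesh")
    if (nrow(f)) {
      p1 <- v[f[, 1], , drop = FALSE]
      p2 <- v[f[, 2], , drop = FALSE]
      p3 <- v[f[, 3], , drop = FALSE]
      a <- p2 - p1; b <- p3 - p1
      n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
      n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
      for (i in seq_len(nrow(f))) {
        lines <- c(lines,
          sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
          "  outer loop",
          sprintf("    vertex %.9g %.9g %.9g", p1[i, 1], p1[i, 2], p1[i, 3]),
          sprintf("    vertex %.9g %.9g %.9g", p2[i, 1], p2[i, 2], p2[i, 3]),
          sprintf("    vertex %.9g %.9g %.9g", p3[i, 1], p3[i, 2], p3[i, 3]),
          "  endloop", "endfacet")
      }
    }
    writeLines(c(lines, "endsolid mesh"), path)
  }
  invisible(path)
}

#' Read a mesh written by [export_mesh]
#'
#' Supports ASCII and binary little-endian PLY (with or without vertex
#' color) and OBJ.
#' @param path mesh file.
#' @return a [surface_mesh].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    lines <- readLines(path)
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    v <- if (length(vl)) {
      do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
        as.numeric(p[2:4])))
    } else matrix(0, 0, 3)
    f <- if (length(fl)) {
      do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
        as.integer(sub("/.*", "", p[2:4]))))
    } else matrix(0L, 0, 3)
    return(surface_mesh(v, f))
  }
  if (ext != "ply") stop("unknown mesh format: ", ext)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)))
  has_color <- any(grepl("property uchar red", hdr))
  binary <- any(grepl("binary_little_endian", hdr))
  if (binary) {
    v <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      v[i, ] <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
      if (has_color) readBin(con, "raw", n = 3L)
    }
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      readBin(con, "raw", n = 1L)
      f[i, ] <- readBin(con, "integer", n = 3L, size = 4L,
                        endian = "little") + 1L
    }
  } else {
    body <- readLines(con)
    v <- if (nv) {
      do.call(rbind, lapply(strsplit(body[seq_len(nv)], "\\s+"), function(p)
        as.numeric(p[1:3])))
    } else matrix(0, 0, 3)
    f <- if (nf) {
      do.call(rbind, lapply(strsplit(body[nv + seq_len(nf)], "\\s+"),
                            function(p) as.integer(p[2:4]) + 1L))
    } else matrix(0L, 0, 3)
  }
  surface_mesh(v, f)
}
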