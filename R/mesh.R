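#' Triangulated cortical surface meshes
#'
#' A \code{cortical_mesh} is a closed triangulated 2-manifold holding the
#' pial vertex set on which thickness is measured. Vertices carry a
#' hemisphere tag; all coordinates are in millimetres.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @param hemisphere Character vector, one of \code{"left"}/\code{"right"}
#'   per vertex.
#' @return An object of class \code{cortical_mesh}.
#' @export
cortical_mesh <- function(vertices, faces, hemisphere) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("'vertices' must be n x 3", call. = FALSE)
  if (ncol(faces) != 3L) stop("'faces' must be m x 3", call. = FALSE)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) == 1L) hemisphere <- rep(hemisphere, nrow(vertices))
  if (length(hemisphere) != nrow(vertices))
    stop("'hemisphere' must have one tag per vertex", call. = FALSE)
  structure(list(vertices = vertices, faces = faces, hemisphere = hemisphere),
            class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("cortical_mesh: %d vertices, %d faces (%s)\n",
              nrow(x$vertices), nrow(x$faces),
              paste(sprintf("%s: %d", names(table(x$hemisphere)),
                            as.integer(table(x$hemisphere))), collapse = ", ")))
  invisible(x)
}

## Unit icosahedron, the seed of all sphere meshes used here.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

## Loop-style midpoint subdivision, vertices re-projected to the unit sphere.
subdivide_sphere <- function(vertices, faces) {
  nv <- nrow(vertices)
  e1 <- pmin(faces[, 1], faces[, 2]); e2 <- pmax(faces[, 1], faces[, 2])
  f1 <- pmin(faces[, 2], faces[, 3]); f2 <- pmax(faces[, 2], faces[, 3])
  g1 <- pmin(faces[, 3], faces[, 1]); g2 <- pmax(faces[, 3], faces[, 1])
  keys <- c(paste(e1, e2), paste(f1, f2), paste(g1, g2))
  uk <- unique(keys)
  mid_id <- match(keys, uk) + nv
  pairs <- do.call(rbind, strsplit(uk, " "))
  a <- as.integer(pairs[, 1]); b <- as.integer(pairs[, 2])
  mids <- (vertices[a, , drop = FALSE] + vertices[b, , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nf <- nrow(faces)
  mab <- mid_id[seq_len(nf)]
  mbc <- mid_id[nf + seq_len(nf)]
  mca <- mid_id[2L * nf + seq_len(nf)]
  newf <- rbind(cbind(faces[, 1], mab, mca),
                cbind(faces[, 2], mbc, mab),
                cbind(faces[, 3], mca, mbc),
                cbind(mab, mbc, mca))
  list(vertices = rbind(vertices, mids), faces = newf)
}

#' Geodesic sphere mesh
#'
#' Icosahedron subdivided \code{level} times and scaled; a near-uniform
#' closed 2-manifold with \code{10 * 4^level + 2} vertices.
#'
#' @param level Subdivision level (non-negative integer).
#' @param radius Sphere radius in mm.
#' @param center Numeric length-3 center (mm).
#' @param hemisphere Hemisphere tag for all vertices.
#' @return A \code{cortical_mesh}.
#' @export
icosphere <- function(level = 3L, radius = 70, center = c(0, 0, 0),
                      hemisphere = "left") {
  m <- icosahedron()
  for (i in seq_len(level)) m <- subdivide_sphere(m$vertices, m$faces)
  v <- m$vertices * radius
  v <- sweep(v, 2, center, "+")
  cortical_mesh(v, m$faces, hemisphere)
}

#' Edge list of a mesh
#' @param mesh A \code{cortical_mesh}.
#' @return Integer e x 2 matrix of unique undirected edges.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Per-vertex barycentric area
#'
#' One third of the total area of the triangles incident to each vertex;
#' sums to the mesh surface area.
#'
#' @param mesh A \code{cortical_mesh}.
#' @return Numeric vector of areas (mm^2).
#' @export
mesh_vertex_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  tri_area <- sqrt(rowSums(cr^2)) / 2
  areas <- numeric(nrow(v))
  for (k in 1:3) {
    s <- tapply(rep(tri_area / 3, 1), f[, k], sum)
    areas[as.integer(names(s))] <- areas[as.integer(names(s))] + s
  }
  areas
}

#' Sparse vertex adjacency matrix
#' @param mesh A \code{cortical_mesh}.
#' @return A symmetric sparse 0/1 \code{Matrix}.
#' @export
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

#' Mean edge length of a mesh
#' @param mesh A \code{cortical_mesh}.
#' @return Mean Euclidean edge length (mm).
#' @export
mesh_mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Check that a mesh is a closed connected 2-manifold
#'
#' Every edge must belong to exactly two faces and the edge graph must be
#' connected within each hemisphere. Defective meshes are rejected rather
#' than repaired.
#'
#' @param mesh A \code{cortical_mesh}.
#' @return \code{TRUE} invisibly; error otherwise.
#' @export
validate_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L))
    stop("mesh is not a closed 2-manifold: ", sum(cnt != 2L),
         " edges not shared by exactly 2 faces", call. = FALSE)
  for (h in unique(mesh$hemisphere)) {
    vids <- which(mesh$hemisphere == h)
    ed <- mesh_edges(mesh)
    ed <- ed[ed[, 1] %in% vids & ed[, 2] %in% vids, , drop = FALSE]
    g <- igraph::graph_from_edgelist(apply(ed, 2, match, vids), directed = FALSE)
    if (igraph::vcount(g) < length(vids) ||
        igraph::components(g)$no != 1L)
      stop("hemisphere '", h, "' edge graph is not connected", call. = FALSE)
  }
  invisible(TRUE)
}
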