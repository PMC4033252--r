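#' Anatomical label atlas for a mesh
#'
#' Assigns exactly one anatomical label to every vertex. Labels
#' \code{1..n_labels_per_hemisphere} belong to the left hemisphere and
#' the following \code{n_labels_per_hemisphere} to the right.
#'
#' @param label_of_vertex Integer label id per vertex.
#' @param n_labels_per_hemisphere Number of labels in each hemisphere.
#' @return An object of class \code{label_atlas}.
#' @export
label_atlas <- function(label_of_vertex, n_labels_per_hemisphere) {
  label_of_vertex <- as.integer(label_of_vertex)
  if (anyNA(label_of_vertex)) stop("every vertex needs a label", call. = FALSE)
  tab <- tabulate(label_of_vertex, nbins = max(label_of_vertex))
  if (any(tab == 0L)) stop("empty label in atlas", call. = FALSE)
  structure(list(label_of_vertex = label_of_vertex,
                 n_labels_per_hemisphere = as.integer(n_labels_per_hemisphere)),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("label_atlas: %d vertices, %d labels (%d per hemisphere)\n",
              length(x$label_of_vertex), length(unique(x$label_of_vertex)),
              x$n_labels_per_hemisphere))
  invisible(x)
}

## Partition one hemisphere's vertices into k spatially contiguous,
## approximately equal labels by k-means on vertex coordinates. Retries
## with fresh (seeded) starts until no label is smaller than min_size.
partition_hemisphere <- function(vertices, k, min_size, seed) {
  if (k == 1L) return(rep(1L, nrow(vertices)))
  with_seed(seed, {
    for (attempt in 1:25) {
      km <- suppressWarnings(stats::kmeans(vertices, centers = k, nstart = 10, iter.max = 200))
      if (min(km$size) >= min_size) break
    }
    if (min(km$size) < min_size)
      stop("could not partition hemisphere into labels of >= ", min_size,
           " vertices; increase vertices_per_label", call. = FALSE)
    ## deterministic label order: sort cluster ids by centroid coordinates
    ord <- order(km$centers[, 1], km$centers[, 2], km$centers[, 3])
    match(km$cluster, ord)
  })
}

#' Synthetic two-hemisphere atlas mesh
#'
#' Builds two disjoint geodesic-sphere meshes (left and right hemisphere)
#' and partitions each into \code{n_labels} spatially contiguous anatomical
#' labels of approximately equal size, emulating a standard 34-label
#' cortical parcellation per hemisphere. Vertex correspondence across
#' subjects is by construction (all subjects share this mesh).
#'
#' @param vertices_per_label Target vertex count per label (>= 10 so each
#'   label can host 10 patches).
#' @param n_labels Labels per hemisphere (default 34).
#' @param radius Sphere radius in mm (default 70, of the order of a human
#'   hemisphere).
#' @param seed Integer seed controlling the label partition.
#' @return A list with components \code{mesh} (\code{cortical_mesh}) and
#'   \code{atlas} (\code{label_atlas}).
#' @export
make_atlas_mesh <- function(vertices_per_label = 30L, n_labels = 34L,
                            radius = 70, seed = 1L) {
  if (vertices_per_label < 1L) stop("'vertices_per_label' must be >= 1", call. = FALSE)
  if (vertices_per_label < 10L)
    stop("'vertices_per_label' must be >= 10 so each label can host 10 patches",
         call. = FALSE)
  if (n_labels < 1L) stop("'n_labels' must be >= 1", call. = FALSE)
  need <- vertices_per_label * n_labels
  level <- 0L
  while (10 * 4^level + 2 < need) level <- level + 1L
  offset <- c(1.2 * radius, 0, 0)
  left <- icosphere(level, radius, center = -offset, hemisphere = "left")
  right <- icosphere(level, radius, center = offset, hemisphere = "right")
  nv <- nrow(left$vertices)
  mesh <- cortical_mesh(rbind(left$vertices, right$vertices),
                        rbind(left$faces, right$faces + nv),
                        c(left$hemisphere, right$hemisphere))
  min_size <- min(10L, vertices_per_label)
  lab_l <- partition_hemisphere(left$vertices, n_labels, min_size,
                                derive_seed(seed, 1L))
  lab_r <- partition_hemisphere(right$vertices, n_labels, min_size,
                                derive_seed(seed, 2L))
  atlas <- label_atlas(c(lab_l, lab_r + n_labels), n_labels)
  list(mesh = mesh, atlas = atlas)
}
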