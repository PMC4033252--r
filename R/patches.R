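#' Subdivide anatomical labels into spatial patches
#'
#' Partitions each anatomical label into \code{k} spatially compact patches
#' by k-means clustering of the label's vertex coordinates (k is reduced to
#' the label's vertex count where necessary). With the standard 34-label
#' parcellation per hemisphere and \code{k = 10} this yields 680 patches.
#' Patch ids are globally numbered in (label id, patch index) order; patch
#' indices within a label follow the lexicographic order of the cluster
#' centroids, so the column order of downstream feature matrices is stable.
#'
#' @param mesh A \code{cortical_mesh}.
#' @param atlas Matching \code{label_atlas}.
#' @param k Target patches per label (default 10).
#' @param seed Integer seed; the clustering is deterministic given it.
#' @return An object of class \code{patch_definition}: fields
#'   \code{patch_of_vertex}, \code{n_patches}, \code{patch_label} (label id
#'   of each patch) and \code{provenance}.
#' @export
make_patches <- function(mesh, atlas, k = 10L, seed = 1L) {
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  labels <- atlas$label_of_vertex
  if (length(labels) != nrow(mesh$vertices))
    stop("atlas does not match mesh", call. = FALSE)
  lab_ids <- sort(unique(labels))
  patch_of_vertex <- integer(length(labels))
  patch_label <- integer(0)
  next_id <- 0L
  for (li in seq_along(lab_ids)) {
    lab <- lab_ids[li]
    vids <- which(labels == lab)
    if (length(vids) == 0L) stop("empty label ", lab, call. = FALSE)
    keff <- min(k, length(vids))
    if (keff == 1L) {
      cl <- rep(1L, length(vids))
    } else if (keff == length(vids)) {
      cl <- seq_along(vids)   # one singleton patch per vertex
    } else {
      co <- mesh$vertices[vids, , drop = FALSE]
      cl <- with_seed(derive_seed(seed, li), {
        km <- suppressWarnings(stats::kmeans(co, centers = keff, nstart = 10, iter.max = 200))
        ord <- order(km$centers[, 1], km$centers[, 2], km$centers[, 3])
        match(km$cluster, ord)
      })
    }
    patch_of_vertex[vids] <- next_id + cl
    patch_label <- c(patch_label, rep(lab, keff))
    next_id <- next_id + keff
  }
  structure(list(patch_of_vertex = patch_of_vertex,
                 n_patches = next_id,
                 patch_label = patch_label,
                 patches_per_label = as.integer(k),
                 provenance = list(seed = seed)),
            class = "patch_definition")
}

#' @export
print.patch_definition <- function(x, ...) {
  sizes <- tabulate(x$patch_of_vertex, nbins = x$n_patches)
  cat(sprintf("patch_definition: %d patches over %d labels (target %d per label), sizes %d-%d vertices\n",
              x$n_patches, length(unique(x$patch_label)),
              x$patches_per_label, min(sizes), max(sizes)))
  invisible(x)
}

#' Patch-mean thickness features
#'
#' Entry (s, p) is the unweighted mean thickness of subject s over the
#' vertices of patch p, reducing a per-vertex map to one feature per patch.
#'
#' @param cohort A \code{cohort_dataset}.
#' @param patches A \code{patch_definition} on the same mesh.
#' @return A \code{feature_matrix}: subjects x patches numeric matrix with
#'   attributes \code{patch_ids} and \code{subject_ids}.
#' @export
patch_means <- function(cohort, patches) {
  X <- cohort$thickness
  if (ncol(X) != length(patches$patch_of_vertex))
    stop("cohort vertex count does not match patch definition", call. = FALSE)
  sizes <- tabulate(patches$patch_of_vertex, nbins = patches$n_patches)
  M <- Matrix::sparseMatrix(i = seq_along(patches$patch_of_vertex),
                            j = patches$patch_of_vertex,
                            x = 1 / sizes[patches$patch_of_vertex],
                            dims = c(ncol(X), patches$n_patches))
  F <- as.matrix(X %*% M)
  colnames(F) <- sprintf("L%02d.P%02d", patches$patch_label,
                         stats::ave(patches$patch_label,
                                    patches$patch_label, FUN = seq_along))
  rownames(F) <- sprintf("S%03d", seq_len(nrow(F)))
  structure(F, patch_ids = colnames(F), subject_ids = rownames(F),
            patch_sizes = sizes, class = c("feature_matrix", "matrix"))
}

#' Regress a binary covariate out of every feature
#'
#' Column-wise ordinary least squares on an intercept plus the indicator;
#' the returned features are the residuals, so the two covariate levels
#' have exactly equal feature means afterwards. Used to remove a scanner
#' factor before classification.
#'
#' @param features A \code{feature_matrix} (or plain matrix).
#' @param covariate Binary per-subject vector (two levels, each with >= 2
#'   subjects).
#' @return A \code{feature_matrix} of residuals (column means ~ 0).
#' @export
residualize <- function(features, covariate) {
  X <- unclass(features)
  lv <- unique(covariate)
  if (length(lv) < 2L) stop("covariate is constant across subjects", call. = FALSE)
  if (length(lv) > 2L) stop("covariate must be binary", call. = FALSE)
  if (min(table(covariate)) < 2L)
    stop("each covariate level needs >= 2 subjects", call. = FALSE)
  ind <- as.numeric(covariate == lv[2])
  qr_d <- qr(cbind(1, ind))
  R <- qr.resid(qr_d, X)
  attributes(R) <- attributes(features)
  R
}
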