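## On-disk conventions: mm units, right-handed coordinates, and 0-based
## vertex indices in every text format (declared in file headers).

#' Write a segmented volume as NIfTI
#'
#' Voxel codes are stored as integers; the isotropic spacing goes to
#' pixdim and the origin (mm of voxel (1,1,1)) into the sform translation.
#'
#' @param vol A \code{segmented_volume}.
#' @param file Output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, file) {
  im <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(im) <- rep(vol$spacing, 3)
  m <- diag(c(rep(vol$spacing, 3), 1))
  m[1:3, 4] <- vol$origin
  im <- RNifti::`sform<-`(im, structure(m, code = 2L))
  RNifti::writeNifti(im, file)
  invisible(file)
}

#' Read a segmented volume from NIfTI
#' @param file Path written by \code{\link{write_volume}}.
#' @return A \code{segmented_volume}.
#' @export
read_volume <- function(file) {
  im <- RNifti::readNifti(file)
  sp <- RNifti::pixdim(im)[1]
  xf <- RNifti::xform(im)
  origin <- if (!is.null(xf)) xf[1:3, 4] else c(0, 0, 0)
  grid <- array(as.integer(round(as.array(im))), dim = dim(im))
  segmented_volume(grid, sp, origin)
}

#' Write a mesh as ASCII PLY
#'
#' Vertices carry x/y/z (mm) plus a hemisphere flag (0 = left, 1 = right);
#' face indices are 0-based on disk.
#'
#' @param mesh A \code{cortical_mesh}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_mesh_ply <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("ply", "format ascii 1.0",
               "comment units mm, right-handed, indices 0-based",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               "property int hemisphere",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  hemi <- as.integer(mesh$hemisphere == "right")
  writeLines(sprintf("%.8g %.8g %.8g %d", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3], hemi), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(file)
}

#' Read an ASCII PLY mesh
#' @param file Path to an ASCII PLY written by \code{\link{write_mesh_ply}}
#'   (or any ASCII PLY with x/y/z vertex properties and triangular faces).
#' @return A \code{cortical_mesh}.
#' @export
read_mesh_ply <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 3L || lines[1] != "ply")
    stop("not a PLY file: ", file, call. = FALSE)
  if (!grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported (line 2: '", lines[2], "')", call. = FALSE)
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("PLY header missing end_header", call. = FALSE)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L)
    stop("PLY header must declare vertex and face elements", call. = FALSE)
  vprops <- sub("^property \\S+ ", "",
                grep("^property (?!list)", hdr[seq(grep("^element vertex", hdr),
                                                   grep("^element face", hdr))],
                     value = TRUE, perl = TRUE))
  vl <- lines[hdr_end + seq_len(nv)]
  vm <- matrix(as.numeric(unlist(strsplit(vl, " +"))), nrow = nv, byrow = TRUE)
  colnames(vm) <- vprops[seq_len(ncol(vm))]
  for (need in c("x", "y", "z"))
    if (!need %in% colnames(vm))
      stop("PLY vertex element lacks property '", need, "'", call. = FALSE)
  fl <- lines[hdr_end + nv + seq_len(nf)]
  fm <- matrix(as.integer(unlist(strsplit(fl, " +"))), nrow = nf, byrow = TRUE)
  if (any(fm[, 1] != 3L)) stop("only triangular faces are supported", call. = FALSE)
  hemi <- if ("hemisphere" %in% colnames(vm))
    ifelse(vm[, "hemisphere"] > 0, "right", "left") else "left"
  cortical_mesh(vm[, c("x", "y", "z"), drop = FALSE], fm[, 2:4] + 1L, hemi)
}

## small TSV helpers with named-column validation
read_tsv_checked <- function(file, required) {
  d <- utils::read.delim(file, sep = "\t", check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("file '", file, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d
}

write_tsv <- function(d, file) {
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a per-vertex thickness map as TSV
#' @param map A \code{thickness_map} (or numeric vector).
#' @param file Output path; columns \code{vertex_id} (0-based) and
#'   \code{value_mm}.
#' @return The path, invisibly.
#' @export
write_thickness_tsv <- function(map, file) {
  v <- if (inherits(map, "thickness_map")) map$values else as.numeric(map)
  write_tsv(data.frame(vertex_id = seq_along(v) - 1L, value_mm = v), file)
}

#' Read a per-vertex thickness map from TSV
#' @param file Path with columns \code{vertex_id}, \code{value_mm}.
#' @return A \code{thickness_map}.
#' @export
read_thickness_tsv <- function(file) {
  d <- read_tsv_checked(file, c("vertex_id", "value_mm"))
  thickness_map(d$value_mm[order(d$vertex_id)])
}

#' Write atlas labels as TSV
#' @param atlas A \code{label_atlas}.
#' @param file Output path; columns \code{vertex_id} (0-based),
#'   \code{label_id}.
#' @return The path, invisibly.
#' @export
write_labels_tsv <- function(atlas, file) {
  write_tsv(data.frame(vertex_id = seq_along(atlas$label_of_vertex) - 1L,
                       label_id = atlas$label_of_vertex), file)
}

#' Read atlas labels from TSV
#' @param file Path with columns \code{vertex_id}, \code{label_id}.
#' @param n_labels_per_hemisphere Label count per hemisphere.
#' @return A \code{label_atlas}.
#' @export
read_labels_tsv <- function(file, n_labels_per_hemisphere) {
  d <- read_tsv_checked(file, c("vertex_id", "label_id"))
  label_atlas(d$label_id[order(d$vertex_id)], n_labels_per_hemisphere)
}

#' Write a patch definition as TSV
#' @param patches A \code{patch_definition}.
#' @param atlas The matching \code{label_atlas}.
#' @param file Output path; columns \code{vertex_id} (0-based),
#'   \code{label_id}, \code{patch_id} (0-based).
#' @return The path, invisibly.
#' @export
write_patches_tsv <- function(patches, atlas, file) {
  write_tsv(data.frame(vertex_id = seq_along(patches$patch_of_vertex) - 1L,
                       label_id = atlas$label_of_vertex,
                       patch_id = patches$patch_of_vertex - 1L), file)
}

#' Write a feature matrix as TSV
#' @param features A \code{feature_matrix}.
#' @param file Output path; first column \code{subject_id}, then one column
#'   per patch id.
#' @return The path, invisibly.
#' @export
write_features_tsv <- function(features, file) {
  d <- data.frame(subject_id = rownames(features), unclass(features),
                  check.names = FALSE)
  write_tsv(d, file)
}

#' Read a feature matrix from TSV
#' @param file Path written by \code{\link{write_features_tsv}}.
#' @return A \code{feature_matrix}.
#' @export
read_features_tsv <- function(file) {
  d <- read_tsv_checked(file, "subject_id")
  m <- as.matrix(d[, setdiff(names(d), "subject_id"), drop = FALSE])
  rownames(m) <- d$subject_id
  structure(m, patch_ids = colnames(m), subject_ids = rownames(m),
            class = c("feature_matrix", "matrix"))
}
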