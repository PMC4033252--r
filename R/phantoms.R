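#' Segmented voxel volumes
#'
#' A \code{segmented_volume} is a 3-D labelled grid with voxel codes
#' 0 = outside, 1 = gray (cortical ribbon), 2 = inner solid (white matter),
#' isotropic spacing in mm, and the mm coordinate of the centre of voxel
#' (1,1,1) as origin.
#'
#' @param grid 3-D integer array of codes \{0, 1, 2\}.
#' @param spacing Voxel edge length, mm.
#' @param origin Numeric length-3, mm position of the first voxel centre.
#' @return An object of class \code{segmented_volume}.
#' @export
segmented_volume <- function(grid, spacing, origin = c(0, 0, 0)) {
  stopifnot_scalar_pos(spacing, "spacing")
  if (length(dim(grid)) != 3L) stop("'grid' must be a 3-D array", call. = FALSE)
  if (!all(grid %in% c(0L, 1L, 2L)))
    stop("grid codes must be 0 (outside), 1 (gray), 2 (inner)", call. = FALSE)
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, spacing = spacing, origin = as.numeric(origin)),
            class = "segmented_volume")
}

#' @export
print.segmented_volume <- function(x, ...) {
  tab <- tabulate(as.integer(x$grid) + 1L, nbins = 3L)
  cat(sprintf(
    "segmented_volume: %s voxels @ %.3g mm (outside %d, gray %d, inner %d)\n",
    paste(dim(x$grid), collapse = "x"), x$spacing, tab[1], tab[2], tab[3]))
  invisible(x)
}

## voxel-centre coordinates along one axis
axis_coords <- function(n, origin, spacing) origin + (seq_len(n) - 1) * spacing

#' Parallel-slab phantom
#'
#' Two parallel planar boundaries a known distance apart: the gray ribbon
#' fills the gap, inner solid lies below, outside above. The analytic
#' thickness everywhere is \code{separation}, which makes the slab the
#' primary accuracy phantom for the Laplace-streamline estimator.
#'
#' @param separation Distance between the boundary planes, mm.
#' @param spacing Voxel size, mm. Must satisfy \code{separation >= 3 * spacing}.
#' @param extent In-plane extent of the volume, mm.
#' @return A \code{segmented_volume}; boundaries fall on voxel faces when
#'   \code{separation} is a multiple of \code{spacing}.
#' @export
make_slab_phantom <- function(separation, spacing, extent) {
  stopifnot_scalar_pos(separation, "separation")
  stopifnot_scalar_pos(spacing, "spacing")
  stopifnot_scalar_pos(extent, "extent")
  if (separation < 3 * spacing)
    stop("slab under-resolved: separation must be >= 3 * spacing", call. = FALSE)
  if (extent <= separation) stop("'extent' must exceed 'separation'", call. = FALSE)
  margin <- max(2 * spacing, 1)
  nxy <- max(4L, as.integer(round(extent / spacing)))
  nz <- as.integer(ceiling((separation + 2 * margin) / spacing))
  ## z voxel centres at (k + 1/2) * spacing - margin_aligned: put the lower
  ## boundary plane z = 0 exactly on a voxel face
  mz <- ceiling(margin / spacing)
  z0 <- -(mz - 0.5) * spacing
  z <- z0 + (seq_len(nz) - 1) * spacing
  code_z <- ifelse(z < 0, 2L, ifelse(z < separation, 1L, 0L))
  grid <- array(rep(code_z, each = nxy * nxy), dim = c(nxy, nxy, nz))
  segmented_volume(grid, spacing, origin = c(0, 0, z[1]))
}

#' Spherical-shell phantom
#'
#' Voxels with centre radius below \code{r_inner} are inner solid, radii in
#' \code{[r_inner, r_outer)} are gray, and the rest outside. The analytic
#' thickness is \code{r_outer - r_inner} along radial streamlines.
#'
#' @param r_inner Inner boundary radius, mm.
#' @param r_outer Outer boundary radius, mm.
#' @param spacing Voxel size, mm; shell must span at least 3 voxels.
#' @return A \code{segmented_volume} centred on the origin.
#' @export
make_shell_phantom <- function(r_inner, r_outer, spacing) {
  stopifnot_scalar_pos(r_inner, "r_inner")
  stopifnot_scalar_pos(spacing, "spacing")
  if (r_outer <= r_inner)
    stop("'r_outer' must exceed 'r_inner'", call. = FALSE)
  if ((r_outer - r_inner) < 3 * spacing)
    stop("shell under-resolved: width must be >= 3 * spacing", call. = FALSE)
  margin <- max(2 * spacing, 1)
  half <- r_outer + margin
  n <- as.integer(2 * ceiling(half / spacing) + 1)
  cc <- (seq_len(n) - (n + 1) / 2) * spacing
  r2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  r <- sqrt(r2)
  grid <- array(0L, dim = c(n, n, n))
  grid[r < r_inner] <- 2L
  grid[r >= r_inner & r < r_outer] <- 1L
  segmented_volume(grid, spacing, origin = rep(cc[1], 3))
}
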