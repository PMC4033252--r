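#' Per-vertex cortical thickness maps
#'
#' @param values Numeric thickness per mesh vertex, mm (NA where tracing
#'   failed).
#' @param fwhm_applied Smoothing FWHM already applied, mm (0 = raw).
#' @param failed Logical mask of vertices whose streamline trace failed.
#' @return An object of class \code{thickness_map}.
#' @export
thickness_map <- function(values, fwhm_applied = 0, failed = NULL) {
  if (is.null(failed)) failed <- is.na(values)
  structure(list(values = as.numeric(values), fwhm_applied = fwhm_applied,
                 failed = failed, n_failed = sum(failed)),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  ok <- x$values[!x$failed]
  cat(sprintf("thickness_map: %d vertices, mean %.3f mm (sd %.3f), fwhm %g mm, %d failed\n",
              length(x$values), mean(ok), stats::sd(ok), x$fwhm_applied,
              x$n_failed))
  invisible(x)
}

## mm point -> continuous (1-based) voxel index
to_index <- function(p, field) sweep(p, 2, field$origin, "-") / field$spacing + 1

## vectorized trilinear interpolation of a 3-D array at continuous indices
trilinear <- function(arr, u, dims) {
  i0 <- pmin(pmax(floor(u), 1), matrix(rep(dims - 1L, each = nrow(u)), ncol = 3))
  f <- u - i0
  f <- pmin(pmax(f, 0), 1)
  s1 <- dims[1]; s2 <- dims[1] * dims[2]
  base <- (i0[, 1]) + (i0[, 2] - 1) * s1 + (i0[, 3] - 1) * s2
  v000 <- arr[base];           v100 <- arr[base + 1]
  v010 <- arr[base + s1];      v110 <- arr[base + 1 + s1]
  v001 <- arr[base + s2];      v101 <- arr[base + 1 + s2]
  v011 <- arr[base + s1 + s2]; v111 <- arr[base + 1 + s1 + s2]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

## central-difference gradient of psi (per mm) as three arrays
field_gradient <- function(field) {
  if (!is.null(field$grad)) return(field$grad)
  psi <- field$psi; dims <- field$dims; h <- field$spacing
  gx <- array(0, dims); gy <- array(0, dims); gz <- array(0, dims)
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  gx[2:(n1 - 1), , ] <- (psi[3:n1, , ] - psi[1:(n1 - 2), , ]) / (2 * h)
  gy[, 2:(n2 - 1), ] <- (psi[, 3:n2, ] - psi[, 1:(n2 - 2), ]) / (2 * h)
  gz[, , 2:(n3 - 1)] <- (psi[, , 3:n3] - psi[, , 1:(n3 - 2)]) / (2 * h)
  list(gx = gx, gy = gy, gz = gz)
}

## unit gradient direction at mm points; rows with tiny gradient are flagged
unit_gradient_at <- function(points, field, grad) {
  u <- to_index(points, field)
  g <- cbind(trilinear(grad$gx, u, field$dims),
             trilinear(grad$gy, u, field$dims),
             trilinear(grad$gz, u, field$dims))
  nrm <- sqrt(rowSums(g^2))
  list(dir = g / pmax(nrm, 1e-300), norm = nrm)
}

psi_at <- function(points, field) {
  trilinear(field$psi, to_index(points, field), field$dims)
}

## Integrate many streamlines toward one boundary level (0 or 1) with RK4
## on the normalized gradient. Returns endpoints, success flags and arc
## lengths. 'sgn' is +1 toward the outer (psi = 1) and -1 toward the inner
## (psi = 0) boundary.
march_to_level <- function(field, grad, starts, step, level, sgn, max_len) {
  n <- nrow(starts)
  p <- starts
  endpoint <- matrix(NA_real_, n, 3)
  ok <- rep(FALSE, n)
  arclen <- numeric(n)
  active <- rep(TRUE, n)
  psi0 <- psi_at(p, field)
  done0 <- if (sgn > 0) psi0 >= level else psi0 <= level
  endpoint[done0, ] <- p[done0, , drop = FALSE]
  ok[done0] <- TRUE
  active[done0] <- FALSE
  while (any(active)) {
    ia <- which(active)
    pa <- p[ia, , drop = FALSE]
    k1 <- unit_gradient_at(pa, field, grad)
    bad <- k1$norm < 1e-12
    k2 <- unit_gradient_at(pa + sgn * step / 2 * k1$dir, field, grad)
    k3 <- unit_gradient_at(pa + sgn * step / 2 * k2$dir, field, grad)
    k4 <- unit_gradient_at(pa + sgn * step * k3$dir, field, grad)
    dirs <- (k1$dir + 2 * k2$dir + 2 * k3$dir + k4$dir) / 6
    pn <- pa + sgn * step * dirs
    psi_prev <- psi_at(pa, field)
    psi_new <- psi_at(pn, field)
    crossed <- if (sgn > 0) psi_new >= level else psi_new <= level
    tfrac <- (level - psi_prev) / (psi_new - psi_prev)
    tfrac[!is.finite(tfrac)] <- 1
    tfrac <- pmin(pmax(tfrac, 0), 1)
    hit <- which(crossed & !bad)
    if (length(hit)) {
      endpoint[ia[hit], ] <- pa[hit, , drop = FALSE] +
        tfrac[hit] * (pn[hit, , drop = FALSE] - pa[hit, , drop = FALSE])
      ok[ia[hit]] <- TRUE
      active[ia[hit]] <- FALSE
    }
    stalled <- which(bad)
    if (length(stalled)) active[ia[stalled]] <- FALSE
    cont <- which(!crossed & !bad)
    if (length(cont)) {
      p[ia[cont], ] <- pn[cont, , drop = FALSE]
      arclen[ia[cont]] <- arclen[ia[cont]] + step
      over <- ia[cont][arclen[ia[cont]] > max_len]
      if (length(over)) active[over] <- FALSE
    }
  }
  list(endpoint = endpoint, ok = ok, arclen = arclen + step * ok)
}

trace_many <- function(field, starts, step) {
  grad <- field_gradient(field)
  diag_len <- sqrt(sum((field$dims * field$spacing)^2))
  max_len <- 10 * diag_len
  inner <- march_to_level(field, grad, starts, step, 0, -1, max_len)
  outer <- march_to_level(field, grad, starts, step, 1, +1, max_len)
  list(inner = inner$endpoint, outer = outer$endpoint,
       ok = inner$ok & outer$ok,
       arclen = inner$arclen + outer$arclen,
       exceeded = (!inner$ok & inner$arclen >= max_len) |
                  (!outer$ok & outer$arclen >= max_len))
}

#' Trace a streamline of the harmonic potential through a point
#'
#' Integrates the normalized gradient of the trilinearly interpolated
#' potential in both directions (4th-order Runge-Kutta) until the psi = 0
#' and psi = 1 level boundaries are crossed; each endpoint is located by
#' linear interpolation of psi along the final segment. A start already on
#' a boundary yields one zero-length leg.
#'
#' @param field A \code{potential_field} from \code{\link{solve_laplace}}.
#' @param vol The matching \code{segmented_volume}.
#' @param start Numeric length-3 point in mm; must lie in the gray
#'   compartment.
#' @param step Integration step, mm; default \code{0.2 * spacing} and must
#'   be below the voxel spacing.
#' @return List with \code{inner} and \code{outer} endpoints (mm),
#'   \code{arc_length} and \code{thickness} (Euclidean endpoint distance).
#' @export
trace_streamline <- function(field, vol, start, step = 0.2 * vol$spacing) {
  if (step >= vol$spacing) stop("'step' must be below the voxel spacing", call. = FALSE)
  start <- matrix(as.numeric(start), ncol = 3)
  vidx <- round(to_index(start, field))
  if (any(vidx < 1) || any(vidx > rep(field$dims, each = nrow(start))) ||
      vol$grid[matrix(vidx, ncol = 3)] != 1L)
    stop("'start' must lie inside the gray compartment", call. = FALSE)
  tr <- trace_many(field, start, step)
  if (any(tr$exceeded))
    stop("streamline exceeded maximum arc length: degenerate field", call. = FALSE)
  if (!tr$ok[1]) stop("streamline stalled (vanishing gradient)", call. = FALSE)
  list(inner = tr$inner[1, ], outer = tr$outer[1, ],
       arc_length = tr$arclen[1],
       thickness = sqrt(sum((tr$outer[1, ] - tr$inner[1, ])^2)))
}

#' Cortical thickness at every pial vertex
#'
#' For each mesh vertex (assumed on or near the outer boundary) a
#' streamline of the harmonic potential is traced in both directions and
#' the thickness is the Euclidean distance between its two boundary
#' endpoints (not the arc length). Vertices whose trace fails are flagged
#' and returned as NA; the count is reported on the map.
#'
#' Vertices sitting exactly on (or outside) the psi = 1 level are first
#' nudged inward along the negative gradient until the potential drops
#' below 1, so the uphill leg can recover the outer crossing next to the
#' vertex.
#'
#' @param mesh A \code{cortical_mesh} of pial vertices.
#' @param field A \code{potential_field}.
#' @param vol The matching \code{segmented_volume}.
#' @param step Integration step, mm.
#' @return A \code{thickness_map}.
#' @export
compute_thickness <- function(mesh, field, vol, step = 0.2 * vol$spacing) {
  starts <- mesh$vertices
  grad <- field_gradient(field)
  field$grad <- grad
  ## nudge starts at/above the outer level slightly inward
  for (i in 1:12) {
    psv <- psi_at(starts, field)
    high <- psv >= 1 - 1e-9
    if (!any(high)) break
    dirs <- unit_gradient_at(starts[high, , drop = FALSE], field, grad)
    starts[high, ] <- starts[high, , drop = FALSE] -
      0.25 * vol$spacing * dirs$dir
  }
  tr <- trace_many(field, starts, step)
  th <- sqrt(rowSums((tr$outer - tr$inner)^2))
  th[!tr$ok] <- NA_real_
  map <- thickness_map(th, fwhm_applied = 0, failed = !tr$ok)
  map$arc_length <- tr$arclen
  map
}
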