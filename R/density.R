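# Real-space observable: electron density integrated beyond planes
# parallel to the molecular plane, with Gaussian-cube I/O.
#
# Internally lengths are in Angstrom; cube files use Bohr (the standard
# dialect, signalled by positive voxel counts) or Angstrom (negative
# counts, honoured on read).

BOHR_ANGSTROM <- 0.529177210903

#' An orbital sampled on a regular grid
#'
#' @param origin Grid origin, Angstrom 3-vector.
#' @param axes 3x3 matrix of voxel step vectors (rows), Angstrom.
#' @param values 3-d array of real amplitudes, `dim = shape`.
#' @param normalization Declared norm `integral |phi|^2 dV`; computed from
#'   the grid when `NULL`. A declared value more than 2% from the numeric
#'   integral is rejected.
#' @return An object of class `grid_orbital`.
#' @export
grid_orbital <- function(origin, axes, values, normalization = NULL) {
  if (length(dim(values)) != 3) stop_invalid("values must be a 3-d array")
  axes <- as.matrix(axes)
  dv <- abs(det(axes))
  num <- sum(values^2) * dv
  if (is.null(normalization)) normalization <- num
  else if (abs(normalization - num) > 0.02 * max(normalization, 1e-300))
    stop_invalid("declared normalization differs from the numeric integral by > 2%")
  structure(list(origin = as.numeric(origin), axes = axes,
                 shape = dim(values), values = values,
                 normalization = normalization),
            class = "grid_orbital")
}

#' @export
print.grid_orbital <- function(x, ...) {
  cat(sprintf("<grid_orbital> %d x %d x %d voxels, norm %.4g\n",
              x$shape[1], x$shape[2], x$shape[3], x$normalization))
  invisible(x)
}

voxel_centres <- function(orb) {
  idx <- as.matrix(expand.grid(i = seq_len(orb$shape[1]) - 1,
                               j = seq_len(orb$shape[2]) - 1,
                               k = seq_len(orb$shape[3]) - 1))
  sweep(idx %*% orb$axes, 2, orb$origin, `+`)
}

#' Write / read Gaussian cube files
#'
#' `write_cube()` emits the standard Bohr-dialect cube (positive voxel
#' counts); `read_cube()` also honours the Angstrom dialect in which
#' negative voxel counts declare the axes and origin to be in Angstrom.
#' Values round-trip within float formatting precision.
#'
#' @param orb A [grid_orbital()].
#' @param path File path.
#' @param comment Two header comment lines.
#' @return `write_cube()` returns `path` invisibly; `read_cube()` a
#'   [grid_orbital()].
#' @export
write_cube <- function(orb, path, comment = c("orbital on grid", "written by chargemig")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment[1:2], con)
  ob <- orb$origin / BOHR_ANGSTROM
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 0L, ob[1], ob[2], ob[3]), con)
  for (a in 1:3) {
    ax <- orb$axes[a, ] / BOHR_ANGSTROM
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", orb$shape[a], ax[1], ax[2], ax[3]), con)
  }
  # value order: outer loop x, then y, inner z, six per line
  v <- aperm(orb$values, c(3, 2, 1)) # z fastest in memory -> write z-inner
  flat <- as.vector(v)
  # as.vector of (z,y,x) runs z fastest with x outermost: matches cube order
  n <- length(flat)
  for (i in seq(1, n, by = 6)) {
    writeLines(paste(sprintf("%13.5e", flat[i:min(i + 5, n)]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6)
    cond_error("chargemig_parse_error", "malformed cube: fewer than 6 lines")
  parse_row <- function(i) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (any(is.na(x)) || length(x) < 4)
      cond_error("chargemig_parse_error", "malformed cube header at line ", i)
    x
  }
  hdr <- parse_row(3)
  natoms <- abs(as.integer(hdr[1]))
  origin <- hdr[2:4]
  counts <- integer(3)
  axes <- matrix(0, 3, 3)
  for (a in 1:3) {
    r <- parse_row(3 + a)
    counts[a] <- as.integer(r[1])
    axes[a, ] <- r[2:4]
  }
  angstrom_dialect <- any(counts < 0)
  shape <- abs(counts)
  scale <- if (angstrom_dialect) 1 else BOHR_ANGSTROM
  origin <- origin * scale
  axes <- axes * scale
  first_val <- 7 + natoms
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[first_val:length(lines)]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(shape))
    cond_error("chargemig_parse_error",
               "cube value count ", length(vals), " != ", prod(shape))
  arr <- aperm(array(vals, rev(shape)), c(3, 2, 1)) # stored z-inner
  grid_orbital(origin = origin, axes = axes, values = arr)
}

#' Gaussian orbital on a grid (analytic fixture)
#'
#' A normalised anisotropic Gaussian `|phi|^2 ~ N(center, diag(sigma^2))`,
#' for which out-of-slab fractions have the closed form
#' `erfc(d / (sigma_n sqrt(2)))` along the slab normal.
#'
#' @param center Centre (Angstrom 3-vector).
#' @param sigma Standard deviations of `|phi|^2` along x, y, z (Angstrom).
#' @param half_extent Grid half-width in units of sigma (default 6).
#' @param n Voxels per axis; a length-3 vector allows an anisotropic grid
#'   (e.g. fine along the slab normal only).
#' @return A [grid_orbital()].
#' @export
gaussian_grid_orbital <- function(center = c(0, 0, 0), sigma = c(1, 1, 1),
                                  half_extent = 6, n = 61) {
  n <- rep(as.integer(n), length.out = 3)
  axes <- diag(2 * half_extent * sigma / (n - 1))
  origin <- center - half_extent * sigma
  g1 <- function(x, c0, s) exp(-(x - c0)^2 / (4 * s^2)) / (2 * pi * s^2)^0.25
  xs <- origin[1] + (seq_len(n[1]) - 1) * axes[1, 1]
  ys <- origin[2] + (seq_len(n[2]) - 1) * axes[2, 2]
  zs <- origin[3] + (seq_len(n[3]) - 1) * axes[3, 3]
  vals <- outer(outer(g1(xs, center[1], sigma[1]), g1(ys, center[2], sigma[2])),
                g1(zs, center[3], sigma[3]))
  dim(vals) <- n
  grid_orbital(origin, axes, vals)
}

#' Best-fit molecular plane
#'
#' Plane through the centroid of the supplied atom coordinates whose normal
#' is the smallest principal axis.
#'
#' @param points Matrix (n x 3) of coordinates (Angstrom).
#' @return A list with `normal` (unit 3-vector) and `point` (centroid).
#' @export
best_fit_plane <- function(points) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  s <- svd(sweep(points, 2, ctr))
  list(normal = s$v[, 3], point = ctr)
}

#' Electron density beyond planes parallel to the molecular plane
#'
#' `Q(t) = sum_k n_k(t) * integral_{|d(r)| > distance} |phi_k(r)|^2 dV`,
#' where `d` is the signed distance to the plane and both half-spaces are
#' included. Voxel membership is decided by the voxel centre.
#'
#' @param orbitals A list of [grid_orbital()] on a common grid, one per
#'   tracked orbital.
#' @param occupations Numeric vector (one weight per orbital) or a matrix
#'   (rows = times, columns = orbitals), e.g. spin-summed occupations from
#'   a propagation.
#' @param plane_normal Plane normal (need not be unit length).
#' @param plane_point A point on the plane.
#' @param distance Slab half-thickness in Angstrom (default 3).
#' @param times Optional time stamps (fs) for matrix input.
#' @return A tibble: `time_fs` (or row index) and `q_out`.
#' @export
out_of_plane_density <- function(orbitals, occupations,
                                 plane_normal = c(0, 0, 1),
                                 plane_point = c(0, 0, 0),
                                 distance = 3, times = NULL) {
  if (distance < 0) stop_invalid("distance must be >= 0")
  nn <- sqrt(sum(plane_normal^2))
  if (nn == 0) stop_invalid("plane_normal must be nonzero")
  un <- plane_normal / nn
  ref <- orbitals[[1]]
  same_grid <- vapply(orbitals, function(o)
    identical(o$shape, ref$shape) &&
      max(abs(o$origin - ref$origin)) < 1e-9 &&
      max(abs(o$axes - ref$axes)) < 1e-9, logical(1))
  if (!all(same_grid)) stop_invalid("all orbitals must share one grid")
  dv <- abs(det(ref$axes))
  d <- abs(as.vector(voxel_centres(ref) %*% un - sum(un * plane_point)))
  outside <- d > distance
  frac <- vapply(orbitals, function(o) sum(o$values[outside]^2) * dv, numeric(1))
  if (is.matrix(occupations)) {
    q <- as.vector(occupations %*% frac)
    tibble::tibble(time_fs = times %||% seq_along(q), q_out = q)
  } else {
    tibble::tibble(time_fs = times %||% NA_real_,
                   q_out = sum(occupations * frac))
  }
}
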