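#' Specification of a voxelized lens phantom
#'
#' Describes a synthetic lens: a solid sphere, ellipsoid or superellipsoid
#' voxelized on a cubic grid, optionally rotated and with seeded radial
#' boundary noise. Used to exercise the shape-metric operations against
#' analytic ground truth.
#'
#' @param shape one of `"sphere"`, `"ellipsoid"`, `"superellipsoid"`.
#' @param semi_axes semi-axes in voxels (scalar for a sphere, length 3
#'   otherwise); must exceed 2 voxels.
#' @param grid grid edge length in voxels (scalar or length 3).
#' @param spacing voxel edge length in mm (scalar or length 3).
#' @param orientation rotation angles in radians about axes 1, 2, 3,
#'   applied in that order (default no rotation).
#' @param exponent superellipsoid exponent (2 = ellipsoid; large = boxy).
#' @param noise boundary noise amplitude in voxels (sd of an i.i.d. radial
#'   perturbation of the implicit surface; 0 = clean).
#' @param seed integer RNG seed for the boundary noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("sphere", "ellipsoid", "superellipsoid"),
                         semi_axes = 40, grid = 96, spacing = 0.01,
                         orientation = c(0, 0, 0), exponent = 2,
                         noise = 0, seed = 1L) {
  shape <- match.arg(shape)
  semi_axes <- rep(as.numeric(semi_axes), length.out = 3L)
  if (shape == "sphere" && length(unique(semi_axes)) != 1L) {
    stop("a sphere has a single radius")
  }
  if (any(semi_axes <= 2)) stop("semi-axes must exceed 2 voxels")
  grid <- rep(as.integer(grid), length.out = 3L)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (shape != "superellipsoid") exponent <- 2
  if (exponent <= 0) stop("exponent must be positive")
  if (noise < 0) stop("noise amplitude must be >= 0")
  structure(list(shape = shape, semi_axes = semi_axes, grid = grid,
                 spacing = spacing, orientation = as.numeric(orientation),
                 exponent = exponent, noise = as.numeric(noise),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rotation matrix from intrinsic rotations about axes 1, 2, 3.
.rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Voxelize a lens phantom with analytic ground truth
#'
#' Renders the phantom described by a [phantom_spec()] into a binary
#' [voxel_volume()] (label 1) and attaches ground truth: true semi-axes in
#' mm, the closed-form volume, and the surface area (closed form for
#' spheres and spheroids, numerical quadrature for scalene ellipsoids;
#' `NA` for noisy or superellipsoidal shapes where no clean reference
#' exists). A voxel is foreground when its center lies inside the
#' (optionally noise-perturbed) implicit surface.
#'
#' Boundary noise perturbs the normalized radius of each near-boundary
#' voxel by i.i.d. Gaussian offsets of `noise` voxels, reproducible under
#' `seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([voxel_volume()]) and `truth`
#'   (list: `semi_axes_mm`, `volume_mm3`, `surface_area_mm2`,
#'   `axis_ratios_sq` — the expected covariance-eigenvalue ratios
#'   `(b/a)^2`, `(c/b)^2` for sorted semi-axes).
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(shape = "sphere", semi_axes = 10, grid = 28))
#' ph$truth$volume_mm3 / (ph$volume$spacing[1]^3 * sum(ph$volume$grid))
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$semi_axes  # in voxels, isotropic voxel units assumed for geometry
  if (length(unique(spec$spacing)) != 1L) {
    stop("phantom voxelization assumes isotropic spacing")
  }
  sp <- spec$spacing[1]
  center <- spec$grid / 2  # in voxel units
  margin <- max(abs(a)) + 4 * spec$noise
  if (any(center - margin < 2) || any(spec$grid - center - margin < 2)) {
    stop("phantom does not fit inside the grid with a 2-voxel margin")
  }
  R <- .rotation_matrix(spec$orientation)
  # voxel centers in voxel units relative to phantom center
  g1 <- seq_len(spec$grid[1]) - 0.5 - center[1]
  g2 <- seq_len(spec$grid[2]) - 0.5 - center[2]
  g3 <- seq_len(spec$grid[3]) - 0.5 - center[3]
  X <- as.matrix(expand.grid(x = g1, y = g2, z = g3))
  U <- X %*% R  # body coordinates (R^T applied to rows)
  e <- spec$exponent
  rho <- (abs(U[, 1] / a[1])^e + abs(U[, 2] / a[2])^e +
            abs(U[, 3] / a[3])^e)^(1 / e)
  if (spec$noise > 0) {
    rgm <- prod(a)^(1 / 3)
    band <- abs(rho - 1) * rgm <= 4 * spec$noise + 1
    z <- numeric(length(rho))
    z[band] <- .with_seed(spec$seed, rnorm(sum(band)))
    inside <- rho <= 1 + spec$noise * z / rgm
  } else {
    inside <- rho <= 1
  }
  grid <- array(0L, dim = spec$grid)
  grid[inside] <- 1L
  vol <- voxel_volume(grid, spec$spacing)

  axes_mm <- sort(a * sp, decreasing = TRUE)
  truth <- list(
    semi_axes_mm = axes_mm,
    volume_mm3 = if (spec$shape == "superellipsoid") {
      8 * prod(axes_mm) * gamma(1 + 1 / e)^3 / gamma(1 + 3 / e)
    } else {
      4 / 3 * pi * prod(axes_mm)
    },
    surface_area_mm2 = if (spec$noise > 0 || spec$shape == "superellipsoid") {
      NA_real_
    } else {
      .ellipsoid_area(axes_mm[1], axes_mm[2], axes_mm[3])
    },
    axis_ratios_sq = c(l2_over_l1 = (axes_mm[2] / axes_mm[1])^2,
                       l3_over_l2 = (axes_mm[3] / axes_mm[2])^2)
  )
  list(volume = vol, truth = truth, spec = spec)
}

# Surface area of a solid ellipsoid with semi-axes a >= b >= c.
# Closed forms for degenerate-to-sphere and spheroids; trapezoidal
# quadrature of the first-fundamental-form integrand otherwise (the
# integrand is smooth and periodic, so convergence is fast).
.ellipsoid_area <- function(a, b, c) {
  tol <- 1e-12
  if (abs(a - b) < tol && abs(b - c) < tol) return(4 * pi * a^2)
  if (abs(a - b) < tol) {        # oblate (a = b > c)
    ecc <- sqrt(1 - c^2 / a^2)
    return(2 * pi * a^2 + pi * c^2 / ecc * log((1 + ecc) / (1 - ecc)))
  }
  if (abs(b - c) < tol) {        # prolate (a > b = c)
    ecc <- sqrt(1 - b^2 / a^2)
    return(2 * pi * b^2 + 2 * pi * a * b / ecc * asin(ecc))
  }
  n_th <- 801L; n_ph <- 800L
  th <- seq(0, pi, length.out = n_th)
  ph <- seq(0, 2 * pi, length.out = n_ph + 1L)[-(n_ph + 1L)]
  st <- sin(th); ct <- cos(th)
  f <- outer(st, ph, function(s, p) s) # placeholder shape
  for (i in seq_len(n_th)) {
    f[i, ] <- st[i] * sqrt(b^2 * c^2 * st[i]^2 * cos(ph)^2 +
                             a^2 * c^2 * st[i]^2 * sin(ph)^2 +
                             a^2 * b^2 * ct[i]^2)
  }
  w <- rep(1, n_th); w[c(1, n_th)] <- 0.5
  sum(f * w) * (pi / (n_th - 1)) * (2 * pi / n_ph)
}
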