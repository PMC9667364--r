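#' Covariance eigenvalues of a segmented label
#'
#' Treats each foreground voxel center of the requested label as an equally
#' weighted point in physical coordinates and returns the eigenvalues of the
#' 3x3 sample covariance matrix of that point cloud, sorted descending
#' (`l1 >= l2 >= l3`, units mm^2). Ratios of these eigenvalues are the basis
#' of the anisotropy, flatness and elongation shape metrics: a uniform solid
#' ellipsoid with semi-axes a >= b >= c has covariance eigenvalues
#' proportional to (a^2, b^2, c^2), so the ratios are squared axis ratios.
#'
#' @param volume a [voxel_volume()].
#' @param label integer label.
#' @return A list of class `eigen_triple` with elements `l1`, `l2`, `l3`
#'   (mm^2), `n_voxels`, and `degenerate` (TRUE when the point cloud is
#'   coplanar/collinear so that `l3` is numerically zero).
#' @export
covariance_eigenvalues <- function(volume, label = 1L) {
  pts <- .label_coords(volume, label)
  n <- nrow(pts)
  if (n < 4L) {
    stop(sprintf("label %d has only %d voxel(s); need >= 4 non-collinear voxels",
                 as.integer(label), n))
  }
  S <- cov(pts)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0 & ev > -1e-12 * ev[1]] <- 0  # clip tiny negative round-off
  degenerate <- ev[3] <= 1e-10 * ev[1]
  if (ev[1] <= 0) stop("degenerate geometry: all voxels coincide")
  structure(list(l1 = ev[1], l2 = ev[2], l3 = ev[3],
                 n_voxels = n, degenerate = degenerate),
            class = "eigen_triple")
}

#' @export
print.eigen_triple <- function(x, ...) {
  cat(sprintf("<eigen_triple> l1 = %.6g, l2 = %.6g, l3 = %.6g mm^2 (n = %d)%s\n",
              x$l1, x$l2, x$l3, x$n_voxels,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Shape ratios from a sorted eigen triple. Raw (not square-rooted)
# eigenvalues: the convention under which a perfect sphere scores
# anisotropy 0, flatness 1, elongation 1.
.eigen_ratios <- function(ev) {
  list(anisotropy = 1 - ev$l3 / ev$l1,
       flatness   = ev$l3 / ev$l2,
       elongation = ev$l2 / ev$l1)
}

#' Compute the four 3D lens-shape metrics for one label
#'
#' Computes, for a segmented lens label:
#' * **anisotropy** `1 - l3/l1` — 0 for a sphere, toward 1 for strong
#'   flattening or elongation;
#' * **flatness** `l3/l2` and **elongation** `l2/l1` — both 1 for a sphere;
#' * **volume** — foreground voxel count times the physical voxel volume;
#' * **surface area** — area of a smoothed closed isosurface mesh
#'   ([extract_surface_mesh()]);
#' * **sphericity** — `pi^(1/3) * (6 V)^(2/3) / A`, the surface area of the
#'   equal-volume sphere divided by the measured surface area; 1 for a
#'   perfect sphere, smaller for any other shape.
#'
#' `l1 >= l2 >= l3` are the covariance eigenvalues of the voxel point cloud
#' ([covariance_eigenvalues()]).
#'
#' @param volume a [voxel_volume()].
#' @param label integer label.
#' @param mesh_smoothing smoothing iterations for the surface mesh
#'   (default 20); see [smooth_mesh()].
#' @return A list of class `lens_shape_metrics` with fields `anisotropy`,
#'   `flatness`, `elongation`, `sphericity`, `volume_mm3`, `surface_area_mm2`,
#'   `n_voxels` and the underlying `eigenvalues`.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(shape = "sphere", semi_axes = 10,
#'                                 grid = 28, spacing = 0.01))
#' m <- compute_shape_metrics(ph$volume, 1)
#' round(c(m$anisotropy, m$flatness, m$elongation, m$sphericity), 3)
compute_shape_metrics <- function(volume, label = 1L, mesh_smoothing = 20L) {
  ev <- covariance_eigenvalues(volume, label)
  if (ev$degenerate) {
    stop("degenerate geometry: voxels of label ", as.integer(label),
         " are coplanar or collinear (l3 = 0)")
  }
  ratios <- .eigen_ratios(ev)
  n_vox <- ev$n_voxels
  volume_mm3 <- n_vox * prod(volume$spacing)
  mesh <- extract_surface_mesh(volume, label, smoothing = mesh_smoothing)
  area <- mesh_area(mesh)
  sphericity <- pi^(1 / 3) * (6 * volume_mm3)^(2 / 3) / area
  if (sphericity > 1 + 0.05) {
    stop(sprintf(
      "sphericity %.3f exceeds 1 beyond mesh tolerance: surface mesh inconsistent",
      sphericity))
  }
  structure(list(anisotropy = ratios$anisotropy,
                 flatness = ratios$flatness,
                 elongation = ratios$elongation,
                 sphericity = sphericity,
                 volume_mm3 = volume_mm3,
                 surface_area_mm2 = area,
                 n_voxels = n_vox,
                 eigenvalues = ev),
            class = "lens_shape_metrics")
}

#' @export
print.lens_shape_metrics <- function(x, ...) {
  cat("<lens_shape_metrics>\n")
  cat(sprintf("  anisotropy %.4f | flatness %.4f | elongation %.4f | sphericity %.4f\n",
              x$anisotropy, x$flatness, x$elongation, x$sphericity))
  cat(sprintf("  volume %.6g mm^3, surface area %.6g mm^2 (%d voxels)\n",
              x$volume_mm3, x$surface_area_mm2, x$n_voxels))
  invisible(x)
}

#' @export
as.data.frame.lens_shape_metrics <- function(x, ...) {
  data.frame(anisotropy = x$anisotropy, flatness = x$flatness,
             elongation = x$elongation, sphericity = x$sphericity,
             volume_mm3 = x$volume_mm3, surface_area_mm2 = x$surface_area_mm2,
             n_voxels = x$n_voxels)
}

#' Maximum transverse diameter of a label along an anatomical axis
#'
#' Returns the maximum caliper width of the label parallel to the named
#' axis over all planes: the full voxel extent (outer edge to outer edge)
#' along that axis, in mm. This is the automated analogue of placing a
#' plane through the rendered eye so that it yields the maximum transverse
#' diameter; the naso-temporal axis (array dimension 3) is the conventional
#' transverse direction.
#'
#' @param volume a [voxel_volume()].
#' @param label integer label.
#' @param axis axis index (1-3) or name (`"anterior-posterior"`,
#'   `"dorso-ventral"`, `"naso-temporal"`); default naso-temporal.
#' @return Diameter in mm.
#' @export
transverse_diameter <- function(volume, label = 1L, axis = "naso-temporal") {
  ax <- .axis_index(axis)
  idx <- which(volume$grid == as.integer(label), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop(sprintf("label %d not present in volume", as.integer(label)))
  }
  (max(idx[, ax]) - min(idx[, ax]) + 1L) * volume$spacing[ax]
}

#' Specimen-level lens diameter averaged over both eyes
#'
#' Measures [transverse_diameter()] separately for each supplied label
#' (typically the left and right lens) and returns the mean, matching the
#' practice of averaging the two eyes of a specimen.
#'
#' @inheritParams transverse_diameter
#' @param labels integer vector of labels (one per eye).
#' @return Mean diameter in mm.
#' @export
paired_eye_diameter <- function(volume, labels = c(1L, 2L),
                                axis = "naso-temporal") {
  mean(vapply(labels, function(l) transverse_diameter(volume, l, axis), 0))
}

#' Shape-metric table for several specimens
#'
#' Convenience wrapper producing one CSV-ready row per (specimen, label).
#'
#' @param volumes named list of [voxel_volume()] objects (names = specimen ids).
#' @param labels integer vector of labels to measure in each volume.
#' @param mesh_smoothing smoothing iterations passed to
#'   [compute_shape_metrics()].
#' @param diameter_axis axis for [transverse_diameter()].
#' @return A data.frame with columns `specimen_id`, `label`, the four shape
#'   metrics, `volume_mm3`, `surface_area_mm2` and `diameter_mm`.
#' @export
shape_metric_table <- function(volumes, labels = 1L, mesh_smoothing = 20L,
                               diameter_axis = "naso-temporal") {
  stopifnot(is.list(volumes), !is.null(names(volumes)))
  rows <- list()
  for (id in names(volumes)) {
    for (lab in labels) {
      m <- compute_shape_metrics(volumes[[id]], lab, mesh_smoothing)
      row <- as.data.frame(m)
      row$n_voxels <- NULL
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(specimen_id = id, label = as.integer(lab)), row,
        data.frame(diameter_mm = transverse_diameter(volumes[[id]], lab,
                                                     diameter_axis)))
    }
  }
  do.call(rbind, rows)
}
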