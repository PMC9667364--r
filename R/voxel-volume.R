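#' Construct a voxel label volume
#'
#' A `voxel_volume` wraps a 3D integer label grid (0 = background) together
#' with its physical voxel spacing in millimetres. Array dimensions follow the
#' fixed anatomical convention: dimension 1 = anterior-posterior, dimension 2 =
#' dorso-ventral, dimension 3 = naso-temporal. Voxel centers sit at
#' `(index - 0.5) * spacing` in physical coordinates.
#'
#' @param grid 3D array of non-negative integer labels.
#' @param spacing numeric length-3 (or scalar, recycled) voxel edge lengths in mm.
#' @return An object of class `voxel_volume` with elements `grid` and `spacing`.
#' @export
#' @examples
#' vol <- voxel_volume(array(1L, dim = c(4, 4, 4)), spacing = 0.01)
#' volume_labels(vol)
voxel_volume <- function(grid, spacing = 1) {
  if (length(dim(grid)) != 3L) {
    stop("grid must be a 3D array (got ", length(dim(grid)), " dimensions)")
  }
  if (anyNA(grid)) stop("grid contains missing values")
  g <- as.integer(round(grid))
  if (any(g < 0L)) stop("labels must be non-negative integers")
  if (max(abs(as.numeric(grid) - g)) > 1e-6) stop("labels must be integers")
  dim(g) <- dim(grid)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite values (mm)")
  }
  structure(list(grid = g, spacing = spacing), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  labs <- volume_labels(x)
  cat(sprintf("  foreground labels: %s\n",
              if (length(labs)) paste(labs, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Foreground labels present in a volume
#' @param volume a [voxel_volume()].
#' @return Sorted integer vector of non-zero labels present in the grid.
#' @export
volume_labels <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  labs <- sort(unique(as.vector(volume$grid)))
  labs[labs != 0L]
}

# Voxel-center coordinates (mm) of all voxels carrying `label`, one row per
# voxel. Errors if the label is absent.
.label_coords <- function(volume, label) {
  idx <- which(volume$grid == as.integer(label), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop(sprintf("label %d not present in volume (available: %s)",
                 as.integer(label),
                 paste(volume_labels(volume), collapse = ", ")))
  }
  sweep(idx - 0.5, 2, volume$spacing, `*`)
}

# Binary mask (logical array) for one label.
.label_mask <- function(volume, label) {
  m <- volume$grid == as.integer(label)
  dim(m) <- dim(volume$grid)
  m
}
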