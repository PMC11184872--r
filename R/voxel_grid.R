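#' Voxel grid geometry
#'
#' A `voxel_grid` is the common 3-D geometry that all dose, LET and dose-rate
#' maps in the package share: integer dimensions (number of voxels per axis),
#' voxel spacing in mm, and the world-frame position (mm, isocenter frame) of
#' the center of voxel index `(0, 0, 0)`.
#'
#' Voxel indices are 0-based in the external convention (file exports, spot
#' logs); internally maps are plain R arrays indexed from 1. World coordinates
#' always refer to voxel centers; masks are binary with no partial-volume
#' weighting.
#'
#' @param dims integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3, voxel spacing in mm (each > 0).
#' @param origin numeric vector of length 3, world position (mm) of the center
#'   of the first voxel. Default centers the grid on the world origin.
#' @param voxel_cap maximum allowed total voxel count; guards against
#'   accidental huge allocations. Default `2e6`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(60, 60, 60), c(2, 2, 2))
#' voxel_volume(g)  # 8 mm^3
#' @export
voxel_grid <- function(dims, spacing, origin = NULL, voxel_cap = 2e6) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be three integers >= 1")
  if (length(spacing) != 3L || any(is.na(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  if (prod(as.double(dims)) > voxel_cap)
    stop(sprintf("grid has %.3g voxels, exceeding the cap of %.3g",
                 prod(as.double(dims)), voxel_cap))
  if (is.null(origin)) origin <- -(dims - 1L) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(is.na(origin)))
    stop("`origin` must be three numbers (mm)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid a `voxel_grid`.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Voxel-center coordinates along one axis
#' @param grid a `voxel_grid`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of world coordinates (mm) of voxel centers.
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' All voxel-center coordinates as an n x 3 matrix
#' @param grid a `voxel_grid`.
#' @return matrix with one row per voxel, in array (column-major) order.
#' @export
voxel_centers <- function(grid) {
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  n <- prod(grid$dims)
  cbind(rep(xs, times = n / grid$dims[1]),
        rep(rep(ys, each = grid$dims[1]), times = grid$dims[3]),
        rep(zs, each = grid$dims[1] * grid$dims[2]))
}

# short signature used to refuse mixing maps from different grids
grid_signature <- function(grid) {
  paste(c(grid$dims, signif(grid$spacing, 10), signif(grid$origin, 10)),
        collapse = "/")
}

same_grid <- function(a, b) identical(grid_signature(a), grid_signature(b))

#' Dense scalar field on a voxel grid
#'
#' Container for total dose, dose-averaged LET, RBE-weighted dose or any other
#' per-voxel scalar. Values are stored as a 3-D array matching the grid's
#' dimensions; `NA` marks voxels where the quantity is undefined (e.g. LET_d
#' in voxels receiving no dose).
#'
#' @param grid a [voxel_grid()].
#' @param values numeric array with `dim == grid$dims` (a scalar is recycled).
#' @param units unit string, e.g. `"Gy"`, `"keV/um"`, `"Gy_RBE/s"`.
#' @param kind short label of what the field is, e.g. `"dose"`, `"letd"`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(grid, values, units = "", kind = "scalar") {
  if (length(values) == 1L) values <- array(values, dim = grid$dims)
  if (!identical(as.integer(dim(values)), grid$dims))
    stop("`values` dimensions do not match the grid")
  structure(list(grid = grid, values = values, units = units, kind = kind),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("scalar_map [%s, %s]: %d x %d x %d; range %.4g..%.4g (%d NA)\n",
              x$kind, x$units, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

#' Binary structure mask on a voxel grid
#'
#' @param name structure label, e.g. `"OC"`, `"ONL"`, `"ONR"`, `"CTV"`.
#' @param grid a [voxel_grid()].
#' @param voxels logical array with `dim == grid$dims`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, grid, voxels) {
  if (!identical(as.integer(dim(voxels)), grid$dims))
    stop("mask dimensions do not match the grid")
  structure(list(name = name, grid = grid, voxels = as.logical(voxels) |>
                   array(dim = grid$dims)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s': %d voxels (%.2f cm^3)\n", x$name,
              sum(x$voxels), sum(x$voxels) * voxel_volume(x$grid) / 1000))
  invisible(x)
}

#' Structure volume in mm^3 (voxel count times voxel volume)
#' @param mask a [structure_mask()].
#' @export
mask_volume <- function(mask) sum(mask$voxels) * voxel_volume(mask$grid)
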