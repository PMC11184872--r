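#' Geometric primitives for synthetic structures
#'
#' Structures of the synthetic head phantom (optic chiasm, optic nerves,
#' clinical target volume) are built from spheres and tubes (finite cylinders
#' with hemispherical caps omitted). A voxel belongs to a structure when its
#' center lies inside any of the structure's primitives.
#'
#' @param center,p0,p1 numeric length-3 world coordinates (mm).
#' @param radius radius in mm (> 0).
#' @return A primitive description usable in a structure spec.
#' @examples
#' sphere_prim(c(0, 0, 0), 5)
#' tube_prim(c(-6, -5, 0), c(-13, -26, 0), 2.5)
#' @export
sphere_prim <- function(center, radius) {
  stop_if_not_scalar_pos(radius, "radius")
  structure(list(type = "sphere", center = as.numeric(center), radius = radius),
            class = "phantom_prim")
}

#' @rdname sphere_prim
#' @export
tube_prim <- function(p0, p1, radius) {
  stop_if_not_scalar_pos(radius, "radius")
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (sum((p1 - p0)^2) == 0) stop("tube endpoints coincide")
  structure(list(type = "tube", p0 = p0, p1 = p1, radius = radius),
            class = "phantom_prim")
}

# vectorized point-in-primitive test; pts is an n x 3 matrix of mm coordinates
prim_contains <- function(prim, pts) {
  switch(prim$type,
    sphere = {
      d2 <- (pts[, 1] - prim$center[1])^2 + (pts[, 2] - prim$center[2])^2 +
            (pts[, 3] - prim$center[3])^2
      d2 <= prim$radius^2
    },
    tube = {
      ax <- prim$p1 - prim$p0
      len2 <- sum(ax^2)
      rel <- sweep(pts, 2, prim$p0)
      t <- (rel %*% ax)[, 1] / len2
      # perpendicular distance to the segment axis
      perp2 <- rowSums(rel^2) - t^2 * len2
      t >= 0 & t <= 1 & perp2 <= prim$radius^2
    },
    stop(sprintf("unknown primitive type '%s'", prim$type)))
}

prim_bbox <- function(prim) {
  switch(prim$type,
    sphere = rbind(prim$center - prim$radius, prim$center + prim$radius),
    tube = rbind(pmin(prim$p0, prim$p1) - prim$radius,
                 pmax(prim$p0, prim$p1) + prim$radius))
}

#' Default optic-apparatus structure spec
#'
#' A stylized intracranial geometry in the isocenter frame: a spherical target
#' volume (CTV) abutting the optic chiasm (OC), with the left and right optic
#' nerves (ONL, ONR) running anteriorly as thin tubes. OC, ONL and ONR are
#' mutually disjoint by construction; the CTV may overlap the chiasm, as is
#' common for chiasm-abutting intracranial tumours.
#'
#' @return Named list of primitive lists, one entry per structure.
#' @export
default_structure_spec <- function() {
  list(
    OC  = list(sphere_prim(c(0, 0, 0), 4)),
    ONL = list(tube_prim(c(-5.5, -3.5, 0), c(-13, -25, 0), 2.5)),
    ONR = list(tube_prim(c(5.5, -3.5, 0), c(13, -25, 0), 2.5)),
    CTV = list(sphere_prim(c(0, 16, 0), 14))
  )
}

#' Build a synthetic phantom: grid plus rasterized structure masks
#'
#' Rasterizes each structure of `structure_spec` onto a fresh voxel grid by
#' testing every voxel center against the structure's primitives. The result is
#' deterministic for fixed inputs.
#'
#' @param dims,spacing,origin passed to [voxel_grid()].
#' @param structure_spec named list: each element is a list of primitives from
#'   [sphere_prim()] / [tube_prim()]. Default [default_structure_spec()].
#' @param voxel_cap passed to [voxel_grid()].
#' @return list with elements `grid` (a `voxel_grid`) and `masks` (named list
#'   of [structure_mask()]).
#' @examples
#' ph <- make_phantom(c(40, 40, 40), c(2, 2, 2))
#' sapply(ph$masks, function(m) sum(m$voxels))
#' @export
make_phantom <- function(dims = c(60, 60, 60), spacing = c(2, 2, 2),
                         structure_spec = default_structure_spec(),
                         origin = NULL, voxel_cap = 2e6) {
  grid <- voxel_grid(dims, spacing, origin, voxel_cap)
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dims - 1) * grid$spacing + grid$spacing / 2
  pts <- voxel_centers(grid)
  masks <- lapply(names(structure_spec), function(nm) {
    prims <- structure_spec[[nm]]
    inside <- rep(FALSE, nrow(pts))
    for (p in prims) {
      bb <- prim_bbox(p)
      if (any(bb[2, ] < lo) || any(bb[1, ] > hi))
        stop(sprintf("structure '%s': primitive lies outside the grid", nm))
      inside <- inside | prim_contains(p, pts)
    }
    if (!any(inside))
      stop(sprintf("structure '%s' rasterized to zero voxels", nm))
    structure_mask(nm, grid, array(inside, dim = grid$dims))
  })
  names(masks) <- names(structure_spec)
  list(grid = grid, masks = masks)
}
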