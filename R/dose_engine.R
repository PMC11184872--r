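#' Sparse per-spot dose/LET contribution
#'
#' Result of [compute_spot_dose()]: the voxels (1-based linear indices into
#' the grid array) where one spot deposits dose at or above the sparse storage
#' cutoff, with the physical dose (Gy) and the spot's LET (keV/um) in each.
#' This is the contract between the dose engine and every metric: any engine
#' (including a Monte Carlo one) producing these records can drive the
#' dose-rate and DVH layers unchanged.
#'
#' @name spot_dose
NULL

new_spot_dose <- function(field_id, spot_id, idx, dose, let, grid) {
  structure(list(field_id = field_id, spot_id = spot_id,
                 idx = as.integer(idx), dose = as.numeric(dose),
                 let = as.numeric(let)),
            grid_sig = grid_signature(grid), class = "spot_dose")
}

#' @export
print.spot_dose <- function(x, ...) {
  cat(sprintf("spot_dose field %s spot %s: %d voxels, max %.4g Gy\n",
              x$field_id, x$spot_id, length(x$idx),
              if (length(x$dose)) max(x$dose) else 0))
  invisible(x)
}

# axis string ("x+", "y-", ...) -> list(beam axis index, sign, lateral axes)
parse_axis <- function(axis) {
  if (!is.character(axis) || length(axis) != 1L ||
      !grepl("^[xyz][+-]$", axis))
    stop("`axis` must be one of 'x+','x-','y+','y-','z+','z-'")
  b <- match(substr(axis, 1, 1), c("x", "y", "z"))
  list(beam = b, sign = if (substr(axis, 2, 2) == "+") 1 else -1,
       lat = setdiff(1:3, b))
}

# depth (mm) of voxel centers along the beam axis, measured from the grid face
# the beam enters (the face acts as the phantom surface)
beam_depths <- function(grid, ax) {
  co <- axis_coords(grid, ax$beam)
  sp <- grid$spacing[ax$beam]
  if (ax$sign > 0) co - (min(co) - sp / 2) else (max(co) + sp / 2) - co
}

#' Compute one spot's dose and LET on the grid
#'
#' Evaluates the analytic pencil-beam model for a single spot: MU-scaled depth
#' dose times a lateral 2-D Gaussian (unit lateral integral), sampled at voxel
#' centers, with a per-depth LET from the residual range. Entries below the
#' sparse storage `cutoff` are omitted. Dose is dose to water, per delivery of
#' the spot (i.e. per fraction when the plan is delivered once per fraction).
#'
#' @param spot list or one-row data.frame with `field_id`, `spot_id`,
#'   `energy_mev`, `x_mm`, `y_mm`, `mu`. `x_mm`/`y_mm` are lateral scanning
#'   coordinates mapped onto the two non-beam grid axes in ascending axis
#'   order.
#' @param grid a [voxel_grid()].
#' @param bm a [beam_model()].
#' @param axis beam direction, e.g. `"y+"` (beam travels along +y, entering
#'   through the grid face at minimal y).
#' @param cutoff sparse storage cutoff in Gy per spot (default `1e-4`);
#'   distinct from the metric-level dose threshold.
#' @return A [`spot_dose`] object (possibly empty, with a warning, if the beam
#'   misses the grid).
#' @export
compute_spot_dose <- function(spot, grid, bm = beam_model(), axis = "y+",
                              cutoff = 1e-4) {
  if (is.data.frame(spot)) spot <- as.list(spot[1, ])
  if (cutoff < 0) stop("`cutoff` must be >= 0")
  e <- spot$energy_mev
  if (is.null(e) || e < bm$e_min || e > bm$e_max)
    stop(sprintf("spot energy %.4g MeV outside commissioned span [%g, %g]",
                 e, bm$e_min, bm$e_max))
  if (spot$mu <= 0) stop("spot mu must be > 0")
  ax <- parse_axis(axis)
  z <- beam_depths(grid, ax)
  r0 <- range_from_energy(e, bm)
  dd <- depth_dose(z, r0, bm)
  keep_z <- which(dd > 1e-4 * max(dd))
  u <- axis_coords(grid, ax$lat[1]) - spot$x_mm
  v <- axis_coords(grid, ax$lat[2]) - spot$y_mm
  empty <- function() {
    warning(sprintf("spot %s/%s deposits no dose >= cutoff on the grid",
                    spot$field_id, spot$spot_id))
    new_spot_dose(spot$field_id, spot$spot_id, integer(0), numeric(0),
                  numeric(0), grid)
  }
  if (!length(keep_z)) return(empty())
  sig <- lateral_sigma(z, bm)
  smax <- max(sig[keep_z])
  ku <- which(abs(u) <= 4 * smax)
  kv <- which(abs(v) <= 4 * smax)
  if (!length(ku) || !length(kv)) return(empty())
  lets <- let_curve(r0 - z, bm)
  nd <- grid$dims
  stride <- c(1L, nd[1], nd[1] * nd[2])
  idx_l <- dose_l <- let_l <- vector("list", length(keep_z))
  n_out <- 0L
  for (j in seq_along(keep_z)) {
    iz <- keep_z[j]
    s2 <- sig[iz]^2
    amp <- spot$mu * bm$mu_calibration * dd[iz] / (2 * pi * s2)
    if (amp * exp(-(min(abs(u[ku]))^2 + min(abs(v[kv]))^2) / (2 * s2)) < cutoff &&
        amp < cutoff) next
    gu <- exp(-u[ku]^2 / (2 * s2))
    gv <- exp(-v[kv]^2 / (2 * s2))
    slab <- amp * outer(gu, gv)
    sel <- which(slab >= cutoff)
    if (!length(sel)) next
    iu <- ku[(sel - 1L) %% length(ku) + 1L]
    iv <- kv[(sel - 1L) %/% length(ku) + 1L]
    pos <- 1L +
      (iu - 1L) * stride[ax$lat[1]] +
      (iv - 1L) * stride[ax$lat[2]] +
      (iz - 1L) * stride[ax$beam]
    n_out <- n_out + 1L
    idx_l[[n_out]] <- pos
    dose_l[[n_out]] <- slab[sel]
    let_l[[n_out]] <- rep(lets[iz], length(sel))
  }
  if (n_out == 0L) return(empty())
  new_spot_dose(spot$field_id, spot$spot_id,
                unlist(idx_l[seq_len(n_out)]),
                unlist(dose_l[seq_len(n_out)]),
                unlist(let_l[seq_len(n_out)]), grid)
}

#' Compute sparse doses for a whole spot table
#'
#' @param spots data.frame with columns `field_id, spot_id, energy_mev, x_mm,
#'   y_mm, mu`.
#' @param grid a [voxel_grid()].
#' @param bm a [beam_model()].
#' @param axes named character vector mapping `field_id` to a beam axis
#'   string, or a single axis used for all fields.
#' @param cutoff sparse storage cutoff in Gy.
#' @return list of [`spot_dose`] objects, in row order of `spots`.
#' @export
compute_spot_doses <- function(spots, grid, bm = beam_model(), axes = "y+",
                               cutoff = 1e-4) {
  fid <- as.character(spots$field_id)
  ax_for <- function(f) {
    if (length(axes) == 1L && is.null(names(axes))) axes
    else {
      a <- axes[[f]]
      if (is.null(a)) stop(sprintf("no beam axis for field '%s'", f))
      a
    }
  }
  lapply(seq_len(nrow(spots)), function(i)
    compute_spot_dose(spots[i, ], grid, bm, ax_for(fid[i]), cutoff))
}

check_same_grid <- function(spot_doses, grid) {
  sigs <- vapply(spot_doses, function(s) attr(s, "grid_sig"), character(1))
  if (length(unique(c(sigs, grid_signature(grid)))) != 1L)
    stop("spot doses computed on different grids cannot be combined")
}

#' Accumulate total dose over spots
#'
#' Voxelwise sum of the sparse contributions; the plan dose map equals the sum
#' of its field dose maps by linearity.
#'
#' @param spot_doses list of [`spot_dose`] objects on one grid.
#' @param grid the common [voxel_grid()].
#' @return A [scalar_map()] of physical dose in Gy (per fraction when spot
#'   doses are per fraction).
#' @export
accumulate_dose <- function(spot_doses, grid) {
  check_same_grid(spot_doses, grid)
  vals <- array(0, dim = grid$dims)
  for (s in spot_doses)
    if (length(s$idx)) vals[s$idx] <- vals[s$idx] + s$dose
  scalar_map(grid, vals, units = "Gy", kind = "dose")
}

#' Accumulate dose-averaged LET over spots
#'
#' \deqn{LET_d(v) = \sum_s d_s(v) L_s(v) / \sum_s d_s(v)} — the dose-weighted
#' mean of each contributing spot's LET. Voxels receiving no dose have
#' undefined LET_d and are `NA` in the result.
#'
#' @inheritParams accumulate_dose
#' @return A [scalar_map()] of LET_d in keV/um with `NA` where no dose.
#' @export
accumulate_letd <- function(spot_doses, grid) {
  check_same_grid(spot_doses, grid)
  num <- array(0, dim = grid$dims)
  den <- array(0, dim = grid$dims)
  for (s in spot_doses) {
    if (!length(s$idx)) next
    num[s$idx] <- num[s$idx] + s$dose * s$let
    den[s$idx] <- den[s$idx] + s$dose
  }
  vals <- num / den
  vals[den == 0] <- NA_real_
  scalar_map(grid, vals, units = "keV/um", kind = "letd")
}

#' Rescale a set of spot doses (and drop entries below a cutoff)
#'
#' Dose is linear in MU, so a global MU rescaling rescales every sparse entry
#' by the same factor. Used for target-dose calibration of generated plans.
#'
#' @param spot_doses list of [`spot_dose`] objects.
#' @param factor multiplicative dose factor (> 0).
#' @param cutoff entries falling below this dose after scaling are dropped.
#' @return list of rescaled [`spot_dose`] objects.
#' @export
scale_spot_doses <- function(spot_doses, factor, cutoff = 0) {
  stop_if_not_scalar_pos(factor, "factor")
  lapply(spot_doses, function(s) {
    s$dose <- s$dose * factor
    if (cutoff > 0) {
      keep <- s$dose >= cutoff
      s$idx <- s$idx[keep]; s$dose <- s$dose[keep]; s$let <- s$let[keep]
    }
    s
  })
}
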