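#' Default synthetic cohort specification
#'
#' Eight intracranial cases emulating the reference cohort this generator is
#' designed around: prescriptions 50.4-55.8 Gy_RBE at 1.8 Gy_RBE per fraction
#' (1.93 for the 54 Gy_RBE case), 3-4 fields per plan and 28 fields in total.
#' Cases are labelled `Tx-yy` where `Tx` is the grade of late visual toxicity
#' and `yy` the position in the group; the two index (toxicity) cases carry
#' `index_flag` and a designated "hot" field that delivers its dose at
#' elevated instantaneous dose rate toward the targeted optic nerve — the
#' planted signal the recovery tests look for.
#'
#' Generator knobs beyond the roster: lateral spot spacing and energy-layer
#' spacing (mm), nominal spot MU and its uniform jitter, the hot-field MU
#' boost for spots aimed near the targeted nerve, the hot-field beam-current
#' factor (shortening durations at fixed MU), and the beam-axis pool fields
#' cycle through.
#'
#' @return list with `cases` (data.frame roster) and generator parameters.
#' @export
default_cohort_spec <- function() {
  cases <- data.frame(
    case_id = c("T0-01", "T0-02", "T4-03", "T0-04",
                "T0-05", "T3-06", "T0-07", "T0-08"),
    diagnosis = c("Meningioma, WHO Grade 2", "Meningioma, WHO Grade 1",
                  "Mature Teratoma", "Meningioma, unspecified",
                  "Meningioma, WHO Grade 1", "Meningioma, unspecified",
                  "Meningioma, WHO Grade 1", "Meningioma, WHO Grade 1"),
    prescribed_dose = c(55.8, 50.4, 50.4, 50.4, 54, 50.4, 50.4, 50.4),
    fraction_dose = c(1.8, 1.8, 1.8, 1.8, 1.93, 1.8, 1.8, 1.8),
    toxicity_grade = c(0L, 0L, 4L, 0L, 0L, 3L, 0L, 0L),
    index_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    n_fields = c(4L, 3L, 4L, 3L, 4L, 3L, 4L, 3L),
    stringsAsFactors = FALSE)
  list(cases = cases,
       spot_spacing_mm = 4, layer_spacing_mm = 5, lateral_margin_mm = 2,
       mu_nominal = 5, mu_jitter = 0.05,
       hot_mu_factor = 1.2, hot_current_factor = 1.5,
       hot_target = "ONL", hot_radius_mm = 12,
       axes_pool = c("z+", "x+", "x-", "y+"))
}

# lateral projection of a world point for a given beam axis
lateral_of <- function(point, ax) point[ax$lat]

# centroid and equivalent-sphere radius of a mask
mask_centroid <- function(mask) {
  pts <- voxel_centers(mask$grid)[as.vector(mask$voxels), , drop = FALSE]
  list(center = colMeans(pts), pts = pts,
       radius = (3 * mask_volume(mask) / (4 * pi))^(1 / 3))
}

# spots of one field: energy layers across the CTV depth span, a lateral
# square grid covering the CTV cross-section per layer, MU ramped toward the
# distal layers (SOBP-like weighting)
field_spots <- function(field_id, axis, ctv, grid, bm, spec, hot,
                        hot_lat = NULL) {
  ax <- parse_axis(axis)
  depth_all <- beam_depths(grid, ax)
  # depth of the CTV voxels along this beam axis
  co_b <- ctv$pts[, ax$beam]
  d_of <- function(w) depth_all[round((w - grid$origin[ax$beam]) /
                                        grid$spacing[ax$beam]) + 1]
  depths <- d_of(co_b)
  dmin <- min(depths); dmax <- max(depths)
  layer_d <- seq(dmin + spec$layer_spacing_mm / 2, dmax,
                 by = spec$layer_spacing_mm)
  if (!length(layer_d)) layer_d <- (dmin + dmax) / 2
  d_center <- d_of(ctv$center[ax$beam])
  c1 <- ctv$center[ax$lat[1]]; c2 <- ctv$center[ax$lat[2]]
  s <- spec$spot_spacing_mm
  off <- seq(-ceiling(ctv$radius / s) * s, ceiling(ctv$radius / s) * s, by = s)
  rows <- list()
  for (li in seq_along(layer_d)) {
    d <- layer_d[li]
    chord <- sqrt(pmax(ctv$radius^2 - (d - d_center)^2, 0))
    rho <- chord + spec$lateral_margin_mm
    g <- expand.grid(u = c1 + off, v = c2 + off)
    g <- g[(g$u - c1)^2 + (g$v - c2)^2 <= rho^2, , drop = FALSE]
    if (hot && !is.null(hot_lat)) {
      # hot fields are patch fields: their spots cluster on the CTV rim
      # nearest the targeted nerve, so the short-duration signal is local
      g <- g[(g$u - hot_lat[1])^2 + (g$v - hot_lat[2])^2 <=
               spec$hot_radius_mm^2, , drop = FALSE]
    }
    if (!nrow(g)) next
    frac <- if (dmax > dmin) (d - dmin) / (dmax - dmin) else 1
    w <- 0.35 + 0.65 * frac^2
    mu <- spec$mu_nominal * 2 * w *
      stats::runif(nrow(g), 1 - spec$mu_jitter, 1 + spec$mu_jitter)
    is_hot <- rep(hot, nrow(g))
    if (hot) mu <- mu * spec$hot_mu_factor
    rows[[length(rows) + 1L]] <- data.frame(
      field_id = field_id, energy_mev = energy_from_range(d, bm),
      x_mm = g$u, y_mm = g$v, mu = mu, hot = is_hot,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$spot_id <- seq_len(nrow(out))
  out[, c("field_id", "spot_id", "energy_mev", "x_mm", "y_mm", "mu", "hot")]
}

#' Generate the synthetic cohort
#'
#' Builds, for every case of the roster, a target-conformal spot map on the
#' phantom: each field covers the CTV with energy layers along its beam axis
#' and a lateral spot grid over the CTV cross-section, with distally-ramped
#' MU weights. Index cases get one hot field (beam axis along z so its
#' scanning plane contains the optic-nerve projection): spots whose lateral
#' position falls near the targeted optic nerve receive an MU boost, and the
#' whole field is marked for a beam-current boost so its spot durations
#' shorten. Fully reproducible for a fixed seed.
#'
#' @param spec cohort specification, see [default_cohort_spec()].
#' @param phantom result of [make_phantom()] (needs a `CTV` mask and the
#'   hot-target structure).
#' @param bm a [beam_model()].
#' @param seed integer seed.
#' @return list of `plan_case` objects, each with the roster fields plus
#'   `n_fractions`, `fields` (data.frame `field_id, axis, hot,
#'   current_factor`) and `spots` (data.frame in spot-map CSV layout plus a
#'   `hot` flag).
#' @export
make_cohort <- function(spec = default_cohort_spec(), phantom = make_phantom(),
                        bm = beam_model(), seed = 1) {
  cases <- spec$cases
  if (any(cases$n_fields < 3L | cases$n_fields > 4L))
    stop("number of fields per case must be 3 or 4")
  n_frac <- cases$prescribed_dose / cases$fraction_dose
  if (any(abs(n_frac - round(n_frac)) > 0.5))
    stop("prescribed/fraction dose is not close to an integer fraction count")
  ctv <- mask_centroid(phantom$masks$CTV)
  hot_mask <- phantom$masks[[spec$hot_target]]
  if (is.null(hot_mask))
    stop(sprintf("hot target structure '%s' not in phantom", spec$hot_target))
  # nerve voxel nearest the CTV: where the planted high-dose-rate cloud
  # should touch the structure
  hpts <- voxel_centers(phantom$grid)[as.vector(hot_mask$voxels), ,
                                      drop = FALSE]
  hot_point <- hpts[which.min(colSums((t(hpts) - ctv$center)^2)), ]
  lapply(seq_len(nrow(cases)), function(i) {
    ci <- cases[i, ]
    with_seed(child_seed(seed, i), {
      nf <- ci$n_fields
      axes <- character(nf)
      axes[1] <- spec$axes_pool[1]
      if (nf > 1)
        axes[-1] <- spec$axes_pool[2 + ((seq_len(nf - 1) + i - 2) %%
                                          (length(spec$axes_pool) - 1))]
      hot_field <- if (ci$index_flag) 1L else 0L
      fields <- data.frame(
        field_id = sprintf("F%d", seq_len(nf)), axis = axes,
        hot = seq_len(nf) == hot_field,
        current_factor = ifelse(seq_len(nf) == hot_field,
                                spec$hot_current_factor, 1),
        stringsAsFactors = FALSE)
      spots <- do.call(rbind, lapply(seq_len(nf), function(f) {
        ax <- parse_axis(axes[f])
        field_spots(fields$field_id[f], axes[f], ctv, phantom$grid, bm, spec,
                    hot = fields$hot[f], hot_lat = hot_point[ax$lat])
      }))
      rownames(spots) <- NULL
      structure(list(case_id = ci$case_id, diagnosis = ci$diagnosis,
                     prescribed_dose = ci$prescribed_dose,
                     fraction_dose = ci$fraction_dose,
                     n_fractions = round(ci$prescribed_dose / ci$fraction_dose),
                     toxicity_grade = ci$toxicity_grade,
                     index_flag = ci$index_flag,
                     fields = fields, spots = spots),
                class = "plan_case")
    })
  })
}

#' @export
print.plan_case <- function(x, ...) {
  cat(sprintf("plan_case %s (%s): %.1f Gy_RBE in %d fx, %d fields, %d spots%s\n",
              x$case_id, x$diagnosis, x$prescribed_dose, x$n_fractions,
              nrow(x$fields), nrow(x$spots),
              if (x$index_flag) " [index]" else ""))
  invisible(x)
}
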