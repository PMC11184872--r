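#' Dose-rate analysis configuration
#'
#' Parameters of the voxel-wise maximum dose-rate (MDR) analysis.
#'
#' * `dose_threshold` — Gy per fraction; a voxel enters the MDR map only when
#'   its total per-fraction RBE-weighted dose reaches this value (default
#'   0.01 Gy = 1 cGy). Absolute MDR values are sensitive to this choice.
#' * `rbe_constant` — the constant RBE factor applied so MDR is reported in
#'   Gy_RBE/s (default 1.1); set to 1 for physical Gy/s.
#' * `percentile_level` — volume level (%) of the near-maximum metrics
#'   (default 2, i.e. D2/LET2/MDR2).
#' * `display_threshold` — Gy_RBE/s; overlay exports show MDR only at or
#'   above this value (default 3). Presentation-only: it never affects
#'   metric values.
#' * `threshold_mode` — `"total"` (default) gates voxel eligibility by total
#'   per-fraction dose; `"per_spot"` instead drops individual spot
#'   contributions below `dose_threshold` and keeps voxels with at least one
#'   qualifying contribution.
#'
#' @param dose_threshold Gy per fraction (>= 0).
#' @param rbe_constant unitless (> 0).
#' @param percentile_level percent of structure volume in (0, 100).
#' @param display_threshold Gy_RBE/s (>= 0).
#' @param threshold_mode `"total"` or `"per_spot"`.
#' @return An object of class `dose_rate_config`.
#' @export
dose_rate_config <- function(dose_threshold = 0.01, rbe_constant = 1.1,
                             percentile_level = 2, display_threshold = 3,
                             threshold_mode = c("total", "per_spot")) {
  if (dose_threshold < 0) stop("`dose_threshold` must be >= 0")
  stop_if_not_scalar_pos(rbe_constant, "rbe_constant")
  if (percentile_level <= 0 || percentile_level >= 100)
    stop("`percentile_level` must be in (0, 100)")
  if (display_threshold < 0) stop("`display_threshold` must be >= 0")
  structure(list(dose_threshold = dose_threshold,
                 rbe_constant = rbe_constant,
                 percentile_level = percentile_level,
                 display_threshold = display_threshold,
                 threshold_mode = match.arg(threshold_mode)),
            class = "dose_rate_config")
}

# duration (s) lookup table from a log: names "field/spot"
duration_lookup <- function(log) {
  d <- log$duration_us * 1e-6
  names(d) <- paste(log$field_id, log$spot_id, sep = "/")
  d
}

#' Instantaneous dose rate of one spot
#'
#' The dose rate a voxel sees during one spot is the ratio of the spot's dose
#' in that voxel to the spot's beam-on delivery time:
#' \eqn{\dot d_s(v) = RBE \cdot d_s(v) / t_s}, in Gy_RBE/s.
#'
#' @param spot_dose a [`spot_dose`] object.
#' @param timing matching one-row log record (needs `duration_us`), or a
#'   duration in microseconds.
#' @param rbe_constant constant RBE factor (default 1.1).
#' @return list with `idx` (voxel indices) and `rate` (Gy_RBE/s).
#' @export
spot_dose_rate <- function(spot_dose, timing, rbe_constant = 1.1) {
  dur_us <- if (is.numeric(timing)) timing else timing$duration_us
  if (is.null(dur_us) || length(dur_us) != 1L || is.na(dur_us))
    stop(sprintf("missing timing for spot %s/%s",
                 spot_dose$field_id, spot_dose$spot_id))
  if (dur_us <= 0) stop("spot duration must be positive")
  list(idx = spot_dose$idx,
       rate = rbe_constant * spot_dose$dose / (dur_us * 1e-6))
}

#' Voxel-wise maximum dose-rate (MDR) map
#'
#' For every voxel, the maximum over all in-scope spots of that spot's dose
#' rate in the voxel. MDR is defined at the treatment-plan level
#' (`scope = "plan"`); passing a field id restricts the maximum (and, under
#' the default gating, the validity dose) to that field's spots. A voxel is
#' valid only when its total per-fraction RBE-weighted dose in scope reaches
#' `config$dose_threshold`; invalid voxels are `NA` and never enter structure
#' metrics.
#'
#' @param spot_doses list of [`spot_dose`] objects (the full plan).
#' @param log delivery log data.frame covering every in-scope spot.
#' @param grid the common [voxel_grid()].
#' @param config a [dose_rate_config()].
#' @param scope `"plan"` or a single field id.
#' @return An object of class `mdr_map` (also a `scalar_map`): fields `grid`,
#'   `values` (Gy_RBE/s, `NA` where invalid), `valid` (logical array),
#'   `provenance` (`"plan"` or the field id), `threshold_used` (Gy).
#' @export
compute_mdr <- function(spot_doses, log, grid, config = dose_rate_config(),
                        scope = "plan") {
  check_same_grid(spot_doses, grid)
  if (!identical(scope, "plan")) {
    spot_doses <- Filter(function(s) as.character(s$field_id) ==
                           as.character(scope), spot_doses)
    if (!length(spot_doses))
      stop(sprintf("scope '%s' selects no spots", scope))
  } else if (!length(spot_doses)) stop("empty scope: no spots")
  dur <- duration_lookup(log)
  rbe <- config$rbe_constant
  thr <- config$dose_threshold
  vals <- array(-Inf, dim = grid$dims)
  total <- array(0, dim = grid$dims)
  per_spot_ok <- array(FALSE, dim = grid$dims)
  for (s in spot_doses) {
    if (!length(s$idx)) next
    key <- paste(s$field_id, s$spot_id, sep = "/")
    t_s <- dur[[key]]
    if (is.null(t_s) || is.na(t_s))
      stop(sprintf("missing timing for spot %s", key))
    rate <- rbe * s$dose / t_s
    idx <- s$idx
    if (config$threshold_mode == "per_spot") {
      keep <- rbe * s$dose >= thr
      if (any(keep)) per_spot_ok[idx[keep]] <- TRUE
      idx <- idx[keep]; rate <- rate[keep]
      if (!length(idx)) next
    } else {
      total[idx] <- total[idx] + s$dose
    }
    vals[idx] <- pmax(vals[idx], rate)
  }
  valid <- if (config$threshold_mode == "total")
    (rbe * total) >= thr else per_spot_ok
  vals[!valid | !is.finite(vals)] <- NA_real_
  structure(list(grid = grid, values = vals, valid = valid,
                 provenance = if (identical(scope, "plan")) "plan"
                              else as.character(scope),
                 threshold_used = thr, rbe_constant = rbe,
                 units = if (rbe == 1) "Gy/s" else "Gy_RBE/s",
                 kind = "mdr"),
            class = c("mdr_map", "scalar_map"))
}

#' Near-maximum value over a structure (DVH-style)
#'
#' The value received by the "hottest" `level`% of the structure's volume:
#' with the structure's eligible voxels sorted in decreasing map value, the
#' k-th largest value where `k = ceiling(level/100 * n)`. This single routine
#' implements D2 (dose), LET2 (dose-averaged LET), variable-RBE D2, and MDR2
#' (dose rate) — all at the default level of 2% of the structure volume.
#' Volume is counted in whole voxels (voxel count times voxel volume), with
#' no interpolation; as `level` approaches 0 the metric tends to the masked
#' maximum, and at 100 it is the masked minimum.
#'
#' Voxels with undefined values (`NA`: invalid MDR voxels, LET_d without
#' dose) are excluded from the eligible set.
#'
#' @param map a [scalar_map()] or `mdr_map`.
#' @param mask a [structure_mask()] on the same grid.
#' @param level percent of structure volume in (0, 100].
#' @return the near-maximum value (same units as the map).
#' @export
near_max <- function(map, mask, level = 2) {
  if (!same_grid(map$grid, mask$grid))
    stop("map and mask are on different grids")
  if (level <= 0 || level > 100) stop("`level` must be in (0, 100]")
  v <- map$values[mask$voxels]
  v <- v[!is.na(v)]
  if (!length(v))
    stop(sprintf("structure '%s' has no eligible voxels in the %s map",
                 mask$name, map$kind %||% "given"))
  k <- ceiling(level / 100 * length(v))
  sort(v, decreasing = TRUE)[k]
}

#' Field-wise MDR2 table
#'
#' One row per (case, field, structure) with the near-maximum dose rate of
#' that field's MDR map over the structure. For the default 8-case, 28-field
#' cohort and the three optic structures this table has 84 rows.
#'
#' @param field_maps nested named list: `field_maps[[case_id]][[field_id]]` is
#'   the field's `mdr_map`.
#' @param masks named list of [structure_mask()] (the structures to score).
#' @param level percent volume level (default 2).
#' @return data.frame `case_id, field_id, structure, metric, value, units`.
#' @export
fieldwise_mdr2_table <- function(field_maps, masks, level = 2) {
  rows <- list()
  for (cid in names(field_maps)) {
    fm <- field_maps[[cid]]
    for (fid in names(fm)) {
      m <- fm[[fid]]
      if (is.null(m)) stop(sprintf("missing MDR map for case %s field %s",
                                   cid, fid))
      for (sn in names(masks)) {
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = cid, field_id = fid, structure = sn,
          metric = sprintf("MDR%g", level),
          value = near_max(m, masks[[sn]], level),
          units = m$units, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative dose delivered at or above a dose-rate threshold
#'
#' Sums, over the masked voxels, only those per-spot dose contributions whose
#' instantaneous dose rate reaches `rate_threshold`, and reports the sum both
#' in Gy_RBE and as a percentage of the total masked dose. A threshold of 0
#' returns 100% of the masked dose; a threshold above every spot rate returns
#' 0.
#'
#' @param spot_doses list of [`spot_dose`] objects.
#' @param log delivery log covering the spots.
#' @param mask a [structure_mask()].
#' @param rate_threshold Gy_RBE/s (>= 0).
#' @param rbe_constant constant RBE factor (default 1.1).
#' @return named numeric vector `c(dose_gyrbe = , pct = )`.
#' @export
dose_above_dose_rate <- function(spot_doses, log, mask, rate_threshold,
                                 rbe_constant = 1.1) {
  if (rate_threshold < 0) stop("`rate_threshold` must be >= 0")
  if (!any(mask$voxels)) stop(sprintf("structure '%s' is empty", mask$name))
  dur <- duration_lookup(log)
  in_mask <- as.vector(mask$voxels)
  tot <- 0; above <- 0
  for (s in spot_doses) {
    if (!length(s$idx)) next
    key <- paste(s$field_id, s$spot_id, sep = "/")
    t_s <- dur[[key]]
    if (is.null(t_s) || is.na(t_s))
      stop(sprintf("missing timing for spot %s", key))
    sel <- in_mask[s$idx]
    if (!any(sel)) next
    d <- rbe_constant * s$dose[sel]
    tot <- tot + sum(d)
    rate <- d / t_s  # rate and dose share the RBE factor; ratio unaffected
    above <- above + sum(d[rate >= rate_threshold])
  }
  c(dose_gyrbe = above, pct = if (tot > 0) 100 * above / tot else 0)
}
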