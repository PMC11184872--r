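# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (no near_max/compute_mdr/accumulate_* calls) so that agreement is
# a genuine cross-check.

# DVH-style near-maximum by explicit sort-and-count over eligible values
oracle_near_max <- function(values, level) {
  v <- sort(values[!is.na(values)], decreasing = TRUE)
  n <- length(v)
  k <- ceiling(level / 100 * n)
  v[k]
}

# exhaustive per-voxel maximum over all spot rates, with total-dose gating
oracle_mdr <- function(spot_doses, durations_us, n_voxels, rbe, threshold) {
  total <- numeric(n_voxels)
  best <- rep(NA_real_, n_voxels)
  for (si in seq_along(spot_doses)) {
    s <- spot_doses[[si]]
    t_s <- durations_us[[paste(s$field_id, s$spot_id, sep = "/")]] * 1e-6
    for (j in seq_along(s$idx)) {
      v <- s$idx[j]
      total[v] <- total[v] + s$dose[j]
      r <- rbe * s$dose[j] / t_s
      if (is.na(best[v]) || r > best[v]) best[v] <- r
    }
  }
  best[rbe * total < threshold] <- NA_real_
  best
}

# per-voxel dose-weighted LET mean by explicit loops
oracle_letd <- function(spot_doses, n_voxels) {
  num <- numeric(n_voxels); den <- numeric(n_voxels)
  for (s in spot_doses)
    for (j in seq_along(s$idx)) {
      v <- s$idx[j]
      num[v] <- num[v] + s$dose[j] * s$let[j]
      den[v] <- den[v] + s$dose[j]
    }
  out <- rep(NA_real_, n_voxels)
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

# filter-and-sum over every (spot, voxel) contribution in the mask
oracle_dadr <- function(spot_doses, durations_us, in_mask, rate_threshold,
                        rbe) {
  tot <- 0; above <- 0
  for (s in spot_doses) {
    t_s <- durations_us[[paste(s$field_id, s$spot_id, sep = "/")]] * 1e-6
    for (j in seq_along(s$idx)) {
      if (!in_mask[s$idx[j]]) next
      d <- rbe * s$dose[j]
      tot <- tot + d
      if (d / t_s >= rate_threshold) above <- above + d
    }
  }
  c(dose_gyrbe = above, pct = if (tot > 0) 100 * above / tot else 0)
}

# point-in-primitive rasterization computed from scratch (own coordinate math)
oracle_rasterize <- function(prims, dims, spacing, origin) {
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  out <- array(FALSE, dim = dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      p <- c(xs[i], ys[j], zs[k])
      for (pr in prims) {
        inside <- if (pr$type == "sphere") {
          sum((p - pr$center)^2) <= pr$radius^2
        } else {
          ax <- pr$p1 - pr$p0
          t <- sum((p - pr$p0) * ax) / sum(ax^2)
          t >= 0 && t <= 1 &&
            sum((p - pr$p0 - t * ax)^2) <= pr$radius^2
        }
        if (inside) { out[i, j, k] <- TRUE; break }
      }
    }
  out
}
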