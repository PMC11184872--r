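test_that("spot dose rate is the dose/duration ratio, RBE-weighted", {
  g <- tiny_grid()
  s <- fake_spot_dose(g, idx = 5, dose = 0.02)
  expect_equal(spot_dose_rate(s, 5000, 1.1)$rate, 4.4)  # 0.02 Gy over 5 ms
  expect_equal(spot_dose_rate(s, 2500, 1.1)$rate,
               2 * spot_dose_rate(s, 5000, 1.1)$rate)
  case <- random_sparse_case(g, n_spots = 6, seed = 3)
  dur <- setNames(case$log$duration_us,
                  paste(case$log$field_id, case$log$spot_id, sep = "/"))
  for (s in case$spot_doses) {
    key <- paste(s$field_id, s$spot_id, sep = "/")
    got <- spot_dose_rate(s, dur[[key]], 1.1)
    expect_equal(got$rate, 1.1 * s$dose / (dur[[key] ] * 1e-6),
                 tolerance = 1e-12)
  }
  expect_error(spot_dose_rate(s, NA_real_), "missing timing")
})

test_that("MDR of a single-spot plan is its rate map on valid voxels", {
  g <- tiny_grid()
  s <- fake_spot_dose(g, idx = c(1, 2, 3), dose = c(0.05, 0.02, 0.004))
  log <- data.frame(field_id = "F1", spot_id = 1L, t_start_us = 0,
                    t_end_us = 5000, duration_us = 5000)
  m <- compute_mdr(list(s), log, g, dose_rate_config(), "plan")
  expect_equal(m$values[1], 1.1 * 0.05 / 0.005)
  expect_equal(m$values[2], 1.1 * 0.02 / 0.005)
  # voxel 3: total RBE dose 0.0044 < 1 cGy threshold -> invalid
  expect_true(is.na(m$values[3]))
  expect_false(m$valid[3])
  expect_true(all(is.na(m$values[-(1:3)])))
})

test_that("MDR equals the exhaustive per-voxel oracle on random cases", {
  g <- tiny_grid(7)
  for (seed in 1:5) {
    case <- random_sparse_case(g, n_spots = 20, n_fields = 3, seed = seed)
    cfg <- dose_rate_config()
    got <- compute_mdr(case$spot_doses, case$log, g, cfg, "plan")
    dur <- as.list(setNames(case$log$duration_us,
                            paste(case$log$field_id, case$log$spot_id,
                                  sep = "/")))
    want <- oracle_mdr(case$spot_doses, dur, prod(g$dims),
                       cfg$rbe_constant, cfg$dose_threshold)
    expect_equal(as.vector(got$values), want, tolerance = 1e-12)
  }
})

test_that("plan MDR is the voxelwise max of field MDRs on shared valid set", {
  g <- tiny_grid(7)
  case <- random_sparse_case(g, n_spots = 24, n_fields = 3, seed = 9)
  cfg <- dose_rate_config()
  plan <- compute_mdr(case$spot_doses, case$log, g, cfg, "plan")
  fids <- unique(case$log$field_id)
  fmaps <- lapply(fids, function(f)
    compute_mdr(case$spot_doses, case$log, g, cfg, f))
  fmax <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE),
                 lapply(fmaps, function(m) m$values))
  shared <- plan$valid & !is.na(fmax)
  expect_equal(plan$values[shared], fmax[shared], tolerance = 1e-12)
  # MDR2 on a shared valid set: plan >= any field (pointwise dominance)
  for (m in fmaps) {
    el <- !is.na(m$values)
    if (!any(el)) next
    msk <- structure_mask("S", g, array(el, dim = g$dims))
    expect_gte(near_max(plan, msk, 2), near_max(m, msk, 2))
  }
})

test_that("raising the dose threshold monotonically shrinks the valid set", {
  g <- tiny_grid(7)
  case <- random_sparse_case(g, n_spots = 15, seed = 2)
  thr <- c(0, 0.005, 0.01, 0.02, 0.05)
  valid_counts <- sapply(thr, function(t)
    sum(compute_mdr(case$spot_doses, case$log, g,
                    dose_rate_config(dose_threshold = t), "plan")$valid))
  expect_true(all(diff(valid_counts) <= 0))
})

test_that("per-spot threshold mode gates individual contributions", {
  g <- tiny_grid()
  s1 <- fake_spot_dose(g, idx = 1, dose = 0.004, spot_id = 1L)  # sub-cGy
  s2 <- fake_spot_dose(g, idx = 1, dose = 0.007, spot_id = 2L)
  log <- data.frame(field_id = "F1", spot_id = 1:2,
                    t_start_us = c(0, 6000), t_end_us = c(5000, 11000),
                    duration_us = c(5000, 5000))
  # total 0.011 Gy_RBE-weighted passes 1 cGy; the max is the faster rate
  tot <- compute_mdr(list(s1, s2), log, g,
                     dose_rate_config(threshold_mode = "total"), "plan")
  expect_equal(tot$values[1], 1.1 * 0.007 / 0.005)
  # per-spot: only contributions >= 1 cGy (RBE) count; both fall below
  ps <- compute_mdr(list(s1, s2), log, g,
                    dose_rate_config(threshold_mode = "per_spot"), "plan")
  expect_true(is.na(ps$values[1]))
})

test_that("near_max follows the DVH convention and its limits", {
  g <- voxel_grid(c(10, 10, 1), c(2, 2, 2))
  vals <- array(as.numeric(1:100), dim = g$dims)
  m <- scalar_map(g, vals)
  msk <- full_mask(g)
  expect_equal(near_max(m, msk, 2), 99)   # two hottest voxels are 2%
  expect_equal(near_max(m, msk, 100), 1)  # level 100 is the minimum
  expect_equal(near_max(m, msk, 1e-9), 100)
  u <- scalar_map(g, array(7, dim = g$dims))
  for (lv in c(0.5, 2, 50, 100)) expect_equal(near_max(u, msk, lv), 7)
  # monotone non-increasing in level, and equal to the sort oracle
  set.seed(4)
  r <- scalar_map(g, array(rexp(100), dim = g$dims))
  lv <- c(0.5, 1, 2, 5, 10, 25, 50, 75, 100)
  got <- sapply(lv, function(l) near_max(r, msk, l))
  expect_true(all(diff(got) <= 0))
  expect_equal(got, sapply(lv, function(l) oracle_near_max(r$values, l)))
  empty <- structure_mask("E", g, array(FALSE, dim = g$dims))
  expect_error(near_max(r, empty, 2), "E")
})

test_that("fieldwise MDR2 table has one row per case-field-structure", {
  g <- tiny_grid(7)
  case <- random_sparse_case(g, n_spots = 24, n_fields = 3, seed = 9)
  cfg <- dose_rate_config()
  fids <- unique(case$log$field_id)
  fmaps <- list(C1 = setNames(lapply(fids, function(f)
    compute_mdr(case$spot_doses, case$log, g, cfg, f)), fids))
  masks <- list(A = full_mask(g, "A"), B = full_mask(g, "B"),
                C = full_mask(g, "C"))
  tb <- fieldwise_mdr2_table(fmaps, masks)
  expect_equal(nrow(tb), 3 * 3)
  expect_false(anyDuplicated(tb[, c("case_id", "field_id", "structure")]) > 0)
  expect_error(fieldwise_mdr2_table(list(C1 = list(Fx = NULL)), masks),
               "missing MDR map")
})

test_that("dose above dose-rate threshold matches the filter-and-sum oracle", {
  g <- tiny_grid(7)
  case <- random_sparse_case(g, n_spots = 18, seed = 5)
  msk <- full_mask(g)
  dur <- as.list(setNames(case$log$duration_us,
                          paste(case$log$field_id, case$log$spot_id,
                                sep = "/")))
  all_d <- dose_above_dose_rate(case$spot_doses, case$log, msk, 0)
  expect_equal(unname(all_d["pct"]), 100)
  none <- dose_above_dose_rate(case$spot_doses, case$log, msk, 1e9)
  expect_equal(unname(none["dose_gyrbe"]), 0)
  expect_equal(unname(none["pct"]), 0)
  thr <- c(0, 1, 2, 5, 10, 20)
  vals <- sapply(thr, function(t) {
    got <- dose_above_dose_rate(case$spot_doses, case$log, msk, t)
    want <- oracle_dadr(case$spot_doses, dur, rep(TRUE, prod(g$dims)), t, 1.1)
    expect_equal(got, want, tolerance = 1e-12)
    got["dose_gyrbe"]
  })
  expect_true(all(diff(vals) <= 1e-12))
  empty <- structure_mask("E", g, array(FALSE, dim = g$dims))
  expect_error(dose_above_dose_rate(case$spot_doses, case$log, empty, 1),
               "empty")
})
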