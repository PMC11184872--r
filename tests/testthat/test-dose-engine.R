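bm <- beam_model()

test_that("beam model curves satisfy their physical constraints", {
  e <- seq(70, 230, by = 5)
  expect_true(all(diff(range_from_energy(e, bm)) > 0))
  expect_equal(energy_from_range(range_from_energy(100, bm), bm), 100,
               tolerance = 1e-10)
  z <- seq(0, 100, by = 0.1)
  dd <- depth_dose(z, 70, bm)
  expect_true(all(dd >= 0))
  # unique global maximum sitting at the Bragg peak, monotone falloff beyond
  imax <- which.max(dd)
  expect_equal(sum(dd == dd[imax]), 1)
  expect_true(abs(z[imax] - 70) < 2 * pbsmdr:::peak_width_mm(70, bm))
  expect_true(all(diff(dd[imax:length(dd)]) <= 1e-12))
  expect_equal(max(dd) / dd[1], bm$peak_entrance_ratio, tolerance = 0.06)
  sig <- lateral_sigma(z, bm)
  expect_true(all(sig > 0) && all(diff(sig) >= 0))
  lets <- let_curve(seq(0, 300, by = 1), bm)
  expect_true(all(diff(lets) <= 0))
  expect_true(all(lets >= 0.2 & lets <= 20))
})

test_that("beam model round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  bm2 <- beam_model(sigma0_mm = 4.5, e_max = 200)
  write_beam_model_yaml(bm2, path)
  expect_equal(read_beam_model_yaml(path), bm2)
})

test_that("spot dose is linear in mu with LET untouched", {
  g <- voxel_grid(c(20, 20, 30), c(2, 2, 2))
  sp <- list(field_id = "F1", spot_id = 1L, energy_mev = 80,
             x_mm = 0, y_mm = 0, mu = 3)
  a <- compute_spot_dose(sp, g, bm, "z+", cutoff = 0)
  sp$mu <- 6
  b <- compute_spot_dose(sp, g, bm, "z+", cutoff = 0)
  expect_identical(a$idx, b$idx)
  expect_equal(b$dose, 2 * a$dose, tolerance = 1e-12)
  expect_identical(a$let, b$let)
})

test_that("lateral profile is symmetric about the spot axis", {
  g <- voxel_grid(c(21, 21, 30), c(2, 2, 2))  # odd: spot centered on voxel
  sp <- list(field_id = "F1", spot_id = 1L, energy_mev = 85,
             x_mm = 0, y_mm = 0, mu = 5)
  sd <- compute_spot_dose(sp, g, bm, "z+", cutoff = 0)
  dense <- array(0, dim = g$dims); dense[sd$idx] <- sd$dose
  mid <- 11L
  expect_equal(dense[mid + 3, mid, ], dense[mid - 3, mid, ], tolerance = 1e-12)
  expect_equal(dense[mid, mid + 5, ], dense[mid, mid - 5, ], tolerance = 1e-12)
  expect_equal(dense[mid + 2, mid - 4, ], dense[mid - 2, mid + 4, ],
               tolerance = 1e-12)
})

test_that("integrated spot dose matches the quadrature of the model", {
  # fine 1 mm grid, wide enough laterally to capture the Gaussian tails
  g <- voxel_grid(c(60, 60, 60), c(1, 1, 1))
  sp <- list(field_id = "F1", spot_id = 1L, energy_mev = 70,
             x_mm = 0, y_mm = 0, mu = 4)
  sd <- compute_spot_dose(sp, g, bm, "z+", cutoff = 0)
  got <- sum(sd$dose) * voxel_volume(g)
  r0 <- range_from_energy(70, bm)
  want <- sp$mu * bm$mu_calibration *
    stats::integrate(function(z) depth_dose(z, r0, bm), 0, 60,
                     rel.tol = 1e-9)$value
  expect_equal(got, want, tolerance = 0.01)
})

test_that("energy span and cutoff handling are enforced", {
  g <- tiny_grid()
  sp <- list(field_id = "F1", spot_id = 1L, energy_mev = 60,
             x_mm = 0, y_mm = 0, mu = 1)
  expect_error(compute_spot_dose(sp, g, bm, "z+"), "commissioned span")
  sp$energy_mev <- 230.1
  expect_error(compute_spot_dose(sp, g, bm, "z+"), "commissioned span")
  # a beam aimed far off the grid deposits nothing and warns
  sp2 <- list(field_id = "F1", spot_id = 2L, energy_mev = 100,
              x_mm = 500, y_mm = 500, mu = 1)
  expect_warning(res <- compute_spot_dose(sp2, g, bm, "z+"), "no dose")
  expect_length(res$idx, 0)
})

test_that("dense accumulation equals brute-force summation", {
  g <- tiny_grid(8)
  set.seed(7)
  sds <- random_sparse_case(g, n_spots = 50, seed = 7)$spot_doses
  got <- accumulate_dose(sds, g)
  want <- numeric(prod(g$dims))
  for (s in sds) for (j in seq_along(s$idx))
    want[s$idx[j]] <- want[s$idx[j]] + s$dose[j]
  expect_equal(as.vector(got$values), want, tolerance = 1e-12)
  # two identical spots double the map; empty list is a zero map
  two <- accumulate_dose(c(sds[1], sds[1]), g)
  one <- accumulate_dose(sds[1], g)
  expect_equal(two$values, 2 * one$values, tolerance = 1e-12)
  expect_true(all(accumulate_dose(list(), g)$values == 0))
})

test_that("LET_d accumulation is the dose-weighted mean", {
  g <- tiny_grid()
  s1 <- fake_spot_dose(g, idx = c(1, 2), dose = c(0.01, 0.01), let = c(2, 2),
                       spot_id = 1L)
  s2 <- fake_spot_dose(g, idx = c(2, 3), dose = c(0.01, 0.02), let = c(4, 4),
                       spot_id = 2L)
  lm <- accumulate_letd(list(s1, s2), g)
  expect_equal(lm$values[1], 2)            # single contribution
  expect_equal(lm$values[2], 3)            # equal doses, LETs 2 and 4
  expect_equal(lm$values[3], 4)
  expect_true(is.na(lm$values[4]))         # no dose, LET_d undefined
})

test_that("LET_d matches the per-voxel oracle and stays within bounds", {
  g <- tiny_grid(7)
  case <- random_sparse_case(g, n_spots = 20, seed = 11)
  got <- accumulate_letd(case$spot_doses, g)
  want <- oracle_letd(case$spot_doses, prod(g$dims))
  expect_equal(as.vector(got$values), want, tolerance = 1e-12)
  # bounded by the contributing spots' LET range per voxel
  lo <- rep(Inf, prod(g$dims)); hi <- rep(-Inf, prod(g$dims))
  for (s in case$spot_doses) for (j in seq_along(s$idx)) {
    lo[s$idx[j]] <- min(lo[s$idx[j]], s$let[j])
    hi[s$idx[j]] <- max(hi[s$idx[j]], s$let[j])
  }
  ok <- !is.na(want)
  expect_true(all(want[ok] >= lo[ok] - 1e-12 & want[ok] <= hi[ok] + 1e-12))
})

test_that("maps from different grids refuse to combine", {
  g1 <- tiny_grid(6); g2 <- tiny_grid(7)
  s <- fake_spot_dose(g1, idx = 1, dose = 0.01)
  expect_error(accumulate_dose(list(s), g2), "different grids")
})
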