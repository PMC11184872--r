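# independent oracle for the variable RBE: solve the linear-quadratic
# iso-effect equation numerically instead of using the closed form
lq_rbe_oracle <- function(D, letd, params = mcnamara_params()) {
  ab <- params$alpha_beta
  rmax <- params$rbe_max_intercept + params$rbe_max_slope * letd / ab
  rmin <- params$rbe_min_intercept +
    params$rbe_min_slope * sqrt(ab) * letd
  # photon effect alpha_x Dx + beta_x Dx^2 with beta_x = 1, alpha_x = ab
  effect_p <- ab * rmax * D + rmin^2 * D^2
  dx <- stats::uniroot(function(x) ab * x + x^2 - effect_p,
                       c(1e-9, 1e6), tol = 1e-12)$root
  dx / D
}

test_that("closed-form RBE matches the iso-effect oracle", {
  p <- mcnamara_params()
  for (D in c(0.5, 1.8, 2, 5)) for (l in c(0, 1, 3, 8, 15)) {
    expect_equal(mcnamara_rbe(D, l, p), lq_rbe_oracle(D, l, p),
                 tolerance = 1e-7,
                 label = sprintf("D=%g LET=%g", D, l))
  }
})

test_that("RBE limits: RBE_min at high dose, RBE_max at low dose", {
  p <- mcnamara_params()
  expect_equal(mcnamara_rbe(1e7, 0, p), p$rbe_min_intercept,
               tolerance = 1e-5)
  expect_equal(mcnamara_rbe(1e7, 10, p),
               p$rbe_min_intercept + p$rbe_min_slope * sqrt(2) * 10,
               tolerance = 1e-4)
  expect_equal(mcnamara_rbe(1e-7, 4, p),
               p$rbe_max_intercept + p$rbe_max_slope * 4 / 2,
               tolerance = 1e-5)
  # decreasing in dose between the asymptotes (RBE_max > RBE_min there)
  d <- c(0.1, 0.5, 1, 2, 5, 20)
  expect_true(all(diff(mcnamara_rbe(d, 8, p)) < 0))
  expect_error(mcnamara_rbe(0, 2, p), "> 0")
})

test_that("RBE is monotone increasing in LET at fixed dose", {
  p <- mcnamara_params()
  lets <- seq(0, 15, by = 0.25)
  for (D in c(0.9, 1.8, 3.6))
    expect_true(all(diff(mcnamara_rbe(D, lets, p)) > 0))
})

test_that("degenerate coefficients reduce variable RBE to the constant 1.1", {
  g <- tiny_grid()
  degen <- mcnamara_params(rbe_max_intercept = 1.1, rbe_max_slope = 0,
                           rbe_min_intercept = 1.1, rbe_min_slope = 0)
  set.seed(8)
  d <- array(runif(prod(g$dims), 0.5, 2.2), dim = g$dims)
  l <- array(runif(prod(g$dims), 0.5, 9), dim = g$dims)
  dose <- scalar_map(g, d, "Gy", "dose")
  letd <- scalar_map(g, l, "keV/um", "letd")
  vr <- variable_rbe_dose(dose, letd, n_fractions = 28, params = degen)
  expect_equal(vr$values, 1.1 * d * 28, tolerance = 1e-12)
  msk <- full_mask(g)
  expect_equal(variable_rbe_d2(dose, letd, msk, 28, params = degen),
               1.1 * near_max(scalar_map(g, d * 28), msk, 2),
               tolerance = 1e-12)
})

test_that("variable RBE exceeds 1.1 beyond the numeric LET crossing", {
  p <- mcnamara_params()
  D <- 1.8 / 1.1  # physical fraction dose
  # LET* where the model crosses the clinical constant at this dose
  lstar <- stats::uniroot(function(l) mcnamara_rbe(D, l, p) - 1.1,
                          c(0, 20))$root
  g <- tiny_grid()
  msk <- full_mask(g)
  d <- scalar_map(g, array(D, dim = g$dims))
  for (l in c(lstar * 1.1, lstar + 2, 12)) {
    lm <- scalar_map(g, array(l, dim = g$dims))
    expect_gt(variable_rbe_d2(d, lm, msk, 28, p),
              1.1 * D * 28)
  }
  lm_lo <- scalar_map(g, array(lstar * 0.5, dim = g$dims))
  expect_lt(variable_rbe_d2(d, lm_lo, msk, 28, p), 1.1 * D * 28)
})

test_that("variable-RBE dose map equals the dense per-voxel evaluation", {
  g <- tiny_grid(5)
  case <- random_sparse_case(g, n_spots = 14, seed = 6)
  dose <- accumulate_dose(case$spot_doses, g)
  letd <- accumulate_letd(case$spot_doses, g)
  p <- mcnamara_params()
  vr <- variable_rbe_dose(dose, letd, 28, p)
  for (v in seq_len(prod(g$dims))) {
    if (dose$values[v] > 0) {
      expect_equal(vr$values[v],
                   lq_rbe_oracle(dose$values[v], letd$values[v], p) *
                     dose$values[v] * 28,
                   tolerance = 1e-6)
    } else expect_equal(vr$values[v], 0)
  }
  # total-dose basis uses D_total in the RBE argument
  vr_tot <- variable_rbe_dose(dose, letd, 28, p, basis = "total")
  pos <- which(dose$values > 0)[1]
  expect_equal(vr_tot$values[pos],
               mcnamara_rbe(dose$values[pos] * 28, letd$values[pos], p) *
                 dose$values[pos] * 28,
               tolerance = 1e-12)
})

test_that("structure metrics are invariant to spot enumeration order", {
  g <- tiny_grid(5)
  case <- random_sparse_case(g, n_spots = 12, seed = 13)
  msk <- full_mask(g)
  perm <- rev(seq_along(case$spot_doses))
  d1 <- accumulate_dose(case$spot_doses, g)
  d2m <- accumulate_dose(case$spot_doses[perm], g)
  expect_equal(d1$values, d2m$values, tolerance = 1e-12)
  l1 <- accumulate_letd(case$spot_doses, g)
  l2 <- accumulate_letd(case$spot_doses[perm], g)
  expect_equal(near_max(l1, msk, 2), near_max(l2, msk, 2), tolerance = 1e-12)
})

test_that("uniform exposures give the trivial metric values", {
  g <- tiny_grid()
  msk <- full_mask(g)
  d <- scalar_map(g, array(50.4, dim = g$dims), "Gy_RBE", "dose_rbe")
  expect_equal(d2(d, msk), 50.4)
  expect_lte(d2(d, msk), max(d$values))
  s <- fake_spot_dose(g, idx = 1:10, dose = rep(0.01, 10),
                      let = rep(3.7, 10))
  lm <- accumulate_letd(list(s), g)
  eligible <- structure_mask("S", g, array(seq_len(prod(g$dims)) <= 10,
                                           dim = g$dims))
  expect_equal(let2(lm, eligible), 3.7)
  zero_mask <- structure_mask("Z", g,
                              array(seq_len(prod(g$dims)) > 100,
                                    dim = g$dims))
  expect_error(let2(lm, zero_mask), "Z")
})
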