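#' McNamara variable-RBE model parameters
#'
#' Phenomenological proton RBE model in which the maximum and minimum RBE
#' (the low-dose and high-dose asymptotes of the linear-quadratic framework)
#' are linear in dose-averaged LET:
#' \deqn{RBE_{max} = c_0 + c_1 \, LET_d / (\alpha/\beta)}
#' \deqn{RBE_{min} = d_0 + d_1 \, \sqrt{\alpha/\beta} \, LET_d}
#' The coefficients are configuration, not constants: the defaults are the
#' published fit values of the model, and tests pin behavior to the closed
#' form rather than to specific coefficients. The default `alpha_beta` of
#' 2 Gy is the conventional choice for optic apparatus structures.
#'
#' @param alpha_beta linear-quadratic alpha/beta ratio in Gy (> 0).
#' @param rbe_max_intercept,rbe_max_slope intercept and LET slope of RBE_max
#'   (slope per (keV/um)/Gy, i.e. applied to `LET/alpha_beta`).
#' @param rbe_min_intercept,rbe_min_slope intercept and LET slope of RBE_min
#'   (slope per (keV/um) Gy^-1/2, applied to `sqrt(alpha_beta) * LET`).
#' @param let_span LET span (keV/um) over which RBE_max >= RBE_min is
#'   enforced at construction.
#' @return An object of class `mcnamara_params`.
#' @export
mcnamara_params <- function(alpha_beta = 2,
                            rbe_max_intercept = 0.99064,
                            rbe_max_slope = 0.35605,
                            rbe_min_intercept = 1.1012,
                            rbe_min_slope = -0.0038703,
                            let_span = c(0.2, 20)) {
  stop_if_not_scalar_pos(alpha_beta, "alpha_beta")
  pr <- structure(list(alpha_beta = alpha_beta,
                       rbe_max_intercept = rbe_max_intercept,
                       rbe_max_slope = rbe_max_slope,
                       rbe_min_intercept = rbe_min_intercept,
                       rbe_min_slope = rbe_min_slope),
                  class = "mcnamara_params")
  # the published fit itself has RBE_min > RBE_max at very low LET, so the
  # sanity check applies to the high-LET end (where the dose enhancement
  # the model encodes must not invert) and to the slopes
  top <- let_span[2]
  if (rbe_max_line(top, pr) < rbe_min_line(top, pr))
    stop("RBE_max < RBE_min at the upper end of the supported LET span")
  pr
}

rbe_max_line <- function(letd, params)
  params$rbe_max_intercept + params$rbe_max_slope * letd / params$alpha_beta

rbe_min_line <- function(letd, params)
  params$rbe_min_intercept +
    params$rbe_min_slope * sqrt(params$alpha_beta) * letd

#' McNamara variable RBE
#'
#' Closed-form RBE of the linear-quadratic phenomenological model:
#' \deqn{RBE(D, LET_d) = \frac{1}{2D}\left(\sqrt{(\alpha/\beta)^2 +
#'   4D(\alpha/\beta)RBE_{max} + 4D^2 RBE_{min}^2} - \alpha/\beta\right)}
#' with `D` the physical dose per fraction. As `D` grows the RBE tends to
#' `RBE_min(LET_d)`; as `D` shrinks it tends to `RBE_max(LET_d)`.
#'
#' @param dose_per_fraction physical dose per fraction in Gy (vector, all
#'   > 0).
#' @param letd dose-averaged LET in keV/um (vector, recycled).
#' @param params a [mcnamara_params()].
#' @return RBE values (unitless).
#' @export
mcnamara_rbe <- function(dose_per_fraction, letd, params = mcnamara_params()) {
  if (any(dose_per_fraction <= 0, na.rm = TRUE))
    stop("dose per fraction must be > 0 wherever RBE is evaluated")
  ab <- params$alpha_beta
  rmax <- rbe_max_line(letd, params)
  rmin <- rbe_min_line(letd, params)
  D <- dose_per_fraction
  disc <- ab^2 + 4 * D * ab * rmax + 4 * D^2 * rmin^2
  stopifnot(all(disc >= 0, na.rm = TRUE))  # guaranteed by construction
  (sqrt(disc) - ab) / (2 * D)
}

#' Variable-RBE weighted dose map
#'
#' Applies the McNamara RBE voxelwise: the RBE is evaluated from the
#' per-fraction physical dose and LET_d (`basis = "fraction"`, the default,
#' matching fractionated delivery), or from the total physical dose
#' (`basis = "total"`), and multiplies the total physical dose. Voxels with
#' zero dose get zero RBE-weighted dose.
#'
#' @param dose_map per-fraction physical dose [scalar_map()] (Gy).
#' @param letd_map LET_d [scalar_map()] (keV/um, `NA` where no dose).
#' @param n_fractions number of fractions delivered.
#' @param params a [mcnamara_params()].
#' @param basis `"fraction"` or `"total"` dose in the RBE formula.
#' @return [scalar_map()] of RBE-weighted total dose (Gy_RBE by the variable
#'   model).
#' @export
variable_rbe_dose <- function(dose_map, letd_map, n_fractions,
                              params = mcnamara_params(),
                              basis = c("fraction", "total")) {
  basis <- match.arg(basis)
  if (!same_grid(dose_map$grid, letd_map$grid))
    stop("dose and LET maps are on different grids")
  stop_if_not_scalar_pos(n_fractions, "n_fractions")
  d <- dose_map$values
  l <- letd_map$values
  out <- array(0, dim = dose_map$grid$dims)
  pos <- which(d > 0 & !is.na(l))
  if (length(pos)) {
    D <- if (basis == "fraction") d[pos] else d[pos] * n_fractions
    out[pos] <- mcnamara_rbe(D, l[pos], params) * d[pos] * n_fractions
  }
  scalar_map(dose_map$grid, out, units = "Gy_RBE", kind = "dose_var_rbe")
}

#' Structure-level near-maximum metrics: D2, LET2, variable-RBE D2
#'
#' Thin wrappers over [near_max()] at the 2%-volume level: `d2` on an
#' (RBE-weighted) dose map, `let2` on a LET_d map (only voxels receiving
#' dose, hence with defined LET_d, are eligible), and `variable_rbe_d2`
#' composing [variable_rbe_dose()] with the near-maximum.
#'
#' @param dose_map,letd_map [scalar_map()]s on the mask's grid.
#' @param mask a [structure_mask()].
#' @param level percent volume level (default 2).
#' @return metric value in the map's units.
#' @export
d2 <- function(dose_map, mask, level = 2) near_max(dose_map, mask, level)

#' @rdname d2
#' @export
let2 <- function(letd_map, mask, level = 2) near_max(letd_map, mask, level)

#' @rdname d2
#' @inheritParams variable_rbe_dose
#' @export
variable_rbe_d2 <- function(dose_map, letd_map, mask, n_fractions,
                            params = mcnamara_params(),
                            basis = c("fraction", "total"), level = 2) {
  near_max(variable_rbe_dose(dose_map, letd_map, n_fractions, params,
                             match.arg(basis)),
           mask, level)
}
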