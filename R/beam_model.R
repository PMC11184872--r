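#' Analytic pencil-beam model
#'
#' Parameterization of the per-spot dose and LET engine. The engine is a
#' deliberately simple analytic stand-in for a Monte Carlo dose calculation:
#' it produces, for every spot, a dose-to-water distribution that is a depth
#' dose (pristine Bragg curve approximation) times a lateral 2-D Gaussian,
#' and a per-voxel LET value driven by the residual range at that depth. The
#' downstream metric layer consumes only the per-spot sparse dose/LET
#' contract, so a Monte Carlo backend could be plugged in without touching
#' any metric. The model is not commissioned against measured data and must
#' not be used clinically.
#'
#' Components:
#' * Range-energy: Bragg-Kleeman \eqn{R = a E^p} with `a` in cm/MeV^p.
#' * Depth dose: plateau with a sigmoid distal falloff plus a Gaussian Bragg
#'   peak of width `peak_width(R0)`, scaled so the peak-to-entrance ratio is
#'   approximately `peak_entrance_ratio`.
#' * Lateral spread: \eqn{\sigma(z) = \sqrt{\sigma_0^2 + (c z)^2}} (in-air
#'   spot size plus depth broadening), non-decreasing with depth.
#' * LET: a monotone non-increasing function of residual range, clamped to
#'   0.2-20 keV/um.
#' * `mu_calibration`: Gy mm^2 per MU, converting MU-weighted fluence to dose.
#'
#' @param a,p Bragg-Kleeman coefficients (defaults 0.0022 cm/MeV^p, 1.77).
#' @param e_min,e_max commissioned energy span in MeV (default 70-230).
#' @param peak_entrance_ratio approximate ratio of Bragg-peak dose to entrance
#'   dose (default 3.5).
#' @param sigma0_mm in-air lateral sigma at the surface (mm).
#' @param sigma_growth dimensionless depth-broadening coefficient.
#' @param mu_calibration Gy mm^2 per MU.
#' @param let_distal,let_scale_mm,let_shape,let_entrance parameters of the
#'   LET-vs-residual-range curve (keV/um at the distal end, mm scale,
#'   shape exponent, asymptotic entrance LET).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(a = 0.0022, p = 1.77, e_min = 70, e_max = 230,
                       peak_entrance_ratio = 3.5,
                       sigma0_mm = 6, sigma_growth = 0.04,
                       mu_calibration = 0.03,
                       let_distal = 11, let_scale_mm = 4,
                       let_shape = 0.9, let_entrance = 0.3) {
  stop_if_not_scalar_pos(a, "a"); stop_if_not_scalar_pos(p, "p")
  stop_if_not_scalar_pos(sigma0_mm, "sigma0_mm")
  stop_if_not_scalar_pos(mu_calibration, "mu_calibration")
  if (peak_entrance_ratio <= 1) stop("`peak_entrance_ratio` must exceed 1")
  if (e_min <= 0 || e_max <= e_min) stop("invalid energy span")
  structure(list(a = a, p = p, e_min = e_min, e_max = e_max,
                 peak_entrance_ratio = peak_entrance_ratio,
                 sigma0_mm = sigma0_mm, sigma_growth = sigma_growth,
                 mu_calibration = mu_calibration,
                 let_distal = let_distal, let_scale_mm = let_scale_mm,
                 let_shape = let_shape, let_entrance = let_entrance),
            class = "beam_model")
}

#' Range in water from beam energy (and back)
#'
#' @param energy_mev beam energy in MeV.
#' @param bm a [beam_model()].
#' @return `range_from_energy`: range in mm; `energy_from_range`: MeV.
#' @export
range_from_energy <- function(energy_mev, bm = beam_model()) {
  10 * bm$a * energy_mev^bm$p  # a is in cm
}

#' @rdname range_from_energy
#' @param range_mm range in water, mm.
#' @export
energy_from_range <- function(range_mm, bm = beam_model()) {
  (range_mm / 10 / bm$a)^(1 / bm$p)
}

# Bragg peak Gaussian width (mm), growing with range (straggling-like)
peak_width_mm <- function(r0_mm, bm) 0.025 * r0_mm + 1

#' Depth-dose curve of the analytic engine
#'
#' Dimensionless depth dose (entrance value approximately 1) at depths
#' `z_mm` for a beam of range `r0_mm`. Non-negative with a single global
#' maximum at the Bragg peak.
#'
#' @param z_mm depths in mm (vector).
#' @param r0_mm beam range in mm.
#' @param bm a [beam_model()].
#' @export
depth_dose <- function(z_mm, r0_mm, bm = beam_model()) {
  w <- peak_width_mm(r0_mm, bm)
  tau <- w / 1.5
  plateau <- 1 / (1 + exp((z_mm - r0_mm) / tau))
  amp <- bm$peak_entrance_ratio - 0.5  # sigmoid contributes 0.5 at the peak
  peak <- amp * exp(-(z_mm - r0_mm)^2 / (2 * w^2))
  out <- plateau + peak
  out[z_mm < 0] <- 0
  out
}

#' Lateral sigma at depth
#' @inheritParams depth_dose
#' @export
lateral_sigma <- function(z_mm, bm = beam_model()) {
  sqrt(bm$sigma0_mm^2 + (bm$sigma_growth * pmax(z_mm, 0))^2)
}

#' LET as a function of residual range
#'
#' Monotone non-increasing in residual range, clamped to 0.2-20 keV/um.
#' Negative residual ranges (beyond the distal edge) take the distal value.
#'
#' @param resid_mm residual range in mm (vector; `r0_mm - depth`).
#' @param bm a [beam_model()].
#' @return LET in keV/um.
#' @export
let_curve <- function(resid_mm, bm = beam_model()) {
  r <- pmax(resid_mm, 0)
  val <- bm$let_entrance + bm$let_distal / (1 + (r / bm$let_scale_mm)^bm$let_shape)
  pmin(pmax(val, 0.2), 20)
}

#' Read / write a beam model as YAML
#'
#' The beam model is plain configuration; storing it as YAML lets a
#' commissioning-style file accompany a run.
#'
#' @param path YAML file path.
#' @return `read_beam_model_yaml`: a [beam_model()].
#' @export
read_beam_model_yaml <- function(path) {
  do.call(beam_model, yaml::read_yaml(path))
}

#' @rdname read_beam_model_yaml
#' @param bm a [beam_model()].
#' @export
write_beam_model_yaml <- function(bm, path) {
  yaml::write_yaml(unclass(bm), path)
  invisible(path)
}
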